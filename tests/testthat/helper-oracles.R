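# Shared fixtures and independent oracles, built in code.

# two-node chain A -> B with P(A = y) and P(B = y | A)
chain_bn <- function(p_a = 0.5, p_b_given_ay = 0.8, p_b_given_an = 0.2) {
  cpt_a <- cpt("A", c("y", "n"), c(p_a, 1 - p_a))
  cpt_b <- cpt("B", c("y", "n"),
               c(p_b_given_ay, 1 - p_b_given_ay,
                 p_b_given_an, 1 - p_b_given_an),
               parents = "A", parent_states = list(A = c("y", "n")))
  bayes_net(dag(c("A", "B"), rbind(c("A", "B"))), list(A = cpt_a, B = cpt_b))
}

# random DAG over n nodes: arcs only forward along a shuffled order
random_dag <- function(seed, n_nodes, arc_prob = 0.35) {
  with_seed <- cvdbn:::with_seed
  with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n_nodes))
    ord <- sample(nodes)
    arcs <- NULL
    for (i in seq_len(n_nodes - 1))
      for (j in seq((i + 1), n_nodes))
        if (stats::runif(1) < arc_prob) arcs <- rbind(arcs, c(ord[i], ord[j]))
    dag(nodes, arcs)
  })
}

# random strictly-positive CPTs on a random DAG
random_bn <- function(seed, n_nodes = 6, max_arity = 3, arc_prob = 0.35) {
  dg <- random_dag(seed, n_nodes, arc_prob)
  cvdbn:::with_seed(seed + 1000L, {
    arity <- sample(2:max_arity, n_nodes, replace = TRUE)
    names(arity) <- dg$nodes
    cpts <- lapply(dg$nodes, function(v) {
      pa <- cvdbn:::dag_parents(dg, v)
      states <- paste0("s", seq_len(arity[v]))
      pa_states <- lapply(stats::setNames(pa, pa),
                          function(p) paste0("s", seq_len(arity[p])))
      nc <- prod(vapply(pa_states, length, integer(1)))
      pm <- vapply(seq_len(nc), function(i) {
        x <- stats::rgamma(arity[v], shape = 1) + 0.05
        x / sum(x)
      }, numeric(arity[v]))
      cpt(v, states, as.vector(pm), parents = pa, parent_states = pa_states)
    })
    names(cpts) <- dg$nodes
    bayes_net(dg, cpts)
  })
}

# independent Bayes-ball reachability oracle for d-separation:
# the ball starts at x going "up" (as if from a child); at an
# unobserved node it passes up->up/down and down->down; at an observed
# node a ball arriving from a parent bounces back up (collider case).
bayes_ball_dsep <- function(dg, x, y, z) {
  parents_of <- function(v) cvdbn:::dag_parents(dg, v)
  children_of <- function(v) cvdbn:::dag_children(dg, v)
  queue <- lapply(x, function(v) list(v = v, dir = "up"))
  seen <- character(0)
  while (length(queue)) {
    it <- queue[[1]]; queue <- queue[-1]
    key <- paste(it$v, it$dir)
    if (key %in% seen) next
    seen <- c(seen, key)
    observed <- it$v %in% z
    if (!observed && it$v %in% y) return(FALSE)
    if (it$dir == "up" && !observed) {
      for (p in parents_of(it$v))
        queue <- c(queue, list(list(v = p, dir = "up")))
      for (ch in children_of(it$v))
        queue <- c(queue, list(list(v = ch, dir = "down")))
    } else if (it$dir == "down") {
      if (!observed)
        for (ch in children_of(it$v))
          queue <- c(queue, list(list(v = ch, dir = "down")))
      if (observed)
        for (p in parents_of(it$v))
          queue <- c(queue, list(list(v = p, dir = "up")))
    }
  }
  TRUE
}

# direct factor-product joint oracle
joint_oracle <- function(bn, assignment) {
  p <- 1
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    k <- match(assignment[[v]], ct$states)
    idx <- k
    if (length(ct$parents)) {
      stride <- length(ct$states)
      for (pv in ct$parents) {
        idx <- idx + (match(assignment[[pv]], ct$parent_states[[pv]]) - 1) * stride
        stride <- stride * length(ct$parent_states[[pv]])
      }
    }
    p <- p * as.vector(ct$prob)[idx]
  }
  p
}

# full-enumeration posterior oracle (independent of the package path)
enum_oracle <- function(bn, query, evidence = NULL) {
  nodes <- bn$dag$nodes
  grids <- lapply(nodes, function(v) bn$cpts[[v]]$states)
  names(grids) <- nodes
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  probs <- vapply(which(keep), function(i)
    joint_oracle(bn, as.list(grid[i, , drop = FALSE])), numeric(1))
  z <- sum(probs)
  states <- bn$cpts[[query]]$states
  out <- vapply(states, function(s)
    sum(probs[grid[[query]][keep] == s]) / z, numeric(1))
  out
}

# all-pairs concordance AUC oracle
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# direct-formula metric oracle
metric_oracle <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  n <- tp + fp + tn + fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(tpr = tp / (tp + fn), tnr = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       accuracy = (tp + tn) / n,
       balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

# deterministic toy model: cardiotoxicity forces the CVD outcome
toy_forced_cvd_bn <- function() {
  yn <- c("Yes", "No")
  ctx <- cpt("cardiotoxicity", yn, c(0.3, 0.7))
  cvd <- cpt("cvds", yn, c(1, 0, 0.01, 0.99),
             parents = "cardiotoxicity",
             parent_states = list(cardiotoxicity = yn))
  bayes_net(dag(c("cardiotoxicity", "cvds"),
                rbind(c("cardiotoxicity", "cvds"))),
            list(cardiotoxicity = ctx, cvds = cvd))
}
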
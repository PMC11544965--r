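# ---- factor algebra ---------------------------------------------------
# A factor is list(vars, card, val): `val` is laid out with the first
# variable in `vars` varying fastest (R array order).

cpt_factor <- function(ct) {
  card <- c(length(ct$states),
            vapply(ct$parent_states, length, integer(1), USE.NAMES = FALSE))
  list(vars = c(ct$child, ct$parents), card = card, val = as.vector(ct$prob))
}

# expand a factor's values over a superset variable layout
f_extend <- function(f, vars, card) {
  n <- prod(card)
  pos <- seq_len(n) - 1L
  fidx <- rep(0, n)
  fstride <- 1
  for (i in seq_along(f$vars)) {
    j <- match(f$vars[i], vars)
    stride_j <- if (j == 1) 1 else prod(card[seq_len(j - 1)])
    state <- (pos %/% stride_j) %% card[j]
    fidx <- fidx + state * fstride
    fstride <- fstride * f$card[i]
  }
  f$val[fidx + 1]
}

f_product <- function(factors) {
  if (length(factors) == 1) return(factors[[1]])
  vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  card <- integer(length(vars))
  for (f in factors) card[match(f$vars, vars)] <- f$card
  val <- 1
  for (f in factors) val <- val * f_extend(f, vars, card)
  list(vars = vars, card = card, val = val)
}

f_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  if (length(f$vars) == 1)
    return(list(vars = character(0), card = integer(0), val = sum(f$val)))
  a <- array(f$val, dim = f$card)
  keep <- seq_along(f$vars)[-i]
  val <- apply(a, keep, sum)
  list(vars = f$vars[keep], card = f$card[keep], val = as.vector(val))
}

f_reduce <- function(f, var, state_idx) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  a <- array(f$val, dim = f$card)
  idx <- rep(list(quote(expr = )), length(f$card))
  idx[[i]] <- state_idx
  a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  keep <- seq_along(f$vars)[-i]
  if (!length(keep))
    return(list(vars = character(0), card = integer(0), val = as.vector(a)))
  list(vars = f$vars[keep], card = f$card[keep], val = as.vector(a))
}

# min-fill elimination order over the factor interaction graph;
# ties broken lexicographically by node name.
min_fill_order <- function(scopes, hidden) {
  adj <- new.env(parent = emptyenv())
  allv <- unique(unlist(scopes))
  for (v in allv) assign(v, character(0), envir = adj)
  link <- function(a, b) {
    assign(a, union(get(a, envir = adj), b), envir = adj)
    assign(b, union(get(b, envir = adj), a), envir = adj)
  }
  for (sc in scopes)
    if (length(sc) > 1)
      for (p in utils::combn(sc, 2, simplify = FALSE)) link(p[1], p[2])
  order_out <- character(0)
  remaining <- sort(hidden)
  while (length(remaining)) {
    fills <- vapply(remaining, function(v) {
      nb <- setdiff(get(v, envir = adj), order_out)
      if (length(nb) < 2) return(0L)
      cnt <- 0L
      for (p in utils::combn(nb, 2, simplify = FALSE))
        if (!p[2] %in% get(p[1], envir = adj)) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fills)]  # remaining is sorted: lexicographic tie-break
    nb <- setdiff(get(v, envir = adj), c(order_out, v))
    if (length(nb) > 1)
      for (p in utils::combn(nb, 2, simplify = FALSE)) link(p[1], p[2])
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}

# exact joint over `query` given evidence, by variable elimination.
# Returns list(factor over query in query order, z = P(evidence)).
ve_joint <- function(bn, query, evidence = NULL) {
  evidence <- check_evidence(bn, evidence)
  factors <- lapply(bn$cpts[bn$dag$nodes], cpt_factor)
  for (v in names(evidence)) {
    k <- match(evidence[[v]], bn_states(bn, v))
    factors <- lapply(factors, f_reduce, var = v, state_idx = k)
  }
  hidden <- setdiff(bn$dag$nodes, c(query, names(evidence)))
  elim <- min_fill_order(lapply(factors, `[[`, "vars"), hidden)
  for (h in elim) {
    touch <- vapply(factors, function(f) h %in% f$vars, logical(1))
    if (!any(touch)) next
    prod_f <- f_product(factors[touch])
    factors <- c(factors[!touch], list(f_marginalize(prod_f, h)))
  }
  final <- f_product(factors)
  z <- sum(final$val)
  if (!is.finite(z) || z <= 0)
    stop_inconsistent("evidence has probability zero under the model")
  final$val <- final$val / z
  # arrange over query vars in requested order
  qv <- intersect(query, final$vars)
  if (length(final$vars)) {
    perm <- match(c(qv, setdiff(final$vars, qv)), final$vars)
    a <- aperm(array(final$val, dim = final$card), perm)
    final <- list(vars = final$vars[perm], card = final$card[perm],
                  val = as.vector(a))
  }
  list(factor = final, z = z)
}

posterior_result <- function(bn, variable, probabilities, method,
                             mc_se = NULL) {
  states <- bn_states(bn, variable)
  if (is.null(mc_se)) mc_se <- rep(0, length(states))
  structure(list(variable = variable, states = states,
                 probabilities = stats::setNames(as.numeric(probabilities), states),
                 mc_standard_errors = stats::setNames(as.numeric(mc_se), states),
                 method = method),
            class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, ...) {
  cat("Posterior P(", x$variable, " | evidence), method = ", x$method,
      "\n", sep = "")
  print(round(x$probabilities, 6))
  invisible(x)
}

#' Exact posterior by brute-force enumeration
#'
#' Computes P(query | evidence) by summing the full joint over every
#' completion of the non-evidence variables. Exponential in network
#' size; guarded by a cap on the log2 state-space size. Intended as the
#' independent oracle for the scalable engines.
#'
#' @param bn a `bn` object.
#' @param query variable name.
#' @param evidence named character vector/list of observed states (may
#'   be empty).
#' @param log2_guard refuse problems whose completion space exceeds
#'   `2 ^ log2_guard` (default 22).
#' @return a `bn_posterior`.
#' @export
enumerate_posterior <- function(bn, query, evidence = NULL, log2_guard = 22) {
  evidence <- check_evidence(bn, evidence)
  stopifnot(query %in% bn$dag$nodes)
  free <- setdiff(bn$dag$nodes, names(evidence))
  bits <- sum(log2(vapply(free, function(v) bn_arity(bn, v), numeric(1))))
  if (bits > log2_guard)
    stop("state space too large for enumeration (2^", round(bits, 1),
         " completions; guard is 2^", log2_guard, ")")
  if (length(free)) {
    grid <- expand.grid(lapply(free, function(v) seq_len(bn_arity(bn, v))),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- free
  } else {
    grid <- data.frame(row.names = 1)  # single empty completion
  }
  n <- nrow(grid)
  p <- rep(1, n)
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    k <- if (v %in% free) grid[[v]] else rep(match(evidence[[v]], ct$states), n)
    if (length(ct$parents)) {
      pidx <- vapply(ct$parents, function(pv) {
        if (pv %in% free) grid[[pv]]
        else rep(match(evidence[[pv]], ct$parent_states[[pv]]), n)
      }, integer(n))
      if (n == 1) pidx <- matrix(pidx, nrow = 1)
      p <- p * cpt_lookup(ct, k, pidx)
    } else {
      p <- p * as.vector(ct$prob)[k]
    }
  }
  z <- sum(p)
  if (z <= 0)
    stop_inconsistent("evidence has probability zero under the model")
  if (query %in% names(evidence)) {
    probs <- as.numeric(bn_states(bn, query) == evidence[[query]])
  } else {
    probs <- vapply(seq_len(bn_arity(bn, query)),
                    function(k) sum(p[grid[[query]] == k]), numeric(1)) / z
  }
  posterior_result(bn, query, probs, "enumeration")
}

#' Exact posterior by variable elimination
#'
#' Scalable exact engine: reduces the CPT factors by the evidence,
#' eliminates the remaining variables in min-fill order (lexicographic
#' tie-break) and renormalizes. Agrees with [enumerate_posterior()] to
#' numerical precision wherever the latter is feasible.
#'
#' @inheritParams enumerate_posterior
#' @return a `bn_posterior`.
#' @export
eliminate_posterior <- function(bn, query, evidence = NULL) {
  evidence <- check_evidence(bn, evidence)
  stopifnot(query %in% bn$dag$nodes)
  if (query %in% names(evidence)) {
    # consistency check, then point mass on the evidenced state
    ve_joint(bn, character(0), evidence)
    probs <- as.numeric(bn_states(bn, query) == evidence[[query]])
    return(posterior_result(bn, query, probs, "variable_elimination"))
  }
  res <- ve_joint(bn, query, evidence)
  posterior_result(bn, query, res$factor$val, "variable_elimination")
}

#' Approximate posterior by likelihood weighting
#'
#' Ancestral sampling with evidence nodes clamped and weighted by their
#' CPT likelihood; posterior probabilities are weighted frequencies with
#' ratio-estimator Monte-Carlo standard errors. Reproducible under
#' `seed`.
#'
#' @inheritParams enumerate_posterior
#' @param n_samples number of weighted samples (>= 1).
#' @param seed integer RNG seed.
#' @return a `bn_posterior` with non-zero `mc_standard_errors`.
#' @export
likelihood_weighting <- function(bn, query, evidence = NULL,
                                 n_samples = 10000L, seed = 1L) {
  evidence <- check_evidence(bn, evidence)
  stopifnot(query %in% bn$dag$nodes, n_samples >= 1)
  ord <- topological_order(bn$dag)
  n <- as.integer(n_samples)
  with_seed(seed, {
    samp <- matrix(0L, nrow = n, ncol = length(ord),
                   dimnames = list(NULL, ord))
    logw <- rep(0, n)
    for (v in ord) {
      ct <- bn$cpts[[v]]
      r <- length(ct$states)
      if (length(ct$parents)) {
        pidx <- samp[, ct$parents, drop = FALSE]
        probs <- vapply(seq_len(r), function(k)
          cpt_lookup(ct, rep(k, n), pidx), numeric(n))
        if (n == 1) probs <- matrix(probs, nrow = 1)
      } else {
        probs <- matrix(as.vector(ct$prob), nrow = n, ncol = r, byrow = TRUE)
      }
      if (v %in% names(evidence)) {
        k <- match(evidence[[v]], ct$states)
        samp[, v] <- k
        logw <- logw + log(probs[, k])
      } else {
        u <- stats::runif(n)
        cum <- probs %*% upper.tri(diag(r), diag = TRUE)
        cum[, r] <- 1  # guard against rounding in the last cumulative sum
        samp[, v] <- r + 1L - as.integer(rowSums(u <= cum))
      }
    }
    w <- exp(logw - max(logw))
    if (!any(w > 0))
      stop_inconsistent("all likelihood weights are zero; evidence is inconsistent")
    sw <- sum(w)
    r <- bn_arity(bn, query)
    probs <- numeric(r)
    ses <- numeric(r)
    for (k in seq_len(r)) {
      ind <- as.numeric(samp[, query] == k)
      probs[k] <- sum(w * ind) / sw
      # ratio-estimator variance of the weighted mean
      ses[k] <- sqrt(sum((w * (ind - probs[k]))^2)) / sw
    }
    posterior_result(bn, query, probs, "likelihood_weighting", mc_se = ses)
  })
}

#' Individual 5-year risk prediction
#'
#' Posterior probability that the target outcome variable takes its
#' positive state given partial patient evidence, plus the binary
#' at-risk call at a probability threshold. By default the cohort
#' context node is left unevidenced (it describes where the data came
#' from, not patient biology); pass it in `evidence` to condition on it.
#'
#' @param bn a `bn` object.
#' @param evidence named character vector/list of observed states;
#'   must not include the target variable.
#' @param threshold classification threshold on the posterior
#'   probability (defaults to the model's marginal prevalence of the
#'   positive state, the standard choice under heavy class imbalance).
#' @param engine `"exact"` (variable elimination) or `"lw"`
#'   (likelihood weighting).
#' @param target target variable name (default `"cvds"`).
#' @param positive positive state label (default `"Yes"`).
#' @param n_samples,seed likelihood-weighting settings (ignored for the
#'   exact engine).
#' @return list with components `probability`, `classified`
#'   (`"at_risk"` / `"not_at_risk"`), `threshold`, `engine`.
#' @export
predict_risk <- function(bn, evidence = NULL, threshold = NULL,
                         engine = c("exact", "lw"), target = "cvds",
                         positive = "Yes", n_samples = 10000L, seed = 1L) {
  engine <- match.arg(engine)
  evidence <- check_evidence(bn, evidence)
  if (target %in% names(evidence))
    stop("the target variable '", target, "' must not appear in the evidence")
  if (is.null(threshold)) {
    prior <- eliminate_posterior(bn, target)
    threshold <- unname(prior$probabilities[positive])
  }
  post <- switch(engine,
    exact = eliminate_posterior(bn, target, evidence),
    lw = likelihood_weighting(bn, target, evidence,
                              n_samples = n_samples, seed = seed))
  p <- unname(post$probabilities[positive])
  list(probability = p,
       classified = if (p >= threshold) "at_risk" else "not_at_risk",
       threshold = threshold,
       engine = engine)
}
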
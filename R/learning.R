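# ---- data encoding ----------------------------------------------------

# data frame of state labels -> integer state-index matrix (NA = missing)
encode_data <- function(data, dict) {
  nodes <- dict_names(dict)
  missing_cols <- setdiff(nodes, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  enc <- matrix(NA_integer_, nrow = nrow(data), ncol = length(nodes),
                dimnames = list(NULL, nodes))
  for (v in nodes) {
    x <- as.character(data[[v]])
    idx <- match(x, dict_states(dict, v))
    bad <- which(!is.na(x) & is.na(idx))
    if (length(bad))
      stop("unknown state '", x[bad[1]], "' for variable '", v,
           "' at row ", bad[1])
    enc[, v] <- idx
  }
  enc
}

bn_as_dict <- function(bn) {
  if (!is.null(bn$dictionary)) return(bn$dictionary)
  vars <- lapply(bn$dag$nodes, function(v)
    list(name = v, states = bn_states(bn, v), group = "risk_factor"))
  vars[[1]]$group <- "selection"
  data_dictionary(vars)
}

# ---- sufficient statistics -------------------------------------------

#' Family co-occurrence counts
#'
#' Counts joint occurrences of a child and its candidate parents: exact
#' counts over the rows where the whole family is observed, optionally
#' weighted (so weighted completions of missing cells can be tallied by
#' passing the completion weights).
#'
#' @param data data frame of state labels (may contain `NA`).
#' @param child,parents variable names.
#' @param dict a `bn_dictionary` (defaults to `attr(data, "dictionary")`).
#' @param weights optional non-negative row weights.
#' @return object of class `family_counts`: list with `child`,
#'   `parents`, `counts` (array, child dimension first) and
#'   `effective_n` (total tallied weight).
#' @export
family_counts <- function(data, child, parents = character(0),
                          dict = attr(data, "dictionary"), weights = NULL) {
  if (is.null(dict)) stop("a data dictionary is required")
  enc <- encode_data(data, dict)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  fam <- c(child, parents)
  stopifnot(all(fam %in% colnames(enc)))
  dims <- vapply(fam, function(v) dict_arity(dict, v), integer(1))
  ok <- if (nrow(enc)) !rowSums(is.na(enc[, fam, drop = FALSE])) else logical(0)
  flat <- numeric(prod(dims))
  if (any(ok)) {
    lin <- rep(1L, sum(ok))
    stride <- 1L
    for (j in seq_along(fam)) {
      lin <- lin + (enc[ok, fam[j]] - 1L) * stride
      stride <- stride * dims[j]
    }
    tal <- rowsum(weights[ok], lin)
    flat[as.integer(rownames(tal))] <- tal[, 1]
  }
  counts <- array(flat, dim = dims,
                  dimnames = lapply(fam, function(v) dict_states(dict, v)))
  structure(list(child = child, parents = parents, counts = counts,
                 effective_n = sum(flat)),
            class = "family_counts")
}

# normalize a counts array (child dimension first) into a CPT
counts_to_cpt <- function(child, states, parents, parent_states, counts,
                          alpha) {
  r <- length(states)
  cm <- matrix(as.vector(counts), nrow = r)  # columns = parent configs
  tot <- colSums(cm)
  pm <- (cm + alpha) / rep(tot + alpha * r, each = r)
  if (alpha == 0) {
    empty <- tot == 0
    if (any(empty)) pm[, empty] <- 1 / r
  }
  cpt(child, states, as.vector(pm), parents = parents,
      parent_states = parent_states)
}

#' Maximum-likelihood (optionally smoothed) parameter fit
#'
#' Fits every CPT of a fixed DAG from complete data:
#' `(count + alpha) / (config_total + alpha * arity)`; configurations
#' never observed get a uniform distribution when `alpha = 0`.
#'
#' @param dag a `bn_dag`.
#' @param data complete data frame (no missing cells).
#' @param dict a `bn_dictionary`.
#' @param alpha pseudo-count (>= 0; `alpha = 1` is Laplace smoothing).
#' @return a `bn`.
#' @export
fit_parameters_mle <- function(dag, data, dict = attr(data, "dictionary"),
                               alpha = 0) {
  if (is.null(dict)) stop("a data dictionary is required")
  stopifnot(alpha >= 0)
  if (anyNA(data[, dict_names(dict)]))
    stop("data contains missing cells; use em_parameters() instead")
  cpts <- lapply(stats::setNames(dag$nodes, dag$nodes), function(v) {
    pa <- dag_parents(dag, v)
    fc <- family_counts(data, v, pa, dict = dict)
    counts_to_cpt(v, dict_states(dict, v), pa,
                  lapply(stats::setNames(pa, pa),
                         function(p) dict_states(dict, p)),
                  fc$counts, alpha)
  })
  bayes_net(dag, cpts, dictionary = dict)
}

# ---- E-step machinery -------------------------------------------------
# Posterior over each row's missing block given its observed cells.
# Because missingness is block-wise, the posterior over a missing block
# depends only on the families whose scope touches the block; rows are
# grouped by the relevant observed sub-vector and one block posterior is
# cached per group. Expected counts for ARBITRARY families (including
# hill-climb candidates) are then cheap tallies.

expected_counts_provider <- function(bn, data, completion_guard = 1e5) {
  dict <- bn_as_dict(bn)
  nodes <- bn$dag$nodes
  enc <- encode_data(data, dict)[, nodes, drop = FALSE]
  n <- nrow(enc)
  arity <- vapply(nodes, function(v) bn_arity(bn, v), integer(1))
  scope <- lapply(stats::setNames(nodes, nodes),
                  function(v) c(v, bn$cpts[[v]]$parents))

  # vectorized log CPT of family `v` at fully-observed rows `rows`
  fam_logp <- function(v, rows) {
    ct <- bn$cpts[[v]]
    k <- enc[rows, v]
    if (length(ct$parents)) {
      pidx <- enc[rows, ct$parents, drop = FALSE]
      log(cpt_lookup(ct, k, pidx))
    } else log(as.vector(ct$prob)[k])
  }

  miss_mat <- is.na(enc)
  pkey <- if (n) as.vector(miss_mat %*% 2^(seq_along(nodes) - 1)) else numeric(0)
  patterns <- list()
  loglik <- 0
  zero_rows <- integer(0)
  for (key in unique(pkey)) {
    rows <- which(pkey == key)
    M <- nodes[miss_mat[rows[1], ]]
    if (!length(M)) {
      for (v in nodes) loglik <- loglik + sum(fam_logp(v, rows))
      patterns[[length(patterns) + 1]] <- list(miss = character(0), rows = rows)
      next
    }
    touched <- nodes[vapply(nodes, function(v) any(scope[[v]] %in% M),
                            logical(1))]
    O_rel <- setdiff(unique(unlist(scope[touched])), M)
    n_comp <- prod(arity[M])
    if (n_comp > completion_guard)
      stop("missing block {", paste(M, collapse = ", "), "} has ",
           n_comp, " completions, above the guard of ", completion_guard)
    comp <- as.matrix(expand.grid(lapply(arity[M], seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
    colnames(comp) <- M
    # group rows by the relevant observed sub-vector
    if (length(O_rel)) {
      gkey <- rep(0, length(rows))
      stride <- 1
      for (v in O_rel) {
        gkey <- gkey + (enc[rows, v] - 1) * stride
        stride <- stride * arity[v]
      }
    } else gkey <- rep(0, length(rows))
    ukey <- sort(unique(gkey))
    grp <- match(gkey, ukey)
    ng <- length(ukey)
    rep_first <- rows[match(ukey, gkey)]
    # completion weights: product of touched-family CPT entries,
    # evaluated over (group x completion)
    logw <- matrix(0, nrow = ng, ncol = n_comp)
    big_idx <- function(v, rf) {
      # (ng*n_comp) state indices of variable v, groups fastest
      if (v %in% M) rep(comp[, v], each = ng)
      else rep(enc[rf, v], times = n_comp)
    }
    for (v in touched) {
      ct <- bn$cpts[[v]]
      k <- big_idx(v, rep_first)
      if (length(ct$parents)) {
        pidx <- vapply(ct$parents, function(p) big_idx(p, rep_first),
                       integer(ng * n_comp))
        if (ng * n_comp == 1) pidx <- matrix(pidx, nrow = 1)
        logw <- logw + matrix(log(cpt_lookup(ct, k, pidx)), nrow = ng)
      } else {
        logw <- logw + matrix(log(as.vector(ct$prob)[k]), nrow = ng)
      }
    }
    w <- exp(logw)
    z <- rowSums(w)
    bad <- z <= 0
    if (any(bad)) {
      zero_rows <- c(zero_rows, rows[grp %in% which(bad)])
      w[bad, ] <- 0
      z[bad] <- NA_real_
    }
    post <- w / ifelse(is.na(z), 1, z)
    logz <- log(z)
    loglik <- loglik + sum(logz[grp])
    for (v in setdiff(nodes, touched))
      loglik <- loglik + sum(fam_logp(v, rows))
    patterns[[length(patterns) + 1]] <-
      list(miss = M, rows = rows, comp = comp, grp = grp, post = post)
  }

  count_fn <- function(child, parents = character(0)) {
    fam <- c(child, parents)
    dims <- arity[fam]
    stride <- c(1, cumprod(dims))[seq_along(fam)]
    names(stride) <- fam
    flat <- numeric(prod(dims))
    for (p in patterns) {
      Fm <- intersect(fam, p$miss)
      if (!length(Fm)) {
        lin <- rep(1, length(p$rows))
        for (v in fam) lin <- lin + (enc[p$rows, v] - 1) * stride[v]
        tal <- rowsum(rep(1, length(p$rows)), lin)
        flat[as.integer(rownames(tal))] <-
          flat[as.integer(rownames(tal))] + tal[, 1]
      } else {
        Fo <- setdiff(fam, Fm)
        base <- rep(1, length(p$rows))
        for (v in Fo) base <- base + (enc[p$rows, v] - 1) * stride[v]
        offm <- rep(0, nrow(p$comp))
        for (v in Fm) offm <- offm + (p$comp[, v] - 1) * stride[v]
        uo <- sort(unique(offm))
        cellmap <- match(offm, uo)
        post_fm <- t(rowsum(t(p$post), cellmap))  # groups x cells
        for (ci in seq_along(uo)) {
          wts <- post_fm[p$grp, ci]
          tal <- rowsum(wts, base + uo[ci])
          flat[as.integer(rownames(tal))] <-
            flat[as.integer(rownames(tal))] + tal[, 1]
        }
      }
    }
    array(flat, dim = dims,
          dimnames = lapply(fam, function(v) bn_states(bn, v)))
  }

  list(count_fn = count_fn, n = n, loglik = loglik,
       zero_rows = sort(zero_rows), dict = dict, bn = bn)
}

# counts provider over complete data (no model needed)
complete_counts_provider <- function(data, dict = attr(data, "dictionary")) {
  if (is.null(dict)) stop("a data dictionary is required")
  force(data)
  list(count_fn = function(child, parents = character(0))
         family_counts(data, child, parents, dict = dict)$counts,
       n = nrow(data), loglik = NA_real_, dict = dict, bn = NULL)
}

#' Observed-data log-likelihood under missingness
#'
#' Sum over rows of `log P(observed cells)`, each computed exactly by
#' marginalizing the missing cells out of the joint. Rows whose observed
#' values have probability zero contribute `-Inf` and are reported in
#' attribute `"zero_rows"`; a fully missing row contributes `log 1 = 0`.
#'
#' @param bn a `bn`.
#' @param data data frame of state labels, `NA` for missing cells.
#' @return numeric scalar with attribute `"zero_rows"`.
#' @export
observed_loglik <- function(bn, data) {
  prov <- expected_counts_provider(bn, data)
  ll <- if (length(prov$zero_rows)) -Inf else prov$loglik
  attr(ll, "zero_rows") <- prov$zero_rows
  ll
}

#' EM settings
#'
#' @param smoothing_alpha pseudo-count used in every M-step (default
#'   0.1: keeps every CPT strictly positive for inference on rare
#'   events, while a full Laplace pseudo-count would overwhelm the
#'   handful of observed events in large-parent-configuration families
#'   and flatten the fitted risk surface).
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param max_iterations cap on EM iterations.
#' @param seed integer seed (recorded; EM itself is deterministic).
#' @param sem_max_outer cap on Structural-EM outer loops.
#' @return list of class `em_config`.
#' @export
em_config <- function(smoothing_alpha = 0.1, rel_tol = 1e-4,
                      max_iterations = 100L, seed = 1L,
                      sem_max_outer = 20L) {
  stopifnot(smoothing_alpha >= 0, rel_tol > 0, max_iterations >= 1,
            sem_max_outer >= 1)
  structure(list(smoothing_alpha = smoothing_alpha, rel_tol = rel_tol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 sem_max_outer = as.integer(sem_max_outer)),
            class = "em_config")
}

m_step <- function(dag, dict, count_fn, alpha) {
  cpts <- lapply(stats::setNames(dag$nodes, dag$nodes), function(v) {
    pa <- dag_parents(dag, v)
    counts_to_cpt(v, dict_states(dict, v), pa,
                  lapply(stats::setNames(pa, pa),
                         function(p) dict_states(dict, p)),
                  count_fn(v, pa), alpha)
  })
  bayes_net(dag, cpts, dictionary = dict)
}

#' Parameter EM on a fixed structure
#'
#' Alternates an exact E-step (expected family counts by marginalizing
#' each row's missing block under the current model) with an M-step
#' (smoothed maximum likelihood on the expected counts) until the
#' observed-data log-likelihood stabilizes. With `smoothing_alpha = 0`
#' the observed log-likelihood trace is non-decreasing (up to numerical
#' tolerance); on complete data a single iteration reproduces the
#' closed-form estimate.
#'
#' @param dag a `bn_dag`.
#' @param data data frame, `NA` for missing cells.
#' @param cfg an [em_config()].
#' @param dict a `bn_dictionary`.
#' @param init optional starting `bn`; by default an available-case
#'   Laplace fit (deterministic).
#' @return list of class `bn_learn_result` with `network`,
#'   `loglik_trace`, `score_trace`, `added_arcs`, `iterations`.
#' @export
em_parameters <- function(dag, data, cfg = em_config(),
                          dict = attr(data, "dictionary"), init = NULL) {
  if (is.null(dict)) stop("a data dictionary is required")
  bn <- if (is.null(init)) available_case_fit(dag, data, dict) else init
  trace <- numeric(0)
  prev <- -Inf
  prov <- NULL
  for (it in seq_len(cfg$max_iterations)) {
    prov <- expected_counts_provider(bn, data)
    ll <- prov$loglik
    trace <- c(trace, ll)
    bn <- m_step(dag, dict, prov$count_fn, cfg$smoothing_alpha)
    if (is.finite(ll) && is.finite(prev) &&
        abs(ll - prev) <= cfg$rel_tol * (abs(prev) + 1e-12)) break
    prev <- ll
  }
  structure(list(network = bn, loglik_trace = trace,
                 score_trace = numeric(0), added_arcs = NULL,
                 iterations = length(trace)),
            class = "bn_learn_result")
}

# deterministic EM initialization: per-family available-case Laplace fit
available_case_fit <- function(dag, data, dict) {
  cpts <- lapply(stats::setNames(dag$nodes, dag$nodes), function(v) {
    pa <- dag_parents(dag, v)
    fc <- family_counts(data, v, pa, dict = dict)
    counts_to_cpt(v, dict_states(dict, v), pa,
                  lapply(stats::setNames(pa, pa),
                         function(p) dict_states(dict, p)),
                  fc$counts, alpha = 1)
  })
  bayes_net(dag, cpts, dictionary = dict)
}

#' @export
print.bn_learn_result <- function(x, ...) {
  cat("Learning result:", length(x$network$dag$nodes), "nodes,",
      nrow(x$network$dag$arcs), "arcs;",
      x$iterations, "iterations\n")
  if (length(x$loglik_trace))
    cat("final observed log-likelihood:",
        format(utils::tail(x$loglik_trace, 1)), "\n")
  if (!is.null(x$added_arcs) && nrow(x$added_arcs))
    cat("arcs added beyond the prior DAG:",
        paste(apply(x$added_arcs, 1, paste, collapse = "->"),
              collapse = ", "), "\n")
  invisible(x)
}

# ---- scoring ----------------------------------------------------------

family_bic <- function(counts, n_child_states, effective_n) {
  r <- n_child_states
  cm <- matrix(as.vector(counts), nrow = r)
  tot <- colSums(cm)
  ll <- sum(ifelse(cm > 0, cm * log(cm / rep(pmax(tot, 1e-300), each = r)), 0))
  free <- (r - 1) * ncol(cm)
  ll - log(max(effective_n, 1)) / 2 * free
}

#' Decomposable BIC score of a DAG
#'
#' `sum over families of [ count * log(MLE) ] - log(n)/2 * free
#' parameters`, computed from (possibly expected, fractional) family
#' counts; decomposes as a sum of per-family terms.
#'
#' @param counts_by_family named list of counts arrays (child dimension
#'   first), one per node, matching `dag`'s parent sets.
#' @param dag a `bn_dag`.
#' @param effective_n total data weight.
#' @return numeric scalar.
#' @export
bic_score <- function(counts_by_family, dag, effective_n) {
  sum(vapply(dag$nodes, function(v) {
    counts <- counts_by_family[[v]]
    family_bic(counts, dim(as.array(counts))[1], effective_n)
  }, numeric(1)))
}

# ---- constraints ------------------------------------------------------

#' Structure-learning knowledge constraints
#'
#' Encodes the prior-knowledge structure: `required_arcs` (the prior
#' DAG, which the search may never remove), `forbidden_arcs`, temporal
#' `tiers` (arcs may only run from an earlier tier to the same or a
#' later tier) and the `context_node`, which sits in the first tier and
#' may have no incoming arcs.
#'
#' @param required_arcs,forbidden_arcs two-column (from, to) matrices or
#'   lists of pairs; may be empty.
#' @param tiers list of character vectors partitioning the variables.
#' @param context_node variable name.
#' @return object of class `knowledge_constraints`.
#' @export
knowledge_constraints <- function(required_arcs = NULL,
                                  forbidden_arcs = NULL,
                                  tiers, context_node) {
  required_arcs <- as_arc_matrix(required_arcs)
  forbidden_arcs <- as_arc_matrix(forbidden_arcs)
  allv <- unlist(tiers)
  if (anyDuplicated(allv))
    stop("variable(s) appear in more than one tier: ",
         paste(unique(allv[duplicated(allv)]), collapse = ", "))
  if (!context_node %in% tiers[[1]])
    stop("the context node must belong to the first tier")
  tier_of <- stats::setNames(rep(seq_along(tiers),
                                 vapply(tiers, length, integer(1))), allv)
  both <- intersect(arc_key(required_arcs), arc_key(forbidden_arcs))
  if (length(both))
    stop("arc(s) both required and forbidden: ",
         gsub("\r", "->", both, fixed = TRUE))
  if (nrow(required_arcs)) {
    bad <- tier_of[required_arcs[, 1]] > tier_of[required_arcs[, 2]]
    if (any(bad, na.rm = TRUE))
      stop("required arc violates the tier ordering: ",
           paste(required_arcs[which(bad)[1], ], collapse = "->"))
    if (any(required_arcs[, 2] == context_node))
      stop("required arc points into the context node")
  }
  structure(list(required_arcs = required_arcs,
                 forbidden_arcs = forbidden_arcs,
                 tiers = tiers, tier_of = tier_of,
                 context_node = context_node),
            class = "knowledge_constraints")
}

#' @rdname knowledge_constraints
#' @param dict a `bn_dictionary`; builds the default shipped constraints
#'   (prior-knowledge DAG as required arcs, model tiers, cohort context
#'   node).
#' @export
default_constraints <- function(dict) {
  knowledge_constraints(required_arcs = knowledge_dag(dict)$arcs,
                        forbidden_arcs = NULL,
                        tiers = model_tiers(dict),
                        context_node = dict$selection)
}

arc_addable <- function(con, from, to) {
  if (to == con$context_node) return(FALSE)
  if (any(con$forbidden_arcs[, 1] == from & con$forbidden_arcs[, 2] == to))
    return(FALSE)
  tf <- con$tier_of[from]; tt <- con$tier_of[to]
  if (!is.na(tf) && !is.na(tt) && tf > tt) return(FALSE)
  TRUE
}

arc_required <- function(con, from, to)
  any(con$required_arcs[, 1] == from & con$required_arcs[, 2] == to)

check_constraints <- function(dag, con) {
  out <- character(0)
  if (nrow(con$required_arcs)) {
    miss <- setdiff(arc_key(con$required_arcs), arc_key(dag$arcs))
    if (length(miss))
      out <- c(out, paste0("missing required arc ",
                           gsub("\r", "->", miss, fixed = TRUE)))
  }
  for (i in seq_len(nrow(dag$arcs))) {
    f <- dag$arcs[i, 1]; t <- dag$arcs[i, 2]
    if (t == con$context_node)
      out <- c(out, paste0("arc into context node: ", f, "->", t))
    if (any(con$forbidden_arcs[, 1] == f & con$forbidden_arcs[, 2] == t))
      out <- c(out, paste0("forbidden arc present: ", f, "->", t))
    tf <- con$tier_of[f]; tt <- con$tier_of[t]
    if (!is.na(tf) && !is.na(tt) && tf > tt)
      out <- c(out, paste0("tier-violating arc: ", f, "->", t))
  }
  if (!is.null(find_cycle(dag))) out <- c(out, "graph is cyclic")
  out
}

# ---- search -----------------------------------------------------------

#' Constrained greedy hill-climbing over DAGs
#'
#' Score-based structure search with add / delete / reverse moves under
#' knowledge constraints: never violates acyclicity, tiers, forbidden
#' arcs or the context node's no-parent rule, and never deletes or
#' reverses a required arc. Deterministic: moves are enumerated in
#' lexicographic order, the best strictly improving move is applied
#' (lexicographic tie-break), and search stops at a local optimum.
#'
#' @param provider a counts provider: either a complete data frame (with
#'   its dictionary attached or passed via `dict`) or the expected-count
#'   provider used internally by [structural_em()].
#' @param constraints a [knowledge_constraints()].
#' @param start a `bn_dag` satisfying the constraints.
#' @param dict dictionary (for data-frame providers).
#' @param max_parents cap on the number of parents per node.
#' @param min_improvement strictly positive score gain required.
#' @return a `bn_dag` with attribute `"score"`.
#' @export
hill_climb <- function(provider, constraints, start,
                       dict = NULL, max_parents = 5L,
                       min_improvement = 1e-9) {
  if (is.data.frame(provider))
    provider <- complete_counts_provider(provider,
      dict = if (is.null(dict)) attr(provider, "dictionary") else dict)
  con <- constraints
  bad <- check_constraints(start, con)
  if (length(bad))
    stop("start DAG violates the constraints: ", paste(bad, collapse = "; "))
  effective_n <- provider$n
  cache <- new.env(parent = emptyenv())
  fam_score <- function(child, parents) {
    parents <- sort(parents)
    key <- paste(child, paste(parents, collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    counts <- provider$count_fn(child, parents)
    r <- dim(as.array(counts))[1]
    if (is.na(r)) r <- length(counts)
    s <- family_bic(counts, r, effective_n)
    cache[[key]] <- s
    s
  }
  dg <- start
  nodes <- sort(dg$nodes)
  repeat {
    cur_par <- lapply(stats::setNames(dg$nodes, dg$nodes),
                      function(v) dag_parents(dg, v))
    cur_fs <- vapply(dg$nodes,
                     function(v) fam_score(v, cur_par[[v]]), numeric(1))
    names(cur_fs) <- dg$nodes
    best <- NULL; best_delta <- min_improvement
    consider <- function(delta, move) {
      if (delta > best_delta + 1e-12) { best <<- move; best_delta <<- delta }
    }
    for (from in nodes) for (to in nodes) {
      if (from == to) next
      if (!has_arc(dg, from, to)) {
        # add
        if (!arc_addable(con, from, to)) next
        if (length(cur_par[[to]]) >= max_parents) next
        if (has_directed_path(dg, to, from)) next  # would create a cycle
        delta <- fam_score(to, c(cur_par[[to]], from)) - cur_fs[to]
        consider(delta, list(type = "add", from = from, to = to))
      } else {
        if (arc_required(con, from, to)) next
        # delete
        delta_del <- fam_score(to, setdiff(cur_par[[to]], from)) - cur_fs[to]
        consider(delta_del, list(type = "delete", from = from, to = to))
        # reverse
        if (arc_addable(con, to, from) &&
            length(cur_par[[from]]) < max_parents) {
          tmp <- remove_arc(dg, from, to)
          if (!has_directed_path(tmp, from, to)) {
            delta <- delta_del +
              fam_score(from, c(cur_par[[from]], to)) - cur_fs[from]
            consider(delta, list(type = "reverse", from = from, to = to))
          }
        }
      }
    }
    if (is.null(best)) break
    dg <- switch(best$type,
      add = add_arc(dg, best$from, best$to),
      delete = remove_arc(dg, best$from, best$to),
      reverse = add_arc(remove_arc(dg, best$from, best$to),
                        best$to, best$from))
  }
  score <- sum(vapply(dg$nodes,
                      function(v) fam_score(v, dag_parents(dg, v)),
                      numeric(1)))
  attr(dg, "score") <- score
  dg
}

#' Structural EM under knowledge constraints
#'
#' Outer loop of the learner: (i) parameter EM on the current structure,
#' (ii) expected sufficient statistics under the fitted model, (iii)
#' constrained hill-climb on the expected BIC score. Stops when the
#' structure no longer changes or after `cfg$sem_max_outer` loops. Works
#' under block-wise missing-not-at-random data because the missingness
#' mechanism (the cohort context node and the prior-knowledge DAG) is
#' part of the model. Arcs found beyond the prior DAG are returned in
#' `added_arcs` as candidates for expert review.
#'
#' @param prior_dag a `bn_dag` satisfying `constraints` (typically the
#'   required-arc prior-knowledge DAG).
#' @param data data frame, `NA` for missing cells; the context node must
#'   be fully observed.
#' @param constraints a [knowledge_constraints()].
#' @param cfg an [em_config()].
#' @param dict a `bn_dictionary`.
#' @param max_parents hill-climb parent cap.
#' @return a `bn_learn_result`; `score_trace` holds the expected-BIC
#'   after each outer loop.
#' @export
structural_em <- function(prior_dag, data, constraints, cfg = em_config(),
                          dict = attr(data, "dictionary"),
                          max_parents = 5L) {
  if (is.null(dict)) stop("a data dictionary is required")
  bad <- check_constraints(prior_dag, constraints)
  if (length(bad))
    stop("prior DAG violates the constraints: ", paste(bad, collapse = "; "))
  if (anyNA(data[[constraints$context_node]]))
    stop("the context node must be fully observed")
  current <- prior_dag
  score_trace <- numeric(0)
  fit <- NULL
  for (outer in seq_len(cfg$sem_max_outer)) {
    fit <- em_parameters(current, data, cfg = cfg, dict = dict,
                         init = fit$network)
    prov <- expected_counts_provider(fit$network, data)
    cand <- hill_climb(prov, constraints, current, dict = dict,
                       max_parents = max_parents)
    score_trace <- c(score_trace, attr(cand, "score"))
    if (same_dag(cand, current)) break
    current <- cand
    fit <- NULL  # refit from scratch on the new structure
  }
  final <- em_parameters(current, data, cfg = cfg, dict = dict)
  added <- current$arcs[!(arc_key(current$arcs) %in% arc_key(prior_dag$arcs)), ,
                        drop = FALSE]
  structure(list(network = final$network,
                 dag = current,
                 loglik_trace = final$loglik_trace,
                 score_trace = score_trace,
                 added_arcs = added,
                 iterations = final$iterations),
            class = "bn_learn_result")
}
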
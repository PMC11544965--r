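#' Conditional probability tables
#'
#' A `bn_cpt` stores P(child | parents) as a numeric array whose first
#' dimension runs over the child's states and whose remaining dimensions
#' run over the parents in their declared order, each in its declared
#' state order. For every joint parent configuration the child
#' probabilities must be non-negative and sum to 1 within `1e-9`.
#'
#' @param child child variable name.
#' @param states character vector of the child's state labels.
#' @param parents character vector of parent names (may be empty).
#' @param parent_states named list of state-label vectors, one per parent.
#' @param prob numeric array (or vector for a root node) of
#'   probabilities, child dimension first.
#' @return an object of class `bn_cpt`.
#' @export
cpt <- function(child, states, prob, parents = character(0),
                parent_states = list()) {
  stopifnot(is.character(child), length(child) == 1,
            is.character(states), length(states) >= 2)
  parents <- as.character(parents)
  if (length(parents) != length(parent_states))
    stop("parent_states must have one entry per parent")
  dims <- c(length(states),
            vapply(parent_states, length, integer(1), USE.NAMES = FALSE))
  prob <- array(as.numeric(prob), dim = dims)
  if (length(prob) != prod(dims))
    stop("probability table for '", child, "' has wrong length")
  dimnames(prob) <- c(list(states), unname(parent_states))
  structure(list(child = child, states = states, parents = parents,
                 parent_states = stats::setNames(parent_states, parents),
                 prob = prob),
            class = "bn_cpt")
}

n_parent_configs <- function(ct)
  prod(vapply(ct$parent_states, length, integer(1)))

# child-state probabilities as a (n_configs x arity) matrix, parent
# configurations in row-major order over the ordered parent list (first
# parent slowest) -- the layout used by counts and the .net writer.
cpt_config_matrix <- function(ct) {
  nc <- n_parent_configs(ct)
  if (!length(ct$parents))
    return(matrix(as.vector(ct$prob), nrow = 1))
  perm <- c(rev(seq_along(ct$parents)) + 1L, 1L)
  matrix(as.vector(aperm(ct$prob, perm)), nrow = nc)
}

# inverse of cpt_config_matrix: (n_configs x arity) matrix -> CPT array
# (child dimension first, parents in declared order).
config_matrix_to_array <- function(m, states, parent_states) {
  if (!length(parent_states)) {
    a <- array(as.vector(t(m)), dim = length(states))
    dimnames(a) <- list(states)
    return(a)
  }
  arities <- vapply(parent_states, length, integer(1), USE.NAMES = FALSE)
  perm <- c(rev(seq_along(parent_states)) + 1L, 1L)
  a_perm <- array(as.vector(m), dim = c(rev(arities), length(states)))
  a <- aperm(a_perm, order(perm))
  dimnames(a) <- c(list(states), unname(parent_states))
  a
}

# row-major (first parent slowest) configuration index from a matrix of
# parent state indices (one column per parent, in parent order).
config_rowmajor_index <- function(state_idx, arities) {
  if (!length(arities)) return(rep(1L, max(1L, nrow(state_idx))))
  idx <- rep(0L, nrow(state_idx))
  for (j in seq_along(arities))
    idx <- idx * arities[j] + (state_idx[, j] - 1L)
  idx + 1L
}

# probability lookup: child state indices k (vector) with parent state
# index matrix (n x p) -> numeric vector.
cpt_lookup <- function(ct, k, parent_idx) {
  r <- length(ct$states)
  if (!length(ct$parents)) return(as.vector(ct$prob)[k])
  arities <- vapply(ct$parent_states, length, integer(1))
  # array linear index: child first (fastest), then parents in order.
  lin <- k
  stride <- r
  for (j in seq_along(arities)) {
    lin <- lin + (parent_idx[, j] - 1L) * stride
    stride <- stride * arities[j]
  }
  as.vector(ct$prob)[lin]
}

#' Discrete Bayesian networks
#'
#' A discrete Bayesian network couples a DAG with one conditional
#' probability table per node; the joint distribution is the product of
#' the tables (chain-rule factorization).
#'
#' @param dictionary a `bn_dictionary` (optional when `cpts` carry all
#'   state information; a group-less internal dictionary is then built).
#' @param dag a `bn_dag`.
#' @param cpts named list of `bn_cpt`, one per node.
#' @return an object of class `bn`.
#' @export
bayes_net <- function(dag, cpts, dictionary = NULL) {
  stopifnot(inherits(dag, "bn_dag"), is.list(cpts))
  if (is.null(names(cpts)))
    names(cpts) <- vapply(cpts, function(ct) ct$child, character(1))
  structure(list(dictionary = dictionary, dag = dag, cpts = cpts),
            class = "bn")
}

#' @export
print.bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$arcs), "arcs\n")
  invisible(x)
}

bn_states <- function(bn, var) bn$cpts[[var]]$states
bn_arity  <- function(bn, var) length(bn$cpts[[var]]$states)

#' Validate a Bayesian network
#'
#' Checks every class invariant — arc sanity (no self-loops, duplicates,
#' unknown nodes), acyclicity, one CPT per node, CPT parents equal to
#' graph parents, table dimensions matching arities, and per-configuration
#' normalization within `1e-9` — and returns diagnostics instead of
#' throwing, so defective models can be inspected.
#'
#' @param bn a `bn` object.
#' @return character vector of human-readable diagnostics; empty iff the
#'   network is valid.
#' @export
validate_network <- function(bn) {
  out <- character(0)
  dg <- bn$dag
  if (any(dg$arcs[, 1] == dg$arcs[, 2]))
    out <- c(out, paste0("self-loop on node ",
                         dg$arcs[dg$arcs[, 1] == dg$arcs[, 2], 1][1]))
  if (anyDuplicated(arc_key(dg$arcs)))
    out <- c(out, "duplicate arcs present")
  cyc <- find_cycle(dg)
  if (!is.null(cyc))
    out <- c(out, paste0("graph is cyclic: ", paste(cyc, collapse = " -> ")))
  missing_cpt <- setdiff(dg$nodes, names(bn$cpts))
  if (length(missing_cpt))
    out <- c(out, paste0("no CPT for node ", missing_cpt))
  for (v in intersect(dg$nodes, names(bn$cpts))) {
    ct <- bn$cpts[[v]]
    gp <- sort(dag_parents(dg, v))
    if (!identical(sort(ct$parents), gp))
      out <- c(out, paste0("CPT parents of ", v, " (",
                           paste(ct$parents, collapse = ","),
                           ") do not match graph parents (",
                           paste(gp, collapse = ","), ")"))
    m <- t(matrix(as.vector(ct$prob), nrow = length(ct$states)))
    if (any(m < -1e-12))
      out <- c(out, paste0("negative probability in CPT of ", v))
    sums <- rowSums(m)
    bad <- which(abs(sums - 1) > 1e-9)
    if (length(bad))
      out <- c(out, paste0("CPT of ", v, ": configuration ", bad[1],
                           " sums to ", format(sums[bad[1]]),
                           " (", length(bad), " configuration(s) affected)"))
  }
  out
}

# evidence: named character vector/list of state labels
check_evidence <- function(bn, evidence) {
  evidence <- unlist(evidence)
  if (!length(evidence)) return(stats::setNames(character(0), character(0)))
  bad <- setdiff(names(evidence), bn$dag$nodes)
  if (length(bad)) stop("unknown variable(s) in evidence: ",
                        paste(bad, collapse = ", "))
  for (v in names(evidence)) {
    if (!evidence[[v]] %in% bn_states(bn, v))
      stop("invalid state '", evidence[[v]], "' for variable '", v,
           "'; valid states: ", paste(bn_states(bn, v), collapse = ", "))
  }
  evidence
}

#' Joint probability of a complete assignment
#'
#' Evaluates the chain-rule product of CPT entries for one full
#' assignment of every network variable.
#'
#' @param bn a `bn` object.
#' @param assignment named character vector/list giving a state for every
#'   node.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' # P(A = y, B = y) = P(A = y) * P(B = y | A = y)
joint_probability <- function(bn, assignment) {
  assignment <- check_evidence(bn, assignment)
  miss <- setdiff(bn$dag$nodes, names(assignment))
  if (length(miss))
    stop("assignment must cover all nodes; missing: ",
         paste(miss, collapse = ", "))
  p <- 1
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    k <- match(assignment[[v]], ct$states)
    if (length(ct$parents)) {
      pidx <- matrix(mapply(function(pv) match(assignment[[pv]],
                                               ct$parent_states[[pv]]),
                            ct$parents),
                     nrow = 1)
      p <- p * cpt_lookup(ct, k, pidx)
    } else {
      p <- p * as.vector(ct$prob)[k]
    }
  }
  p
}
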
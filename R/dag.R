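#' Directed graphs over named variables
#'
#' A `bn_dag` holds an ordered node set and a set of directed arcs
#' (parent, child). Construction checks that arcs reference known nodes;
#' self-loops, duplicate arcs and cycles are reported by
#' [validate_network()] so that defective structures can still be built
#' and diagnosed.
#'
#' @param nodes character vector of node names (order is kept and used
#'   for deterministic tie-breaking).
#' @param arcs two-column character matrix (from, to), or a data frame /
#'   list of length-2 vectors; may be empty.
#' @return an object of class `bn_dag`.
#' @export
dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), length(nodes) > 0)
  if (anyDuplicated(nodes))
    stop("duplicate node names")
  arcs <- as_arc_matrix(arcs)
  bad <- !(arcs[, 1] %in% nodes) | !(arcs[, 2] %in% nodes)
  if (any(bad))
    stop("arc references unknown node: ",
         paste(apply(arcs[bad, , drop = FALSE], 1, paste, collapse = "->"),
               collapse = ", "))
  structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0) ||
      (!is.matrix(arcs) && length(arcs) == 0))
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.list(arcs)) arcs <- do.call(rbind, arcs)
  if (is.character(arcs) && is.null(dim(arcs)) && length(arcs) == 2)
    arcs <- matrix(arcs, ncol = 2)
  storage.mode(arcs) <- "character"
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  arcs
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$arcs), "arcs\n")
  invisible(x)
}

dag_parents <- function(dag, node) unname(dag$arcs[dag$arcs[, 2] == node, 1])
dag_children <- function(dag, node) unname(dag$arcs[dag$arcs[, 1] == node, 2])

has_arc <- function(dag, from, to)
  any(dag$arcs[, 1] == from & dag$arcs[, 2] == to)

add_arc <- function(dag, from, to) {
  dag$arcs <- rbind(dag$arcs, c(from, to))
  dag
}

remove_arc <- function(dag, from, to) {
  keep <- !(dag$arcs[, 1] == from & dag$arcs[, 2] == to)
  dag$arcs <- dag$arcs[keep, , drop = FALSE]
  dag
}

arc_key <- function(arcs) paste(arcs[, 1], arcs[, 2], sep = "\r")

same_dag <- function(a, b) {
  setequal(a$nodes, b$nodes) && setequal(arc_key(a$arcs), arc_key(b$arcs))
}

# TRUE iff a directed path from `from` to `to` exists (used to keep
# hill-climbing moves acyclic).
has_directed_path <- function(dag, from, to) {
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(dag$arcs[dag$arcs[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

find_cycle <- function(dag) {
  # Kahn peeling; returns a character vector tracing one cycle, or NULL.
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(dag$arcs[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  active <- rep(TRUE, length(nodes)); names(active) <- nodes
  repeat {
    zero <- names(indeg)[active & indeg == 0]
    if (!length(zero)) break
    for (z in zero) {
      active[z] <- FALSE
      ch <- dag$arcs[dag$arcs[, 1] == z & active[dag$arcs[, 2]], 2]
      if (length(ch)) indeg[ch] <- indeg[ch] - 1L
    }
  }
  rem <- names(active)[active]
  if (!length(rem)) return(NULL)
  # walk within the remaining sub-graph until a node repeats
  cur <- rem[1]; path <- cur
  repeat {
    nxt <- dag$arcs[dag$arcs[, 1] == cur & dag$arcs[, 2] %in% rem, 2][1]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt); cur <- nxt
  }
}

#' Topological ordering of a DAG
#'
#' Returns an ordering in which every parent precedes all of its
#' children. Deterministic: among the nodes available at each step the
#' one earliest in the dictionary (node-set) order is emitted first.
#'
#' @param dag a `bn_dag`.
#' @return character vector of node names.
#' @export
#' @examples
#' topological_order(dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))))
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(dag$arcs[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0]
    if (!length(avail)) {
      cyc <- find_cycle(dag)
      stop("graph is cyclic: ", paste(cyc, collapse = " -> "))
    }
    nxt <- avail[1]  # `remaining` keeps dictionary order
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- dag_children(dag, nxt)
    if (length(ch)) indeg[ch] <- indeg[ch] - 1L
  }
  out
}

ancestors_of <- function(dag, nodes) {
  anc <- character(0)
  frontier <- nodes
  while (length(frontier)) {
    pa <- unique(dag$arcs[dag$arcs[, 2] %in% frontier, 1])
    pa <- setdiff(pa, c(anc, nodes))
    anc <- c(anc, pa)
    frontier <- pa
  }
  anc
}

#' Graphical conditional independence (d-separation)
#'
#' Tests whether every path between `x` and `y` is blocked by `z` under
#' the standard d-separation criterion, via the ancestral moral graph:
#' restrict to ancestors of `x`, `y`, `z`; marry co-parents; drop `z`;
#' `x` and `y` are d-separated iff they are disconnected in the result.
#'
#' @param dag a `bn_dag`.
#' @param x,y,z disjoint character vectors of node names (`z` may be
#'   empty).
#' @return logical scalar.
#' @export
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
#' d_separated(g, "A", "B", character(0))  # TRUE: collider unobserved
#' d_separated(g, "A", "B", "C")           # FALSE: conditioning opens it
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(all(c(x, y, z) %in% dag$nodes))
  if (length(intersect(x, y)) || length(intersect(x, z)) ||
      length(intersect(y, z)))
    stop("x, y and z must be disjoint")
  keep <- unique(c(x, y, z, ancestors_of(dag, c(x, y, z))))
  arcs <- dag$arcs[dag$arcs[, 1] %in% keep & dag$arcs[, 2] %in% keep, ,
                   drop = FALSE]
  # undirected adjacency: original arcs plus married co-parents
  und <- rbind(arcs, arcs[, 2:1, drop = FALSE])
  for (v in keep) {
    pa <- unique(arcs[arcs[, 2] == v, 1])
    if (length(pa) > 1) {
      prs <- utils::combn(pa, 2)
      und <- rbind(und, t(prs), t(prs)[, 2:1, drop = FALSE])
    }
  }
  # remove conditioning nodes, test connectivity from x to y
  und <- und[!(und[, 1] %in% z) & !(und[, 2] %in% z), , drop = FALSE]
  frontier <- setdiff(x, z)
  seen <- frontier
  while (length(frontier)) {
    nxt <- unique(und[und[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (any(nxt %in% y)) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  !any(seen %in% y)
}
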
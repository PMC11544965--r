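# ---- HUGIN-style .net serialization ----------------------------------
# Dialect (see FORMAT.md): `node` blocks declare states in printed
# order; `potential ( child | p1 p2 )` blocks list probabilities
# row-major over the ordered parent list (first parent slowest), one
# parenthesized row of child-state probabilities per parent
# configuration.

#' Write a network to a HUGIN-style .net document
#'
#' @param bn a `bn`.
#' @param path file path; if `NULL` the document is returned as a
#'   character vector of lines.
#' @return invisibly, the document lines.
#' @export
write_net <- function(bn, path = NULL) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c("net", "{", "}")
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    lines <- c(lines,
               paste0("node ", v), "{",
               paste0("  states = ( ",
                      paste0('"', ct$states, '"', collapse = " "), " );"),
               "}")
  }
  for (v in bn$dag$nodes) {
    ct <- bn$cpts[[v]]
    head <- if (length(ct$parents))
      paste0("potential ( ", v, " | ",
             paste(ct$parents, collapse = " "), " )")
    else paste0("potential ( ", v, " )")
    m <- cpt_config_matrix(ct)  # configs (first parent slowest) x states
    rows <- apply(m, 1, function(p)
      paste0("( ", paste(num(p), collapse = " "), " )"))
    body <- if (length(ct$parents))
      c("  data = (", paste0("    ", rows), "  );")
    else paste0("  data = ", rows, ";")
    lines <- c(lines, head, "{", body, "}")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

net_tokenize <- function(lines) {
  toks <- list()
  for (i in seq_along(lines)) {
    s <- sub("%.*$", "", lines[i])  # % comments
    pat <- '"[^"]*"|[A-Za-z_][A-Za-z0-9_.]*|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?|[(){}|;=]'
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (tk in regmatches(s, list(m))[[1]])
        toks[[length(toks) + 1]] <- list(t = tk, line = i)
    }
  }
  toks
}

#' Read a network from a HUGIN-style .net document
#'
#' Permissive on whitespace and nesting of the `data` parentheses; the
#' probability layout must be row-major over the declared parent order
#' (first parent slowest). Malformed input produces errors that name the
#' offending node and line.
#'
#' @param path file path, or a character vector of document lines via
#'   `lines`.
#' @param dictionary optional `bn_dictionary` to attach (states are
#'   checked against it).
#' @param lines alternative to `path`.
#' @return a `bn`.
#' @export
read_net <- function(path = NULL, dictionary = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  toks <- net_tokenize(lines)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$t else NULL
  line <- function() if (pos <= length(toks)) toks[[pos]]$line else length(lines)
  nxt <- function() { tk <- toks[[pos]]; pos <<- pos + 1L; tk$t }
  expect <- function(what) {
    tk <- peek()
    if (is.null(tk) || tk != what)
      stop("parse error at line ", line(), ": expected '", what,
           "' but found '", if (is.null(tk)) "<eof>" else tk, "'")
    nxt()
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  skip_block <- function() {  # consume a balanced { ... }
    expect("{")
    depth <- 1L
    while (depth > 0) {
      tk <- nxt()
      if (tk == "{") depth <- depth + 1L
      if (tk == "}") depth <- depth - 1L
    }
  }
  states <- list(); order_nodes <- character(0)
  potentials <- list()
  while (!is.null(peek())) {
    kw <- nxt()
    if (kw == "net") {
      skip_block()
    } else if (kw == "node") {
      name <- nxt()
      expect("{")
      st <- NULL
      while (peek() != "}") {
        field <- nxt()
        if (field == "states") {
          expect("="); expect("(")
          st <- character(0)
          while (peek() != ")") st <- c(st, unquote(nxt()))
          expect(")"); expect(";")
        } else {
          # skip unknown field up to ';'
          while (peek() != ";") nxt()
          nxt()
        }
      }
      expect("}")
      if (is.null(st))
        stop("node '", name, "' declares no states (line ", line(), ")")
      states[[name]] <- st
      order_nodes <- c(order_nodes, name)
    } else if (kw == "potential") {
      expect("(")
      child <- nxt()
      parents <- character(0)
      if (peek() == "|") {
        nxt()
        while (peek() != ")") parents <- c(parents, nxt())
      }
      expect(")")
      expect("{")
      vals <- numeric(0)
      start_line <- line()
      while (peek() != "}") {
        field <- nxt()
        if (field == "data") {
          expect("=")
          depth <- 0L
          repeat {
            tk <- nxt()
            if (tk == "(") depth <- depth + 1L
            else if (tk == ")") {
              depth <- depth - 1L
              if (depth == 0L && peek() == ";") { nxt(); break }
            } else if (tk == ";" && depth == 0L) break
            else vals <- c(vals, suppressWarnings(as.numeric(tk)))
          }
        } else {
          while (peek() != ";") nxt()
          nxt()
        }
      }
      expect("}")
      if (anyNA(vals))
        stop("non-numeric entry in potential for node '", child,
             "' near line ", start_line)
      potentials[[child]] <- list(parents = parents, vals = vals,
                                  line = start_line)
    } else {
      stop("parse error at line ", line(), ": unknown block '", kw, "'")
    }
  }
  cpts <- list()
  arcs <- NULL
  for (v in order_nodes) {
    pt <- potentials[[v]]
    if (is.null(pt))
      stop("no potential block for node '", v, "'")
    unknown <- setdiff(pt$parents, order_nodes)
    if (length(unknown))
      stop("potential for '", v, "' references unknown parent(s): ",
           paste(unknown, collapse = ", "))
    r <- length(states[[v]])
    pa_states <- lapply(stats::setNames(pt$parents, pt$parents),
                        function(p) states[[p]])
    nc <- prod(vapply(pa_states, length, integer(1)))
    if (length(pt$vals) != r * nc)
      stop("potential for node '", v, "' near line ", pt$line, " has ",
           length(pt$vals), " entries; expected ", r * nc)
    m <- matrix(pt$vals, nrow = nc, byrow = TRUE)
    sums <- rowSums(m)
    if (any(abs(sums - 1) > 1e-6))
      stop("potential for node '", v, "' near line ", pt$line,
           " is not normalized (configuration ",
           which(abs(sums - 1) > 1e-6)[1], " sums to ",
           format(sums[which(abs(sums - 1) > 1e-6)[1]]), ")")
    prob <- config_matrix_to_array(m, states[[v]], pa_states)
    cpts[[v]] <- cpt(v, states[[v]], prob, parents = pt$parents,
                     parent_states = pa_states)
    if (length(pt$parents)) arcs <- rbind(arcs, cbind(pt$parents, v))
  }
  if (!is.null(dictionary)) {
    for (v in order_nodes)
      if (v %in% dict_names(dictionary) &&
          !identical(states[[v]], dict_states(dictionary, v)))
        stop("states of node '", v, "' do not match the dictionary")
  }
  bayes_net(dag(order_nodes, arcs), cpts, dictionary = dictionary)
}

# ---- dataset CSV ------------------------------------------------------

#' Write a dataset as CSV (missing cells as empty strings)
#'
#' @param data data frame of state labels.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a dataset CSV against a dictionary
#'
#' Header must contain every dictionary variable (any column order);
#' empty strings and `"NA"` become missing; every non-missing cell must
#' be one of the variable's state labels.
#'
#' @param path CSV file path.
#' @param dict a `bn_dictionary`.
#' @return data frame (dictionary column order) with the dictionary
#'   attached as attribute `"dictionary"`.
#' @export
read_dataset <- function(path, dict) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(dict_names(dict), names(raw))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), dict_names(dict))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  out <- raw[, dict_names(dict), drop = FALSE]
  for (v in names(out)) {
    x <- out[[v]]
    x[x == "" | x == "NA"] <- NA_character_
    bad <- which(!is.na(x) & !(x %in% dict_states(dict, v)))
    if (length(bad))
      stop("invalid state '", x[bad[1]], "' for variable '", v,
           "' at row ", bad[1], "; valid states: ",
           paste(dict_states(dict, v), collapse = "; "))
    out[[v]] <- x
  }
  message("read ", nrow(out), " rows x ", ncol(out), " columns (",
          sum(is.na(out)), " missing cells)")
  attr(out, "dictionary") <- dict
  out
}

# ---- dictionary JSON/YAML ---------------------------------------------

#' Write / read a data dictionary (JSON or YAML by file extension)
#'
#' @param dict a `bn_dictionary`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns a `bn_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  obj <- list(variables = lapply(unname(dict$variables), function(v)
    list(name = v$name, states = v$states, group = v$group)))
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(obj, path)
  else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  data_dictionary(lapply(obj$variables, function(v)
    list(name = v$name, states = unlist(v$states), group = v$group)))
}

# ---- constraints ------------------------------------------------------

#' Write / read knowledge constraints (YAML or JSON by file extension)
#'
#' The file holds `context_node`, `tiers` (list of variable lists) and
#' optional `required` / `forbidden` arc lists (each arc a `[from, to]`
#' pair). Reading validates the constraint invariants (tiers partition,
#' no arc both required and forbidden, required arcs respect tiers and
#' the context node).
#'
#' @param constraints a [knowledge_constraints()].
#' @param path file path.
#' @return `write_constraints` returns `path` invisibly;
#'   `read_constraints` returns a `knowledge_constraints`.
#' @export
write_constraints <- function(constraints, path) {
  arcs_list <- function(m) if (nrow(m)) apply(m, 1, as.list) else list()
  obj <- list(context_node = constraints$context_node,
              tiers = lapply(constraints$tiers, as.list),
              required = arcs_list(constraints$required_arcs),
              forbidden = arcs_list(constraints$forbidden_arcs))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  obj <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  to_arcs <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    do.call(rbind, lapply(x, function(a) unlist(a, use.names = FALSE)))
  }
  knowledge_constraints(required_arcs = to_arcs(obj$required),
                        forbidden_arcs = to_arcs(obj$forbidden),
                        tiers = lapply(obj$tiers, function(t)
                          unlist(t, use.names = FALSE)),
                        context_node = obj$context_node)
}
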
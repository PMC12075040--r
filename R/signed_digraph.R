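#' Construct a signed directed graph
#'
#' The structural substrate of the package: a directed graph whose edges carry
#' a regulatory sign, +1 for activation and -1 for repression.  At most one
#' edge may connect an ordered pair of nodes; self-edges are permitted.
#'
#' @param nodes Character vector of node identifiers (order is preserved and
#'   fixes the matrix index of each node downstream).
#' @param edges A data frame with columns `from`, `to` and `sign`
#'   (values in \{-1, +1\}), or `NULL` for an edgeless graph.
#' @return An object of class `signed_digraph` with elements `nodes` and
#'   `edges`.
#' @examples
#' g <- signed_digraph(c("a", "b"),
#'                     data.frame(from = c("a", "b"), to = c("b", "a"),
#'                                sign = c(1, -1)))
#' repression_fraction(g)
#' @export
signed_digraph <- function(nodes = character(), edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        sign = as.integer(edges$sign),
                        stringsAsFactors = FALSE)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge signs must be +1 or -1")
    }
    if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
      stop("edge endpoints must appear in `nodes`")
    }
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      stop("duplicate ordered (from, to) pairs")
    }
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf(
    "signed_digraph: %d nodes, %d edges (mean degree %.2f, repression %.1f%%)\n",
    st$n_nodes, st$n_edges, st$mean_degree, 100 * st$repression_fraction))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' Fraction of repressing edges
#'
#' @param g A `signed_digraph`.
#' @return Proportion of edges with sign -1 (`NaN` for an edgeless graph).
#' @export
repression_fraction <- function(g) {
  if (n_edges(g) == 0L) return(NaN)
  mean(g$edges$sign == -1L)
}

# integer (from, to) index columns relative to g$nodes
edge_indices <- function(g) {
  list(from = match(g$edges$from, g$nodes),
       to = match(g$edges$to, g$nodes))
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

# induced subgraph on `keep` (character ids); node order inherited from g
induced_subgraph_signed <- function(g, keep) {
  keep <- g$nodes[g$nodes %in% keep]
  e <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]
  signed_digraph(keep, e)
}

SIGN_TOKENS <- c("+" = 1L, "-" = -1L, "activation" = 1L, "repression" = -1L,
                 "+1" = 1L, "-1" = -1L)

#' Read a signed edge list
#'
#' Parses a tab-separated regulator/target/sign file into a
#' [signed_digraph()].  Recognised sign tokens are `+`, `-`, `activation`,
#' `repression`, `+1` and `-1`.  Lines starting with `#` and blank lines are
#' ignored.  Duplicate ordered pairs collapse to the last row seen, with a
#' warning.
#'
#' @param path Path to a UTF-8 TSV file with at least three columns:
#'   source, target, sign.
#' @return A `signed_digraph`; nodes appear in order of first mention.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  from <- character(0); to <- character(0); sgn <- integer(0)
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (!nzchar(trimws(raw)) || startsWith(trimws(raw), "#")) next
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("line %d: expected >= 3 tab-separated fields", ln))
    }
    tok <- trimws(fields[3])
    if (!tok %in% names(SIGN_TOKENS)) {
      stop(sprintf("line %d: unknown sign token '%s'", ln, tok))
    }
    from <- c(from, trimws(fields[1]))
    to <- c(to, trimws(fields[2]))
    sgn <- c(sgn, SIGN_TOKENS[[tok]])
  }
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (source, target) rows collapsed; last sign wins",
                    sum(duplicated(key))))
    last <- !duplicated(key, fromLast = TRUE)
    # keep first-occurrence order of pairs, but the sign of the last row
    first <- !duplicated(key)
    ord_key <- key[first]
    sgn <- sgn[last][match(ord_key, key[last])]
    from <- from[first]; to <- to[first]
  }
  nodes <- unique(c(rbind(from, to)))  # order of first mention
  signed_digraph(nodes, data.frame(from = from, to = to, sign = sgn))
}

#' Write a signed edge list
#'
#' @param g A `signed_digraph`.
#' @param path Output path; the same TSV dialect accepted by
#'   [read_edge_list()], with `+`/`-` sign tokens.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  tok <- ifelse(g$edges$sign == 1L, "+", "-")
  writeLines(sprintf("%s\t%s\t%s", g$edges$from, g$edges$to, tok), path)
  invisible(path)
}

#' Basic network statistics
#'
#' Node and edge counts, mean total degree and repression fraction.  Mean
#' degree is the in- plus out-degree averaged over nodes, 2m/n.
#'
#' @param g A `signed_digraph`.
#' @return A list of class `network_stats` with `n_nodes`, `n_edges`,
#'   `mean_degree` and `repression_fraction`.
#' @export
network_stats <- function(g) {
  n <- n_nodes(g); m <- n_edges(g)
  structure(list(
    n_nodes = n,
    n_edges = m,
    mean_degree = if (n == 0L) 0 else 2 * m / n,
    repression_fraction = repression_fraction(g)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("nodes %d  edges %d  mean degree %.4f  repression %.3f\n",
              x$n_nodes, x$n_edges, x$mean_degree, x$repression_fraction))
  invisible(x)
}

#' Extract the recurrent core of a network
#'
#' The recurrent core ("reservoir") is the induced subgraph on all nodes that
#' lie on at least one directed cycle: members of a strongly connected
#' component of size two or more, plus nodes bearing a self-loop.  These are
#' the nodes that can sustain recurrent dynamics.
#'
#' @param g A `signed_digraph`.
#' @return The induced `signed_digraph` on cycle-participating nodes (empty
#'   for acyclic input).
#' @export
extract_recurrent_core <- function(g) {
  if (n_nodes(g) == 0L) return(g)
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = "strong")
  in_big_scc <- comp$csize[comp$membership] >= 2L
  has_self <- g$nodes %in% g$edges$from[g$edges$from == g$edges$to]
  keep <- g$nodes[in_big_scc[match(g$nodes, igraph::V(ig)$name)] | has_self]
  induced_subgraph_signed(g, keep)
}

# TRUE iff the graph equals its own recurrent core
is_recurrent <- function(g) {
  core <- extract_recurrent_core(g)
  n_nodes(core) == n_nodes(g)
}

is_weakly_connected <- function(g) {
  if (n_nodes(g) == 0L) return(FALSE)
  igraph::is_connected(as_igraph(g), mode = "weak")
}

#' Giant connected component
#'
#' Induced subgraph on the largest connected component, weakly connected by
#' default.  Ties between equally large components are broken in favour of
#' the component containing the lexicographically smallest node id.
#'
#' @param g A non-empty `signed_digraph`.
#' @param mode `"weak"` (default) or `"strong"` connectivity.
#' @return The induced `signed_digraph` on the selected component.
#' @export
giant_component <- function(g, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  if (n_nodes(g) == 0L) stop("empty graph has no components")
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = mode)
  membership <- comp$membership[match(g$nodes, igraph::V(ig)$name)]
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1L) {
    # smallest node id among candidate components wins
    mins <- vapply(biggest, function(b) min(sort(g$nodes[membership == b])),
                   character(1))
    biggest <- biggest[order(mins)][1]
  }
  induced_subgraph_signed(g, g$nodes[membership == biggest])
}
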
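#' Random signed digraph (uniform null model)
#'
#' Draws exactly `n_edges` distinct ordered pairs uniformly without
#' replacement from all permitted pairs, then assigns sign -1 to exactly
#' `round(repression_fraction * n_edges)` uniformly chosen edges.  This is
#' the null ensemble used throughout for motif z-scores and normalised motif
#' counts: node and edge counts are matched, nothing else is constrained.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of directed edges.
#' @param repression_fraction Proportion of repressing (-1) edges; the count
#'   is exact, not Bernoulli, so sign composition carries no sampling noise.
#' @param allow_self_loops Whether self-edges are permitted (default `TRUE`,
#'   matching the null model).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [signed_digraph()] with nodes `g0001`, `g0002`, ...
#' @export
random_signed_digraph <- function(n_nodes, n_edges, repression_fraction = 0,
                                  allow_self_loops = TRUE, seed = 1L) {
  stopifnot(n_nodes >= 0, n_edges >= 0,
            repression_fraction >= 0, repression_fraction <= 1)
  max_pairs <- if (allow_self_loops) n_nodes^2 else n_nodes * (n_nodes - 1)
  if (n_edges > max_pairs) {
    stop(sprintf("cannot place %d distinct edges on %d nodes", n_edges, n_nodes))
  }
  width <- max(4L, nchar(as.character(n_nodes)))
  nodes <- sprintf(paste0("g%0", width, "d"), seq_len(n_nodes))
  if (n_edges == 0L) return(signed_digraph(nodes))
  withr::with_seed(seed, {
    idx <- sample.int(max_pairs, n_edges)
    if (allow_self_loops) {
      from <- (idx - 1L) %/% n_nodes + 1L
      to <- (idx - 1L) %% n_nodes + 1L
    } else {
      from <- (idx - 1L) %/% (n_nodes - 1L) + 1L
      off <- (idx - 1L) %% (n_nodes - 1L) + 1L
      to <- off + (off >= from)
    }
    sgn <- rep(1L, n_edges)
    n_neg <- round(repression_fraction * n_edges)
    if (n_neg > 0L) sgn[sample.int(n_edges, n_neg)] <- -1L
  })
  signed_digraph(nodes, data.frame(from = nodes[from], to = nodes[to],
                                   sign = sgn))
}

#' Surrogate of the E. coli recurrent core
#'
#' Generates a random signed digraph with the connectivity statistics of the
#' recurrent core of the \emph{E. coli} transcriptional network: 70 nodes,
#' 317 edges, 41\% repression.  Draws are repeated until the graph is fully
#' recurrent (equals its own recurrent core) and weakly connected, so it can
#' serve as a single reservoir.
#'
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param n_nodes,n_edges,repression_fraction Target statistics; defaults are
#'   the published core values.
#' @param max_tries Resampling budget before giving up.
#' @return A fully recurrent, weakly connected [signed_digraph()].
#' @export
ecoli_core_surrogate <- function(seed = 1L, n_nodes = 70L, n_edges = 317L,
                                 repression_fraction = 0.41,
                                 max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    g <- random_signed_digraph(n_nodes, n_edges, repression_fraction,
                               allow_self_loops = TRUE,
                               seed = sub_seed(seed, i, stream = 11L))
    if (is_recurrent(g) && is_weakly_connected(g)) return(g)
  }
  stop("could not draw a fully recurrent, weakly connected surrogate; ",
       "increase max_tries or edge density")
}

#' Re-randomise edge signs at a fixed repression fraction
#'
#' Keeps the topology of `g` and assigns sign -1 to exactly
#' `round(repression_fraction * m)` uniformly chosen edges, +1 to the rest.
#' This is the operation behind activation/repression-balance sweeps.
#'
#' @param g A `signed_digraph` with at least one edge.
#' @param repression_fraction Target proportion of repressing edges.
#' @param seed Integer seed.
#' @return A `signed_digraph` with identical nodes and edge pairs.
#' @export
randomize_signs <- function(g, repression_fraction, seed = 1L) {
  m <- n_edges(g)
  if (m == 0L) stop("graph has no edges to sign")
  stopifnot(repression_fraction >= 0, repression_fraction <= 1)
  sgn <- rep(1L, m)
  n_neg <- round(repression_fraction * m)
  if (n_neg > 0L) {
    withr::with_seed(seed, sgn[sample.int(m, n_neg)] <- -1L)
  }
  e <- g$edges
  e$sign <- sgn
  signed_digraph(g$nodes, e)
}

#' Activating delay chain
#'
#' A near-delay-line fixture: nodes v1 -> v2 -> ... -> vL with all-activating
#' edges plus a self-loop on v1, so the chain survives recurrent-core
#' extraction and has nonzero spectral radius.
#'
#' @param L Chain length (>= 1).
#' @return A `signed_digraph` with `L` nodes and `L` edges.
#' @export
delay_chain <- function(L) {
  stopifnot(L >= 1)
  nodes <- sprintf("v%d", seq_len(L))
  from <- c(nodes[1], nodes[-L])
  to <- c(nodes[1], if (L > 1) nodes[-1])
  signed_digraph(nodes, data.frame(from = from, to = to,
                                   sign = rep(1L, length(from))))
}

#' Random graph with planted memory motifs
#'
#' Draws a uniform random base graph, then plants the requested number of
#' extra self-loops, mutual-regulation pairs and feedforward loops on
#' uniformly chosen nodes.  Planted instances are rejected and resampled if
#' they already exist, so each planting adds at least one new instance of its
#' motif (planted FFL edges may create additional incidental FFLs).  The
#' final edge count is whatever the plantings produce.
#'
#' @inheritParams random_signed_digraph
#' @param extra_self_loops,extra_mutual,extra_ffl Number of motif instances
#'   to plant on top of the random base.
#' @param max_tries Rejection-sampling budget per planted instance.
#' @return A `signed_digraph`.
#' @export
motif_enriched_graph <- function(n_nodes, n_edges, repression_fraction = 0,
                                 allow_self_loops = TRUE,
                                 extra_self_loops = 0L, extra_mutual = 0L,
                                 extra_ffl = 0L, seed = 1L,
                                 max_tries = 1000L) {
  g <- random_signed_digraph(n_nodes, n_edges, repression_fraction,
                             allow_self_loops, seed = sub_seed(seed, 1L, 21L))
  nodes <- g$nodes
  edges <- g$edges
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  draw_sign <- function() if (stats::runif(1) < repression_fraction) -1L else 1L
  add_edge <- function(a, b) {
    if (!has_edge(a, b)) {
      edges <<- rbind(edges, data.frame(from = a, to = b, sign = draw_sign()))
    }
  }
  plant <- function(n_wanted, propose, exists) {
    for (j in seq_len(n_wanted)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- propose()
        if (!exists(cand)) {
          lapply(cand$add, function(ab) add_edge(ab[1], ab[2]))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not plant requested motif without duplication")
    }
  }
  withr::with_seed(sub_seed(seed, 2L, 21L), {
    plant(extra_self_loops,
          propose = function() {
            v <- sample(nodes, 1L)
            list(v = v, add = list(c(v, v)))
          },
          exists = function(cand) has_edge(cand$v, cand$v))
    plant(extra_mutual,
          propose = function() {
            p <- sample(nodes, 2L)
            list(p = p, add = list(c(p[1], p[2]), c(p[2], p[1])))
          },
          exists = function(cand) has_edge(cand$p[1], cand$p[2]) &&
            has_edge(cand$p[2], cand$p[1]))
    plant(extra_ffl,
          propose = function() {
            t3 <- sample(nodes, 3L)
            list(t3 = t3, add = list(c(t3[1], t3[2]), c(t3[2], t3[3]),
                                     c(t3[1], t3[3])))
          },
          exists = function(cand) has_edge(cand$t3[1], cand$t3[2]) &&
            has_edge(cand$t3[2], cand$t3[3]) && has_edge(cand$t3[1], cand$t3[3]))
  })
  signed_digraph(nodes, edges)
}
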
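#' Memory motif counters
#'
#' The three smallest feedback/feedforward circuits ("memory motifs"):
#' self-loops, mutual-regulation pairs and feedforward loops.  All counts are
#' sign-blind.
#'
#' * `count_self_loops(g)`: edges (v, v).
#' * `count_mutual_regulation(g)`: unordered pairs \{i, j\}, i != j, with
#'   both i -> j and j -> i present.
#' * `count_ffl(g)`: ordered triples (x, y, z) of distinct nodes with
#'   x -> y, y -> z and x -> z all present (so a fully bidirectionally
#'   connected triangle yields 6).
#'
#' @param g A `signed_digraph`.
#' @return A non-negative integer count.
#' @name motif_counts
NULL

#' @rdname motif_counts
#' @export
count_self_loops <- function(g) {
  sum(g$edges$from == g$edges$to)
}

#' @rdname motif_counts
#' @export
count_mutual_regulation <- function(g) {
  ei <- edge_indices(g)
  n <- n_nodes(g)
  if (length(ei$from) == 0L) return(0L)
  id <- (ei$from - 1) * n + ei$to
  rev <- (ei$to - 1) * n + ei$from
  # each mutual pair contributes exactly one edge with from < to
  sum(ei$from < ei$to & rev %in% id)
}

#' @rdname motif_counts
#' @export
count_ffl <- function(g) {
  ei <- edge_indices(g)
  n <- n_nodes(g)
  off <- ei$from != ei$to
  if (sum(off) < 3L) return(0L)
  A0 <- Matrix::sparseMatrix(i = ei$from[off], j = ei$to[off], x = 1,
                             dims = c(n, n))
  # paths x->y->z with distinct endpoints, intersected with direct edges x->z
  as.integer(sum((A0 %*% A0) * A0))
}

#' Full motif census
#'
#' @param g A `signed_digraph`.
#' @return Named integer vector with elements `self_loops`,
#'   `mutual_regulation` and `ffl`.
#' @export
motif_census <- function(g) {
  c(self_loops = count_self_loops(g),
    mutual_regulation = count_mutual_regulation(g),
    ffl = count_ffl(g))
}

# analytic expectations under the uniform null (m edges without replacement
# among the n^2 ordered pairs, self-loops allowed)
analytic_null_means <- function(n, m) {
  np <- as.numeric(n)^2
  mm <- as.numeric(m)
  c(self_loops = mm * n / np,
    mutual_regulation = n * (n - 1) / 2 * mm * (mm - 1) / (np * (np - 1)),
    ffl = as.numeric(n) * (n - 1) * (n - 2) *
      mm * (mm - 1) * (mm - 2) / (np * (np - 1) * (np - 2)))
}

null_census_ensemble <- function(g, n_rand, seed) {
  n <- n_nodes(g); m <- n_edges(g)
  counts <- matrix(0, n_rand, 3L,
                   dimnames = list(NULL, c("self_loops", "mutual_regulation",
                                           "ffl")))
  for (i in seq_len(n_rand)) {
    r <- random_signed_digraph(n, m, allow_self_loops = TRUE,
                               seed = sub_seed(seed, i, 71L))
    counts[i, ] <- motif_census(r)
  }
  counts
}

#' Motif z-scores against the uniform null ensemble
#'
#' Compares the motif census of `g` to an ensemble of random digraphs with
#' the same number of nodes and edges (self-loops allowed): z =
#' (N_real - <N>_rand) / sigma_rand, with the sample (n - 1) standard
#' deviation.  A zero null s.d. yields z = +/-Inf and sets the `degenerate`
#' flag.
#'
#' @param g A `signed_digraph`.
#' @param n_rand Ensemble size (default 1000).
#' @param seed Integer seed for the ensemble.
#' @return A data frame of class `motif_zscores` with one row per motif and
#'   columns `motif`, `real`, `null_mean`, `null_sd`, `zscore`,
#'   `degenerate`.
#' @export
motif_zscores <- function(g, n_rand = 1000L, seed = 1L) {
  stopifnot(n_rand >= 2)
  real <- motif_census(g)
  counts <- null_census_ensemble(g, n_rand, seed)
  mu <- colMeans(counts)
  sdev <- apply(counts, 2, stats::sd)
  z <- ifelse(sdev == 0,
              ifelse(real == mu, NaN, sign(real - mu) * Inf),
              (real - mu) / sdev)
  out <- data.frame(motif = names(real), real = as.integer(real),
                    null_mean = unname(mu), null_sd = unname(sdev),
                    zscore = unname(z), degenerate = unname(sdev == 0),
                    row.names = NULL)
  class(out) <- c("motif_zscores", "data.frame")
  out
}

#' Motif counts normalised by the null expectation
#'
#' Real count divided by the null-ensemble mean count, per motif.  If the
#' sampled null mean is zero the analytic uniform-model expectation is used
#' instead, so the normalisation never divides by zero.
#'
#' @inheritParams motif_zscores
#' @param n_rand Ensemble size (default 1000).
#' @return Named numeric vector (`self_loops`, `mutual_regulation`, `ffl`).
#' @export
normalized_motif_counts <- function(g, n_rand = 1000L, seed = 1L) {
  stopifnot(n_rand >= 1)
  real <- motif_census(g)
  mu <- colMeans(null_census_ensemble(g, n_rand, seed))
  analytic <- analytic_null_means(n_nodes(g), n_edges(g))
  denom <- ifelse(mu == 0, analytic, mu)
  ifelse(real == 0, 0, real / denom)
}
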
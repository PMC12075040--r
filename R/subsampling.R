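#' Sample a library of sub-reservoirs by iterated node removal
#'
#' Starting from a fully recurrent reservoir, repeatedly (i) deletes one
#' uniformly chosen node, (ii) prunes the result back to its recurrent core
#' with [extract_recurrent_core()], and (iii) keeps the giant weakly
#' connected component; every intermediate graph with at least `min_size`
#' nodes is recorded.  The process stops when the graph falls below
#' `min_size` or empties, and is repeated `n_runs` times from the full
#' reservoir.  Duplicates across runs are retained.
#'
#' @param core A non-empty, fully recurrent `signed_digraph`.
#' @param n_runs Number of independent removal trajectories (default 100).
#' @param min_size Smallest recorded sub-reservoir (default 3).
#' @param seed Integer seed; the library is reproducible given the seed.
#' @param record_initial Also record the unmodified parent at step 0 of each
#'   run (default `FALSE`).
#' @return An object of class `subreservoir_library`: list with `members`
#'   (list of `signed_digraph`s), `manifest` (data frame: id, run, step, n,
#'   m, self_loops, mutual_regulation, ffl) and `seed`.
#' @export
sample_subreservoirs <- function(core, n_runs = 100L, min_size = 3L,
                                 seed = 1L, record_initial = FALSE) {
  if (n_nodes(core) == 0L) stop("empty starting reservoir")
  if (!is_recurrent(core)) {
    stop("starting graph is not fully recurrent; run extract_recurrent_core first")
  }
  members <- list()
  rows <- list()
  idx <- 0L
  record <- function(g, run, step) {
    idx <<- idx + 1L
    members[[idx]] <<- g
    cen <- motif_census(g)
    rows[[idx]] <<- data.frame(id = idx, run = run, step = step,
                               n = n_nodes(g), m = n_edges(g),
                               self_loops = cen[["self_loops"]],
                               mutual_regulation = cen[["mutual_regulation"]],
                               ffl = cen[["ffl"]])
  }
  for (run in seq_len(n_runs)) {
    g <- core
    if (record_initial) record(g, run, 0L)
    step <- 0L
    repeat {
      step <- step + 1L
      victim <- withr::with_seed(sub_seed(seed, run * 100000L + step, 81L),
                                 sample(g$nodes, 1L))
      g <- induced_subgraph_signed(g, setdiff(g$nodes, victim))
      g <- extract_recurrent_core(g)
      if (n_nodes(g) == 0L) break
      g <- giant_component(g, mode = "weak")
      if (n_nodes(g) < min_size) break
      record(g, run, step)
    }
  }
  structure(list(members = members,
                 manifest = do.call(rbind, rows) %||%
                   data.frame(id = integer(), run = integer(),
                              step = integer(), n = integer(), m = integer(),
                              self_loops = integer(),
                              mutual_regulation = integer(),
                              ffl = integer()),
                 seed = seed),
            class = "subreservoir_library")
}

#' @export
print.subreservoir_library <- function(x, ...) {
  sizes <- x$manifest$n
  cat(sprintf("subreservoir_library: %d members%s\n", length(x$members),
              if (length(sizes)) sprintf(", sizes %d-%d", min(sizes),
                                         max(sizes)) else ""))
  invisible(x)
}

#' @export
length.subreservoir_library <- function(x) length(x$members)

#' Keep values within a band around the mean
#'
#' The performance-outlier filter: `mask[i]` is `TRUE` when `values[i]` lies
#' within `width` sample standard deviations of the mean.  A zero standard
#' deviation keeps everything.
#'
#' @param values Numeric vector (length >= 2).
#' @param width Band half-width in standard deviations (default 1.25).
#' @return Logical mask of the same length.
#' @export
performance_filter <- function(values, width = 1.25) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= width * s
}
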
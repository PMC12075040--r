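# Orchestration of the headline experiments.  Every sweep derives one
# sub-seed per realization from the master seed, so results are exactly
# reproducible from (arguments, seed); provenance columns (seed, gamma,
# washout) are carried on every output table.

proto_with_seed <- function(protocol, seed) {
  protocol$seed <- as.integer(seed)
  protocol
}

#' Spectral-radius sweep: Lyapunov exponent and memory capacity
#'
#' For each spectral radius in `rho_grid`, builds `n_real` reservoir
#' realizations (fresh recurrent weights, input weights and input series),
#' estimates the maximum Lyapunov exponent and the critical memory capacity
#' of each, and reports their mean and standard deviation.  The edge of
#' chaos is where the mean exponent crosses zero; memory capacity peaks in
#' its vicinity.
#'
#' @param g A `signed_digraph` (the reservoir topology).
#' @param rho_grid Spectral radii to scan.
#' @param n_real Realizations per grid point.
#' @param protocol A [task_protocol()] template (its seed is replaced per
#'   realization).
#' @param k_max Largest delay scanned for k*.
#' @param mle An [mle_config()] template.
#' @param mle_input `"uniform"` (default; the same U(-1, 1) drive as the
#'   memory task) or `"zero"` for the autonomous exponent.
#' @param gamma Ridge coefficient.
#' @param seed Master seed.
#' @return A data frame with one row per rho: `rho`, `lambda_mean`,
#'   `lambda_sd`, `kstar_mean`, `kstar_sd`, `n`, plus provenance columns.
#' @export
sweep_spectral_radius <- function(g, rho_grid = seq(0.1, 2, by = 0.1),
                                  n_real = 50L,
                                  protocol = task_protocol(), k_max = 30L,
                                  mle = mle_config(),
                                  mle_input = c("uniform", "zero"),
                                  gamma = 1e-6, seed = 1L) {
  mle_input <- match.arg(mle_input)
  stopifnot(length(rho_grid) >= 1, n_real >= 1)
  rows <- lapply(seq_along(rho_grid), function(j) {
    rho <- rho_grid[j]
    lam <- numeric(n_real)
    kst <- numeric(n_real)
    for (i in seq_len(n_real)) {
      # common random numbers across the grid: realization i shares its
      # weights, drive and series at every rho, so grid contrasts are paired
      s_i <- sub_seed(seed, i, 91L)
      sys <- build_reservoir(g, rho, n_inputs = 1L, seed = s_i)
      cfg <- mle
      cfg$seed <- s_i
      lam[i] <- max_lyapunov(sys, cfg = cfg, input = mle_input)
      kst[i] <- critical_memory_capacity(sys, k_max,
                                         proto_with_seed(protocol, s_i),
                                         gamma)$score
    }
    data.frame(rho = rho, lambda_mean = mean(lam), lambda_sd = stats::sd(lam),
               kstar_mean = mean(kst), kstar_sd = stats::sd(kst), n = n_real)
  })
  out <- do.call(rbind, rows)
  out$seed <- seed
  out$gamma <- gamma
  out$washout <- protocol$washout
  out
}

#' Repression-fraction sweep: NARMA error and memory capacity
#'
#' For each repression fraction, re-signs the edges of `g` (exact sign
#' counts) per realization and runs the NARMA-10 and critical memory
#' capacity tasks at fixed spectral radius.  The unmodified network's own
#' scores are appended as a reference row (`reference = TRUE`) at its native
#' repression fraction.
#'
#' @inheritParams sweep_spectral_radius
#' @param fractions Repression fractions to scan.
#' @param rho Spectral radius used throughout (default 0.95).
#' @param tasks Character subset of `c("narma", "mc")`.
#' @return A data frame with one row per fraction plus the reference row:
#'   `repression_fraction`, `narma_mean`, `narma_sd`, `kstar_mean`,
#'   `kstar_sd`, `n`, `reference`, plus provenance columns.
#' @export
sweep_repression <- function(g, fractions = seq(0, 1, by = 0.1),
                             n_real = 100L, rho = 0.95,
                             protocol = task_protocol(), k_max = 30L,
                             gamma = 1e-6, seed = 1L,
                             tasks = c("narma", "mc")) {
  stopifnot(length(fractions) >= 1, n_real >= 1)
  tasks <- match.arg(tasks, several.ok = TRUE)
  score_point <- function(graph_for) {
    nar <- rep(NA_real_, n_real)
    kst <- rep(NA_real_, n_real)
    for (i in seq_len(n_real)) {
      # paired realizations across fractions (common random numbers)
      s_i <- sub_seed(seed, i, 92L)
      gi <- graph_for(s_i)
      sys <- build_reservoir(gi, rho, n_inputs = 1L, seed = s_i)
      pr <- proto_with_seed(protocol, s_i)
      if ("narma" %in% tasks) nar[i] <- narma10_task(sys, pr, gamma)$score
      if ("mc" %in% tasks) {
        kst[i] <- critical_memory_capacity(sys, k_max, pr, gamma)$score
      }
    }
    data.frame(narma_mean = mean(nar), narma_sd = stats::sd(nar),
               kstar_mean = mean(kst), kstar_sd = stats::sd(kst), n = n_real)
  }
  rows <- lapply(seq_along(fractions), function(j) {
    f <- fractions[j]
    cbind(data.frame(repression_fraction = f),
          score_point(function(s) randomize_signs(g, f, seed = s)),
          data.frame(reference = FALSE))
  })
  ref <- cbind(data.frame(repression_fraction = repression_fraction(g)),
               score_point(function(s) g),
               data.frame(reference = TRUE))
  out <- rbind(do.call(rbind, rows), ref)
  out$seed <- seed
  out$gamma <- gamma
  out$washout <- protocol$washout
  out
}

#' Motif content versus memory capacity across a sub-reservoir library
#'
#' For every library member, computes its raw and null-normalised motif
#' counts and its mean critical memory capacity over `n_real` reservoir
#' realizations.  Also returns threshold splits: the k* values of members
#' whose raw count of each motif falls below each threshold.
#'
#' @param library A [sample_subreservoirs()] result.
#' @inheritParams sweep_spectral_radius
#' @param n_rand Null-ensemble size for the normalisation (default 1000).
#' @param rho Spectral radius (default 0.95).
#' @param thresholds Raw-count thresholds for the split distributions
#'   (defaults 28 and 55).
#' @return A list with `table` (one row per member: id, n, m, raw and
#'   normalised counts, `kstar_mean`, `kstar_sd`, provenance) and `splits`
#'   (data frame: motif, threshold, id, kstar_mean).
#' @export
motif_memory_analysis <- function(library, n_real = 50L, n_rand = 1000L,
                                  rho = 0.95, protocol = task_protocol(),
                                  k_max = 30L, gamma = 1e-6,
                                  thresholds = c(28L, 55L), seed = 1L) {
  if (length(library$members) == 0L) stop("empty sub-reservoir library")
  man <- library$manifest
  norm <- matrix(NA_real_, nrow(man), 3L)
  kmean <- numeric(nrow(man))
  ksd <- numeric(nrow(man))
  for (r in seq_len(nrow(man))) {
    g <- library$members[[r]]
    norm[r, ] <- normalized_motif_counts(g, n_rand,
                                         seed = sub_seed(seed, r, 93L))
    kst <- numeric(n_real)
    for (i in seq_len(n_real)) {
      s_i <- sub_seed(seed, r * 10000L + i, 94L)
      sys <- build_reservoir(g, rho, n_inputs = 1L, seed = s_i)
      kst[i] <- critical_memory_capacity(sys, k_max,
                                         proto_with_seed(protocol, s_i),
                                         gamma)$score
    }
    kmean[r] <- mean(kst)
    ksd[r] <- stats::sd(kst)
  }
  tab <- cbind(man,
               data.frame(norm_self_loops = norm[, 1],
                          norm_mutual_regulation = norm[, 2],
                          norm_ffl = norm[, 3],
                          kstar_mean = kmean, kstar_sd = ksd,
                          seed = seed, gamma = gamma,
                          washout = protocol$washout))
  splits <- do.call(rbind, lapply(c("self_loops", "mutual_regulation", "ffl"),
    function(motif) {
      do.call(rbind, lapply(thresholds, function(th) {
        sel <- man[[motif]] < th
        if (!any(sel)) return(NULL)
        data.frame(motif = motif, threshold = th, id = man$id[sel],
                   kstar_mean = kmean[sel])
      }))
    }))
  list(table = tab, splits = splits)
}

#' Size-performance analysis across a sub-reservoir library
#'
#' For every library member, computes the mean critical memory capacity,
#' NARMA-10 NRMSE and delayed-AND NRMSE over `n_real` realizations, applies
#' the outlier filter ([performance_filter()]) per task, and flags
#' Pareto-efficient members: those not dominated on (small size, high k*,
#' low NARMA error, low delayed-AND error) by any other member.
#'
#' @param library A [sample_subreservoirs()] result.
#' @inheritParams sweep_spectral_radius
#' @param rho Spectral radius (default 0.95).
#' @param dand_protocol Protocol for the delayed AND task (600-step series
#'   by default).
#' @param width Filter half-width in standard deviations (default 1.25).
#' @return A data frame with one row per member: id, n, m, task means and
#'   s.d.s, `keep_*` filter masks, `pareto` flag and provenance columns.
#' @export
size_performance <- function(library, n_real = 50L, rho = 0.95,
                             protocol = task_protocol(), k_max = 30L,
                             dand_protocol = task_protocol(series_length = 600L),
                             gamma = 1e-6, width = 1.25, seed = 1L) {
  if (length(library$members) == 0L) stop("empty sub-reservoir library")
  man <- library$manifest
  nr <- nrow(man)
  kmean <- numeric(nr); narma <- numeric(nr); dand <- numeric(nr)
  ksd <- numeric(nr); narsd <- numeric(nr); dansd <- numeric(nr)
  for (r in seq_len(nr)) {
    g <- library$members[[r]]
    kst <- numeric(n_real); nar <- numeric(n_real); dnd <- numeric(n_real)
    for (i in seq_len(n_real)) {
      s_i <- sub_seed(seed, r * 10000L + i, 95L)
      sys1 <- build_reservoir(g, rho, n_inputs = 1L, seed = s_i)
      sys2 <- build_reservoir(g, rho, n_inputs = 2L, seed = s_i)
      pr <- proto_with_seed(protocol, s_i)
      kst[i] <- critical_memory_capacity(sys1, k_max, pr, gamma)$score
      nar[i] <- narma10_task(sys1, pr, gamma)$score
      dnd[i] <- delayed_and_task(sys2, proto_with_seed(dand_protocol, s_i),
                                 gamma = gamma)$score
    }
    kmean[r] <- mean(kst); ksd[r] <- stats::sd(kst)
    narma[r] <- mean(nar); narsd[r] <- stats::sd(nar)
    dand[r] <- mean(dnd); dansd[r] <- stats::sd(dnd)
  }
  keep_k <- performance_filter(kmean, width)
  keep_n <- performance_filter(narma, width)
  keep_d <- performance_filter(dand, width)
  # Pareto efficiency: minimize size and both errors, maximize k*
  pareto <- vapply(seq_len(nr), function(i) {
    dominated <- (man$n <= man$n[i]) & (kmean >= kmean[i]) &
      (narma <= narma[i]) & (dand <= dand[i]) &
      ((man$n < man$n[i]) | (kmean > kmean[i]) |
         (narma < narma[i]) | (dand < dand[i]))
    !any(dominated)
  }, logical(1))
  cbind(man[, c("id", "run", "step", "n", "m")],
        data.frame(kstar_mean = kmean, kstar_sd = ksd,
                   narma_mean = narma, narma_sd = narsd,
                   dand_mean = dand, dand_sd = dansd,
                   keep_kstar = keep_k, keep_narma = keep_n,
                   keep_dand = keep_d, pareto = pareto,
                   seed = seed, gamma = gamma,
                   washout = protocol$washout))
}
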
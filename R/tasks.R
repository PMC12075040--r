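#' Benchmark task protocol
#'
#' Shared experimental protocol for the benchmark tasks: a number of
#' independent input-output series, of which all but the last train the
#' readout and the last one is held out for scoring.  The first `washout`
#' steps of every series are discarded from both states and targets before
#' fitting and scoring.
#'
#' @param n_series Number of series (default 10).
#' @param series_length Steps per series (default 1000).
#' @param n_train Number of training series (default 9; the remaining series
#'   are used for testing, of which the last is scored).
#' @param washout Leading transient steps discarded per series (default 100).
#' @param seed Integer seed governing all series generation.
#' @return A list of class `task_protocol`.
#' @export
task_protocol <- function(n_series = 10L, series_length = 1000L,
                          n_train = 9L, washout = 100L, seed = 1L) {
  stopifnot(n_train < n_series, series_length > washout, washout >= 0)
  structure(list(n_series = as.integer(n_series),
                 series_length = as.integer(series_length),
                 n_train = as.integer(n_train),
                 washout = as.integer(washout),
                 seed = as.integer(seed)),
            class = "task_protocol")
}

task_result <- function(score, task, parameters, seed, details = NULL) {
  structure(list(score = score, task = task, parameters = parameters,
                 seed = seed, details = details),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("task_result [%s]: score = %g (seed %d)\n",
              x$task, x$score, x$seed))
  invisible(x)
}

#' Memory coefficient between a readout output and a delayed input
#'
#' The per-delay memory statistic MC_k = cov^2(u_\{t-k\}, y_t) /
#' (sigma^2(u_\{t-k\}) sigma^2(y_t)), i.e. the squared Pearson correlation
#' between the delayed input and the output, bounded in [0, 1].
#'
#' @param y Readout output series.
#' @param u_delayed The k-step-delayed input series, aligned with `y`.
#' @return MC in [0, 1]; a degenerate (zero-variance) series scores 0 with a
#'   warning.
#' @export
memory_coefficient <- function(y, u_delayed) {
  stopifnot(length(y) == length(u_delayed))
  if (stats::sd(y) == 0 || stats::sd(u_delayed) == 0) {
    warning("zero-variance series; memory coefficient set to 0")
    return(0)
  }
  stats::cor(u_delayed, y)^2
}

#' Largest delay with memory above threshold
#'
#' Reduces a profile MC_1, MC_2, ... to the critical memory capacity k*: by
#' default the largest k with MC_k > threshold even across non-monotone
#' profiles, or the last delay before the first crossing with
#' `rule = "first"`.
#'
#' @param mc Numeric vector of memory coefficients for k = 1, 2, ...
#' @param threshold Memory threshold (default 0.5).
#' @param rule `"max"` (default) or `"first"`.
#' @return Integer k* (0 if no delay clears the threshold).
#' @export
critical_k <- function(mc, threshold = 0.5, rule = c("max", "first")) {
  rule <- match.arg(rule)
  above <- which(mc > threshold)
  if (length(above) == 0L) return(0L)
  if (rule == "max") return(max(above))
  below <- which(mc <= threshold)
  if (length(below) == 0L) length(mc) else min(below) - 1L
}

# Shared machinery: run the reservoir over the protocol's uniform input
# series once and score MC_k for every k in 1..k_max.  Targets are the
# delayed inputs, so all delays reuse the same state matrices.
mc_profile <- function(sys, k_max, protocol, gamma = 1e-6) {
  p <- protocol
  if (k_max > p$washout) {
    stop("k_max must not exceed the washout (delayed targets would be undefined)")
  }
  keep <- (p$washout + 1L):p$series_length
  us <- vector("list", p$n_series)
  Xs <- vector("list", p$n_series)
  for (s in seq_len(p$n_series)) {
    us[[s]] <- withr::with_seed(sub_seed(p$seed, s, 31L),
                                stats::runif(p$series_length, -1, 1))
    X <- run_reservoir(sys, us[[s]])
    Xs[[s]] <- X[, keep, drop = FALSE]
  }
  train <- seq_len(p$n_train)
  test <- p$n_series
  Xtr <- do.call(cbind, Xs[train])
  n <- nrow(Xtr)
  A <- tcrossprod(Xtr) + gamma^2 * diag(n)
  # factor once, reuse across delays (targets change, states do not)
  R <- tryCatch(chol(A), error = function(e) NULL)
  qrA <- if (is.null(R)) {
    if (gamma == 0) {
      stop("state Gram matrix is singular with gamma = 0; use gamma > 0",
           call. = FALSE)
    }
    qr(rbind(t(Xtr), diag(gamma, n)), LAPACK = TRUE)
  }
  mc <- numeric(k_max)
  for (k in seq_len(k_max)) {
    ytr <- unlist(lapply(us[train], function(u) u[keep - k]),
                  use.names = FALSE)
    w <- if (is.null(R)) {
      qr.coef(qrA, c(ytr, numeric(n)))
    } else {
      backsolve(R, forwardsolve(t(R), Xtr %*% ytr))
    }
    yhat <- as.numeric(crossprod(w, Xs[[test]]))
    mc[k] <- memory_coefficient(yhat, us[[test]][keep - k])
  }
  mc
}

#' Memory capacity at a single delay
#'
#' Trains a ridge readout to reconstruct the input delayed by `k` steps from
#' the instantaneous reservoir state (input drawn from U(-1, 1)), and scores
#' the held-out series with [memory_coefficient()].
#'
#' @param sys A single-input `grn_reservoir`.
#' @param k Delay (>= 1, at most the protocol washout).
#' @param protocol A [task_protocol()].
#' @param gamma Ridge coefficient.
#' @return A `task_result` whose `score` is MC_k in [0, 1].
#' @export
memory_capacity_at_k <- function(sys, k, protocol = task_protocol(),
                                 gamma = 1e-6) {
  stopifnot(k >= 1)
  mc <- mc_profile(sys, k, protocol, gamma)
  task_result(mc[k], "memory_capacity",
              list(k = k, gamma = gamma, protocol = unclass(protocol)),
              protocol$seed)
}

#' Critical memory capacity
#'
#' Scans delays k = 1..k_max and returns the largest delay whose memory
#' coefficient exceeds 0.5 on the held-out series (0 if none does).  The full
#' MC profile is returned in `details$profile`.
#'
#' @inheritParams memory_capacity_at_k
#' @param k_max Largest delay scanned (default 30).
#' @param rule Passed to [critical_k()].
#' @return A `task_result` whose `score` is the integer k*.
#' @export
critical_memory_capacity <- function(sys, k_max = 30L,
                                     protocol = task_protocol(),
                                     gamma = 1e-6, rule = "max") {
  stopifnot(k_max >= 1)
  mc <- mc_profile(sys, k_max, protocol, gamma)
  task_result(critical_k(mc, rule = rule), "critical_memory_capacity",
              list(k_max = k_max, gamma = gamma, rule = rule,
                   protocol = unclass(protocol)),
              protocol$seed, details = list(profile = mc))
}

#' Generate a 10th-order NARMA series
#'
#' Iterates the 10th-order nonlinear autoregressive moving-average system
#' y(t+1) = 0.3 y(t) + 0.05 y(t) sum_\{i=0\}^\{9\} y(t-i) + 1.5 s(t-9) s(t)
#' + 0.1 with inputs s(t) ~ U(0, 0.5) and zero initial history.  The
#' recursion occasionally diverges for unlucky input draws; such series are
#' resampled with the next derived sub-seed and the event is logged via
#' `message()`.
#'
#' @param length Series length (> 10).
#' @param seed Integer seed.
#' @param max_tries Resampling budget for divergent draws.
#' @return List with `input` (s), `output` (y) and `resampled` (number of
#'   divergent draws discarded).
#' @export
narma10_series <- function(length, seed = 1L, max_tries = 100L) {
  stopifnot(length > 10)
  for (try in seq_len(max_tries)) {
    s <- withr::with_seed(sub_seed(seed, try, 41L),
                          stats::runif(length, 0, 0.5))
    y <- numeric(length)
    y[1] <- 0.1  # from zero history: all terms but the constant vanish
    diverged <- FALSE
    for (t in seq_len(length - 1L)) {
      acc <- sum(y[max(1L, t - 9L):t])
      s_tm9 <- if (t > 9L) s[t - 9L] else 0
      y[t + 1L] <- 0.3 * y[t] + 0.05 * y[t] * acc + 1.5 * s_tm9 * s[t] + 0.1
      if (!is.finite(y[t + 1L]) || abs(y[t + 1L]) > 10) {
        diverged <- TRUE
        break
      }
    }
    if (!diverged) {
      return(list(input = s, output = y, resampled = try - 1L))
    }
    message("NARMA series diverged; resampling with next sub-seed")
  }
  stop("NARMA series diverged for all attempted seeds")
}

#' 10th-order NARMA benchmark task
#'
#' Drives the reservoir with the NARMA input s(t) through a single input
#' node, trains a ridge readout on the NARMA output over the training
#' series, and scores the held-out series with [nrmse()].
#'
#' @inheritParams memory_capacity_at_k
#' @return A `task_result` whose `score` is the test NRMSE (>= 0).
#' @export
narma10_task <- function(sys, protocol = task_protocol(), gamma = 1e-6) {
  p <- protocol
  keep <- (p$washout + 1L):p$series_length
  ys <- vector("list", p$n_series)
  Xs <- vector("list", p$n_series)
  for (s in seq_len(p$n_series)) {
    ser <- narma10_series(p$series_length, seed = sub_seed(p$seed, s, 42L))
    X <- run_reservoir(sys, ser$input)
    ys[[s]] <- ser$output[keep]
    Xs[[s]] <- X[, keep, drop = FALSE]
  }
  train <- seq_len(p$n_train)
  fit <- ridge_fit(do.call(cbind, Xs[train]),
                   unlist(ys[train], use.names = FALSE), gamma)
  yhat <- as.numeric(predict(fit, Xs[[p$n_series]]))
  task_result(nrmse(yhat, ys[[p$n_series]]), "narma10",
              list(gamma = gamma, protocol = unclass(p)), p$seed)
}

#' Random pulse train
#'
#' A binary series of unit-height pulses of fixed duration.  Pulse onsets
#' are drawn as a Bernoulli process thinned by a refractory gap of
#' `pulse_duration + 6` steps between onsets, so pulses never overlap and
#' delayed pulse pairs remain resolvable.
#'
#' @param length Series length (default 600).
#' @param pulse_duration Steps per pulse (default 3).
#' @param rate Per-step onset probability before thinning (default 0.02).
#' @param seed Integer seed.
#' @return Integer 0/1 vector of the given length.
#' @export
pulse_train <- function(length = 600L, pulse_duration = 3L, rate = 0.02,
                        seed = 1L) {
  stopifnot(pulse_duration >= 1, rate >= 0, rate <= 1)
  draws <- withr::with_seed(seed, stats::runif(length))
  x <- integer(length)
  next_ok <- 1L
  for (t in seq_len(length)) {
    if (t >= next_ok && draws[t] < rate &&
        t + pulse_duration - 1L <= length) {
      x[t:(t + pulse_duration - 1L)] <- 1L
      next_ok <- t + pulse_duration + 6L
    }
  }
  x
}

# starts of runs of 1s
run_onsets <- function(x) {
  which(x == 1L & c(0L, x[-length(x)]) == 0L)
}

#' Delayed AND target
#'
#' target[i] = I1[i - k] AND I2[i]; indices before the start of the series
#' read as 0.
#'
#' @param I1,I2 Binary series of equal length.
#' @param k Delay (>= 0).
#' @return Integer 0/1 vector.
#' @export
delayed_and_target <- function(I1, I2, k) {
  stopifnot(length(I1) == length(I2), k >= 0)
  L <- length(I1)
  shifted <- if (k == 0L) I1 else c(integer(min(k, L)), I1)[seq_len(L)]
  as.integer(shifted == 1L & I2 == 1L)
}

# Generate a paired pulse-train stimulus: I2 contains a pulse at lag k after
# a fraction of I1's pulses (so AND coincidences occur) plus independent
# pulses (so I2-alone events occur).
delayed_and_stimulus <- function(length, k, pulse_duration = 3L, rate = 0.02,
                                 coincidence_prob = 0.5, seed = 1L) {
  I1 <- pulse_train(length, pulse_duration, rate, sub_seed(seed, 1L, 51L))
  on1 <- run_onsets(I1)
  coin <- withr::with_seed(sub_seed(seed, 2L, 51L),
                           stats::runif(base::length(on1)) < coincidence_prob)
  planted <- on1[coin] + k
  planted <- planted[planted + pulse_duration - 1L <= length]
  indep <- run_onsets(pulse_train(length, pulse_duration, rate,
                                  sub_seed(seed, 3L, 51L)))
  onsets2 <- planted
  gap <- pulse_duration + 6L
  for (o in indep) {
    if (base::length(onsets2) == 0L || min(abs(onsets2 - o)) >= gap) {
      onsets2 <- c(onsets2, o)
    }
  }
  I2 <- integer(length)
  for (o in onsets2) I2[o:(o + pulse_duration - 1L)] <- 1L
  list(I1 = I1, I2 = I2, target = delayed_and_target(I1, I2, k))
}

#' Delayed AND benchmark task
#'
#' The biologically inspired coincidence task: two pulse-train inputs drive
#' the reservoir through two input nodes, and a readout is trained to fire
#' when input 1 pulsed k steps before input 2 (k = 6 by default).  The
#' real-valued readout is binarised at 0.5 and the binarised prediction is
#' scored against the target with [nrmse()] on the held-out series.  Half of
#' the I1 pulses carry a planted I2 coincidence at lag k so both AND classes
#' occur; series whose held-out target is constant are resampled.
#'
#' @param sys A two-input `grn_reservoir`.
#' @param protocol A [task_protocol()]; the default uses 600-step series.
#' @param k Coincidence delay (default 6).
#' @param gamma Ridge coefficient.
#' @param pulse_duration,rate,coincidence_prob Stimulus parameters; see
#'   [pulse_train()].
#' @return A `task_result` whose `score` is the binarised test NRMSE.
#' @export
delayed_and_task <- function(sys,
                             protocol = task_protocol(series_length = 600L),
                             k = 6L, gamma = 1e-6, pulse_duration = 3L,
                             rate = 0.02, coincidence_prob = 0.5) {
  if (ncol(sys$W_in) != 2L) stop("delayed AND task needs a two-input reservoir")
  p <- protocol
  keep <- (p$washout + 1L):p$series_length
  ys <- vector("list", p$n_series)
  Xs <- vector("list", p$n_series)
  for (s in seq_len(p$n_series)) {
    for (try in 0:50) {
      stim <- delayed_and_stimulus(p$series_length, k, pulse_duration, rate,
                                   coincidence_prob,
                                   seed = sub_seed(p$seed, s + 1000L * try, 52L))
      if (stats::sd(stim$target[keep]) > 0) break
    }
    if (stats::sd(stim$target[keep]) == 0) {
      stop("could not generate a non-constant delayed AND target")
    }
    X <- run_reservoir(sys, rbind(stim$I1, stim$I2))
    ys[[s]] <- stim$target[keep]
    Xs[[s]] <- X[, keep, drop = FALSE]
  }
  train <- seq_len(p$n_train)
  fit <- ridge_fit(do.call(cbind, Xs[train]),
                   unlist(ys[train], use.names = FALSE), gamma)
  yhat <- as.numeric(predict(fit, Xs[[p$n_series]]))
  ybin <- as.integer(yhat > 0.5)
  task_result(nrmse(ybin, ys[[p$n_series]]), "delayed_and",
              list(k = k, gamma = gamma, pulse_duration = pulse_duration,
                   rate = rate, coincidence_prob = coincidence_prob,
                   protocol = unclass(p)), p$seed)
}
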
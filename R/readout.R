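#' Fit a ridge-regression readout
#'
#' Trains the linear readout W_out = Y X' (X X' + gamma^2 I)^{-1} mapping
#' reservoir states to target outputs.  The system is solved with a stable
#' linear solve rather than explicit inversion.  Washout columns are assumed
#' to have been removed by the caller.
#'
#' @param X N x T state matrix (training columns only).
#' @param Y_target N_out x T target matrix (a vector is taken as one row).
#' @param gamma Ridge regularisation coefficient; `0` requests ordinary least
#'   squares and fails with a hint if the state Gram matrix is singular.
#' @return An object of class `ridge_readout` with elements `W_out` and
#'   `gamma`; supports [predict()] and [coef()].
#' @export
ridge_fit <- function(X, Y_target, gamma = 1e-6) {
  if (is.vector(Y_target)) Y_target <- matrix(Y_target, nrow = 1L)
  stopifnot(ncol(X) == ncol(Y_target), gamma >= 0)
  if (ncol(X) < nrow(X)) {
    warning("fewer time points than reservoir nodes; fit is underdetermined")
  }
  structure(list(W_out = ridge_solve(X, Y_target, gamma), gamma = gamma),
            class = "ridge_readout")
}

# Solve W_out = Y X' (X X' + gamma^2 I)^{-1} stably.  Fast path: Cholesky of
# the Gram matrix.  When states are nearly collinear (e.g. a saturated
# reservoir) the Gram matrix can be numerically semidefinite even though the
# ridge problem is well posed; then fall back to QR of the augmented
# least-squares system [X'; gamma I] w = [y'; 0], which never forms X X'.
ridge_solve <- function(X, Ymat, gamma) {
  n <- nrow(X)
  A <- tcrossprod(X) + gamma^2 * diag(n)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R)) {
    B <- tcrossprod(X, Ymat)  # X Y'
    return(t(backsolve(R, forwardsolve(t(R), B))))
  }
  if (gamma == 0) {
    stop("state Gram matrix is singular with gamma = 0; use gamma > 0",
         call. = FALSE)
  }
  aug <- rbind(t(X), diag(gamma, n))
  rhs <- rbind(t(Ymat), matrix(0, n, nrow(Ymat)))
  t(qr.coef(qr(aug, LAPACK = TRUE), rhs))
}

#' @export
print.ridge_readout <- function(x, ...) {
  cat(sprintf("ridge_readout: %d output(s) x %d nodes, gamma = %g\n",
              nrow(x$W_out), ncol(x$W_out), x$gamma))
  invisible(x)
}

#' @export
coef.ridge_readout <- function(object, ...) object$W_out

#' Predict from a ridge readout
#'
#' @param object A `ridge_readout`.
#' @param X N x T state matrix.
#' @param ... Unused.
#' @return The N_out x T linear output `W_out %*% X`; no output
#'   nonlinearity is applied.
#' @export
predict.ridge_readout <- function(object, X, ...) {
  if (ncol(object$W_out) != nrow(X)) stop("state dimension mismatch")
  object$W_out %*% X
}

#' Normalised root mean squared error
#'
#' NRMSE = sqrt(<(y - y_target)^2>_t / <(y_target - <y_target>_t)^2>_t),
#' with time averages taken over all supplied points (population variance).
#' 0 means a perfect fit; 1 is the score of the constant mean predictor.
#'
#' @param y Predicted series.
#' @param y_target Target series (must not be constant).
#' @return A non-negative scalar.
#' @export
nrmse <- function(y, y_target) {
  stopifnot(length(y) == length(y_target), length(y) >= 2)
  denom <- mean((y_target - mean(y_target))^2)
  if (denom == 0) stop("target series is constant; NRMSE undefined")
  sqrt(mean((y - y_target)^2) / denom)
}
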
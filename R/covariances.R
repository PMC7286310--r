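#' Spatiotemporal covariance pair (FC0 / FC1)
#'
#' Container for the fitting target of the MOU estimation: the zero-lag
#' covariance `q0` and the lagged covariance `q1` (rows = earlier time),
#' with the lag in seconds.
#'
#' @param q0 N x N symmetric zero-lag covariance.
#' @param q1 N x N lagged covariance (row region leads, column region lags).
#' @param lag Lag in seconds (typically one TR).
#' @param n_samples Number of time points the estimate is based on.
#' @return An object of class `"mou_cov"`.
#' @export
mou_cov <- function(q0, q1, lag, n_samples = NA_integer_) {
  q0 <- as.matrix(q0); q1 <- as.matrix(q1)
  n <- nrow(q0)
  if (ncol(q0) != n || any(dim(q1) != n)) stop("q0 and q1 must be square N x N")
  if (any(!is.finite(q0)) || any(!is.finite(q1))) stop("covariances must be finite")
  if (max(abs(q0 - t(q0))) > 1e-12 * max(1, max(abs(q0))))
    stop("q0 must be symmetric")
  if (!is.numeric(lag) || length(lag) != 1L || lag < 0)
    stop("'lag' must be a nonnegative scalar (seconds)")
  structure(list(q0 = (q0 + t(q0)) / 2, q1 = q1, lag = lag,
                 n_samples = as.integer(n_samples)),
            class = "mou_cov")
}

#' @export
print.mou_cov <- function(x, ...) {
  cat(sprintf("Spatiotemporal covariance: %d regions, lag %g s, %s samples\n",
              nrow(x$q0), x$lag,
              ifelse(is.na(x$n_samples), "?", x$n_samples)))
  invisible(x)
}

#' Empirical zero-lag and lagged covariances of a session
#'
#' Each region's row is demeaned over the whole session; both matrices are
#' computed on the overlapping window of length T - lag with denominator
#' T - lag - 1, so the (q0, q1) pair is mutually consistent. q0 is
#' symmetrized.
#'
#' @param session A [mou_session()].
#' @param lag_tr Lag in sampling periods (default 1).
#' @return A [mou_cov()] with `lag = lag_tr * tr` seconds.
#' @export
empirical_covariances <- function(session, lag_tr = 1) {
  stopifnot(inherits(session, "mou_session"))
  X <- session$data
  T_ <- ncol(X)
  lag_tr <- as.integer(lag_tr)
  if (T_ < lag_tr + 2) stop("session too short: need T >= lag + 2 time points")
  X <- X - rowMeans(X)
  w <- T_ - lag_tr
  X0 <- X[, seq_len(w), drop = FALSE]
  X1 <- X[, lag_tr + seq_len(w), drop = FALSE]
  denom <- w - 1
  q0 <- tcrossprod(X0) / denom
  q0 <- (q0 + t(q0)) / 2
  q1 <- tcrossprod(X0, X1) / denom
  if (max(abs(q0)) > 0) {
    kap <- kappa(q0, exact = FALSE)
    if (is.finite(kap) && kap > 1e8)
      message(sprintf("empirical_covariances: q0 is quasi-singular (condition number %.3g)", kap))
  }
  mou_cov(q0, q1, lag = lag_tr * session$tr, n_samples = T_)
}

#' Estimate the leakage time constant from autocovariance decay
#'
#' For each region, regresses the log autocovariance against the lag (in
#' seconds) over lags 0..`max_lag_tr`; the pooled estimate is
#' tau = -1 / mean(slopes). Regions whose autocovariance is not positive at
#' every used lag are excluded (reported via `message`).
#'
#' @param session A [mou_session()].
#' @param max_lag_tr Largest lag (in TRs) used in the regression (default 2).
#' @return Estimated time constant in seconds, with attribute `"slopes"`
#'   holding the per-region log-slopes used.
#' @export
estimate_tau <- function(session, max_lag_tr = 2) {
  stopifnot(inherits(session, "mou_session"))
  X <- session$data - rowMeans(session$data)
  n <- nrow(X); T_ <- ncol(X)
  if (T_ < max_lag_tr + 2) stop("session too short for requested max_lag_tr")
  lags <- 0:max_lag_tr
  ac <- sapply(lags, function(k) {
    w <- T_ - k
    rowSums(X[, seq_len(w), drop = FALSE] * X[, k + seq_len(w), drop = FALSE]) / (w - 1)
  })
  ac <- matrix(ac, nrow = n)
  ok <- apply(ac > 0, 1, all)
  if (!any(ok)) stop("estimate_tau: all regions have non-positive autocovariance at some lag")
  if (any(!ok))
    message(sprintf("estimate_tau: excluding %d region(s) with non-positive autocovariance", sum(!ok)))
  tsec <- lags * session$tr
  slopes <- apply(log(ac[ok, , drop = FALSE]), 1, function(v) {
    sum((tsec - mean(tsec)) * (v - mean(v))) / sum((tsec - mean(tsec))^2)
  })
  tau <- -1 / mean(slopes)
  if (!is.finite(tau) || tau <= 0)
    stop("estimate_tau: autocovariances do not decay (non-positive tau estimate)")
  structure(tau, slopes = slopes)
}

#' Model error of a MOU model against an empirical covariance pair
#'
#' E = ( ||q0 - Q0||_F / ||q0||_F + ||q1 - Q1||_F / ||q1||_F ) / 2, where
#' Q0 and Q1 are the model's theoretical covariances at the target's lag.
#' Zero iff the model reproduces both matrices exactly.
#'
#' @param target A [mou_cov()].
#' @param model A stable `"mou"` object.
#' @return Scalar model error.
#' @export
model_error <- function(target, model) {
  stopifnot(inherits(target, "mou_cov"), inherits(model, "mou"))
  Q0 <- stationary_cov(model)
  Q1 <- lagged_cov(model, target$lag)
  (.frob(target$q0 - Q0) / .frob(target$q0) +
     .frob(target$q1 - Q1) / .frob(target$q1)) / 2
}
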
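#' Control parameters for the MOU fit
#'
#' @param rate_c Learning rate for the EC update. The natural-gradient step
#'   is already expressed in Jacobian units, so this is a dimensionless
#'   relative step size.
#' @param rate_sigma Learning rate for the diagonal Sigma update.
#' @param max_iter Maximum number of iterations.
#' @param patience Iterations without improvement of the best model error
#'   before stopping.
#' @param sigma_min Floor for the Sigma diagonal.
#' @param c_max Optional cap on EC weights (default none).
#' @return A list of class `"mou_control"`.
#' @export
mou_control <- function(rate_c = 0.005, rate_sigma = 0.05, max_iter = 10000,
                        patience = 100, sigma_min = 1e-6, c_max = Inf) {
  stopifnot(rate_c > 0, rate_sigma > 0, max_iter >= 1, patience >= 1,
            patience <= max_iter, sigma_min > 0, c_max > 0)
  structure(list(rate_c = rate_c, rate_sigma = rate_sigma,
                 max_iter = as.integer(max_iter), patience = as.integer(patience),
                 sigma_min = sigma_min, c_max = c_max),
            class = "mou_control")
}

#' Fit a MOU effective-connectivity model
#'
#' Estimates the directed EC matrix and the diagonal input covariance Sigma
#' so that the model's theoretical covariances reproduce the empirical
#' zero-lag and lagged covariances (FC0, FC1), by a Lyapunov-based
#' natural-gradient descent constrained to a structural mask
#' (`method = "gradient"`). The `"heuristic"` variant constrains EC to be
#' symmetric and tunes it to reproduce the zero-lag covariance only.
#'
#' At each iteration the model covariances are obtained from the Lyapunov
#' equation, the best-fitting Jacobian update is
#' `t(dJ) = solve(Q0, dQ0 + dQ1 expm(-J' lag))`, EC moves by `rate_c`
#' times that step on masked off-diagonal entries (clipped to
#' `[0, c_max]`), and the Sigma diagonal moves down the Lyapunov residual
#' `diag(J dQ0 + dQ0 J')`. The parameters at the minimum model error are
#' returned. If an update destabilizes the Jacobian the previous state is
#' restored and the rates are halved (at most 5 times).
#'
#' @param x A [mou_session()], an N x T matrix (rows = regions; requires
#'   `tr`), or a precomputed [mou_cov()] (requires `tau`).
#' @param mask Optional N x N binary structural mask restricting which EC
#'   entries may be nonzero (`mask[i, j]` = connection from source i to
#'   target j). Default: all off-diagonal entries allowed.
#' @param tau Leakage time constant in seconds; estimated from the session
#'   autocovariance decay ([estimate_tau()]) when `NULL` and `x` carries
#'   time series.
#' @param lag_tr Lag (in sampling periods) of the lagged covariance when
#'   `x` is a session or matrix.
#' @param method `"gradient"` (directed EC, fits FC0 and FC1) or
#'   `"heuristic"` (symmetric EC, fits FC0 only).
#' @param control A [mou_control()] list.
#' @param tr Sampling period in seconds, needed when `x` is a bare matrix.
#' @param ... Unused.
#' @return An object of class `"mou_fit"` with components `model` (the
#'   best-fit [mou()] object), `error_history`, `best_error`,
#'   `best_iteration`, `converged`, `tau`, `target`, `mask`, `method`,
#'   `control`.
#' @examples
#' truth <- mou(ec = matrix(c(0, 0.4, 0.1, 0, 0, 0.3, 0, 0.2, 0), 3, 3,
#'                          byrow = TRUE), tau = 2)
#' target <- mou_cov(stationary_cov(truth), lagged_cov(truth, 2), lag = 2)
#' fit <- mou_fit(target, tau = 2)
#' cor(coef(fit)[truth$ec > 0], truth$ec[truth$ec > 0])
#' @export
mou_fit <- function(x, mask = NULL, tau = NULL, lag_tr = 1,
                    method = c("gradient", "heuristic"),
                    control = mou_control(), tr = NULL, ...) {
  method <- match.arg(method)
  if (is.matrix(x) && !inherits(x, "mou_cov")) {
    if (is.null(tr)) stop("'tr' is required when 'x' is a bare matrix")
    x <- mou_session(x, tr = tr)
  }
  if (inherits(x, "mou_session")) {
    if (is.null(tau)) tau <- as.numeric(estimate_tau(x))
    target <- empirical_covariances(x, lag_tr = lag_tr)
  } else if (inherits(x, "mou_cov")) {
    if (is.null(tau)) stop("'tau' is required when fitting a covariance pair directly")
    target <- x
  } else {
    stop("'x' must be a mou_session, an N x T matrix, or a mou_cov")
  }
  n <- nrow(target$q0)
  mask <- .check_mask(mask, n)
  if (method == "heuristic") mask <- (mask | t(mask)) * 1L

  fit <- .mou_descent(target, mask, tau, control, method)
  roi <- rownames(target$q0)
  model <- mou(ec = fit$C, sigma = fit$sigma, tau = tau, roi_names = roi)
  structure(
    list(model = model, error_history = fit$history, best_error = fit$best_error,
         best_iteration = fit$best_iter, converged = fit$converged,
         tau = tau, target = target, mask = mask, method = method,
         control = control),
    class = "mou_fit"
  )
}

.check_mask <- function(mask, n) {
  if (is.null(mask)) {
    mask <- matrix(1L, n, n); diag(mask) <- 0L
    return(mask)
  }
  mask <- as.matrix(mask)
  if (any(dim(mask) != n)) stop("'mask' must be N x N")
  if (!all(mask %in% c(0, 1))) stop("'mask' entries must be 0/1")
  if (any(diag(mask) != 0)) stop("'mask' diagonal must be zero")
  storage.mode(mask) <- "integer"
  mask
}

# Shared descent loop for both optimization variants.
.mou_descent <- function(target, mask, tau, control, method) {
  n <- nrow(target$q0)
  lag <- target$lag
  q0 <- target$q0
  q1 <- target$q1
  nq0 <- .frob(q0); nq1 <- .frob(q1)
  if (nq0 == 0) stop("q0 is identically zero; nothing to fit")

  # ridge jitter if q0 is quasi-singular
  ev <- eigen(q0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.eps) > 1e8) {
    jit <- 1e-6 * mean(diag(q0))
    q0 <- q0 + jit * diag(n)
    message(sprintf("mou_fit: q0 quasi-singular, ridge jitter %.3g applied", jit))
  }

  C <- matrix(0, n, n)
  sig <- pmax(2 / tau * diag(q0), control$sigma_min)
  rate_c <- control$rate_c
  rate_s <- control$rate_sigma
  off <- mask > 0
  sym <- method == "heuristic"

  best_error <- Inf
  best <- list(C = C, sig = sig)
  history <- numeric(0)
  best_iter <- 0L
  halvings <- 0L
  stale <- 0L
  converged <- FALSE

  for (it in seq_len(control$max_iter)) {
    J <- t(C); diag(J) <- -1 / tau
    ed <- .jac_eig(J)
    Q0 <- .lyap_solve(J, diag(sig, n), ed)
    dQ0 <- q0 - Q0
    if (sym) {
      E <- .frob(dQ0) / nq0
      dC <- dQ0
    } else {
      Elag <- .expm_t(J, lag, ed)
      Q1 <- Q0 %*% t(Elag)
      dQ1 <- q1 - Q1
      E <- (.frob(dQ0) / nq0 + .frob(dQ1) / nq1) / 2
      Elag_inv <- .expm_t(J, -lag, ed)
      dJt <- tryCatch(solve(Q0, dQ0 + dQ1 %*% t(Elag_inv)),
                      error = function(cond) stop("mou_fit: model Q0 is singular"))
      # C[source, target] corresponds to J[target, source], so the EC step
      # is the transpose of dJ, i.e. dJt itself.
      dC <- dJt
    }
    history <- c(history, E)
    if (E < best_error) {
      best_error <- E
      best <- list(C = C, sig = sig)
      best_iter <- it
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= control$patience) { converged <- TRUE; break }
    }

    grad_s <- diag(J %*% dQ0 + dQ0 %*% t(J))
    sig_new <- pmax(sig - rate_s * grad_s, control$sigma_min)

    # backtracking step: when the full EC update destabilizes the Jacobian,
    # retry from the last stable state with the step halved (up to 8 times)
    # so the descent can track the stability boundary
    alpha <- 1
    accepted <- FALSE
    for (bt in 0:8) {
      C_new <- C
      C_new[off] <- C_new[off] + alpha * rate_c * dC[off]
      if (sym) C_new <- (C_new + t(C_new)) / 2
      C_new[off] <- pmin(pmax(C_new[off], 0), control$c_max)
      C_new[!off] <- 0
      diag(C_new) <- 0
      J_new <- t(C_new); diag(J_new) <- -1 / tau
      if (max(Re(eigen(J_new, only.values = TRUE)$values)) < -1e-9) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      # even a 1/256 step crosses the boundary; count consecutive failures
      halvings <- halvings + 1L
      if (halvings > 5L) {
        message("mou_fit: stability boundary reached; returning best stable parameters")
        converged <- TRUE
        break
      }
      sig <- sig_new
      next
    }
    halvings <- 0L
    C <- C_new
    sig <- sig_new
  }
  list(C = best$C, sigma = best$sig, history = history,
       best_error = best_error, best_iter = best_iter, converged = converged)
}

# --- methods ----------------------------------------------------------------

#' @export
print.mou_fit <- function(x, ...) {
  cat(sprintf("MOU-EC fit (%s optimization)\n", x$method))
  cat(sprintf("  regions: %d, tau: %.3g s, lag: %g s\n",
              x$model$n_rois, x$tau, x$target$lag))
  cat(sprintf("  model error: %.4g at iteration %d/%d (%s)\n",
              x$best_error, x$best_iteration, length(x$error_history),
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.mou_fit <- function(object, ...) {
  ec <- object$model$ec
  links <- ec[object$mask > 0]
  out <- list(
    n_rois = object$model$n_rois,
    n_links = sum(object$mask),
    method = object$method,
    tau = object$tau,
    lag = object$target$lag,
    best_error = object$best_error,
    iterations = length(object$error_history),
    converged = object$converged,
    ec_summary = summary(links),
    sigma_summary = summary(diag(object$model$sigma))
  )
  class(out) <- "summary.mou_fit"
  out
}

#' @export
print.summary.mou_fit <- function(x, ...) {
  cat(sprintf("MOU-EC fit summary (%s optimization)\n", x$method))
  cat(sprintf("  %d regions, %d allowed links, tau = %.3g s, lag = %g s\n",
              x$n_rois, x$n_links, x$tau, x$lag))
  cat(sprintf("  model error %.4g after %d iterations (%s)\n",
              x$best_error, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat("  EC weights (allowed links):\n")
  print(x$ec_summary)
  cat("  Sigma diagonal:\n")
  print(x$sigma_summary)
  invisible(x)
}

#' @export
coef.mou_fit <- function(object, ...) object$model$ec

#' Theoretical covariances reproduced by a fitted MOU model
#' @param object A `"mou_fit"`.
#' @param ... Unused.
#' @return List with `q0` and `q1`, the model covariances at the target lag.
#' @export
fitted.mou_fit <- function(object, ...) {
  list(q0 = stationary_cov(object$model),
       q1 = lagged_cov(object$model, object$target$lag))
}

#' @export
residuals.mou_fit <- function(object, ...) {
  f <- fitted(object)
  list(q0 = object$target$q0 - f$q0, q1 = object$target$q1 - f$q1)
}

#' @export
plot.mou_fit <- function(x, ...) {
  plot(seq_along(x$error_history), x$error_history, type = "l",
       xlab = "iteration", ylab = "model error",
       main = sprintf("MOU fit (%s): error trajectory", x$method), ...)
  abline(v = x$best_iteration, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
simulate.mou_fit <- function(object, nsim = 300, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}
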
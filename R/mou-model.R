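#' Multivariate Ornstein-Uhlenbeck network model
#'
#' Constructs a MOU model object. The process on the N-dimensional state
#' x(t) is dx = J x dt + dW with Jacobian J = -I/tau + t(C) and input noise
#' of covariance `sigma` per unit time. `ec` is the directed
#' effective-connectivity matrix with the convention that `ec[i, j]` is the
#' weight of the connection FROM region i (source) TO region j (target);
#' the Jacobian uses its transpose so that state evolution reads
#' target-from-source.
#'
#' @param ec N x N matrix of nonnegative directed weights (1/time units),
#'   zero diagonal; `ec[i, j]` is the connection from source i to target j.
#' @param sigma Input covariance of the driving noise (signal^2/time units):
#'   a scalar (isotropic), a length-N vector (diagonal), or a full symmetric
#'   positive-semidefinite N x N matrix with positive diagonal.
#' @param tau Leakage time constant in seconds (> 0), shared by all regions.
#' @param roi_names Optional character vector of N region labels.
#' @return An object of class `"mou"`.
#' @examples
#' m <- mou(ec = matrix(c(0, 0.3, 0, 0), 2, 2, byrow = TRUE), tau = 1)
#' jacobian(m)
#' stationary_cov(m)
#' @export
mou <- function(ec, sigma = 1, tau = 1, roi_names = NULL) {
  ec <- as.matrix(ec)
  n <- nrow(ec)
  if (ncol(ec) != n) stop("'ec' must be a square matrix")
  if (any(!is.finite(ec))) stop("'ec' must be finite")
  if (any(abs(diag(ec)) > 0)) stop("'ec' must have a zero diagonal")
  if (any(ec < 0)) stop("'ec' weights must be nonnegative")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive scalar (seconds)")
  sigma <- .as_sigma(sigma, n)
  if (is.null(roi_names)) {
    roi_names <- rownames(ec)
    if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  }
  if (length(roi_names) != n) stop("'roi_names' must have length N")
  dimnames(ec) <- list(roi_names, roi_names)
  dimnames(sigma) <- list(roi_names, roi_names)
  structure(
    list(ec = ec, sigma = sigma, tau = tau, n_rois = n, roi_names = roi_names),
    class = "mou"
  )
}

.as_sigma <- function(sigma, n) {
  if (is.matrix(sigma)) {
    if (nrow(sigma) != n || ncol(sigma) != n) stop("'sigma' matrix must be N x N")
    if (max(abs(sigma - t(sigma))) > 1e-10 * max(1, max(abs(sigma))))
      stop("'sigma' must be symmetric")
    sigma <- (sigma + t(sigma)) / 2
  } else if (length(sigma) == 1L) {
    sigma <- diag(rep(as.numeric(sigma), n), n)
  } else if (length(sigma) == n) {
    sigma <- diag(as.numeric(sigma), n)
  } else {
    stop("'sigma' must be a scalar, length-N vector, or N x N matrix")
  }
  if (any(!is.finite(sigma))) stop("'sigma' must be finite")
  if (any(diag(sigma) <= 0)) stop("diag(sigma) must be positive")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("'sigma' must be positive semidefinite")
  sigma
}

#' @export
print.mou <- function(x, ...) {
  dens <- mean(x$ec[row(x$ec) != col(x$ec)] > 0)
  st <- is_stable(x)
  cat("MOU network model\n")
  cat(sprintf("  regions: %d, tau: %g s\n", x$n_rois, x$tau))
  cat(sprintf("  EC density: %.3f, max weight: %.4g\n", dens, max(x$ec)))
  cat(sprintf("  stable: %s (spectral margin %.4g)\n",
              st, attr(st, "margin")))
  invisible(x)
}

#' Jacobian of a MOU model
#'
#' Returns J = -I/tau + t(C): entry J\[i, j\] is the weight of the directed
#' connection from source j to target i, with leakage -1/tau on the diagonal.
#'
#' @param model A `"mou"` object.
#' @return N x N Jacobian matrix.
#' @export
jacobian <- function(model) {
  stopifnot(inherits(model, "mou"))
  J <- t(model$ec)
  diag(J) <- -1 / model$tau
  J
}

#' Stability of a MOU model
#'
#' A MOU model is stable (and has a stationary covariance) iff all
#' eigenvalues of its Jacobian have negative real part. The spectral margin
#' (maximum real part) is attached as an attribute; models whose margin
#' exceeds -1e-9 are declared unstable.
#'
#' @param model A `"mou"` object.
#' @return Logical, with attribute `"margin"` = max Re(eig(J)).
#' @export
is_stable <- function(model) {
  J <- jacobian(model)
  margin <- max(Re(eigen(J, only.values = TRUE)$values))
  structure(margin < -1e-9, margin = margin)
}

.stop_if_unstable <- function(model) {
  st <- is_stable(model)
  if (!st)
    stop(sprintf("MOU model is unstable (spectral margin %.4g >= -1e-9); no stationary covariance",
                 attr(st, "margin")))
  invisible(st)
}

# --- linear-algebra kernels -------------------------------------------------
# Lyapunov solve and matrix exponential via eigendecomposition of J, with a
# Kronecker / Matrix::expm fallback when J is too close to defective.

.jac_eig <- function(J) {
  e <- eigen(J)
  Vi <- tryCatch(solve(e$vectors), error = function(cond) NULL)
  list(V = e$vectors, lam = e$values, Vi = Vi)
}

.lyap_from_eig <- function(ed, Sigma) {
  if (is.null(ed$Vi)) return(NULL)
  M <- ed$Vi %*% Sigma %*% Conj(t(ed$Vi))
  X <- -M / outer(ed$lam, Conj(ed$lam), `+`)
  Q <- Re(ed$V %*% X %*% Conj(t(ed$V)))
  (Q + t(Q)) / 2
}

.lyap_kron <- function(J, Sigma) {
  n <- nrow(J)
  A <- kronecker(diag(n), J) + kronecker(J, diag(n))
  matrix(solve(A, -as.vector(Sigma)), n, n)
}

# Solves J Q + Q J' + Sigma = 0 for stable J.
.lyap_solve <- function(J, Sigma, ed = NULL) {
  if (is.null(ed)) ed <- .jac_eig(J)
  Q <- .lyap_from_eig(ed, Sigma)
  ref <- max(.frob(Sigma), .Machine$double.eps)
  if (is.null(Q) || !all(is.finite(Q)) ||
      .frob(J %*% Q + Q %*% t(J) + Sigma) / ref > 1e-10) {
    Q <- .lyap_kron(J, Sigma)
    Q <- (Q + t(Q)) / 2
  }
  Q
}

.expm_from_eig <- function(ed, t) {
  if (is.null(ed$Vi)) return(NULL)
  Re(ed$V %*% (exp(ed$lam * t) * ed$Vi))
}

.expm_t <- function(J, t, ed = NULL) {
  if (is.null(ed)) ed <- .jac_eig(J)
  E <- .expm_from_eig(ed, t)
  if (is.null(E) || !all(is.finite(E)))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(J * t)))
  E
}

.frob <- function(M) sqrt(sum(M * M))

# --- theoretical covariances ------------------------------------------------

#' Stationary (zero-lag) covariance of a MOU model
#'
#' Solves the continuous Lyapunov equation J Q0 + Q0 J' + Sigma = 0.
#'
#' @param model A stable `"mou"` object.
#' @return Symmetric positive-definite N x N covariance matrix.
#' @export
stationary_cov <- function(model) {
  .stop_if_unstable(model)
  J <- jacobian(model)
  Q0 <- .lyap_solve(J, model$sigma)
  res <- .frob(J %*% Q0 + Q0 %*% t(J) + model$sigma) / .frob(model$sigma)
  if (res > 1e-10)
    stop(sprintf("Lyapunov solve failed: relative residual %.3g > 1e-10", res))
  dimnames(Q0) <- list(model$roi_names, model$roi_names)
  Q0
}

#' Lagged covariance of a MOU model
#'
#' Covariance between x(t) (rows) and x(t + lag) (columns):
#' Q_lag = Q0 expm(J' lag). At lag 0 this is the stationary covariance.
#'
#' @param model A stable `"mou"` object.
#' @param lag Nonnegative lag in seconds.
#' @return N x N lagged covariance matrix.
#' @export
lagged_cov <- function(model, lag) {
  if (!is.numeric(lag) || length(lag) != 1L || !is.finite(lag) || lag < 0)
    stop("'lag' must be a nonnegative scalar (seconds)")
  Q0 <- stationary_cov(model)
  if (lag == 0) return(Q0)
  J <- jacobian(model)
  Ql <- Q0 %*% t(.expm_t(J, lag))
  dimnames(Ql) <- list(model$roi_names, model$roi_names)
  Ql
}

# --- simulation -------------------------------------------------------------

.sigma_factor <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values), .Machine$double.eps)
  if (min(e$values) < -sqrt(tol))
    stop("'sigma' factorization failed: matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a MOU session
#'
#' Euler-Maruyama integration of dx = J x dt + sqrt(dt) L xi with L the
#' symmetric square-root factor of Sigma and xi standard normal, subsampled
#' at the repetition time `tr` after discarding a burn-in. Identical seeds
#' give identical sessions.
#'
#' @param object A stable `"mou"` object.
#' @param nsim Number of time points (TRs) to return.
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @param tr Sampling period in seconds.
#' @param dt Integration step in seconds; must satisfy dt <= tr/10
#'   (default tr/20).
#' @param burn_in Burn-in duration in seconds, discarded before sampling
#'   (default 100 * tau).
#' @param subject_id,condition Metadata labels stored in the session.
#' @param ... Unused.
#' @return A [mou_session()] with an N x nsim data matrix.
#' @export
simulate.mou <- function(object, nsim = 300, seed = NULL, tr = 2,
                         dt = tr / 20, burn_in = 100 * object$tau,
                         subject_id = "sim", condition = "sim", ...) {
  .stop_if_unstable(object)
  if (nsim < 3) stop("'nsim' must be at least 3 time points")
  if (dt > tr / 10 + 1e-12) stop("'dt' must be <= tr/10")
  if (!is.null(seed)) set.seed(seed)
  J <- jacobian(object)
  L <- .sigma_factor(object$sigma)
  sub <- max(1L, as.integer(round(tr / dt)))
  burn <- as.integer(ceiling(burn_in / dt))
  X <- mou_sim_core(J, L, as.integer(nsim), sub, burn, dt)
  rownames(X) <- object$roi_names
  mou_session(X, tr = tr, subject_id = subject_id, condition = condition)
}

#' Region-by-time signal session
#'
#' Container for one multi-region recording: an N x T matrix (rows = regions,
#' columns = time points) with its sampling period and labels.
#'
#' @param data N x T numeric matrix, rows = regions.
#' @param tr Sampling period (repetition time) in seconds.
#' @param subject_id,condition Character labels.
#' @return An object of class `"mou_session"`.
#' @export
mou_session <- function(data, tr, subject_id = "", condition = "") {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("session data must be finite")
  if (ncol(data) < 3) stop("a session needs at least 3 time points")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive scalar (seconds)")
  if (is.null(rownames(data))) rownames(data) <- paste0("ROI", seq_len(nrow(data)))
  structure(
    list(data = data, tr = tr, subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "mou_session"
  )
}

#' @export
print.mou_session <- function(x, ...) {
  cat(sprintf("MOU session: %d regions x %d time points, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  if (nzchar(x$subject_id) || nzchar(x$condition))
    cat(sprintf("  subject: %s, condition: %s\n", x$subject_id, x$condition))
  invisible(x)
}
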
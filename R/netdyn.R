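#' Dynamic communicability of a MOU model
#'
#' The network response beyond leakage across integration time:
#' C(t) = (expm(J t) - expm(J0 t)) / ||J0|| with J0 = -I/tau the
#' leakage-only Jacobian and ||J0|| = N/tau its entrywise L1 norm, which
#' makes the measure dimensionless. Slice `[i, j, k]` is the interaction
#' from source region i to target region j at integration time
#' `t_grid[k]`.
#'
#' @param model A stable `"mou"` object.
#' @param t_grid Increasing integration times (same time units as `tau`,
#'   i.e. seconds), starting at 0. Default 0 to 20 TR in steps of 0.5 TR
#'   with `tr = 2` s.
#' @param tr Sampling period used only to build the default `t_grid`.
#' @return A `"flow_tensor"`: an N x N x T array with attributes `t_grid`,
#'   `kind` and `norm_constant`.
#' @export
dynamic_communicability <- function(model, t_grid = NULL, tr = 2) {
  .stop_if_unstable(model)
  t_grid <- .check_tgrid(t_grid, tr)
  J <- jacobian(model)
  ed <- .jac_eig(J)
  n <- model$n_rois
  nrm <- n / model$tau
  vals <- vapply(t_grid, function(t) {
    t((.expm_t(J, t, ed) - exp(-t / model$tau) * diag(n))) / nrm
  }, matrix(0, n, n))
  vals <- array(vals, dim = c(n, n, length(t_grid)),
                dimnames = list(model$roi_names, model$roi_names, NULL))
  structure(vals, t_grid = t_grid, kind = "communicability",
            norm_constant = nrm, class = "flow_tensor")
}

.check_tgrid <- function(t_grid, tr) {
  if (is.null(t_grid)) t_grid <- seq(0, 20 * tr, by = 0.5 * tr)
  if (t_grid[1] != 0) stop("'t_grid' must start at 0")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  t_grid
}

#' Dynamic flow of a MOU model
#'
#' Communicability with the source side scaled by the input amplitudes:
#' for diagonal Sigma, row i (source i) is multiplied by sqrt(Sigma\[i,i\]);
#' for a full Sigma the symmetric matrix square root is applied on the
#' source axis. With Sigma = I the flow equals the communicability.
#'
#' @inheritParams dynamic_communicability
#' @return A `"flow_tensor"` with `kind = "flow"`.
#' @export
dynamic_flow <- function(model, t_grid = NULL, tr = 2) {
  ft <- dynamic_communicability(model, t_grid = t_grid, tr = tr)
  S <- model$sigma
  offd <- S; diag(offd) <- 0
  vals <- unclass(ft)
  if (max(abs(offd)) == 0) {
    amp <- sqrt(diag(S))
    vals <- vals * amp  # recycles over the first (source) axis
  } else {
    R <- .sigma_factor(S)
    for (k in seq_len(dim(vals)[3])) vals[, , k] <- R %*% vals[, , k]
  }
  dimnames(vals) <- list(model$roi_names, model$roi_names, NULL)
  structure(vals, t_grid = attr(ft, "t_grid"), kind = "flow",
            norm_constant = attr(ft, "norm_constant"), class = "flow_tensor")
}

#' @export
print.flow_tensor <- function(x, ...) {
  d <- dim(x)
  tg <- attr(x, "t_grid")
  cat(sprintf("Dynamic %s tensor: %d x %d regions, %d integration times (%g to %g)\n",
              attr(x, "kind"), d[1], d[2], d[3], tg[1], tg[length(tg)]))
  invisible(x)
}

#' Total network flow over integration time
#'
#' Sum of all N^2 pairwise interactions at each integration time.
#'
#' @param ft A `"flow_tensor"`.
#' @return Numeric series aligned with the tensor's `t_grid` (attached as
#'   attribute).
#' @export
total_flow <- function(ft) {
  stopifnot(inherits(ft, "flow_tensor"))
  structure(apply(unclass(ft), 3, sum), t_grid = attr(ft, "t_grid"))
}

#' Input and output flow per region
#'
#' The input flow of region k sums all interactions targeting k (column
#' sums); the output flow sums all interactions sourced at k (row sums).
#' Each sums over regions to the total flow at every integration time.
#'
#' @param ft A `"flow_tensor"`.
#' @return List with N x T matrices `input` and `output`.
#' @export
input_output_flow <- function(ft) {
  stopifnot(inherits(ft, "flow_tensor"))
  vals <- unclass(ft)
  list(input = apply(vals, 3, colSums),
       output = apply(vals, 3, rowSums))
}

#' Flow diversity (heterogeneity) over integration time
#'
#' Coefficient of variation (population standard deviation over mean) of
#' the N^2 tensor entries at each integration time; `NA` where the mean is
#' at or below 1e-15.
#'
#' @param ft A `"flow_tensor"`.
#' @return Numeric series aligned with `t_grid`.
#' @export
flow_diversity <- function(ft) {
  stopifnot(inherits(ft, "flow_tensor"))
  vals <- unclass(ft)
  out <- apply(vals, 3, function(M) {
    m <- mean(M)
    if (!is.finite(m) || m <= 1e-15) return(NA_real_)
    sqrt(mean((M - m)^2)) / m
  })
  structure(out, t_grid = attr(ft, "t_grid"))
}

#' Detect flow-based communities at one integration time
#'
#' The flow matrix at time `t` is symmetrized (default: entrywise minimum
#' with its transpose, so a pair is strongly connected only if both
#' directions carry flow), the diagonal is zeroed, negatives are clipped,
#' and weighted modularity maximization (Louvain) is run with `n_runs`
#' seeded restarts; the best-modularity partition is kept (ties broken by
#' the lowest run index).
#'
#' @param ft A `"flow_tensor"`.
#' @param t Integration time, must be on the tensor's `t_grid`.
#' @param n_runs Number of seeded Louvain restarts.
#' @param seed Base seed for the restarts.
#' @param resolution Modularity resolution parameter.
#' @param symmetrize `"min"` (default) or `"mean"`.
#' @return Named integer vector of community labels, with attributes
#'   `"modularity"` and `"t"`.
#' @export
detect_communities <- function(ft, t, n_runs = 20, seed = 0, resolution = 1,
                               symmetrize = c("min", "mean")) {
  stopifnot(inherits(ft, "flow_tensor"))
  symmetrize <- match.arg(symmetrize)
  tg <- attr(ft, "t_grid")
  k <- which(abs(tg - t) < 1e-9)
  if (length(k) != 1L) stop("'t' must be one of the tensor's t_grid values")
  F_ <- unclass(ft)[, , k]
  if (max(F_) - min(F_) < 1e-15)
    stop("flow matrix at t is homogeneous; community structure undefined")
  W <- if (symmetrize == "min") pmin(F_, t(F_)) else (F_ + t(F_)) / 2
  diag(W) <- 0
  W[W < 0] <- 0
  if (max(W) == 0) stop("symmetrized flow matrix is all-zero")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_runs)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    q <- max(cl$modularity)
    if (q > best_q + 1e-12) { best_q <- q; best <- cl }
  }
  memb <- igraph::membership(best)
  structure(as.integer(memb), names = rownames(F_),
            modularity = best_q, t = tg[k])
}

#' Coparticipation matrix across community partitions
#'
#' Entry (i, j) is the fraction of partitions in which regions i and j
#' share a community; the diagonal is 1.
#'
#' @param partitions List of labeled partitions (named vectors as returned
#'   by [detect_communities()]) over the same region set.
#' @return An object of class `"community_result"` with elements
#'   `partitions`, `coparticipation`, `n_runs`.
#' @export
coparticipation <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one partition")
  nm <- names(partitions[[1]])
  n <- length(partitions[[1]])
  cp <- matrix(0, n, n)
  for (p in partitions) {
    if (length(p) != n || !identical(names(p), nm))
      stop("all partitions must cover the same region set in the same order")
    cp <- cp + outer(p, p, `==`)
  }
  cp <- cp / length(partitions)
  dimnames(cp) <- list(nm, nm)
  structure(list(partitions = partitions, coparticipation = cp,
                 n_runs = length(partitions)),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("Community coparticipation over %d partition(s), %d regions\n",
              x$n_runs, nrow(x$coparticipation)))
  cat(sprintf("  mean off-diagonal coparticipation: %.3f\n",
              mean(x$coparticipation[row(x$coparticipation) !=
                                       col(x$coparticipation)])))
  invisible(x)
}
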
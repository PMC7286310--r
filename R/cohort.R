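#' Specification of a synthetic multi-subject cohort
#'
#' Defines the study design emulated by the generator: a shared structural
#' mask and ground-truth EC, per-subject multiplicative variability on the
#' existing links, and condition-specific EC/input modulations. The default
#' desk-scale design is 20 regions, 10 subjects, 2 rest + 3 movie sessions
#' of 300 time points at TR = 2 s; `paper_scale = TRUE` switches to
#' 66 regions and 22 subjects.
#'
#' Condition effects: every non-rest condition multiplies a shared set of
#' `n_effect_links` links by `effect_size` (the coarse rest-vs-task
#' signal); when there are several non-rest conditions each additionally
#' gets its own `n_extra_links` modulated links, so the fine task
#' contrasts nest the coarse one. Non-rest conditions also scale the input
#' variance of the first `n_sensory` regions by `sigma_boost` (stimulus
#' load on sensory regions).
#'
#' @param n_rois Number of regions (default 20).
#' @param n_subjects Number of subjects (default 10).
#' @param conditions Named integer vector of sessions per condition
#'   (default `c(rest = 2, movie = 3)`).
#' @param density Structural-mask density over off-diagonal entries
#'   (default 0.28).
#' @param tr Sampling period in seconds (default 2).
#' @param tau Leakage time constant in seconds (default 2 * tr).
#' @param duration_tr Time points per session (default 300).
#' @param n_effect_links Links modulated in every non-rest condition
#'   (default 10).
#' @param effect_size Multiplicative effect on modulated links
#'   (default 1.5).
#' @param n_extra_links Condition-specific extra links per non-rest
#'   condition (default 5).
#' @param subject_sd Lognormal spread (sdlog) of per-subject EC jitter
#'   (default 0.1).
#' @param sigma_boost Input-variance factor on sensory regions in non-rest
#'   conditions (default 1.5).
#' @param n_sensory Number of designated sensory regions (default
#'   `max(2, round(0.2 * n_rois))`).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of (spec, seed).
#' @param paper_scale Use the 66-region, 22-subject preset.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_rois = 20, n_subjects = 10,
                        conditions = c(rest = 2, movie = 3),
                        density = 0.28, tr = 2, tau = 2 * tr,
                        duration_tr = 300, n_effect_links = 10,
                        effect_size = 1.5, n_extra_links = 5,
                        subject_sd = 0.1, sigma_boost = 1.5,
                        n_sensory = max(2L, round(0.2 * n_rois)),
                        seed = 0, paper_scale = FALSE) {
  if (paper_scale) { n_rois <- 66; n_subjects <- 22 }
  stopifnot(n_rois >= 2, n_subjects >= 1, all(conditions >= 1),
            density > 0, density < 1, tr > 0, tau > 0, duration_tr >= 3,
            effect_size > 0, subject_sd >= 0, sigma_boost > 0)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("'conditions' must be a named vector of session counts")
  structure(list(n_rois = as.integer(n_rois),
                 n_subjects = as.integer(n_subjects),
                 conditions = conditions, density = density, tr = tr,
                 tau = tau, duration_tr = as.integer(duration_tr),
                 n_effect_links = as.integer(n_effect_links),
                 effect_size = effect_size,
                 n_extra_links = as.integer(n_extra_links),
                 subject_sd = subject_sd, sigma_boost = sigma_boost,
                 n_sensory = as.integer(n_sensory),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.rescale_stable <- function(C, tau, margin = 0.1 / tau, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    J <- t(C); diag(J) <- -1 / tau
    if (max(Re(eigen(J, only.values = TRUE)$values)) <= -margin) return(C)
    C <- C * 0.75
  }
  stop("could not stabilize the ground-truth network after 20 rescalings")
}

#' Generate a ground-truth network
#'
#' Draws a random directed structural mask at the requested density
#' (exactly `round(density * N * (N - 1))` links, no self-loops), draws
#' positive lognormal weights on the mask, and rescales them globally
#' until the Jacobian's spectral margin is at most -0.1/tau. Sigma = I.
#'
#' @param spec A [cohort_spec()].
#' @return List with `mask` (0/1 matrix) and `model` (a stable [mou()]).
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_rois
  off <- which(row(diag(n)) != col(diag(n)))
  n_links <- round(spec$density * n * (n - 1))
  mask <- matrix(0L, n, n)
  mask[sample(off, n_links)] <- 1L
  C <- matrix(0, n, n)
  # initial scale ~ 1/(tau * in-degree) keeps the first draw near stability
  C[mask == 1L] <- rlnorm(n_links, meanlog = log(1 / (spec$tau * n * spec$density)),
                          sdlog = 0.5)
  C <- .rescale_stable(C, spec$tau)
  rn <- paste0("ROI", seq_len(n))
  dimnames(mask) <- list(rn, rn)
  list(mask = mask, model = mou(ec = C, sigma = 1, tau = spec$tau,
                                roi_names = rn))
}

#' Generate a synthetic multi-subject, multi-condition cohort
#'
#' Per subject, the ground-truth EC is jittered multiplicatively
#' (lognormal, existing links only, topology shared) and restabilized;
#' per condition, effect links are multiplied by the effect size and the
#' input variance of sensory regions is boosted; sessions are then
#' simulated with [simulate.mou()]. Every session's true parameters are
#' recorded for recovery tests. Regeneration from the same spec is
#' bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `"mou_cohort"`: list with `spec`, `mask`,
#'   `ground_truth` (the group-level [mou()]), `effect_links` (shared and
#'   per-condition extra links), `sessions` (list of [mou_session()]),
#'   `manifest` (data frame: session_id, subject, condition, seed), and
#'   `true_models` (per-session [mou()] objects).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gt <- make_ground_truth(spec)
  n <- spec$n_rois
  mask_idx <- which(gt$mask == 1L)
  set.seed(spec$seed + 1L)

  cond_names <- names(spec$conditions)
  task_conds <- cond_names[cond_names != "rest"]
  n_eff <- min(spec$n_effect_links, length(mask_idx))
  shared <- sample(mask_idx, n_eff)
  extra <- list()
  if (length(task_conds) > 1) {
    pool <- setdiff(mask_idx, shared)
    for (cn in task_conds) {
      n_x <- min(spec$n_extra_links, length(pool))
      extra[[cn]] <- sample(pool, n_x)
      pool <- setdiff(pool, extra[[cn]])
    }
  }
  sensory <- seq_len(min(spec$n_sensory, n))

  subj_seeds <- sample.int(2^30, spec$n_subjects)
  sessions <- list()
  true_models <- list()
  manifest <- NULL
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%02d", s)
    set.seed(subj_seeds[s])
    Cs <- gt$model$ec
    Cs[mask_idx] <- Cs[mask_idx] *
      rlnorm(length(mask_idx), meanlog = 0, sdlog = spec$subject_sd)
    Cs <- tryCatch(.rescale_stable(Cs, spec$tau),
                   error = function(cond)
                     stop(sprintf("subject %s: %s", sid, conditionMessage(cond))))
    sess_seeds <- sample.int(2^30, sum(spec$conditions))
    si <- 0L
    for (cn in cond_names) {
      for (rep in seq_len(spec$conditions[[cn]])) {
        si <- si + 1L
        Csc <- Cs
        sig <- rep(1, n)
        if (cn != "rest") {
          Csc[shared] <- Csc[shared] * spec$effect_size
          if (!is.null(extra[[cn]]))
            Csc[extra[[cn]]] <- Csc[extra[[cn]]] * spec$effect_size
          sig[sensory] <- sig[sensory] * spec$sigma_boost
        }
        Csc <- tryCatch(.rescale_stable(Csc, spec$tau),
                        error = function(cond)
                          stop(sprintf("subject %s condition %s: %s",
                                       sid, cn, conditionMessage(cond))))
        m <- mou(ec = Csc, sigma = sig, tau = spec$tau,
                 roi_names = gt$model$roi_names)
        id <- sprintf("%s_%s%d", sid, cn, rep)
        sessions[[id]] <- simulate(m, nsim = spec$duration_tr,
                                   seed = sess_seeds[si], tr = spec$tr,
                                   subject_id = sid, condition = cn)
        true_models[[id]] <- m
        manifest <- rbind(manifest,
                          data.frame(session_id = id, subject = sid,
                                     condition = cn, seed = sess_seeds[si],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(spec = spec, mask = gt$mask, ground_truth = gt$model,
                 effect_links = list(shared = shared, extra = extra),
                 sessions = sessions, manifest = manifest,
                 true_models = true_models),
            class = "mou_cohort")
}

#' @export
print.mou_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MOU cohort: %d subjects x %d sessions (%s), %d regions\n",
              x$spec$n_subjects, sum(x$spec$conditions),
              paste(sprintf("%s x%d", names(x$spec$conditions),
                            x$spec$conditions), collapse = ", "),
              x$spec$n_rois))
  cat(sprintf("  %d sessions of %d TRs at TR = %g s; mask density %.3f\n",
              length(x$sessions), x$spec$duration_tr, x$spec$tr,
              mean(x$mask[row(x$mask) != col(x$mask)])))
  invisible(x)
}

#' Connectivity features for every session of a cohort
#'
#' Computes one feature vector per session: `"fc"` takes the upper
#' triangle of the empirical zero-lag covariance (cheap, model-free);
#' `"ec"` fits the MOU model to each session ([mou_fit()]) and vectorizes
#' the estimated EC over the structural mask; `"true_ec"` vectorizes the
#' session's ground-truth EC (noise-free reference).
#'
#' @param cohort A `"mou_cohort"`.
#' @param type `"fc"`, `"ec"`, or `"true_ec"`.
#' @param control [mou_control()] used for per-session fits when
#'   `type = "ec"`.
#' @param verbose Print a progress message per session.
#' @return A [cohort_features()] object.
#' @export
cohort_features_of <- function(cohort, type = c("fc", "ec", "true_ec"),
                               control = mou_control(), verbose = FALSE) {
  stopifnot(inherits(cohort, "mou_cohort"))
  type <- match.arg(type)
  n <- cohort$spec$n_rois
  ids <- names(cohort$sessions)
  rows <- lapply(ids, function(id) {
    if (type == "fc") {
      v <- vectorize_connectivity(empirical_covariances(cohort$sessions[[id]])$q0)
    } else if (type == "true_ec") {
      v <- vectorize_connectivity(cohort$true_models[[id]]$ec, mask = cohort$mask)
    } else {
      if (verbose) message("fitting ", id)
      fit <- mou_fit(cohort$sessions[[id]], mask = cohort$mask,
                     tau = cohort$spec$tau, control = control)
      v <- vectorize_connectivity(coef(fit), mask = cohort$mask)
    }
    v
  })
  features <- do.call(rbind, lapply(rows, `[[`, "values"))
  cohort_features(features,
                  subject = cohort$manifest$subject,
                  condition = cohort$manifest$condition,
                  index = rows[[1]]$index, session = ids)
}
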
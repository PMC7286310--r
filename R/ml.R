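#' Vectorize a connectivity matrix into a feature vector
#'
#' EC mode (`mask` given) takes the masked entries in row-major order
#' (source-major); FC mode (`mask = NULL`) takes the upper triangle in
#' row-major order. The index of (source, target) pairs is recorded so
#' features map back to region pairs.
#'
#' @param m Square connectivity matrix.
#' @param mask Optional 0/1 mask selecting directed entries; `NULL` for
#'   upper-triangle (symmetric) mode.
#' @return List with `values` (length-L numeric) and `index` (L x 2 matrix
#'   of source/target indices).
#' @export
vectorize_connectivity <- function(m, mask = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("'m' must be square")
  if (is.null(mask)) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
  } else {
    mask <- as.matrix(mask)
    if (any(dim(mask) != n)) stop("mask shape does not match matrix")
    idx <- which(mask != 0, arr.ind = TRUE)
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("source", "target")
  list(values = m[idx], index = idx)
}

#' Scatter a feature vector back into a matrix
#'
#' Inverse of [vectorize_connectivity()] on the indexed entries; all other
#' entries are zero (FC mode is mirrored to keep symmetry).
#'
#' @param values Length-L numeric vector.
#' @param index L x 2 source/target index matrix.
#' @param n Matrix dimension.
#' @param symmetric Mirror entries across the diagonal (FC mode).
#' @return N x N matrix.
#' @export
scatter_connectivity <- function(values, index, n, symmetric = FALSE) {
  m <- matrix(0, n, n)
  m[index] <- values
  if (symmetric) m[index[, c(2, 1), drop = FALSE]] <- values
  m
}

#' Assemble per-session connectivity features for classification
#'
#' @param features S x L numeric matrix, one row per session.
#' @param subject,condition Length-S label vectors.
#' @param index Optional L x 2 source/target index (from
#'   [vectorize_connectivity()]).
#' @param session Optional session identifiers.
#' @return An object of class `"cohort_features"`.
#' @export
cohort_features <- function(features, subject, condition, index = NULL,
                            session = NULL) {
  features <- as.matrix(features)
  s <- nrow(features)
  if (length(subject) != s || length(condition) != s)
    stop("labels must match the number of feature rows")
  if (any(!is.finite(features))) stop("features must be finite")
  if (is.null(session)) session <- as.character(seq_len(s))
  structure(list(features = features, subject = as.character(subject),
                 condition = as.character(condition),
                 session = as.character(session), index = index),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("Cohort features: %d sessions x %d links, %d subjects, conditions: %s\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$subject)),
              paste(names(table(x$condition)), collapse = ", ")))
  invisible(x)
}

.get_labels <- function(cf, label_field) {
  switch(label_field, condition = cf$condition, subject = cf$subject,
         stop("'label_field' must be 'condition' or 'subject'"))
}

#' Majority-class chance level
#'
#' The frequency of the most common label, the accuracy of always
#' predicting the majority class.
#'
#' @param labels Label vector.
#' @return Scalar in (0, 1].
#' @export
chance_level <- function(labels) max(table(labels)) / length(labels)

#' Probability of repeating a group test split
#'
#' Analytic birthday-problem probability that `n_draws` random draws of a
#' test set of `test_size` groups out of `n_groups` repeat at least one
#' split: 1 - prod_{i=0}^{n_draws-1} (1 - i / choose(n_groups, test_size)).
#'
#' @param n_groups Number of groups (e.g. subjects).
#' @param test_size Groups per test set.
#' @param n_draws Number of random splits.
#' @return Collision probability in \[0, 1\].
#' @export
split_collision_probability <- function(n_groups, test_size, n_draws) {
  m <- choose(n_groups, test_size)
  1 - prod(1 - (0:(n_draws - 1)) / m)
}

# --- cross-validated classification ----------------------------------------

.make_splits <- function(cf, label_field, scheme, n_splits, test_frac, seed) {
  subjects <- unique(cf$subject)
  set.seed(seed)
  splits <- list()
  if (label_field == "subject") {
    if (scheme == "loso")
      stop("leave-one-subject-out is incompatible with subject identification")
    # split sessions within each subject so every subject is in train and test
    for (r in seq_len(n_splits)) {
      test <- logical(length(cf$subject))
      for (s in subjects) {
        id <- which(cf$subject == s)
        n_test <- max(1L, round(test_frac * length(id)))
        if (n_test >= length(id)) n_test <- length(id) - 1L
        test[sample(id, n_test)] <- TRUE
      }
      splits[[r]] <- test
    }
  } else if (scheme == "shuffle") {
    n_test <- max(1L, round(test_frac * length(subjects)))
    if (n_test >= length(subjects)) stop("test fraction leaves no training subjects")
    for (r in seq_len(n_splits)) {
      ts <- sample(subjects, n_test)
      splits[[r]] <- cf$subject %in% ts
    }
  } else { # loso
    splits <- lapply(subjects, function(s) cf$subject == s)
  }
  splits
}

.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

.fit_predict <- function(classifier, xtr, ytr, xte, k = 1) {
  ytr <- factor(ytr)
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))
  if (classifier == "mlr") {
    df <- data.frame(.y = ytr, xtr, check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = df, decay = 1.0, trace = FALSE,
                          maxit = 200, MaxNWts = 1e6)
    as.character(predict(fit, newdata = data.frame(xte, check.names = FALSE)))
  } else if (classifier == "lda") {
    fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
    as.character(predict(fit, xte)$class)
  } else { # knn with 1 - Pearson correlation distance
    S <- cor(t(xte), t(xtr))
    apply(S, 1, function(s) {
      nb <- order(s, decreasing = TRUE)[seq_len(k)]
      votes <- table(as.character(ytr[nb]))
      names(votes)[which.max(votes)]
    })
  }
}

#' Cross-validated classification of connectivity features
#'
#' Classifies sessions by condition or subject identity from vectorized
#' connectivity features. For condition prediction, splits are made by
#' subject groups (all sessions of a subject fall on one side) to avoid
#' paired sessions inflating the test accuracy; for subject prediction,
#' sessions are split within each subject. Features are standardized on
#' the training fold only.
#'
#' @param cf A [cohort_features()] object.
#' @param label_field `"condition"` or `"subject"`.
#' @param classifier `"mlr"` (multinomial logistic regression, L2 penalty),
#'   `"lda"`, or `"knn"` (1 - Pearson correlation distance).
#' @param scheme `"shuffle"` (repeated 80:20 subject splits) or `"loso"`
#'   (leave one subject out).
#' @param n_splits Number of shuffle repetitions (default 40).
#' @param test_frac Test fraction of subjects (default 0.2).
#' @param k Neighbors for the kNN classifier (default 1).
#' @param seed Seed controlling the splits.
#' @param standardize Standardize features on the train fold (default TRUE).
#' @return An object of class `"classification_result"` with per-split
#'   accuracies, their mean, the majority-class chance level, and the
#'   summed confusion matrix (true x predicted).
#' @export
classify_cv <- function(cf, label_field = c("condition", "subject"),
                        classifier = c("mlr", "lda", "knn"),
                        scheme = c("shuffle", "loso"), n_splits = 40,
                        test_frac = 0.2, k = 1, seed = 0,
                        standardize = TRUE) {
  stopifnot(inherits(cf, "cohort_features"))
  label_field <- match.arg(label_field)
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  y <- .get_labels(cf, label_field)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  splits <- .make_splits(cf, label_field, scheme, n_splits, test_frac, seed)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  acc <- numeric(length(splits))
  for (r in seq_along(splits)) {
    test <- splits[[r]]
    if (!all(classes %in% y[!test]))
      stop("a split leaves a class absent from the training set")
    xtr <- cf$features[!test, , drop = FALSE]
    xte <- cf$features[test, , drop = FALSE]
    if (standardize) {
      z <- .standardize(xtr, xte); xtr <- z$train; xte <- z$test
    }
    pred <- .fit_predict(classifier, xtr, y[!test], xte, k = k)
    acc[r] <- mean(pred == y[test])
    for (i in seq_along(pred))
      conf[y[test][i], pred[i]] <- conf[y[test][i], pred[i]] + 1L
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 chance_level = chance_level(y), confusion = conf,
                 classifier = classifier, scheme = scheme,
                 label_field = label_field, n_splits = length(splits),
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s classification of %s (%s CV, %d splits)\n",
              toupper(x$classifier), x$label_field, x$scheme, x$n_splits))
  cat(sprintf("  mean accuracy %.3f (sd %.3f), chance level %.3f\n",
              x$mean_accuracy, sd(x$accuracies), x$chance_level))
  invisible(x)
}

# --- recursive feature elimination ------------------------------------------

.mlr_ranking <- function(x, y, step_frac) {
  # elimination order on (x, y); returns feature ranks (1 = kept longest)
  L <- ncol(x)
  remaining <- seq_len(L)
  order_out <- integer(0)
  colnames(x) <- paste0("f", seq_len(L))
  while (length(remaining) > 1) {
    df <- data.frame(.y = factor(y), x[, remaining, drop = FALSE],
                     check.names = FALSE)
    fit <- nnet::multinom(.y ~ ., data = df, decay = 1.0, trace = FALSE,
                          maxit = 200, MaxNWts = 1e6)
    co <- coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
    w <- apply(abs(co[, -1, drop = FALSE]), 2, max)  # drop intercept
    n_drop <- max(1L, floor(step_frac * length(remaining)))
    n_drop <- min(n_drop, length(remaining) - 1L)
    drop_idx <- order(w)[seq_len(n_drop)]
    order_out <- c(order_out, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  order_out <- c(order_out, remaining)
  rank <- integer(L)
  rank[rev(order_out)] <- seq_len(L)  # last eliminated = rank 1
  rank
}

#' Recursive feature elimination biomarker
#'
#' Iteratively fits the L2-penalized multinomial logistic regression and
#' drops the `step` fraction of remaining features with the smallest
#' maximum-absolute coefficient across classes, yielding a full feature
#' ranking. Cross-validated accuracy is recorded along the elimination
#' path (eliminations recomputed inside each training fold, so no test
#' information leaks), and the support network is the top-k ranked
#' features at the accuracy maximum (smallest set on ties).
#'
#' @param cf A [cohort_features()] object.
#' @param label_field `"condition"` or `"subject"`.
#' @param step Fraction of remaining features eliminated per iteration
#'   (default 0.05).
#' @param scheme,n_splits,test_frac,seed Cross-validation settings as in
#'   [classify_cv()].
#' @param standardize Standardize on train folds (default TRUE).
#' @return An object of class `"biomarker_ranking"` with `rank` (1 = most
#'   informative), `support` (logical), `accuracy_curve` (data frame of
#'   retained-set size vs mean CV accuracy), and `fold_orders` (per-fold
#'   elimination orders, for leakage audits).
#' @export
rfe_biomarker <- function(cf, label_field = c("condition", "subject"),
                          step = 0.05, scheme = c("shuffle", "loso"),
                          n_splits = 10, test_frac = 0.2, seed = 0,
                          standardize = TRUE) {
  stopifnot(inherits(cf, "cohort_features"))
  label_field <- match.arg(label_field)
  scheme <- match.arg(scheme)
  L <- ncol(cf$features)
  if (L < 2) stop("need at least 2 features for elimination")
  y <- .get_labels(cf, label_field)
  classes <- sort(unique(y))
  splits <- .make_splits(cf, label_field, scheme, n_splits, test_frac, seed)

  # retained-set sizes along the elimination path
  sizes <- L
  while (tail(sizes, 1) > 1) {
    n_drop <- max(1L, floor(step * tail(sizes, 1)))
    sizes <- c(sizes, max(1L, tail(sizes, 1) - n_drop))
  }

  acc <- matrix(NA_real_, length(splits), length(sizes))
  fold_orders <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    test <- splits[[r]]
    if (!all(classes %in% y[!test]))
      stop("a split leaves a class absent from the training set")
    xtr <- cf$features[!test, , drop = FALSE]
    xte <- cf$features[test, , drop = FALSE]
    if (standardize) {
      z <- .standardize(xtr, xte); xtr <- z$train; xte <- z$test
    }
    rk <- .mlr_ranking(xtr, y[!test], step)
    fold_orders[[r]] <- order(rk)  # feature indices, most informative first
    for (ci in seq_along(sizes)) {
      keep <- fold_orders[[r]][seq_len(sizes[ci])]
      pred <- .fit_predict("mlr", xtr[, keep, drop = FALSE], y[!test],
                           xte[, keep, drop = FALSE])
      acc[r, ci] <- mean(pred == y[test])
    }
  }
  curve <- data.frame(n_features = sizes, accuracy = colMeans(acc))
  # final ranking refit on all samples (standardized globally)
  xall <- cf$features
  if (standardize) xall <- .standardize(xall, xall)$train
  rank <- .mlr_ranking(xall, y, step)
  best_size <- min(sizes[curve$accuracy >= max(curve$accuracy) - 1e-12])
  support <- rank <= best_size
  structure(list(rank = rank, support = support, accuracy_curve = curve,
                 fold_orders = fold_orders, label_field = label_field,
                 seed = seed),
            class = "biomarker_ranking")
}

#' @export
print.biomarker_ranking <- function(x, ...) {
  cat(sprintf("RFE biomarker: %d features, support size %d, peak CV accuracy %.3f\n",
              length(x$rank), sum(x$support), max(x$accuracy_curve$accuracy)))
  invisible(x)
}

# --- dimensionality reduction ----------------------------------------------

#' Dimensionality reduction with clustering quality
#'
#' Projects feature vectors with PCA (unsupervised) or LDA (supervised)
#' and scores how well the labels separate in the reduced space with the
#' mean silhouette coefficient (Euclidean distance).
#'
#' @param cf A [cohort_features()] object.
#' @param method `"pca"` or `"lda"`.
#' @param n_components Number of components (< min(L, S - 1)).
#' @param label_field Labels used by LDA and by the silhouette.
#' @return List with `components` (S x n_components scores), `silhouette`,
#'   and for PCA `explained_variance`.
#' @export
reduce_and_silhouette <- function(cf, method = c("pca", "lda"),
                                  n_components = 2,
                                  label_field = c("condition", "subject")) {
  stopifnot(inherits(cf, "cohort_features"))
  method <- match.arg(method)
  label_field <- match.arg(label_field)
  y <- factor(.get_labels(cf, label_field))
  S <- nrow(cf$features)
  if (n_components >= min(ncol(cf$features), S - 1))
    stop("'n_components' must be < min(n_features, n_samples - 1)")
  if (method == "pca") {
    pc <- prcomp(cf$features, center = TRUE, scale. = FALSE)
    comp <- pc$x[, seq_len(n_components), drop = FALSE]
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    out <- list(components = comp, explained_variance = expl[seq_len(n_components)],
                rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
  } else {
    if (any(table(y) < 2)) stop("LDA needs at least 2 samples per class")
    n_components <- min(n_components, length(levels(y)) - 1L)
    fit <- suppressWarnings(MASS::lda(cf$features, grouping = y))
    comp <- predict(fit)$x[, seq_len(n_components), drop = FALSE]
    out <- list(components = comp)
  }
  sil <- cluster::silhouette(as.integer(y), dist(out$components))
  out$silhouette <- mean(sil[, "sil_width"])
  out
}

# --- link-wise statistical testing ------------------------------------------

#' Link-wise nonparametric tests across conditions
#'
#' Two-sided Mann-Whitney (or Welch t) test per link and condition pair;
#' for K conditions the per-link p value is the minimum over the
#' K(K-1)/2 pairs. Reports the Bonferroni threshold alpha/L and the
#' Benjamini-Hochberg rejections at FDR alpha.
#'
#' @param cf A [cohort_features()] object.
#' @param alpha Significance level (default 0.05).
#' @param test `"mann-whitney"` (default) or `"welch"`.
#' @return An object of class `"link_test_result"` with `p_values`,
#'   `bonferroni_threshold`, `bh_rejections`, `n_pairs_tested`.
#' @export
linkwise_tests <- function(cf, alpha = 0.05, test = c("mann-whitney", "welch")) {
  stopifnot(inherits(cf, "cohort_features"))
  test <- match.arg(test)
  y <- cf$condition
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 conditions")
  if (any(table(y) < 2)) stop("need at least 2 samples per condition")
  L <- ncol(cf$features)
  const <- apply(cf$features, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop(sprintf("constant feature(s) cannot be tested: %s",
                 paste(which(const), collapse = ", ")))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pmat <- vapply(pairs, function(pr) {
    a <- cf$features[y == pr[1], , drop = FALSE]
    b <- cf$features[y == pr[2], , drop = FALSE]
    vapply(seq_len(L), function(j) {
      if (test == "mann-whitney")
        suppressWarnings(wilcox.test(a[, j], b[, j], exact = FALSE)$p.value)
      else
        t.test(a[, j], b[, j])$p.value
    }, 0)
  }, numeric(L))
  pmat <- matrix(pmat, nrow = L)
  p <- apply(pmat, 1, min)
  structure(list(p_values = p, bonferroni_threshold = alpha / L,
                 bh_rejections = p.adjust(p, method = "BH") <= alpha,
                 n_pairs_tested = length(pairs), alpha = alpha, test = test),
            class = "link_test_result")
}

#' @export
print.link_test_result <- function(x, ...) {
  cat(sprintf("Link-wise %s tests over %d pair(s) of conditions\n",
              x$test, x$n_pairs_tested))
  cat(sprintf("  %d / %d links pass Bonferroni (threshold %.3g)\n",
              sum(x$p_values < x$bonferroni_threshold), length(x$p_values),
              x$bonferroni_threshold))
  cat(sprintf("  %d links rejected at BH FDR %.2g\n",
              sum(x$bh_rejections), x$alpha))
  invisible(x)
}
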
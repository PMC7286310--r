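test_that("connectivity vectorization is ordered, indexed, and invertible", {
  M <- matrix(1:9, 3, 3, byrow = TRUE)
  mask <- matrix(0, 3, 3); mask[1, 2] <- 1; mask[3, 1] <- 1
  v <- vectorize_connectivity(M, mask)
  expect_equal(v$values, c(M[1, 2], M[3, 1]))
  expect_equal(unname(v$index[, 1]), c(1, 3))
  M2 <- scatter_connectivity(v$values, v$index, 3)
  expect_equal(M2[mask == 1], M[mask == 1])
  expect_equal(sum(M2 != 0), 2)
  # FC mode: upper triangle of a 4x4 has 6 entries
  v4 <- vectorize_connectivity(matrix(rnorm(16), 4))
  expect_equal(length(v4$values), 6L)
  expect_error(vectorize_connectivity(M, matrix(0, 2, 2)), "shape")
})

test_that("chance level and split collision follow the design arithmetic", {
  labels <- rep(c("movie", "movie", "movie", "rest", "rest"), 22)
  expect_equal(chance_level(labels), 0.6)
  p <- split_collision_probability(22, 4, 100)
  expect_gte(p, 0.45)
  expect_lte(p, 0.50)
  # exhaustive tiny case: 2 draws from 3 possible test sets collide with p = 1/3
  expect_equal(split_collision_probability(3, 1, 2), 1 / 3)
})

test_that("a linearly separable cohort is classified perfectly", {
  cf <- synthetic_features(n_subjects = 10, n_features = 30,
                           informative = 1:10, shift = 5, seed = 1)
  res <- classify_cv(cf, "condition", "mlr", "shuffle", n_splits = 10, seed = 0)
  expect_equal(res$mean_accuracy, 1.0)
  for (clf in c("lda", "knn")) {
    res2 <- classify_cv(cf, "condition", clf, "shuffle", n_splits = 10, seed = 0)
    expect_gte(res2$mean_accuracy, 0.95)
  }
  expect_equal(res$chance_level, 0.6)
  expect_equal(sum(res$confusion), 100L)  # 10 splits x 2 test subjects x 5 sessions
})

test_that("shuffled labels give chance-level accuracy", {
  cf <- synthetic_features(n_subjects = 10, n_features = 30,
                           informative = 1:10, shift = 5, seed = 2)
  set.seed(99)
  cf$condition <- sample(cf$condition)  # break label-subject pairing
  res <- classify_cv(cf, "condition", "mlr", "shuffle", n_splits = 40, seed = 0)
  se <- sd(res$accuracies) / 1  # spread of split accuracies
  expect_lt(abs(res$mean_accuracy - res$chance_level), 3 * max(se, 0.05))
})

test_that("subject-grouped splits never leak subjects and are reproducible", {
  cf <- synthetic_features(n_subjects = 8, n_features = 10, seed = 3)
  r1 <- classify_cv(cf, "condition", "mlr", "shuffle", n_splits = 5, seed = 7)
  r2 <- classify_cv(cf, "condition", "mlr", "shuffle", n_splits = 5, seed = 7)
  expect_identical(r1$accuracies, r2$accuracies)
  # loso: one subject out per split, 8 splits
  r3 <- classify_cv(cf, "condition", "mlr", "loso", seed = 1)
  expect_equal(r3$n_splits, 8L)
  expect_equal(unname(rowSums(r3$confusion)), as.numeric(table(cf$condition)))
})

test_that("RFE ranks planted informative links at the top", {
  cf <- synthetic_features(n_subjects = 12, n_features = 100,
                           informative = c(4, 19, 33, 57, 90), shift = 2.5,
                           seed = 4)
  bm <- rfe_biomarker(cf, "condition", n_splits = 5, seed = 0)
  expect_true(all(sort(bm$rank) == seq_len(100)))
  expect_true(all(bm$rank[c(4, 19, 33, 57, 90)] <= 10))
  expect_true(all(bm$rank[bm$support] <= sum(bm$support)))
})

test_that("the RFE accuracy curve at the full set matches plain classification", {
  cf <- synthetic_features(n_subjects = 8, n_features = 20,
                           informative = 1:4, shift = 1.5, seed = 5)
  bm <- rfe_biomarker(cf, "condition", n_splits = 5, seed = 3)
  res <- classify_cv(cf, "condition", "mlr", "shuffle", n_splits = 5, seed = 3)
  expect_equal(bm$accuracy_curve$accuracy[1], res$mean_accuracy)
})

test_that("RFE eliminations ignore the test fold (no leakage sentinel)", {
  cf <- synthetic_features(n_subjects = 8, n_features = 15,
                           informative = 1:3, shift = 2, seed = 6)
  bm1 <- rfe_biomarker(cf, "condition", n_splits = 3, seed = 1)
  # corrupt only sessions in the first split's test fold
  splits <- mouflow:::.make_splits(cf, "condition", "shuffle", 3, 0.2, 1)
  cf2 <- cf
  cf2$features[splits[[1]], ] <- cf2$features[splits[[1]], ] + 1e4
  bm2 <- rfe_biomarker(cf2, "condition", n_splits = 3, seed = 1)
  expect_identical(bm1$fold_orders[[1]], bm2$fold_orders[[1]])
})

test_that("nested contrasts share biomarker support", {
  # 4-condition design whose fine effects extend the coarse rest-vs-task set
  set.seed(7)
  n_sub <- 12; L <- 60
  coarse <- 1:6
  fine <- list(task1 = 7:9, task2 = 10:12, task3 = 13:15)
  rows <- list(); subject <- condition <- character(0)
  for (s in seq_len(n_sub)) {
    for (cn in c("rest", "rest", "task1", "task2", "task3")) {
      x <- rnorm(L)
      if (cn != "rest") {
        x[coarse] <- x[coarse] + 2
        x[fine[[cn]]] <- x[fine[[cn]]] + 2
      }
      rows[[length(rows) + 1]] <- x
      subject <- c(subject, sprintf("sub%02d", s)); condition <- c(condition, cn)
    }
  }
  cf4 <- cohort_features(do.call(rbind, rows), subject, condition)
  cf2 <- cf4
  cf2$condition <- ifelse(cf4$condition == "rest", "rest", "task")
  bm2 <- rfe_biomarker(cf2, "condition", n_splits = 4, seed = 0)
  bm4 <- rfe_biomarker(cf4, "condition", n_splits = 4, seed = 0)
  overlap <- sum(bm2$support & bm4$support) / max(1, sum(bm2$support))
  expect_gte(overlap, 0.5)
})

test_that("dimensionality reduction scores cluster separation", {
  cf <- synthetic_features(n_subjects = 10, n_features = 20,
                           informative = 1:10, shift = 8, seed = 8)
  pca <- reduce_and_silhouette(cf, "pca", n_components = 2)
  expect_gt(pca$silhouette, 0.9)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  rot <- pca$rotation
  expect_equal(crossprod(rot), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  lda <- reduce_and_silhouette(cf, "lda", n_components = 1)
  expect_gt(lda$silhouette, 0.9)
  # one blob randomly split into two labels: silhouette near zero
  cf0 <- synthetic_features(n_subjects = 10, n_features = 20, seed = 9)
  set.seed(1); cf0$condition <- sample(cf0$condition)
  pca0 <- reduce_and_silhouette(cf0, "pca", n_components = 2)
  expect_lt(abs(pca0$silhouette), 0.2)
})

test_that("link-wise tests calibrate under the null and detect planted shifts", {
  # null: identical distributions in both conditions
  cf0 <- synthetic_features(n_subjects = 20, sessions_per = c(rest = 1, task = 1),
                            n_features = 200, seed = 10)
  lt0 <- linkwise_tests(cf0)
  expect_lte(mean(lt0$bh_rejections), 0.05)
  # planted 3-pooled-SD shift on 10 of 200 links, 20 per group
  cf1 <- synthetic_features(n_subjects = 20, sessions_per = c(rest = 1, task = 1),
                            n_features = 200, informative = 1:10, shift = 3,
                            seed = 11)
  lt1 <- linkwise_tests(cf1)
  expect_true(all(lt1$p_values[1:10] < lt1$bonferroni_threshold))
  # BH monotonicity across FDR levels
  rej01 <- p.adjust(lt1$p_values, "BH") <= 0.01
  expect_true(all(which(rej01) %in% which(lt1$bh_rejections)))
})

test_that("the Bonferroni threshold matches the whole-brain link count", {
  cf <- synthetic_features(n_subjects = 4, sessions_per = c(rest = 1, task = 1),
                           n_features = 5, seed = 12)
  lt <- linkwise_tests(cf)
  expect_equal(lt$bonferroni_threshold, 0.05 / 5)
  # the paper-scale threshold in -log10 units: 1180 links
  expect_equal(-log10(0.05 / 1180), 4.373, tolerance = 1e-3)
  # constant features are reported, not dropped
  cfc <- cf
  cfc$features[, 2] <- 1
  expect_error(linkwise_tests(cfc), "constant")
})

test_that("multi-condition tests keep the smallest pairwise p value", {
  cf <- synthetic_features(n_subjects = 10,
                           sessions_per = c(rest = 1, a = 1, b = 1),
                           n_features = 10, seed = 13)
  # shift link 1 only in condition b so only one pair is informative
  cf$features[cf$condition == "b", 1] <- cf$features[cf$condition == "b", 1] + 5
  lt <- linkwise_tests(cf)
  expect_equal(lt$n_pairs_tested, 3L)
  expect_lt(lt$p_values[1], 0.01)
})
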
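# PCA reduction, the dense-layer classifier, false-label management,
# leave-one-subject-out cross-validation, and group evaluation.

test_that("PCA reduces 13 features to 6 orthonormal components", {
  set.seed(15)
  x <- matrix(rnorm(50 * 13), 50, 13)
  pca <- fit_pca(x)
  proj <- predict(pca, x)
  expect_identical(ncol(proj), 6L)
  expect_equal(crossprod(pca$rotation), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA matches the covariance-eigendecomposition oracle up to sign", {
  set.seed(16)
  x <- matrix(rnorm(50 * 13), 50, 13)
  pca <- fit_pca(x)
  oracle <- pca_eigen_oracle(x, 6)
  expect_equal(pca$sdev[1:6]^2, oracle$values, tolerance = 1e-8)
  for (j in 1:6) {
    expect_equal(abs(sum(pca$rotation[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient training features are rejected with the rank named", {
  set.seed(17)
  base <- matrix(rnorm(30 * 3), 30, 3)
  x <- base[, c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3, 1)]  # rank 3
  expect_error(fit_pca(x), "rank 3")
  expect_error(fit_pca(matrix(rnorm(5 * 13), 5, 13)), "at least 7")
})

test_that("the classifier emits a probability simplex and is seed-deterministic", {
  set.seed(18)
  x <- matrix(rnorm(60 * 6), 60, 6)
  labels <- rep(pain_classes(), each = 20)
  m1 <- train_classifier(x, labels, seed = 3)
  m2 <- train_classifier(x, labels, seed = 3)
  expect_identical(m1$net$wts, m2$net$wts)
  p <- predict(m1, x)
  expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-9)
  expect_true(all(p >= 0))
  # simplex also holds far outside the training range
  extreme <- matrix(c(1e4, -1e4, 0, 50, -50, 3), 7, 6, byrow = TRUE)
  pe <- predict(m1, extreme)
  expect_equal(rowSums(pe), rep(1, 7), tolerance = 1e-9)
})

test_that("training demands all three classes", {
  x <- matrix(rnorm(20 * 6), 20, 6)
  expect_error(train_classifier(x, rep(c("pain", "non-pain"), 10), seed = 1),
               "absent.*analgesic")
})

test_that("linearly separable classes are learned to high accuracy", {
  set.seed(19)
  centers <- rbind(c(3, 0), c(-3, 3), c(-3, -3))
  x <- matrix(0, 90, 6)
  labels <- rep(pain_classes(), each = 30)
  for (i in 1:90) {
    k <- (i - 1) %/% 30 + 1
    x[i, 1:2] <- centers[k, ] + rnorm(2, sd = 0.3)
  }
  m <- train_classifier(x, labels, seed = 5)
  acc <- mean(predict(m, x, type = "class") == labels)
  expect_gte(acc, 0.95)
})

test_that("the false-label filter removes exactly the bottom pain fraction", {
  fe <- random_feature_cohort(10, 1, seed = 20, pain_shift = 0.3)
  n_pain <- sum(fe$class == "pain")
  out <- false_label_filter(fe, fraction = 0.10, seed = 1)
  expect_identical(nrow(out$removed), as.integer(floor(0.10 * n_pain)))
  expect_identical(nrow(out$features), nrow(fe) - nrow(out$removed))
  expect_false(any(out$removed$session_id %in% out$features$session_id))
  # only pain-labeled sessions are ever removed
  removed_classes <- fe$class[fe$session_id %in% out$removed$session_id]
  expect_true(all(removed_classes == "pain"))
  # fraction 0 leaves the cohort untouched
  out0 <- false_label_filter(fe, fraction = 0, seed = 1)
  expect_identical(out0$features, fe)
  expect_error(false_label_filter(fe, fraction = 1), "fraction")
})

test_that("planted mislabels are enriched among the removed sessions", {
  # pain sessions carry a shift except for a planted 10% that look non-pain
  fe <- random_feature_cohort(10, 2, seed = 21, pain_shift = 0.4,
                              shift_cols = 1:4)
  pain_idx <- which(fe$class == "pain")
  planted <- pain_idx[seq(1, length(pain_idx), by = 10)]  # 10% of 20
  for (j in 1:4) fe[planted, feature_names()[j]] <- runif(length(planted), 0, 0.2)
  out <- false_label_filter(fe, fraction = 0.10, seed = 2)
  hits <- sum(out$removed$session_id %in% fe$session_id[planted])
  # hypergeometric: P(X >= hits) under random removal must be small
  k <- nrow(out$removed)
  pval <- phyper(hits - 1, length(planted), length(pain_idx) - length(planted),
                 k, lower.tail = FALSE)
  expect_lt(pval, 0.05)
})

test_that("LOSO folds partition the cohort by subject", {
  fe <- random_feature_cohort(6, 2, seed = 22, pain_shift = 0.2)
  res <- loso_cv(fe, seed = 3)
  expect_identical(sort(res$session_id), sort(fe$session_id))
  expect_identical(anyDuplicated(res$session_id), 0L)
  by_fold <- split(res$subject_id, res$fold)
  expect_length(by_fold, 6L)
  for (f in by_fold) expect_length(unique(f), 1L)
  expect_true(all(res$predicted_pain_value >= 0 & res$predicted_pain_value <= 1))
  expect_equal(res$p_nonpain + res$p_pain + res$p_analgesic,
               rep(1, nrow(res)), tolerance = 1e-9)
})

test_that("the LOSO pipeline is deterministic under a fixed seed", {
  fe <- random_feature_cohort(5, 2, seed = 23, pain_shift = 0.2)
  r1 <- loso_cv(fe, seed = 7)
  r2 <- loso_cv(fe, seed = 7)
  attr(r1, "folds") <- attr(r2, "folds") <- NULL
  expect_identical(r1, r2)
})

test_that("held-out subjects cannot influence their fold's model", {
  fe <- random_feature_cohort(5, 2, seed = 24, pain_shift = 0.2)
  res <- loso_cv(fe, seed = 11)
  for (s in c("S01", "S04")) {
    corrupted <- fe
    sel <- corrupted$subject_id == s
    corrupted[sel, feature_names()] <- matrix(runif(sum(sel) * 13, 5, 50),
                                              sum(sel), 13)
    corrupted$class[sel] <- sample(pain_classes(), sum(sel), replace = TRUE)
    res_c <- loso_cv(corrupted, seed = 11)
    f0 <- attr(res, "folds")[[s]]
    f1 <- attr(res_c, "folds")[[s]]
    expect_identical(f0$clf$net$wts, f1$clf$net$wts)
    expect_identical(f0$pca$rotation, f1$pca$rotation)
    expect_identical(f0$means, f1$means)
  }
})

test_that("group evaluation reports means, tests, and AUC", {
  set.seed(25)
  a <- rnorm(20, 0.5, 0.05)
  ev_same <- evaluate_groups(c(a, a), rep(c("g1", "g2"), each = 20))
  expect_gt(ev_same$p_value, 0.99)
  expect_equal(ev_same$auc, 0.5)
  ev_far <- evaluate_groups(c(rnorm(10, 0), rnorm(10, 10)),
                            rep(c("g1", "g2"), each = 10))
  expect_equal(ev_far$auc, 1)
  # Welch t statistic matches the textbook formula
  x <- rnorm(15); y <- rnorm(12, 0.4)
  ev <- evaluate_groups(c(x, y), rep(c("a", "b"), c(15, 12)))
  expect_equal(ev$statistic, welch_t_oracle(x, y), tolerance = 1e-10)
  expect_error(evaluate_groups(c(1, 2, 3), c("a", "a", "b")), ">= 2")
  ev_mw <- evaluate_groups(c(x, y), rep(c("a", "b"), c(15, 12)),
                           test = "mann-whitney")
  expect_true(ev_mw$p_value >= 0 && ev_mw$p_value <= 1)
})
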
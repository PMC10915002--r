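# Activity shares, the D statistic, cell ratios, the correlation feature,
# the 13-feature vector, and the ROC-AUC screen.

test_that("activity shares are floored, renormalized means over the subset", {
  sig <- rbind(rep(3, 10), rep(1, 10))
  s <- make_norm_session(sig)
  expect_equal(activity_shares(s, "total"), c(0.75, 0.25))
  # all-equal ROIs split evenly
  s2 <- make_norm_session(matrix(2, 5, 8))
  expect_equal(activity_shares(s2, "total"), rep(0.2, 5))
  # brute-force oracle on random signals
  set.seed(3)
  for (i in 1:10) {
    sig <- matrix(rnorm(6 * 30, mean = 0.5), 6, 30)
    mask <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    s3 <- make_norm_session(sig, mask)
    m <- numeric(6)
    for (r in 1:6) m[r] <- max(mean(sig[r, mask]), 0)
    expect_equal(activity_shares(s3, "movement"), m / sum(m), tolerance = 1e-12)
  }
})

test_that("empty or degenerate subsets raise classed errors", {
  s <- make_norm_session(matrix(1, 3, 10), rep(FALSE, 10))
  expect_error(activity_shares(s, "movement"), class = "painstate_empty_subset")
  s2 <- make_norm_session(matrix(-1, 3, 10))
  expect_error(activity_shares(s2, "total"), class = "painstate_degenerate_session")
})

test_that("D is the share difference over matched ROIs and sums to zero", {
  a <- make_norm_session(rbind(rep(7, 10), rep(3, 10)))
  b <- make_norm_session(rbind(rep(1, 10), rep(1, 10)))
  D <- compute_D(session_pair(a, b))
  expect_equal(D, c(0.2, -0.2))
  # identical sessions give the zero vector
  expect_equal(compute_D(session_pair(a, a)), c(0, 0))
  # conservation on random pairs
  set.seed(5)
  for (i in 1:20) {
    sa <- make_norm_session(matrix(rnorm(8 * 25, 1), 8, 25))
    sb <- make_norm_session(matrix(rnorm(8 * 25, 1), 8, 25))
    expect_lt(abs(sum(compute_D(session_pair(sa, sb)))), 1e-9)
  }
})

test_that("session pairs validate method, subject, and the ROI map", {
  a <- make_norm_session(matrix(1, 3, 10), method = "deltaF")
  b <- make_norm_session(matrix(1, 3, 10), method = "zscore")
  expect_error(session_pair(a, b), "same normalization")
  c2 <- make_norm_session(matrix(1, 3, 10), subject = "S02")
  expect_error(session_pair(a, c2), "same subject")
  d <- make_norm_session(matrix(1, 3, 10))
  expect_error(session_pair(a, d, cbind(c(1, 1), c(1, 2))), "one-to-one")
  expect_error(session_pair(a, d, cbind(1:3, c(1, 2, 9))), "out of range")
})

test_that("cell ratios count threshold crossings and always sum to one", {
  expect_equal(cell_ratios(c(0.5, -0.5, 0)), c(up = 1/3, down = 1/3, stable = 1/3))
  expect_equal(cell_ratios(rep(0, 4)), c(up = 0, down = 0, stable = 1))
  expect_error(cell_ratios(c(0.1), up_threshold = -0.3, down_threshold = 0.2),
               "exceed")
  set.seed(6)
  for (i in 1:50) {
    D <- runif(20, -1, 1)
    thr <- sort(runif(2, -1, 1))
    r <- cell_ratios(D, up_threshold = thr[2], down_threshold = thr[1])
    expect_equal(unname(r["up"]), sum(D > thr[2]) / 20)
    expect_equal(unname(r["down"]), sum(D < thr[1]) / 20)
    expect_identical(unname(r[["up"]] + r[["down"]] + r[["stable"]]), 1)
  }
})

test_that("raising the up threshold never raises the up ratio", {
  set.seed(7)
  D <- runif(50, -1, 1)
  ups <- vapply(seq(-0.1, 0.9, by = 0.1), function(th)
    cell_ratios(D, up_threshold = th, down_threshold = -0.95)[["up"]],
    numeric(1))
  expect_true(all(diff(ups) <= 0))
})

test_that("swapping the pair negates D and exchanges up/down counts", {
  set.seed(9)
  a <- make_norm_session(matrix(rnorm(10 * 30, 1), 10, 30))
  b <- make_norm_session(matrix(rnorm(10 * 30, 1), 10, 30))
  D1 <- compute_D(session_pair(a, b))
  D2 <- compute_D(session_pair(b, a))
  expect_equal(D1, -D2, tolerance = 1e-12)
  r1 <- cell_ratios(D1, 0.05, -0.05)
  r2 <- cell_ratios(D2, 0.05, -0.05)
  expect_equal(unname(r1["up"]), unname(r2["down"]))
})

test_that("the correlation feature is the mean over all ROI pairs", {
  sig <- rbind(sin(1:50), sin(1:50))
  expect_equal(correlation_feature(sig), 1)
  sig2 <- rbind(sin(1:50), -sin(1:50))
  expect_equal(correlation_feature(sig2), -1)
  set.seed(10)
  sig3 <- matrix(rnorm(10 * 40), 10, 40)
  expect_equal(correlation_feature(sig3), corr_loop_oracle(sig3),
               tolerance = 1e-12)
  # zero-variance ROIs are dropped with a warning
  sig4 <- rbind(rnorm(30), rnorm(30), rep(1, 30))
  expect_warning(cf <- correlation_feature(sig4), "zero-variance")
  expect_equal(cf, cor(sig4[1, ], sig4[2, ]))
  expect_error(suppressWarnings(correlation_feature(rbind(rep(1, 30), rep(2, 30)))),
               "fewer than 2")
})

test_that("feature extraction yields the 13 named features in frozen order", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  p <- cohort_pairs(coh)[[1]]
  fv <- extract_features(p$a, p$b, p$roi_map)
  expect_length(fv, 13L)
  expect_identical(names(fv), feature_names())
  expect_identical(feature_names()[1], "zscore_up_movement")
  expect_identical(feature_names()[13], "correlation")
  ratio <- fv[1:12]
  expect_true(all(ratio >= 0 & ratio <= 1, na.rm = TRUE))
  expect_true(fv["correlation"] >= -1 && fv["correlation"] <= 1)
})

test_that("a session paired with itself has all ratio features zero", {
  cfg <- small_config()
  s <- generate_session(cfg, "S01", "pain", seed = 4)
  fv <- extract_features(s, s)
  expect_equal(unname(fv[1:12]), rep(0, 12))
  expect_equal(unname(fv["correlation"]),
               correlation_feature(normalize_session(s, "deltaF")$signal))
})

test_that("sessions without movement frames get NA sentinels, not errors", {
  cfg <- small_config(movement_bout_rate = 0)
  s1 <- generate_session(cfg, "S01", "pain", seed = 1)
  s2 <- generate_session(cfg, "S01", "non-pain", seed = 2)
  expect_false(any(s1$movement_mask))
  fv <- extract_features(s1, s2)
  expect_true(all(is.na(fv[grep("_movement$", names(fv))])))
  expect_true(all(!is.na(fv[grep("_(stationary|total)$", names(fv))])))
  expect_setequal(attr(fv, "missing_subsets"),
                  c("zscore:movement", "deltaf:movement"))
})

test_that("feature AUC equals the all-pairs Mann-Whitney oracle", {
  expect_equal(feature_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)), 1)
  expect_equal(feature_auc(rep(5, 8), rep(c(FALSE, TRUE), 4)), 0.5)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    v <- sample(c(rnorm(n), round(rnorm(n), 1)), n)  # include ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(feature_auc(v, lab), auc_oracle(v, lab), tolerance = 1e-12)
  }
  expect_error(feature_auc(1:4, rep(TRUE, 4)), "two nonempty groups")
  expect_equal(feature_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                           rectify = TRUE), 1)
})

test_that("the AUC table is 13 x 3 and sits at chance for a null cohort", {
  fe <- random_feature_cohort(6, 2, seed = 12)
  tab <- build_auc_table(fe)
  expect_identical(dim(tab), c(13L, 4L))
  expect_identical(tab$feature, feature_names())
  aucs <- as.matrix(tab[, -1])
  expect_true(all(aucs >= 0 & aucs <= 1))
  expect_lt(max(abs(aucs - 0.5)), 0.25)  # sampling noise around chance
  # planted pain shift drives the affected contrast above chance
  fe2 <- random_feature_cohort(6, 2, seed = 13, pain_shift = 0.5, shift_cols = 1)
  tab2 <- build_auc_table(fe2)
  expect_gt(tab2$baseline_vs_pain[1], 0.9)
})

test_that("the AUC table round-trips through CSV", {
  fe <- random_feature_cohort(4, 1, seed = 14)
  tab <- build_auc_table(fe)
  f <- tempfile(fileext = ".csv")
  data.table::fwrite(tab, f)
  back <- as.data.frame(data.table::fread(f))
  expect_equal(back, tab, tolerance = 1e-12)
})
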
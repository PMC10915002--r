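# Independent brute-force oracles used to pin down expected values.

# Direct dot-product convolution of x with a unit-sum window w at interior
# index i (1-based), no padding.
conv_oracle <- function(x, w, i) {
  half <- (length(w) - 1) / 2
  sum(x[(i - half):(i + half)] * w)
}

# All-pairs Mann-Whitney AUC with ties counted half.
auc_oracle <- function(values, pos) {
  vp <- values[pos]
  vn <- values[!pos]
  wins <- 0
  for (a in vp) for (b in vn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(vp) * length(vn))
}

# PCA via explicit eigendecomposition of the covariance of the
# standardized matrix.
pca_eigen_oracle <- function(x, k) {
  xs <- scale(x)
  e <- eigen(stats::cov(xs), symmetric = TRUE)
  list(values = e$values[seq_len(k)], vectors = e$vectors[, seq_len(k), drop = FALSE])
}

# Mean pairwise Pearson correlation by explicit loop over ROI pairs.
corr_loop_oracle <- function(sig) {
  n <- nrow(sig)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, stats::cor(sig[i, ], sig[j, ]))
  mean(vals)
}

# Welch t statistic from the textbook formula.
welch_t_oracle <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# Small, fast simulation settings for unit tests (overridable).
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2L, n_rois = 10L, duration_s = 60, seed = 99L)
  do.call(simulation_config,
          c(args, defaults[setdiff(names(defaults), names(args))]))
}

# A normalized_session built directly from a signal matrix (bypasses
# preprocessing; used for feature-level tests).
make_norm_session <- function(signal, movement_mask = rep(FALSE, ncol(signal)),
                              subject = "S01", method = "deltaF",
                              session_id = "synth") {
  structure(list(signal = signal, method = method,
                 baseline_mu = rep(1, nrow(signal)),
                 baseline_sigma = rep(1, nrow(signal)),
                 baseline_frames = vector("list", nrow(signal)),
                 movement_mask = movement_mask, subject_id = subject,
                 state_label = "non-pain", session_id = session_id),
            class = "normalized_session")
}

# Random feature-level cohort (no trace simulation); classes get optional
# mean shifts on a subset of columns.
random_feature_cohort <- function(n_subjects, per_class, seed,
                                  pain_shift = 0, shift_cols = 1:3) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    for (cl in pain_classes()) {
      for (r in seq_len(per_class)) {
        k <- k + 1
        fv <- stats::runif(13, 0, 0.2)
        if (cl == "pain" && pain_shift != 0)
          fv[shift_cols] <- fv[shift_cols] + pain_shift
        rows[[k]] <- cbind(
          data.frame(session_id = sprintf("S%02d_%s_%d", s, cl, r),
                     subject_id = sprintf("S%02d", s),
                     state_label = cl, class = cl,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(fv, feature_names()))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
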
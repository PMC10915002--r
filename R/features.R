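# Handcrafted session-pair features.
#
# The core statistic is the per-ROI activity-share difference
#   D_i = (X_i / sum_j X_j)_A - (X_i / sum_j X_j)_B
# between an evaluation session A and a reference session B over matched
# ROIs, where X_i is ROI i's mean normalized signal over a frame subset
# (movement, stationary, or all frames). Cells with D above +0.3 count as
# up-regulated, below -0.2 as down-regulated; the two ratios, taken for
# each normalization (Z score, delta-F/F) and each movement condition,
# give 12 features, and the session's mean pairwise ROI correlation is the
# 13th.

#' Names and order of the 13 features
#'
#' The order is frozen so principal-component loadings stay interpretable:
#' (zscore, deltaf) x (up, down) x (movement, stationary, total), then the
#' correlation feature.
#'
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  g <- expand.grid(ms = c("movement", "stationary", "total"),
                   dyn = c("up", "down"),
                   method = c("zscore", "deltaf"),
                   stringsAsFactors = FALSE)
  c(sprintf("%s_%s_%s", g$method, g$dyn, g$ms), "correlation")
}

#' Pair an evaluation session with a reference session
#'
#' @param a,b `normalized_session` objects from the same subject, produced
#'   with the same normalization method.
#' @param roi_map Two-column integer matrix mapping ROI rows of `a` to ROI
#'   rows of `b`; one-to-one, at least 2 matched ROIs. Default: identity.
#' @return An object of class `session_pair`.
#' @export
session_pair <- function(a, b, roi_map = NULL) {
  stopifnot(inherits(a, "normalized_session"), inherits(b, "normalized_session"))
  if (!identical(a$method, b$method))
    stop("both sessions must use the same normalization method (",
         a$method, " vs ", b$method, ")")
  if (!identical(a$subject_id, b$subject_id))
    stop("session pair must come from the same subject (",
         a$subject_id, " vs ", b$subject_id, ")")
  if (is.null(roi_map)) {
    if (nrow(a$signal) != nrow(b$signal))
      stop("ROI counts differ; an explicit roi_map is required")
    roi_map <- cbind(a = seq_len(nrow(a$signal)), b = seq_len(nrow(a$signal)))
  }
  roi_map <- as.matrix(roi_map)
  if (ncol(roi_map) != 2L || nrow(roi_map) < 2L)
    stop("roi_map must be a two-column matrix with >= 2 matched ROIs")
  if (anyDuplicated(roi_map[, 1L]) || anyDuplicated(roi_map[, 2L]))
    stop("roi_map must be one-to-one")
  if (max(roi_map[, 1L]) > nrow(a$signal) || max(roi_map[, 2L]) > nrow(b$signal) ||
      min(roi_map) < 1L)
    stop("roi_map indices out of range")
  structure(list(a = a, b = b, roi_map = roi_map), class = "session_pair")
}

subset_frames <- function(movement_mask,
                          frame_subset = c("total", "movement", "stationary")) {
  frame_subset <- match.arg(frame_subset)
  switch(frame_subset,
         total = seq_along(movement_mask),
         movement = which(movement_mask),
         stationary = which(!movement_mask))
}

# Shares from a normalized signal matrix restricted to given frames.
.shares <- function(signal, frames, eps = 1e-8) {
  if (length(frames) == 0L)
    stop_classed("painstate_empty_subset", "frame subset is empty")
  m <- pmax(rowMeans(signal[, frames, drop = FALSE]), 0)
  tot <- sum(m)
  if (tot <= eps)
    stop_classed("painstate_degenerate_session",
                 "total activity share is <= %g after flooring", eps)
  m / tot
}

#' Per-ROI activity shares over a frame subset
#'
#' Each ROI's mean normalized signal over the subset, floored at 0 and
#' divided by the total across ROIs; shares sum to 1.
#'
#' @param session A `normalized_session`.
#' @param frame_subset `"total"`, `"movement"`, or `"stationary"` (frames
#'   taken from the session's movement mask).
#' @return Numeric vector of shares, one per ROI, summing to 1.
#' @export
activity_shares <- function(session, frame_subset = "total") {
  stopifnot(inherits(session, "normalized_session"))
  if (nrow(session$signal) < 2L) stop("need at least 2 ROIs")
  .shares(session$signal, subset_frames(session$movement_mask, frame_subset))
}

#' Activity-share difference D between matched ROIs
#'
#' `D_i = share_i(A) - share_i(B)` over the matched ROIs, with shares
#' computed within the matched set, so `sum(D) == 0` up to rounding.
#'
#' @param pair A [session_pair()].
#' @param frame_subset Frame subset; see [activity_shares()].
#' @return Numeric vector of length `nrow(roi_map)`.
#' @export
compute_D <- function(pair, frame_subset = "total") {
  stopifnot(inherits(pair, "session_pair"))
  sa <- pair$a$signal[pair$roi_map[, 1L], , drop = FALSE]
  sb <- pair$b$signal[pair$roi_map[, 2L], , drop = FALSE]
  .shares(sa, subset_frames(pair$a$movement_mask, frame_subset)) -
    .shares(sb, subset_frames(pair$b$movement_mask, frame_subset))
}

#' Up-, down-, and stable-cell ratios of a D vector
#'
#' @param D Numeric vector of activity-share differences.
#' @param up_threshold Cells with `D > up_threshold` count as up-regulated
#'   (default 0.3).
#' @param down_threshold Cells with `D < down_threshold` count as
#'   down-regulated (default -0.2).
#' @return Named vector `c(up, down, stable)`; the three sum to 1 exactly.
#' @export
cell_ratios <- function(D, up_threshold = 0.3, down_threshold = -0.2) {
  if (length(D) == 0L) stop("D is empty")
  if (up_threshold <= down_threshold)
    stop("up_threshold must exceed down_threshold")
  up <- sum(D > up_threshold) / length(D)
  down <- sum(D < down_threshold) / length(D)
  # 1 - (up + down) keeps up + down + stable == 1 exact in floating point
  c(up = up, down = down, stable = 1 - (up + down))
}

#' Mean pairwise ROI correlation of a session
#'
#' Mean Pearson correlation over all unordered ROI pairs across the whole
#' session. Zero-variance ROIs are excluded with a warning.
#'
#' @param session A `normalized_session`, or a numeric ROI-by-frame matrix.
#' @return Scalar in `[-1, 1]`.
#' @export
correlation_feature <- function(session) {
  sig <- if (inherits(session, "normalized_session")) session$signal else as.matrix(session)
  if (nrow(sig) < 2L) stop("need at least 2 ROIs")
  if (ncol(sig) < 3L) stop("need at least 3 frames")
  v <- apply(sig, 1L, stats::var)
  usable <- v > 0
  if (any(!usable)) {
    warning(sum(!usable), " zero-variance ROI(s) excluded from the correlation feature")
    sig <- sig[usable, , drop = FALSE]
  }
  if (nrow(sig) < 2L) stop("fewer than 2 ROIs with nonzero variance")
  cm <- stats::cor(t(sig))
  mean(cm[upper.tri(cm)])
}

#' Extract the 13 handcrafted features for a session pair
#'
#' Normalizes both raw sessions with each method (Z score and delta-F/F),
#' computes D over matched ROIs for each movement condition, converts each
#' D vector into up-/down-regulated cell ratios at the fixed thresholds,
#' and appends the mean pairwise correlation of the (delta-F/F-normalized)
#' evaluation session. If a session has no movement (or no stationary)
#' frames, the affected features are returned as `NA` and listed in the
#' `"missing_subsets"` attribute; the classification stage imputes them
#' from training-set means.
#'
#' @param session_a Evaluation session (a [calcium_session()]).
#' @param session_b Reference session from the same subject.
#' @param roi_map Optional two-column matched-ROI index matrix (default
#'   identity).
#' @param window,sigma,baseline_percentile,baseline_mode Preprocessing
#'   settings; see [normalize_session()].
#' @param up_threshold,down_threshold D thresholds; see [cell_ratios()].
#' @return Named numeric vector of length 13 in [feature_names()] order.
#' @export
extract_features <- function(session_a, session_b, roi_map = NULL,
                             window = 29L, sigma = NULL,
                             baseline_percentile = 30,
                             baseline_mode = "subset-mean",
                             up_threshold = 0.3, down_threshold = -0.2) {
  out <- stats::setNames(rep(NA_real_, 13L), feature_names())
  missing_subsets <- character(0)
  deltaf_pair <- NULL
  for (method in c("zscore", "deltaF")) {
    na <- normalize_session(session_a, method, window = window, sigma = sigma,
                            baseline_percentile = baseline_percentile,
                            baseline_mode = baseline_mode)
    nb <- normalize_session(session_b, method, window = window, sigma = sigma,
                            baseline_percentile = baseline_percentile,
                            baseline_mode = baseline_mode)
    pair <- session_pair(na, nb, roi_map)
    if (method == "deltaF") deltaf_pair <- pair
    key <- if (method == "deltaF") "deltaf" else "zscore"
    for (ms in c("movement", "stationary", "total")) {
      D <- tryCatch(compute_D(pair, ms),
                    painstate_empty_subset = function(e) NULL)
      if (is.null(D)) {
        missing_subsets <- union(missing_subsets, paste0(key, ":", ms))
        next
      }
      r <- cell_ratios(D, up_threshold, down_threshold)
      out[sprintf("%s_up_%s", key, ms)] <- r[["up"]]
      out[sprintf("%s_down_%s", key, ms)] <- r[["down"]]
    }
  }
  sig_a <- deltaf_pair$a$signal[deltaf_pair$roi_map[, 1L], , drop = FALSE]
  out["correlation"] <- correlation_feature(sig_a)
  attr(out, "missing_subsets") <- missing_subsets
  out
}

#' Feature matrix for a whole cohort
#'
#' Runs [extract_features()] on every evaluation/reference pair of the
#' cohort and returns one row per session with its metadata.
#'
#' @param cohort A `calcium_cohort` (see [generate_cohort()]).
#' @inheritParams extract_features
#' @return `data.frame` with columns `session_id`, `subject_id`,
#'   `state_label`, `class`, and the 13 feature columns.
#' @export
cohort_features <- function(cohort, window = 29L, sigma = NULL,
                            baseline_percentile = 30,
                            baseline_mode = "subset-mean",
                            up_threshold = 0.3, down_threshold = -0.2) {
  pairs <- cohort_pairs(cohort)
  rows <- lapply(pairs, function(p) {
    fv <- tryCatch(
      extract_features(p$a, p$b, p$roi_map, window = window, sigma = sigma,
                       baseline_percentile = baseline_percentile,
                       baseline_mode = baseline_mode,
                       up_threshold = up_threshold,
                       down_threshold = down_threshold),
      error = function(e) stop("session ", p$a$session_id, ": ",
                               conditionMessage(e), call. = FALSE))
    cbind(data.frame(session_id = p$a$session_id,
                     subject_id = p$a$subject_id,
                     state_label = p$a$state_label,
                     class = state_class(p$a$state_label),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC-AUC of a single feature for a binary contrast
#'
#' Computed as the Mann-Whitney U statistic divided by `n1 * n2`, ties
#' counted half: the probability that a session from the positive group
#' scores above one from the negative group. Raw orientation is reported
#' by default, so 0.5 is chance; set `rectify = TRUE` to fold below-chance
#' values to `max(AUC, 1 - AUC)`.
#'
#' @param values Numeric feature values, one per session.
#' @param labels Binary labels (logical, or anything with two levels).
#' @param positive Value of `labels` treated as the positive group;
#'   default `TRUE` for logical labels, otherwise the last sorted level.
#' @param rectify Fold orientation; default `FALSE`.
#' @return Scalar AUC in `[0, 1]`.
#' @export
feature_auc <- function(values, labels, positive = NULL, rectify = FALSE) {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly two nonempty groups")
  positive <- positive %||% if (is.logical(labels)) TRUE else sort(as.character(lev))[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both groups must be nonempty")
  r <- rank(values)  # midranks handle ties as half-wins
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (rectify) max(auc, 1 - auc) else auc
}

#' Per-feature AUC screen over the three class contrasts
#'
#' For every feature, the ROC-AUC (pain as the positive group) for the
#' contrasts baseline vs. pain, pain vs. analgesics, and pain vs.
#' analgesics + baseline (raw session pooling).
#'
#' @param features Feature data.frame as from [cohort_features()].
#' @param rectify Passed to [feature_auc()].
#' @return `data.frame` with 13 rows (one per feature, in
#'   [feature_names()] order) and one column per contrast.
#' @export
build_auc_table <- function(features, rectify = FALSE) {
  cls <- features$class
  if (is.null(cls)) stop("features must have a 'class' column")
  contrasts <- list(
    baseline_vs_pain = cls %in% c("non-pain", "pain"),
    pain_vs_analgesics = cls %in% c("pain", "analgesic"),
    pain_vs_analgesics_baseline = rep(TRUE, length(cls)))
  missing <- setdiff(PAIN_CLASSES, unique(cls))
  if (length(missing))
    stop("contrast group(s) missing from cohort: ", paste(missing, collapse = ", "))
  out <- data.frame(feature = feature_names(), stringsAsFactors = FALSE)
  for (cn in names(contrasts)) {
    sel <- contrasts[[cn]]
    out[[cn]] <- vapply(feature_names(), function(f)
      feature_auc(features[[f]][sel], cls[sel] == "pain", positive = TRUE,
                  rectify = rectify),
      numeric(1))
  }
  rownames(out) <- NULL
  out
}
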
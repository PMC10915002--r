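# Dimensionality reduction, three-class classification, false-label
# management, and leave-one-subject-out cross-validation.
#
# Features are standardized and reduced to six principal components fitted
# on training data only; a small dense-layer network with a softmax head
# maps the components to probabilities over (non-pain, pain, analgesic).
# Because spontaneous pain cannot be guaranteed present throughout every
# pain-labeled recording, a model trained on the full training set scores
# all pain-labeled sessions and the bottom fraction (default 10%) by
# predicted pain value is removed before the final fit.

feature_matrix <- function(features) {
  cols <- feature_names()
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("feature column(s) missing: ", paste(missing, collapse = ", "))
  as.matrix(features[, cols, drop = FALSE])
}

# Replace NA entries (empty-subset sentinels) by column means, taken from
# the training set when `means` is supplied.
impute_features <- function(x, means = NULL) {
  if (is.null(means)) means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- means[j]
  }
  list(x = x, means = means)
}

#' Fit the PCA transform (13 features to 6 components)
#'
#' Columns are standardized with training statistics, then orthonormal
#' principal components ordered by explained variance are fitted; all six
#' are retained for the classifier.
#'
#' @param x Numeric training feature matrix (rows = session pairs).
#' @param n_components Number of components, default 6.
#' @return An object of class `pain_pca` with `center`, `scale`,
#'   `rotation` and `sdev`.
#' @export
fit_pca <- function(x, n_components = 6L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains NA; impute empty-subset sentinels first")
  n_components <- as.integer(n_components)
  if (nrow(x) < n_components + 1L)
    stop("need at least ", n_components + 1L, " training rows, got ", nrow(x))
  if (ncol(x) < n_components)
    stop("fewer feature columns than components requested")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1  # constant columns carry no variance; rank check below
  xs <- scale(x, center = ctr, scale = scl)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-8)
  if (rank < n_components)
    stop("training features are rank-deficient: rank ", rank,
         " < ", n_components, " components requested")
  structure(list(center = ctr, scale = scl,
                 rotation = p$rotation[, seq_len(n_components), drop = FALSE],
                 sdev = p$sdev, n_components = n_components),
            class = "pain_pca")
}

#' Project features onto the fitted components
#'
#' @param object A `pain_pca`.
#' @param newdata Feature matrix with the same columns as the training set.
#' @param ... Unused.
#' @return Matrix with `n_components` columns.
#' @export
predict.pain_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scale(newdata, center = object$center, scale = object$scale) %*% object$rotation
}

#' @export
print.pain_pca <- function(x, ...) {
  var_kept <- sum(x$sdev[seq_len(x$n_components)]^2) / sum(x$sdev^2)
  cat(sprintf("<pain_pca> %d -> %d components (%.1f%% variance)\n",
              length(x$center), x$n_components, 100 * var_kept))
  invisible(x)
}

#' Train the dense-layer three-class classifier
#'
#' A single-hidden-layer network with a softmax head, fitted by BFGS on
#' the cross-entropy loss with inverse-class-frequency weights (pain
#' sessions typically outnumber the other classes). Deterministic given
#' the seed.
#'
#' @param x Numeric matrix of projected features (rows = sessions).
#' @param labels Class labels drawn from [pain_classes()]; all three
#'   classes must be present.
#' @param seed Integer seed for the weight initialization.
#' @param size Hidden units, default 8.
#' @param decay Weight decay, default 0.01.
#' @param maxit Maximum optimizer iterations.
#' @return An object of class `pain_classifier`.
#' @export
train_classifier <- function(x, labels, seed = 1L, size = 8L, decay = 0.01,
                             maxit = 500L) {
  x <- as.matrix(x)
  cls <- state_class(as.character(labels))
  absent <- setdiff(PAIN_CLASSES, unique(cls))
  if (length(absent))
    stop("class(es) absent from training data: ", paste(absent, collapse = ", "))
  y <- nnet::class.ind(factor(cls, levels = PAIN_CLASSES))
  counts <- table(factor(cls, levels = PAIN_CLASSES))
  w_class <- as.numeric(length(cls) / (length(PAIN_CLASSES) * counts))
  names(w_class) <- names(counts)
  fit <- with_preserved_seed(as.integer(seed),
    nnet::nnet(x = x, y = y, size = size, softmax = TRUE, decay = decay,
               maxit = maxit, weights = w_class[cls], trace = FALSE))
  structure(list(net = fit, levels = PAIN_CLASSES, size = size,
                 decay = decay, seed = as.integer(seed)),
            class = "pain_classifier")
}

#' Class probabilities from the classifier
#'
#' @param object A `pain_classifier`.
#' @param newdata Matrix of projected features.
#' @param type `"prob"` for the 3-column probability matrix (rows sum to
#'   1), `"class"` for the argmax label.
#' @param ... Unused.
#' @export
predict.pain_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  p <- stats::predict(object$net, newdata)
  p <- matrix(p, ncol = length(object$levels),
              dimnames = list(rownames(newdata), object$levels))
  if (type == "prob") p else object$levels[max.col(p, ties.method = "first")]
}

#' @export
print.pain_classifier <- function(x, ...) {
  cat(sprintf("<pain_classifier> dense layers %d-%d-3 (softmax), decay %g, seed %d\n",
              x$net$n[1], x$size, x$decay, x$seed))
  invisible(x)
}

# Fit PCA + classifier on one feature data.frame; used by the false-label
# filter and by every LOSO fold.
fit_stage <- function(features, seed, n_components, size, decay, maxit,
                      means = NULL) {
  X <- feature_matrix(features)
  imp <- impute_features(X, means)
  pca <- fit_pca(imp$x, n_components)
  proj <- predict(pca, imp$x)
  clf <- train_classifier(proj, features$class, seed = seed, size = size,
                          decay = decay, maxit = maxit)
  list(pca = pca, clf = clf, means = imp$means)
}

#' Remove probable false pain labels from a cohort
#'
#' Trains on the full cohort, scores every pain-labeled session's
#' predicted pain value, and removes the `floor(fraction * n_pain)`
#' pain-labeled sessions with the lowest scores (sessions recorded while
#' pain was plausibly absent). Non-pain and analgesic sessions are never
#' touched. Ties at the removal boundary are broken by session-id order.
#'
#' @param features Feature data.frame (see [cohort_features()]).
#' @param fraction Fraction of pain-labeled sessions to drop, in `[0, 1)`;
#'   default 0.10.
#' @param seed Integer seed for the scoring model.
#' @param iterations Number of train-score-remove passes; default 1.
#' @param n_components,size,decay,maxit Model settings.
#' @return List with `features` (filtered data.frame) and `removed`
#'   (removal log: session, subject, predicted pain value, pass).
#' @export
false_label_filter <- function(features, fraction = 0.10, seed = 1L,
                               iterations = 1L, n_components = 6L,
                               size = 8L, decay = 0.01, maxit = 500L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)")
  if (!any(features$class == "pain")) stop("cohort has no pain-labeled sessions")
  removed <- NULL
  df <- features
  for (it in seq_len(iterations)) {
    pain_idx <- which(df$class == "pain")
    k <- floor(fraction * length(pain_idx))
    if (k == 0L) break
    stage <- fit_stage(df, make_seed(seed, it), n_components, size, decay, maxit)
    p_pain <- predict(stage$clf, predict(stage$pca,
                                         impute_features(feature_matrix(df),
                                                         stage$means)$x))[, "pain"]
    ord <- pain_idx[order(p_pain[pain_idx], df$session_id[pain_idx])]
    drop <- ord[seq_len(k)]
    removed <- rbind(removed,
                     data.frame(session_id = df$session_id[drop],
                                subject_id = df$subject_id[drop],
                                predicted_pain_value = p_pain[drop],
                                pass = it,
                                stringsAsFactors = FALSE))
    df <- df[-drop, , drop = FALSE]
  }
  list(features = df,
       removed = removed %||% data.frame(session_id = character(0),
                                         subject_id = character(0),
                                         predicted_pain_value = numeric(0),
                                         pass = integer(0)))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: all of that subject's sessions form the test set,
#' and false-label filtering, feature imputation, PCA fitting, and
#' classifier training use only the remaining subjects, so no test-set
#' information enters the fitted transform or model. Each session appears
#' in exactly one test set.
#'
#' @param features Feature data.frame (see [cohort_features()]).
#' @param seed Root seed; per-fold seeds are derived from it.
#' @param false_label_fraction Fraction for [false_label_filter()].
#' @param filter_iterations Passes of the false-label filter.
#' @param n_components,size,decay,maxit Model settings.
#' @return A `data.frame` of class `loso_result`: one row per session with
#'   fold index, true class, the three class probabilities, the predicted
#'   pain value (probability of the pain class), and the predicted class.
#'   Fitted per-fold models and removal logs are in `attr(, "folds")`.
#' @export
loso_cv <- function(features, seed = 1L, false_label_fraction = 0.10,
                    filter_iterations = 1L, n_components = 6L, size = 8L,
                    decay = 0.01, maxit = 500L) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects")
  folds <- list()
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    train <- features[features$subject_id != s, , drop = FALSE]
    test <- features[features$subject_id == s, , drop = FALSE]
    fold_seed <- make_seed(seed, i)
    flt <- false_label_filter(train, false_label_fraction, seed = fold_seed,
                              iterations = filter_iterations,
                              n_components = n_components, size = size,
                              decay = decay, maxit = maxit)
    stage <- fit_stage(flt$features, make_seed(fold_seed, 9999L),
                       n_components, size, decay, maxit)
    testX <- impute_features(feature_matrix(test), stage$means)$x
    probs <- predict(stage$clf, predict(stage$pca, testX))
    rows[[i]] <- data.frame(
      session_id = test$session_id,
      subject_id = test$subject_id,
      fold = i,
      state_label = test$state_label,
      class = test$class,
      p_nonpain = probs[, "non-pain"],
      p_pain = probs[, "pain"],
      p_analgesic = probs[, "analgesic"],
      predicted_pain_value = probs[, "pain"],
      predicted_class = PAIN_CLASSES[max.col(probs, ties.method = "first")],
      stringsAsFactors = FALSE)
    folds[[s]] <- list(subject = s, pca = stage$pca, clf = stage$clf,
                       means = stage$means, removed = flt$removed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loso_result", class(out))
  attr(out, "folds") <- folds
  out
}

#' Compare predicted pain values between two groups
#'
#' Group means with SEM, a two-sided test (unpaired t or Mann-Whitney),
#' and the ROC-AUC of the predicted pain value for the contrast.
#'
#' @param values Numeric predicted pain values.
#' @param groups Two-level grouping of the same length.
#' @param test `"t-test"` (Welch) or `"mann-whitney"`.
#' @param positive Group treated as positive for the AUC; default the last
#'   sorted level.
#' @return List with `summary` (per-group n/mean/sem), `statistic`,
#'   `p_value`, `auc`, and `test`.
#' @export
evaluate_groups <- function(values, groups, test = c("t-test", "mann-whitney"),
                            positive = NULL) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  a <- values[groups == lev[1L]]
  b <- values[groups == lev[2L]]
  if (test == "t-test" && (length(a) < 2L || length(b) < 2L))
    stop("each group needs >= 2 values for the t-test")
  ht <- if (test == "t-test") stats::t.test(a, b)
        else stats::wilcox.test(a, b, exact = FALSE)
  summary_df <- data.frame(
    group = lev,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b))))
  list(summary = summary_df,
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       auc = feature_auc(values, groups, positive = positive %||% lev[2L]),
       test = test)
}
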
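# Denoising, normalization and movement partitioning of calcium sessions.
#
# Raw per-ROI fluorescence is Gaussian-smoothed, a per-ROI baseline is taken
# from the frames at or below the 30th percentile of the smoothed trace, and
# the trace is expressed either as delta-F/F, (X - mu)/mu, or as a Z score,
# (X - mu)/sigma, where mu and sigma are the mean and standard deviation of
# the baseline frames. Movement is detected on a video-rate motion-energy
# trace and mapped down to the imaging frame clock.

#' Construct a calcium imaging session
#'
#' Container for one recording: an ROI-by-frame fluorescence matrix, the
#' imaging frame times, a per-frame movement mask, and identifying metadata.
#'
#' @param fluorescence Numeric matrix, rows = ROIs, columns = frames.
#' @param frame_times Numeric vector of frame onset times in seconds,
#'   strictly increasing, one per column of `fluorescence`.
#' @param movement_mask Logical vector, one flag per imaging frame; `TRUE`
#'   marks frames recorded while the animal was moving.
#' @param subject_id,session_id Identifiers.
#' @param state_label State of the session: one of `"non-pain"`, `"pain"`,
#'   `"analgesic"`, optionally suffixed with `":<detail>"` (e.g.
#'   `"pain:CFA"`).
#' @param ground_truth Optional list sidecar (used by the synthetic
#'   generator to expose planted structure to tests).
#'
#' @return An object of class `calcium_session`.
#' @export
calcium_session <- function(fluorescence, frame_times, movement_mask,
                            subject_id, state_label,
                            session_id = paste0(subject_id, "_", state_label),
                            ground_truth = NULL) {
  fluorescence <- as.matrix(fluorescence)
  if (!is.numeric(fluorescence)) stop("fluorescence must be numeric")
  if (nrow(fluorescence) < 2L) stop("a session needs at least 2 ROIs")
  if (ncol(fluorescence) < 2L) stop("a session needs at least 2 frames")
  if (length(frame_times) != ncol(fluorescence))
    stop("frame_times length must equal the number of frames")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (length(movement_mask) != ncol(fluorescence))
    stop("movement_mask length must equal the number of frames")
  state_class(state_label)  # validates
  structure(
    list(fluorescence = fluorescence,
         frame_times = as.numeric(frame_times),
         movement_mask = as.logical(movement_mask),
         subject_id = as.character(subject_id),
         state_label = as.character(state_label),
         session_id = as.character(session_id),
         ground_truth = ground_truth),
    class = "calcium_session")
}

#' @export
print.calcium_session <- function(x, ...) {
  cat(sprintf("<calcium_session> %s  subject %s  state %s\n",
              x$session_id, x$subject_id, x$state_label))
  cat(sprintf("  %d ROIs x %d frames (%.1f s), %.1f%% movement frames\n",
              nrow(x$fluorescence), ncol(x$fluorescence),
              diff(range(x$frame_times)) + median(diff(x$frame_times)),
              100 * mean(x$movement_mask)))
  invisible(x)
}

#' Threshold a motion-energy trace into a movement mask
#'
#' A video frame is movement-positive iff its summed absolute inter-frame
#' pixel intensity difference strictly exceeds the threshold.
#'
#' @param energy Nonnegative numeric vector, one value per video frame.
#' @param threshold Nonnegative scalar.
#' @return Logical vector, one flag per video frame.
#' @export
detect_movement <- function(energy, threshold) {
  if (length(energy) == 0L) stop("motion-energy trace is empty")
  if (!is.numeric(energy) || any(energy < 0)) stop("motion energy must be nonnegative")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a nonnegative scalar")
  energy > threshold
}

#' Map a video-rate movement mask onto imaging frames
#'
#' Each imaging frame inherits the flags of the video frames whose onset
#' falls inside its inter-frame interval; it is flagged movement-positive if
#' any covered video frame is.
#'
#' @param video_mask Logical vector at video rate.
#' @param video_rate_hz Video frame rate (Hz), positive.
#' @param frame_times Imaging frame onset times (seconds).
#' @return Logical vector, one flag per imaging frame.
#' @export
map_video_to_imaging <- function(video_mask, video_rate_hz, frame_times) {
  if (!is.numeric(video_rate_hz) || video_rate_hz <= 0) stop("video_rate_hz must be positive")
  n <- length(frame_times)
  if (n < 1L) stop("frame_times is empty")
  dt <- if (n > 1L) stats::median(diff(frame_times)) else 1 / video_rate_hz
  edges <- c(frame_times, frame_times[n] + dt)
  video_t <- (seq_along(video_mask) - 1) / video_rate_hz
  video_end <- length(video_mask) / video_rate_hz
  if (video_end < edges[n + 1L] - 1e-9)
    stop("video recording is shorter than the imaging span")
  bin <- findInterval(video_t, edges)
  hit <- video_mask & bin >= 1L & bin <= n
  out <- logical(n)
  out[unique(bin[hit])] <- TRUE
  out
}

# Unit-sum Gaussian window; sigma defaults so +/-3 sigma spans the window.
gaussian_window <- function(size, sigma = (size - 1) / 6) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian-smooth a fluorescence trace
#'
#' Convolves the trace with a unit-sum Gaussian window (default size 29).
#' Edges are handled by reflect padding, so constant traces stay constant.
#'
#' @param x Numeric vector.
#' @param window Odd window size, `1 <= window <= length(x)`.
#' @param sigma Gaussian standard deviation in frames; default
#'   `(window - 1)/6`, placing three standard deviations inside the window.
#' @return Smoothed vector, same length as `x`.
#' @export
smooth_trace <- function(x, window = 29L, sigma = NULL) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > n) stop("window (", window, ") is larger than the series (", n, ")")
  if (window == 1L) return(as.numeric(x))
  half <- (window - 1L) %/% 2L
  w <- gaussian_window(window, sigma %||% ((window - 1) / 6))
  pad <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
  sm <- stats::filter(pad, w, method = "convolution", sides = 2)
  as.numeric(sm[half + seq_len(n)])
}

#' Baseline statistics of a (smoothed) trace
#'
#' The baseline frame set comprises all frames whose value is at or below
#' the given percentile of the trace (linear-interpolation percentile; ties
#' at the percentile value are included). `mu` and `sigma` are the mean and
#' standard deviation over that set. Alternatively `mode =
#' "percentile-value"` takes `mu` as the percentile value itself while
#' `sigma` remains the baseline-frame standard deviation.
#'
#' @param x Numeric vector (typically a smoothed trace).
#' @param percentile Baseline percentile, default 30.
#' @param mode `"subset-mean"` (default) or `"percentile-value"`.
#' @return List with `mu`, `sigma`, `baseline_frames` (indices), and
#'   `degenerate` (`TRUE` when `sigma` is 0, which invalidates Z scoring).
#' @export
baseline_stats <- function(x, percentile = 30,
                           mode = c("subset-mean", "percentile-value")) {
  if (length(x) == 0L) stop("empty trace")
  mode <- match.arg(mode)
  q <- unname(stats::quantile(x, percentile / 100, type = 7, names = FALSE))
  idx <- which(x <= q)
  b <- x[idx]
  sigma <- if (length(b) >= 2L) stats::sd(b) else 0
  if (!is.finite(sigma)) sigma <- 0
  list(mu = if (mode == "subset-mean") mean(b) else q,
       sigma = sigma,
       baseline_frames = idx,
       degenerate = sigma == 0)
}

#' Normalize a session to delta-F/F or Z scores
#'
#' Each ROI trace is Gaussian-smoothed, its baseline statistics are taken
#' from the same session, and the stated formula is applied: delta-F/F is
#' `(X - mu)/mu`; the Z score is `(X - mu)/sigma`.
#'
#' @param session A [calcium_session()].
#' @param method `"deltaF"` or `"zscore"` (case-insensitive).
#' @param window,sigma Smoothing window passed to [smooth_trace()].
#' @param baseline_percentile,baseline_mode Passed to [baseline_stats()].
#' @param smooth Set `FALSE` to skip denoising (for already-smoothed input).
#' @return An object of class `normalized_session` carrying the normalized
#'   ROI-by-frame `signal`, the per-ROI baseline statistics, and the
#'   session's movement mask and metadata.
#' @export
normalize_session <- function(session, method = c("zscore", "deltaF"),
                              window = 29L, sigma = NULL,
                              baseline_percentile = 30,
                              baseline_mode = "subset-mean",
                              smooth = TRUE) {
  stopifnot(inherits(session, "calcium_session"))
  method <- match.arg(tolower(method[1L]), c("zscore", "deltaf"))
  method <- if (method == "deltaf") "deltaF" else "zscore"
  fl <- session$fluorescence
  sm <- if (smooth) t(apply(fl, 1L, smooth_trace, window = window, sigma = sigma)) else fl
  n_roi <- nrow(sm)
  stats_list <- lapply(seq_len(n_roi), function(i)
    baseline_stats(sm[i, ], baseline_percentile, baseline_mode))
  mu <- vapply(stats_list, `[[`, numeric(1), "mu")
  sg <- vapply(stats_list, `[[`, numeric(1), "sigma")
  if (method == "deltaF" && any(mu == 0))
    stop("delta-F/F undefined: baseline mean is 0 for ROI(s) ",
         paste(which(mu == 0), collapse = ", "), call. = FALSE)
  if (method == "zscore" && any(sg == 0))
    stop("Z score undefined: baseline sd is 0 for ROI(s) ",
         paste(which(sg == 0), collapse = ", "), call. = FALSE)
  denom <- if (method == "deltaF") mu else sg
  signal <- (sm - mu) / denom
  dimnames(signal) <- dimnames(fl)
  structure(
    list(signal = signal,
         method = method,
         baseline_mu = mu,
         baseline_sigma = sg,
         baseline_frames = lapply(stats_list, `[[`, "baseline_frames"),
         movement_mask = session$movement_mask,
         subject_id = session$subject_id,
         state_label = session$state_label,
         session_id = session$session_id),
    class = "normalized_session")
}

#' @export
print.normalized_session <- function(x, ...) {
  cat(sprintf("<normalized_session> %s  method %s  %d ROIs x %d frames\n",
              x$session_id, x$method, nrow(x$signal), ncol(x$signal)))
  invisible(x)
}
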
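# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# GCaMP6s-like transients (Poisson event trains convolved with a
# double-exponential kernel), locomotion bouts with a video-rate
# motion-energy trace, state- and movement-dependent shifts in the
# fractions of up- and down-regulated cells, and a state-dependent shared
# latent drive that sets the mean pairwise correlation. Ground truth
# (planted up/down ROI sets, bout intervals, motion threshold) is always
# emitted in the session's `ground_truth` sidecar so oracle tests can
# verify recovery.

default_modulation_fractions <- function() {
  states <- PAIN_CLASSES
  conds <- c("movement", "stationary")
  up <- matrix(0, 3, 2, dimnames = list(states, conds))
  down <- matrix(0, 3, 2, dimnames = list(states, conds))
  # Pain raises both up- and down-regulated fractions during movement, and
  # mainly the down-regulated fraction when stationary; the analgesic state
  # keeps a movement up-shift of its own while its down-regulation returns
  # toward baseline. Up fractions are kept small: share conservation means
  # at most floor(1/up_threshold) cells can ever exceed the up threshold at
  # once, so planting many simultaneous up-cells makes each undetectable.
  up["pain", ] <- c(0.07, 0.03)
  up["analgesic", ] <- c(0.07, 0.03)
  down["pain", ] <- c(0.10, 0.10)
  down["analgesic", ] <- c(0.03, 0.03)
  list(up = up, down = down)
}

#' Settings for the synthetic imaging cohort
#'
#' Defines the generative model for synthetic calcium sessions. Per-ROI
#' transient amplitudes are heterogeneous (log-normal across ROIs), so a
#' few high-amplitude cells carry a large share of total activity, as in
#' sparse cortical recordings; this matters because the activity-share
#' difference statistic D can only flag cells whose *share* of session
#' activity moves past the fixed thresholds. State effects are planted as
#' multiplicative event-rate changes on designated up-/down-regulated ROI
#' sets that are fixed per subject, with down-regulated cells drawn from
#' the highest-amplitude cells and up-regulated cells from the
#' mid-amplitude band.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject_per_state Evaluation sessions generated per
#'   subject and state (a separate reference baseline session is always
#'   generated per subject in [generate_cohort()]).
#' @param n_rois ROIs per subject.
#' @param duration_s Session duration in seconds (default 240, a ~4 min
#'   session).
#' @param imaging_rate_hz Two-photon frame rate (default 5 Hz).
#' @param video_rate_hz Behavior video rate (default 30 Hz); must exceed
#'   the imaging rate.
#' @param movement_bout_rate Locomotion bouts per minute.
#' @param movement_bout_len_s Bout duration in seconds.
#' @param base_event_rate_hz Mean calcium-event rate per ROI (Hz) before
#'   per-ROI dispersion and state modulation.
#' @param amplitude_dispersion Log-sd of the per-ROI transient-amplitude
#'   multiplier (log-normal); larger values concentrate total activity in
#'   fewer cells while leaving event sparsity (and hence the percentile
#'   baseline) untouched.
#' @param up_fraction,down_fraction 3 x 2 matrices (rows `"non-pain"`,
#'   `"pain"`, `"analgesic"`; columns `"movement"`, `"stationary"`) giving
#'   the fraction of ROIs with elevated / suppressed rate in that state and
#'   movement condition. `NULL` uses the package defaults described above.
#' @param effect_size Multiplicative rate change applied to up-ROIs
#'   (divided into for down-ROIs).
#' @param shared_drive_weight Named vector of per-state weights of a
#'   common latent signal added to every ROI; controls the mean pairwise
#'   correlation of the session.
#' @param kernel_rise_s,kernel_decay_s Rise / decay time constants of the
#'   GCaMP6s-like transient kernel (seconds).
#' @param transient_amplitude Fluorescence amplitude of a unit event (a.u.).
#' @param session_gain_sd Log-sd of a per-session, per-ROI gain multiplier
#'   emulating longitudinal recording variability (window clarity, focus,
#'   expression drift). This is what gives reference/baseline session
#'   pairs their natural nonzero up-/down-regulated ratios.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param baseline_fluorescence Resting fluorescence offset (a.u.).
#' @param motion_threshold Motion-energy threshold separating bouts from
#'   rest in the emitted video-rate energy trace.
#' @param seed Root seed; all subject-level structure derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 8L,
                              sessions_per_subject_per_state = 1L,
                              n_rois = 30L,
                              duration_s = 240,
                              imaging_rate_hz = 5,
                              video_rate_hz = 30,
                              movement_bout_rate = 5,
                              movement_bout_len_s = 4,
                              base_event_rate_hz = 0.08,
                              amplitude_dispersion = 1.8,
                              up_fraction = NULL,
                              down_fraction = NULL,
                              effect_size = 8,
                              shared_drive_weight = c("non-pain" = 0.05,
                                                      "pain" = 0.05,
                                                      "analgesic" = 0.15),
                              kernel_rise_s = 0.2,
                              kernel_decay_s = 1.5,
                              transient_amplitude = 1,
                              session_gain_sd = 0.45,
                              noise_sd = 0.02,
                              baseline_fluorescence = 1,
                              motion_threshold = 1,
                              seed = 1L) {
  defaults <- default_modulation_fractions()
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         sessions_per_subject_per_state = as.integer(sessions_per_subject_per_state),
         n_rois = as.integer(n_rois),
         duration_s = duration_s,
         imaging_rate_hz = imaging_rate_hz,
         video_rate_hz = video_rate_hz,
         movement_bout_rate = movement_bout_rate,
         movement_bout_len_s = movement_bout_len_s,
         base_event_rate_hz = base_event_rate_hz,
         amplitude_dispersion = amplitude_dispersion,
         up_fraction = up_fraction %||% defaults$up,
         down_fraction = down_fraction %||% defaults$down,
         effect_size = effect_size,
         shared_drive_weight = shared_drive_weight,
         kernel_rise_s = kernel_rise_s,
         kernel_decay_s = kernel_decay_s,
         transient_amplitude = transient_amplitude,
         session_gain_sd = session_gain_sd,
         noise_sd = noise_sd,
         baseline_fluorescence = baseline_fluorescence,
         motion_threshold = motion_threshold,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_subjects", "sessions_per_subject_per_state", "n_rois",
           "duration_s", "imaging_rate_hz", "video_rate_hz")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(f, " must be a positive scalar", call. = FALSE)
  }
  nonneg <- c("movement_bout_rate", "movement_bout_len_s", "base_event_rate_hz",
              "amplitude_dispersion", "noise_sd", "transient_amplitude",
              "session_gain_sd",
              "baseline_fluorescence", "motion_threshold", "kernel_rise_s",
              "kernel_decay_s")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0))
      stop(f, " must be nonnegative", call. = FALSE)
  }
  if (cfg$imaging_rate_hz >= cfg$video_rate_hz)
    stop("imaging_rate_hz must be smaller than video_rate_hz", call. = FALSE)
  if (cfg$effect_size <= 0) stop("effect_size must be positive", call. = FALSE)
  for (f in c("up_fraction", "down_fraction")) {
    m <- cfg[[f]]
    if (!is.matrix(m) || !identical(dim(m), c(3L, 2L)))
      stop(f, " must be a 3 x 2 matrix (states x movement conditions)", call. = FALSE)
    if (any(m < 0) || any(m > 1)) stop(f, " entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$up_fraction + cfg$down_fraction > 1))
    stop("up_fraction + down_fraction must be <= 1 for every state/movement cell",
         call. = FALSE)
  if (!all(PAIN_CLASSES %in% names(cfg$shared_drive_weight)))
    stop("shared_drive_weight must be named for all of: ",
         paste(PAIN_CLASSES, collapse = ", "), call. = FALSE)
  if (any(cfg$shared_drive_weight < 0))
    stop("shared_drive_weight must be nonnegative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects, %d ROIs, %.0f s at %g Hz, effect size %g, seed %d\n",
              x$n_subjects, x$n_rois, x$duration_s, x$imaging_rate_hz,
              x$effect_size, x$seed))
  invisible(x)
}

# Per-subject structure: ROI rate multipliers and the planted up/down ROI
# orderings, fixed across all of that subject's sessions so matched-ROI
# modulation is consistent within a subject (required for D to detect
# planted effects across a session pair).
subject_profile <- function(config, subject_id) {
  n <- config$n_rois
  with_preserved_seed(make_seed(config$seed, string_seed(subject_id)), {
    # Fixed log-normal quantile ladder, permuted per subject: every subject
    # has the same heavy-tailed amplitude profile (so dominance structure is
    # comparable across subjects) with random cell identities.
    amp_mult <- exp(config$amplitude_dispersion *
                      stats::qnorm(stats::ppoints(n)))[sample.int(n)]
    ord <- order(amp_mult, decreasing = TRUE)
    # Candidate pools come from the high-amplitude band (interleaved, so up
    # and down candidates are disjoint but amplitude-matched): only cells
    # holding an appreciable share of total activity can move the
    # activity-share difference past the fixed thresholds.
    k_max <- max(c(round(config$down_fraction * n), round(config$up_fraction * n)))
    band <- max(2L * k_max, ceiling(0.3 * n))
    if (band > n)
      stop("modulation fractions too large for n_rois = ", n, call. = FALSE)
    down_pool <- ord[seq(1L, band, by = 2L)]
    up_pool <- ord[seq(2L, band, by = 2L)]
    if (length(down_pool) < k_max || length(up_pool) < k_max)
      stop("modulation fractions too large for n_rois = ", n, call. = FALSE)
    up_order <- lapply(stats::setNames(PAIN_CLASSES, PAIN_CLASSES),
                       function(s) sample(up_pool))
    down_order <- lapply(stats::setNames(PAIN_CLASSES, PAIN_CLASSES),
                         function(s) sample(down_pool))
    list(amp_mult = amp_mult, up_order = up_order, down_order = down_order)
  })
}

# Planted up/down ROI index sets for one state, per movement condition.
# Sets for the two conditions are nested prefixes of a per-(subject, state)
# permutation, so a cell up-regulated while stationary is also up-regulated
# during movement.
planted_sets <- function(config, profile, cls) {
  n <- config$n_rois
  take <- function(ord, k) if (k >= 1L) ord[seq_len(k)] else integer(0)
  list(
    up = list(
      movement = take(profile$up_order[[cls]], round(config$up_fraction[cls, "movement"] * n)),
      stationary = take(profile$up_order[[cls]], round(config$up_fraction[cls, "stationary"] * n))),
    down = list(
      movement = take(profile$down_order[[cls]], round(config$down_fraction[cls, "movement"] * n)),
      stationary = take(profile$down_order[[cls]], round(config$down_fraction[cls, "stationary"] * n))))
}

# GCaMP6s-like transient kernel sampled at the imaging rate, peak 1.
calcium_kernel <- function(rate_hz, rise_s, decay_s) {
  t <- seq(0, rise_s + 8 * decay_s, by = 1 / rate_hz)
  k <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  k / max(k)
}

# Causal convolution of an event train with a kernel, truncated to length(x).
convolve_events <- function(x, kernel) {
  stats::convolve(x, rev(kernel), type = "open")[seq_along(x)]
}

merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

in_any_interval <- function(t, intervals) {
  out <- logical(length(t))
  for (i in seq_len(nrow(intervals)))
    out <- out | (t >= intervals[i, 1] & t < intervals[i, 2])
  out
}

#' Generate one synthetic calcium session
#'
#' Samples locomotion bouts, builds a video-rate motion-energy trace and
#' the induced imaging-frame movement mask, draws per-ROI Poisson event
#' trains whose rates are multiplied by `effect_size` for the planted
#' up-ROIs (divided for down-ROIs) conditional on state and movement,
#' convolves events with the transient kernel, adds the state-weighted
#' shared drive and Gaussian noise, and floors fluorescence at zero.
#'
#' @param config A [simulation_config()].
#' @param subject_id Subject identifier; the planted ROI structure is a
#'   deterministic function of `config$seed` and this id, so all of a
#'   subject's sessions share it.
#' @param state State label (`"non-pain"`, `"pain"`, `"analgesic"`, with
#'   optional `":<detail>"` tag).
#' @param seed Session seed (integer).
#' @param session_id Optional identifier.
#' @return A [calcium_session()] whose `ground_truth` sidecar holds the
#'   planted up/down ROI sets per movement condition, rate multipliers,
#'   bout intervals, and the video-rate motion energy with its threshold.
#' @export
generate_session <- function(config, subject_id, state, seed,
                             session_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cls <- state_class(state)
  if (length(seed) != 1L || !is.finite(seed)) stop("seed must be a finite scalar")
  profile <- subject_profile(config, subject_id)
  sets <- planted_sets(config, profile, cls)
  with_preserved_seed(as.integer(seed), {
    n <- config$n_rois
    rate_hz <- config$imaging_rate_hz
    n_frames <- round(config$duration_s * rate_hz)
    frame_times <- (seq_len(n_frames) - 1) / rate_hz

    # locomotion bouts and motion energy
    len <- config$movement_bout_len_s
    n_bouts <- stats::rpois(1, config$movement_bout_rate * config$duration_s / 60)
    n_bouts <- min(n_bouts, max(floor(config$duration_s / max(len, 1e-9)), 0))
    starts <- stats::runif(n_bouts, 0, max(config$duration_s - len, 0))
    bouts <- merge_intervals(starts, starts + len)
    n_video <- round(config$duration_s * config$video_rate_hz)
    video_t <- (seq_len(n_video) - 1) / config$video_rate_hz
    video_mask <- in_any_interval(video_t, bouts)
    energy <- numeric(n_video)
    thr <- config$motion_threshold
    energy[video_mask] <- thr * (1.2 + stats::runif(sum(video_mask)))
    energy[!video_mask] <- stats::runif(sum(!video_mask), 0, 0.7 * thr)
    movement_mask <- map_video_to_imaging(video_mask, config$video_rate_hz, frame_times)

    # per-frame event rates with planted state modulation
    rate <- matrix(config$base_event_rate_hz, nrow = n, ncol = n_frames)
    e <- config$effect_size
    mov <- which(movement_mask); sta <- which(!movement_mask)
    if (length(mov)) {
      rate[sets$up$movement, mov] <- rate[sets$up$movement, mov] * e
      rate[sets$down$movement, mov] <- rate[sets$down$movement, mov] / e
    }
    if (length(sta)) {
      rate[sets$up$stationary, sta] <- rate[sets$up$stationary, sta] * e
      rate[sets$down$stationary, sta] <- rate[sets$down$stationary, sta] / e
    }

    counts <- matrix(stats::rpois(n * n_frames, rate / rate_hz), nrow = n)
    jitter <- matrix(exp(stats::rnorm(n * n_frames, 0, 0.2)), nrow = n)
    gain <- exp(stats::rnorm(n, 0, config$session_gain_sd))
    events <- counts * config$transient_amplitude * profile$amp_mult * gain * jitter
    kernel <- calcium_kernel(rate_hz, config$kernel_rise_s, config$kernel_decay_s)
    traces <- t(apply(events, 1L, convolve_events, kernel = kernel))

    # shared latent drive (smooth, unit-sd) sets pairwise correlation
    w <- config$shared_drive_weight[[cls]]
    drive <- smooth_trace(stats::rnorm(n_frames), window = 11L)
    drive <- (drive - mean(drive)) / stats::sd(drive)
    fl <- config$baseline_fluorescence + traces +
      w * matrix(drive, nrow = n, ncol = n_frames, byrow = TRUE) +
      matrix(stats::rnorm(n * n_frames, 0, config$noise_sd), nrow = n)
    fl <- pmax(fl, 0)
    rownames(fl) <- sprintf("roi_%03d", seq_len(n))

    calcium_session(
      fluorescence = fl,
      frame_times = frame_times,
      movement_mask = movement_mask,
      subject_id = subject_id,
      state_label = state,
      session_id = session_id %||% sprintf("%s_%s_seed%d", subject_id, cls, as.integer(seed)),
      ground_truth = list(
        up_rois = sets$up,
        down_rois = sets$down,
        amplitude_multipliers = profile$amp_mult,
        session_gains = gain,
        bouts = as.data.frame(bouts),
        motion_threshold = thr,
        motion_energy = energy,
        video_mask = video_mask,
        seed = as.integer(seed)))
  })
}

#' Generate a synthetic cohort
#'
#' Produces, per subject, one reference baseline (non-pain) recording plus
#' `sessions_per_subject_per_state` evaluation sessions for each of the
#' three states. The reference recording is held separately from the
#' evaluation sessions (a session evaluated against itself would have an
#' identically zero D vector); the matched-ROI mapping between a subject's
#' sessions is the identity.
#'
#' @param config A [simulation_config()].
#' @return An object of class `calcium_cohort`: a list with `sessions`
#'   (evaluation sessions), `references` (one per subject, named by
#'   subject), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  sessions <- list()
  references <- list()
  counter <- 0L
  for (subj in subjects) {
    counter <- counter + 1L
    references[[subj]] <- generate_session(
      config, subj, "non-pain", make_seed(config$seed, counter),
      session_id = paste0(subj, "_reference"))
    for (st in PAIN_CLASSES) {
      for (rep in seq_len(config$sessions_per_subject_per_state)) {
        counter <- counter + 1L
        sid <- sprintf("%s_%s_%02d", subj, gsub("-", "", st), rep)
        sessions[[sid]] <- generate_session(
          config, subj, st, make_seed(config$seed, counter), session_id = sid)
      }
    }
  }
  structure(list(sessions = sessions, references = references, config = config),
            class = "calcium_cohort")
}

#' @export
print.calcium_cohort <- function(x, ...) {
  states <- vapply(x$sessions, function(s) state_class(s$state_label), character(1))
  cat(sprintf("<calcium_cohort> %d sessions, %d subjects (+%d reference recordings)\n",
              length(x$sessions), length(x$references), length(x$references)))
  print(table(state = states))
  invisible(x)
}

#' Evaluation/reference session pairs of a cohort
#'
#' Pairs every evaluation session with its subject's reference baseline
#' recording under the identity ROI mapping.
#'
#' @param cohort A `calcium_cohort`.
#' @return List of lists with elements `a` (evaluation session), `b`
#'   (reference session) and `roi_map`.
#' @export
cohort_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "calcium_cohort"))
  lapply(cohort$sessions, function(s) {
    ref <- cohort$references[[s$subject_id]]
    if (is.null(ref)) stop("no reference recording for subject ", s$subject_id)
    n <- nrow(s$fluorescence)
    list(a = s, b = ref, roi_map = cbind(a = seq_len(n), b = seq_len(n)))
  })
}
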
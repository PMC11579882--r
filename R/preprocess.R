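#' Signal preprocessing
#'
#' Zero-lag filtering of kinematic/inertial streams and the raw-EMG to
#' normalised muscle-specific envelope chain: noisy-channel zeroing,
#' re-referencing, 20 Hz high-pass, full rectification, 0.16 s moving median,
#' task-maximum normalisation, and averaging onto the seven target muscles.
#'
#' Kinematic and kinetic streams from lab systems are conventionally low-pass
#' filtered at 6 Hz; sensor-derived velocities and accelerations at 3 Hz (the
#' lower corner suppresses soft-tissue motion between sensor and bone). Both
#' use the same zero-lag operator below.
#'
#' @name preprocess
NULL

#' Zero-lag 2nd-order Butterworth filter
#'
#' Forward-backward (two-pass) 2nd-order Butterworth filter with odd
#' (reflective, point-symmetric) edge padding, giving zero phase shift and a
#' squared magnitude response. Operates column-wise on matrices.
#'
#' @param x numeric vector or matrix (columns are channels), uniformly
#'   sampled.
#' @param rate sampling rate, Hz.
#' @param cutoff corner frequency, Hz; must lie in (0, rate/2).
#' @param kind `"low"` or `"high"`.
#' @param order filter order per pass (default 2).
#' @return filtered series, same shape as `x`.
#' @export
butterworth_zero_lag <- function(x, rate, cutoff, kind = c("low", "high"),
                                 order = 2) {
  kind <- match.arg(kind)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  pad <- min(n - 1, max(3 * (order + 1), ceiling(3 * rate / cutoff)))
  if (pad < 3 * (order + 1))
    stop("series too short for zero-lag edge padding")
  bf <- signal::butter(order, cutoff / (rate / 2), type = kind)
  dc_gain <- sum(bf$b) / sum(bf$a)
  # single pass with steady-state initial conditions for the edge value, so a
  # constant input passes through exactly (no start-up transient)
  one_pass <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], order),
                              init.y = rep(v[1] * dc_gain, order)))
  }
  out <- apply(x, 2, function(col) {
    # odd reflection about both endpoints
    ext <- c(2 * col[1] - col[(pad + 1):2], col, 2 * col[n] - col[(n - 1):(n - pad)])
    fwd <- one_pass(ext)
    bwd <- rev(one_pass(rev(fwd)))
    bwd[(pad + 1):(pad + n)]
  })
  if (vec) as.numeric(out) else out
}

#' Flag noisy EMG channels
#'
#' A channel is flagged when its robust amplitude (median absolute deviation
#' of the raw signal) exceeds `mult` times the median amplitude across
#' channels — the "large voltage fluctuations" signature of movement
#' artifacts. Flagged channels are zeroed downstream.
#'
#' @param emg an `"EmgRecording"` or an n x p signal matrix.
#' @param mult threshold multiplier on the across-channel median amplitude.
#' @return logical vector (length = number of channels), `TRUE` = noisy.
#' @export
detect_noisy_channels <- function(emg, mult = 5) {
  sig <- if (inherits(emg, "EmgRecording")) emg$signals else emg
  if (ncol(sig) < 2) stop("need at least two channels")
  amp <- apply(sig, 2, stats::mad)
  mask <- amp > mult * stats::median(amp)
  if (all(mask))
    stop("all channels flagged as noisy; check recording or threshold")
  mask
}

#' Re-reference an average-referenced EMG recording
#'
#' The front-end amplifies each electrode against the average of all 64
#' inputs, so artifacts on noisy channels leak into every channel. Given the
#' noisy-channel mask, the common average is rebuilt from the clean channels
#' only and removed, which cancels the noisy channels' contribution to the
#' original average reference. Noisy channels are output as zeros.
#'
#' This is a simplified stand-in for the re-referencing procedure of the
#' garment's processing chain, which is specified in prior work; the algebra
#' implemented here is exact when the recorded signals are
#' `s_i = e_i - mean(e)`.
#'
#' @param emg an `"EmgRecording"`.
#' @param mask logical noisy-channel mask from [detect_noisy_channels()].
#' @return `"EmgRecording"` with re-referenced signals.
#' @export
rereference <- function(emg, mask = detect_noisy_channels(emg)) {
  stopifnot(inherits(emg, "EmgRecording"))
  sig <- emg$signals
  if (all(mask)) stop("no clean channels to re-reference against")
  clean <- !mask
  cm <- rowMeans(sig[, clean, drop = FALSE])
  out <- sig - cm
  out[, mask] <- 0
  emg$signals <- out
  emg$noisy_mask <- mask
  emg
}

#' Extract linear envelopes from a re-referenced recording
#'
#' Per channel: zero-lag 20 Hz 2nd-order Butterworth high-pass, full
#' rectification, then a centred moving median of `round(0.16 s * rate)`
#' samples (forced odd for a symmetric, zero-lag window; 321 samples at
#' 2000 Hz). The median removes residual movement-artifact spikes that a
#' linear 6 Hz low-pass would smear.
#'
#' @param emg an `"EmgRecording"` (ideally after [rereference()]).
#' @param highpass_hz high-pass corner, Hz.
#' @param median_window_s moving-median window, s.
#' @return object of class `"EnvelopeSet"`: `time`, `rate`, `envelopes`
#'   (n x channels, non-negative), `labels`, `normalization` (NULL until
#'   [normalize_envelopes()]).
#' @export
extract_envelope <- function(emg, highpass_hz = 20, median_window_s = 0.16) {
  stopifnot(inherits(emg, "EmgRecording"))
  win <- round(median_window_s * emg$rate)
  if (win %% 2 == 0) win <- win + 1
  if (win >= nrow(emg$signals)) stop("median window longer than the series")
  hp <- butterworth_zero_lag(emg$signals, rate = emg$rate,
                             cutoff = highpass_hz, kind = "high")
  rect <- abs(hp)
  env <- apply(rect, 2, function(col) stats::runmed(col, win, endrule = "median"))
  structure(list(time = emg$time, rate = emg$rate, envelopes = env,
                 labels = emg$channel_map, window_samples = win,
                 normalization = NULL),
            class = "EnvelopeSet")
}

#' Normalise envelopes against the per-channel maximum across tasks
#'
#' Each channel is divided by its maximum envelope value over all supplied
#' tasks, so the largest excursion of each channel across the session equals
#' one. All-zero channels are left at zero (with a message) rather than
#' producing NaN.
#'
#' @param sets list of `"EnvelopeSet"` objects, one per task, with identical
#'   channel layouts.
#' @return list of `"EnvelopeSet"` objects with `normalization` (the
#'   per-channel constants) filled in.
#' @export
normalize_envelopes <- function(sets) {
  if (inherits(sets, "EnvelopeSet")) sets <- list(sets)
  stopifnot(length(sets) >= 1)
  nch <- ncol(sets[[1]]$envelopes)
  if (!all(vapply(sets, function(s) ncol(s$envelopes), 0L) == nch))
    stop("all tasks must share the same channels")
  maxes <- apply(do.call(rbind, lapply(sets, `[[`, "envelopes")), 2, max)
  zero <- maxes <= 0
  if (any(zero))
    message(sum(zero), " all-zero channel(s) left unnormalised")
  div <- ifelse(zero, 1, maxes)
  lapply(sets, function(s) {
    s$envelopes <- sweep(s$envelopes, 2, div, "/")
    s$normalization <- maxes
    s
  })
}

#' Muscle-specific envelopes from a channel-to-muscle assignment
#'
#' Averages the normalised envelopes of the channels assigned to each of the
#' seven target muscles (tibialis anterior, extensor hallucis longus, medial
#' and lateral gastrocnemius, soleus, peroneus brevis and longus) and clips
#' to [0, 1]. The assignment itself (muscle localisation on the garment
#' grid) is an input, not computed here.
#'
#' @param set a normalised `"EnvelopeSet"`.
#' @param assignment character vector (one label per channel) naming the
#'   muscle of each channel; channels labelled otherwise (e.g. `"noisy"`)
#'   are ignored. Defaults to the recording's channel map.
#' @return `"EnvelopeSet"` with a 7-column envelope matrix (one per muscle).
#' @export
muscle_envelopes <- function(set, assignment = set$labels) {
  stopifnot(inherits(set, "EnvelopeSet"))
  missing <- setdiff(MUSCLES, unique(assignment))
  if (length(missing))
    stop("no channels assigned to muscle(s): ", paste(missing, collapse = ", "))
  env <- sapply(MUSCLES, function(m) {
    rowMeans(set$envelopes[, assignment == m, drop = FALSE])
  })
  env <- pmin(pmax(env, 0), 1)
  structure(list(time = set$time, rate = set$rate, envelopes = env,
                 labels = MUSCLES, normalization = set$normalization),
            class = "EnvelopeSet")
}

#' Full raw-EMG to muscle-envelope chain
#'
#' Convenience wrapper: noisy-channel detection, zeroing and re-referencing,
#' envelope extraction, task-maximum normalisation and muscle averaging.
#'
#' @param emg an `"EmgRecording"`.
#' @param noise_mult threshold multiplier for [detect_noisy_channels()].
#' @param highpass_hz,median_window_s see [extract_envelope()].
#' @return list with `muscle` (7-muscle `"EnvelopeSet"`), `channels`
#'   (normalised per-channel set) and `noisy_mask`.
#' @export
process_emg <- function(emg, noise_mult = 5, highpass_hz = 20,
                        median_window_s = 0.16) {
  mask <- detect_noisy_channels(emg, mult = noise_mult)
  reref <- rereference(emg, mask)
  env <- extract_envelope(reref, highpass_hz, median_window_s)
  norm <- normalize_envelopes(list(env))[[1]]
  assignment <- emg$channel_map
  assignment[mask] <- "noisy"
  list(muscle = muscle_envelopes(norm, assignment),
       channels = norm, noisy_mask = mask)
}
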
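#' Gait-event detection from foot-worn inertial sensors
#'
#' Foot-flat (FF) intervals are found where all three (by default angular)
#' velocity components simultaneously stay within a small band around their
#' trial mean. Initial contact (IC) is the local maximum of the angular
#' velocity signal-vector magnitude (SVM) right before each FF run —
#' the heel-strike spike — and terminal contact (TC) the local maximum right
#' after it — the push-off spike. The four gait phases are then tiled from
#' the two sides' events: double stance 1 from impaired IC to contralateral
#' TC, single stance to contralateral IC, double stance 2 to impaired TC,
#' swing to the next impaired IC.
#'
#' @name gait_events
NULL

# contiguous TRUE runs of a logical vector as (start, end) index pairs
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect foot-flat samples
#'
#' A sample is foot-flat when, simultaneously in all three directions,
#' `|x - mean(x)| <= k * sd(x)` (mean and sd taken over the whole trial,
#' per direction). Runs shorter than `min_duration` are discarded.
#'
#' @param motion n x 3 matrix of filtered foot angular velocities (rad/s) —
#'   or linear velocities, the criterion is the same; see Details.
#' @param rate sampling rate, Hz.
#' @param k threshold multiplier on the per-direction standard deviation.
#'   The signal should sit near its mean (which is close to zero for a
#'   periodic gait) throughout FF, so `k` is small.
#' @param min_duration minimum FF run length, s; shorter runs are chatter.
#' @return logical vector, `TRUE` = foot flat.
#' @details The criterion is classically written for the foot's linear
#'   velocities, but the same small-variation logic applies to the angular
#'   velocities (no foot rotation while the whole sole is on the ground),
#'   which is what the SVM-based event picking uses; this implementation
#'   accepts either, and the pipeline default is angular velocity.
#' @export
detect_foot_flat <- function(motion, rate, k = 0.5, min_duration = 0.05) {
  stopifnot(ncol(motion) == 3)
  if (nrow(motion) < rate) stop("need at least one second of data")
  mu <- colMeans(motion)
  sd3 <- apply(motion, 2, stats::sd)
  if (any(sd3 == 0))
    stop("degenerate constant input: zero variance in direction(s) ",
         paste(which(sd3 == 0), collapse = ", "))
  dev <- abs(sweep(motion, 2, mu))
  mask <- dev[, 1] <= k * sd3[1] & dev[, 2] <= k * sd3[2] & dev[, 3] <= k * sd3[3]
  min_len <- max(1L, round(min_duration * rate))
  runs <- .runs(mask)
  for (i in seq_len(nrow(runs))) {
    if (runs[i, "end"] - runs[i, "start"] + 1L < min_len)
      mask[runs[i, "start"]:runs[i, "end"]] <- FALSE
  }
  mask
}

#' Signal vector magnitude of a 3-axis series
#'
#' Per-sample Euclidean norm `sqrt(wx^2 + wy^2 + wz^2)`.
#'
#' @param motion n x 3 matrix (angular velocity components).
#' @return non-negative numeric vector.
#' @export
signal_vector_magnitude <- function(motion) {
  stopifnot(ncol(motion) == 3)
  sqrt(rowSums(motion^2))
}

# nearest strict local maximum of x at or before/after index i0, bounded
.nearest_local_max <- function(x, i0, direction, lo, hi) {
  n <- length(x)
  if (direction < 0) {
    from <- min(i0, n - 1L); to <- max(lo, 2L)
    if (from < to) return(NA_integer_)
    idx <- seq(from, to)
  } else {
    from <- max(i0, 2L); to <- min(hi, n - 1L)
    if (from > to) return(NA_integer_)
    idx <- seq(from, to)
  }
  for (i in idx) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) return(i)
  }
  NA_integer_
}

#' Detect initial and terminal contacts from SVM and foot-flat runs
#'
#' For each foot-flat run: IC is the nearest local maximum of the SVM before
#' the run start, TC the nearest local maximum after the run end. The search
#' is bounded by the neighbouring runs so an event cannot be captured from
#' another cycle. Runs touching the series boundary yield no event (logged).
#'
#' @param svm SVM series from [signal_vector_magnitude()].
#' @param ff logical foot-flat mask from [detect_foot_flat()].
#' @param rate sampling rate, Hz (for reporting seconds).
#' @return list with sorted `ic` and `tc` sample indices, the matching
#'   `ic_time`/`tc_time` in seconds, and the FF `runs` used.
#' @export
detect_ic_tc <- function(svm, ff, rate) {
  runs <- .runs(ff)
  if (nrow(runs) == 0) stop("no foot-flat runs found")
  n <- length(svm)
  ic <- tc <- rep(NA_integer_, nrow(runs))
  for (i in seq_len(nrow(runs))) {
    lo <- if (i > 1) runs[i - 1, "end"] + 1L else 1L
    hi <- if (i < nrow(runs)) runs[i + 1, "start"] - 1L else n
    if (runs[i, "start"] > 1L)
      ic[i] <- .nearest_local_max(svm, runs[i, "start"] - 1L, -1, lo, hi)
    if (runs[i, "end"] < n)
      tc[i] <- .nearest_local_max(svm, runs[i, "end"] + 1L, +1, lo, hi)
  }
  dropped <- sum(is.na(ic)) + sum(is.na(tc))
  if (dropped > 0)
    message(dropped, " event(s) skipped at series boundaries or without a local maximum")
  ic <- sort(ic[!is.na(ic)])
  tc <- sort(tc[!is.na(tc)])
  list(ic = ic, tc = tc,
       ic_time = (ic - 1) / rate, tc_time = (tc - 1) / rate,
       runs = runs)
}

#' Segment gait phases from both sides' events
#'
#' Per impaired cycle (impaired IC to the next impaired IC), the four phases
#' are built exactly as defined: double stance 1 `[IC_imp, TC_contra)`,
#' single stance `[TC_contra, IC_contra)`, double stance 2
#' `[IC_contra, TC_imp)`, swing `[TC_imp, IC_imp_next)`. Cycles missing a
#' contralateral event are dropped (logged). Event alternation is checked
#' per side and violations abort with the offending indices.
#'
#' @param impaired,contralateral event lists from [detect_ic_tc()] (need
#'   `ic` and `tc` sample indices).
#' @param rate sampling rate, Hz.
#' @return object of class `"GaitPhaseTable"`: a data.frame with one row per
#'   complete cycle (`ic_imp`, `tc_contra`, `ic_contra`, `tc_imp`,
#'   `ic_next`, all sample indices), plus `rate` and the raw per-side events
#'   as attributes.
#' @export
segment_gait_phases <- function(impaired, contralateral, rate) {
  check_alt <- function(ev, side) {
    merged <- sort(c(ev$ic, ev$tc))
    lab <- ifelse(merged %in% ev$ic, "ic", "tc")
    bad <- which(lab[-1] == lab[-length(lab)])
    if (length(bad))
      stop("events do not alternate IC/TC on the ", side,
           " side at sample(s) ", paste(merged[bad + 1], collapse = ", "))
  }
  check_alt(impaired, "impaired")
  check_alt(contralateral, "contralateral")
  ics <- impaired$ic
  rows <- list()
  dropped <- 0L
  for (j in seq_len(length(ics) - 1L)) {
    a <- ics[j]; b <- ics[j + 1]
    tc_c <- contralateral$tc[contralateral$tc > a & contralateral$tc < b]
    ic_c <- contralateral$ic[contralateral$ic > a & contralateral$ic < b]
    tc_i <- impaired$tc[impaired$tc > a & impaired$tc < b]
    if (length(tc_c) != 1 || length(ic_c) != 1 || length(tc_i) != 1 ||
        !(tc_c < ic_c && ic_c < tc_i)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ic_imp = a, tc_contra = tc_c, ic_contra = ic_c, tc_imp = tc_i, ic_next = b)
  }
  if (dropped > 0) message(dropped, " cycle(s) dropped: missing contralateral events")
  if (!length(rows)) stop("no complete gait cycles")
  tab <- do.call(rbind, rows)
  structure(tab, class = c("GaitPhaseTable", "data.frame"), rate = rate,
            impaired = impaired, contralateral = contralateral)
}

#' Phase fractions of each cycle
#'
#' @param phases a `"GaitPhaseTable"`.
#' @return data.frame of per-cycle fractions of double stance 1, single
#'   stance, double stance 2 and swing (each row sums to 1).
#' @export
phase_fractions <- function(phases) {
  len <- phases$ic_next - phases$ic_imp
  data.frame(
    double_stance_1 = (phases$tc_contra - phases$ic_imp) / len,
    single_stance = (phases$ic_contra - phases$tc_contra) / len,
    double_stance_2 = (phases$tc_imp - phases$ic_contra) / len,
    swing = (phases$ic_next - phases$tc_imp) / len
  )
}

#' Detect events for both feet from an inertial trial
#'
#' Filters each foot's gyroscope at `filter_hz` (zero-lag), applies
#' [detect_foot_flat()], [signal_vector_magnitude()] and [detect_ic_tc()]
#' per side, and assembles the [segment_gait_phases()] table.
#'
#' @param trial an `"ImuTrial"`.
#' @param k,min_duration see [detect_foot_flat()].
#' @param filter_hz zero-lag low-pass corner for the foot signals, Hz.
#' @param use_linear_velocity if `TRUE`, apply the FF criterion to linear
#'   velocities obtained by integrating the gravity-compensated
#'   accelerations (per-stride drift removed); default uses angular
#'   velocities.
#' @return list with per-side events (`impaired`, `contralateral`), the
#'   phase table `phases`, and the filtered SVM series.
#' @export
detect_gait_events <- function(trial, k = 0.5, min_duration = 0.05,
                               filter_hz = 3, use_linear_velocity = FALSE) {
  stopifnot(inherits(trial, "ImuTrial"))
  per_foot <- function(sensor) {
    gyr <- butterworth_zero_lag(trial$sensors[[sensor]]$gyro, rate = trial$rate,
                                cutoff = filter_hz, kind = "low")
    series <- gyr
    if (use_linear_velocity) {
      acc <- to_model_frame(trial$sensors[[sensor]]$acc, trial$sensors[[sensor]]$quat)
      acc <- sweep(acc, 2, -GRAVITY)   # remove gravity reaction
      vel <- apply(acc, 2, cumsum) / trial$rate
      vel <- apply(vel, 2, function(v) v - stats::fitted(stats::lm(v ~ seq_along(v))))
      series <- butterworth_zero_lag(vel, rate = trial$rate,
                                     cutoff = filter_hz, kind = "low")
    }
    ff <- detect_foot_flat(series, trial$rate, k = k, min_duration = min_duration)
    svm <- signal_vector_magnitude(gyr)
    ev <- detect_ic_tc(svm, ff, trial$rate)
    ev$ff <- ff
    ev$svm <- svm
    ev
  }
  imp <- per_foot("foot_imp")
  contra <- per_foot("foot_contra")
  phases <- segment_gait_phases(imp, contra, trial$rate)
  list(impaired = imp, contralateral = contra, phases = phases)
}
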
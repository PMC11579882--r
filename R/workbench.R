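#' File formats, configuration and the end-to-end pipeline
#'
#' Raw device streams travel as CSV, biomechanics time series as OpenSim
#' storage (.sto/.mot), events and calibration results as JSON, and the
#' configuration as YAML. [run_pipeline()] chains preprocessing, gait-event
#' detection, kinetics, joint mechanics and (optionally) the EMG-driven
#' model, writing all intermediates plus a metrics report.
#'
#' @name workbench
NULL

.imu_cols <- function(sensor) {
  paste0(sensor, "_", c("q_w", "q_x", "q_y", "q_z",
                        "acc_x", "acc_y", "acc_z",
                        "gyr_x", "gyr_y", "gyr_z"))
}

#' Write an inertial trial to CSV
#'
#' One `time` column plus, per sensor, quaternion (w, x, y, z), acceleration
#' and gyroscope columns.
#'
#' @param trial an `"ImuTrial"`.
#' @param path output file.
#' @export
write_imu_table <- function(trial, path) {
  cols <- list(time = trial$time)
  for (nm in names(trial$sensors)) {
    s <- trial$sensors[[nm]]
    block <- cbind(s$quat, s$acc, s$gyro)
    colnames(block) <- .imu_cols(nm)
    cols <- c(cols, as.data.frame(block))
  }
  df <- do.call(data.frame, c(cols, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an inertial trial from CSV
#'
#' Validates the time base (uniform within 1 % jitter) and quaternion norms
#' (renormalised when within `1e-3` of unit, rejected otherwise, naming the
#' offending columns).
#'
#' @param path CSV written by [write_imu_table()] (or matching its layout).
#' @return an `"ImuTrial"`.
#' @export
read_imu_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column")
  dt <- diff(df$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if ((max(dt) - min(dt)) / stats::median(dt) > 0.01)
    stop("non-uniform time base (jitter exceeds 1%)")
  rate <- 1 / stats::median(dt)
  sensors <- list()
  for (nm in SEGMENTS) {
    cols <- .imu_cols(nm)
    if (!all(cols %in% names(df))) {
      miss <- setdiff(cols, names(df))
      stop("missing column(s): ", paste(miss, collapse = ", "))
    }
    q <- as.matrix(df[cols[1:4]])
    norms <- sqrt(rowSums(q^2))
    if (any(abs(norms - 1) > 1e-3))
      stop("quaternion norms off unit beyond 1e-3 in columns ",
           paste(cols[1:4], collapse = ", "))
    sensors[[nm]] <- list(quat = quat(q[, 1], q[, 2], q[, 3], q[, 4]) / norms,
                          acc = as.matrix(df[cols[5:7]]),
                          gyro = as.matrix(df[cols[8:10]]))
    dimnames(sensors[[nm]]$acc) <- dimnames(sensors[[nm]]$gyro) <- NULL
  }
  structure(list(time = df$time, rate = rate, sensors = sensors,
                 labels = stats::setNames(SEGMENTS, SEGMENTS)),
            class = "ImuTrial")
}

#' Write a named time series in OpenSim storage format
#'
#' Header with `nRows`, `nColumns`, `inDegrees` and `endheader`, then a
#' tab-delimited body whose first column is `time`. Values are written with
#' 15 significant digits so a read-back reproduces them to better than
#' 1e-12. NA values are permitted only in columns named like CoP
#' (`_p` components), where they encode the undefined swing samples as
#' empty fields; NA anywhere else is rejected.
#'
#' @param series data.frame or named list of equal-length numeric vectors,
#'   including `time` (uniform).
#' @param path output file.
#' @param name storage name written in the header.
#' @param in_degrees logical, header flag.
#' @export
write_sto <- function(series, path, name = "wearlab", in_degrees = FALSE) {
  df <- as.data.frame(series, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  dt <- diff(df$time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * stats::median(dt) + 1e-12)
    stop("time vector must be uniform and increasing")
  na_ok <- grepl("_p[xyz]$", names(df))
  bad <- vapply(seq_along(df), function(j) any(is.na(df[[j]])) && !na_ok[j], TRUE)
  if (any(bad))
    stop("NA values only allowed in CoP columns; offending: ",
         paste(names(df)[bad], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               paste0("nRows=", nrow(df)),
               paste0("nColumns=", ncol(df)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(df), collapse = "\t")), con)
  body <- vapply(df, function(col) {
    out <- sprintf("%.15g", col)
    out[is.na(col)] <- ""
    out
  }, character(nrow(df)))
  writeLines(apply(matrix(body, nrow = nrow(df)), 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an OpenSim storage file
#'
#' @param path .sto/.mot file.
#' @return data.frame (empty fields become NA).
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "endheader")[1]
  if (is.na(hdr_end)) stop("not a storage file: no endheader")
  cols <- strsplit(lines[hdr_end + 1], "\t")[[1]]
  df <- utils::read.table(text = lines[-seq_len(hdr_end + 1)], sep = "\t",
                          col.names = cols, na.strings = "", check.names = FALSE)
  names(df) <- cols
  df
}

#' Write external loads (both feet) as a storage file
#'
#' Standard external-loads column dialect: per side `ground_force_vx/vy/vz`
#' (force), `ground_force_px/py/pz` (point of application, the CoP), with a
#' side prefix for the second foot.
#'
#' @param time time vector.
#' @param loads `"ExternalLoadSeries"` from [split_grf_sta()].
#' @param cop list with `imp`, `contra` CoP matrices.
#' @param path output file.
#' @export
write_external_loads <- function(time, loads, cop, path) {
  keep <- !is.na(loads$share)
  df <- data.frame(time = time,
                   ground_force_vx = loads$imp[, 1], ground_force_vy = loads$imp[, 2],
                   ground_force_vz = loads$imp[, 3],
                   ground_force_px = cop$imp[, 1], ground_force_py = cop$imp[, 2],
                   ground_force_pz = cop$imp[, 3],
                   contra_ground_force_vx = loads$contra[, 1],
                   contra_ground_force_vy = loads$contra[, 2],
                   contra_ground_force_vz = loads$contra[, 3],
                   contra_ground_force_px = cop$contra[, 1],
                   contra_ground_force_py = cop$contra[, 2],
                   contra_ground_force_pz = cop$contra[, 3])
  write_sto(df[keep, ], path, name = "external_loads")
}

#' Default pipeline configuration
#'
#' Every parameter defaults to the documented value where the processing
#' chain prescribes one (6 / 3 / 20 Hz corners, 0.16 s median window, 1.68 m
#' generic height, +/- 5 % calibration bounds); the rest are implementation
#' defaults, all overridable. Round-trips through YAML unchanged.
#'
#' @param height,mass participant, m / kg.
#' @param seed integer seed driving the generator and calibration.
#' @param ... overrides for any nested field.
#' @return nested list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(height = 1.775, mass = 94.2, seed = 1L, ...) {
  cfg <- list(
    participant = list(height = height, mass = mass, impaired_side = "left"),
    synthetic = list(cadence = 100, walking_speed = 1.1, n_cycles = 10,
                     duty_factor = 0.6, imu_noise_sd_acc = 0.05,
                     imu_noise_sd_gyro = 0.01),
    filters = list(lab_lowpass_hz = 6, imu_lowpass_hz = 3),
    emg = list(highpass_hz = 20, median_window_s = 0.16, noise_mult = 5),
    events = list(k = 0.5, min_ff_duration_s = 0.05),
    calibration = list(enabled = TRUE, length_bound_frac = 0.05,
                       strength_bounds = c(0.5, 2.0), shape_bounds = c(-3, -0.01),
                       pop = 30, gens = 60),
    seed = as.integer(seed)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a `"PipelineConfig"`.
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.fmt_num <- function(x) sprintf("%.10g", x)

#' Run the full wearable-lab pipeline on a synthetic trial
#'
#' Simulates a walking trial (kinematics, inertial signals, EMG, ground
#' truth), then runs the wearable chain in order: stream filtering and the
#' EMG envelope chain; gait-event detection; body-model scaling, total-GRF
#' estimation and smooth-transition split; CoP progression; sensor
#' registration, joint angles and planar ankle inverse dynamics; optionally
#' the EMG-driven model calibration (on the first complete cycle, against
#' the wearable inverse-dynamics torque) and novel-cycle torque estimation.
#' Agreement metrics (R^2, RMSE) against the generator's ground truth are
#' reported per quantity. All randomness is driven by `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes the inertial CSV, events JSON,
#'   external loads / angles / torques .sto, metrics report CSV and a
#'   parameter log. Outputs are deterministic for a fixed seed.
#' @param emg logical: include the EMG chain and EMG-driven model (pipeline
#'   degrades gracefully to the inverse-dynamics stages without it).
#' @return result bundle (invisible when writing): trial objects, events,
#'   loads, angles, torques, calibration and the `metrics` data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, emg = TRUE) {
  stage <- "simulate"
  res <- tryCatch({
    syn <- synthetic_config(
      cadence = config$synthetic$cadence,
      walking_speed = config$synthetic$walking_speed,
      n_cycles = config$synthetic$n_cycles,
      duty_factor = config$synthetic$duty_factor,
      height = config$participant$height, mass = config$participant$mass,
      imu_noise_sd_acc = config$synthetic$imu_noise_sd_acc,
      imu_noise_sd_gyro = config$synthetic$imu_noise_sd_gyro,
      rng_seed = config$seed)
    poses <- generate_segment_kinematics(syn)
    trial <- derive_imu_signals(poses, syn)
    body <- scale_body_model(config$participant$height, config$participant$mass)
    truth <- truth_loads(poses, body, syn)
    static <- derive_imu_signals(generate_static_trial(syn), syn)

    stage <- "preprocess"
    emg_proc <- NULL
    if (emg) {
      rec <- generate_emg(syn, truth)
      emg_proc <- process_emg(rec, noise_mult = config$emg$noise_mult,
                              highpass_hz = config$emg$highpass_hz,
                              median_window_s = config$emg$median_window_s)
    }

    stage <- "gait_events"
    events <- detect_gait_events(trial, k = config$events$k,
                                 min_duration = config$events$min_ff_duration_s,
                                 filter_hz = config$filters$imu_lowpass_hz)
    phases <- events$phases

    stage <- "kinetics"
    acc_model <- lapply(trial$sensors, function(s) {
      butterworth_zero_lag(to_model_frame(s$acc, s$quat), trial$rate,
                           config$filters$imu_lowpass_hz, "low")
    })
    names(acc_model) <- names(trial$sensors)
    names(acc_model)[names(acc_model) == "pelvis"] <- "pelvis"
    total <- total_grf(acc_model, body)
    loads <- split_grf_sta(total, phases)
    lmk_imp <- landmark_trajectories(poses$segments$foot_imp$pos,
                                     poses$segments$foot_imp$quat, body)
    lmk_con <- landmark_trajectories(poses$segments$foot_contra$pos,
                                     poses$segments$foot_contra$quat, body)
    st <- stance_tables(phases)
    n <- length(trial$time)
    cop <- list(imp = estimate_cop(st$imp, lmk_imp, n),
                contra = estimate_cop(st$contra, lmk_con, n))

    stage <- "joint_mechanics"
    reg <- register_sensors_static(static)
    angles <- joint_angles(trial, reg)
    torque_id <- ankle_inverse_dynamics(
      poses$segments$foot_imp$pos, poses$segments$foot_imp$quat,
      acc_model$foot_imp, loads$imp, cop$imp, body, trial$rate,
      filter_hz = config$filters$imu_lowpass_hz)

    stage <- "mtu_model"
    calib <- NULL; torque_emg <- NULL
    if (emg) {
      geometry <- scale_mtu_geometry(generic_mtu_table(), body$scale)
      init <- precalibrate_lom_lst(geometry, body$scale)
      env100 <- apply(emg_proc$muscle$envelopes, 2, function(col) {
        stats::approx(emg_proc$muscle$time, col, xout = trial$time, rule = 2)$y
      })
      p1 <- phases[1, ]
      idx <- p1$ic_imp:p1$ic_next
      cal_angles <- list(knee = angles$knee[idx], ankle = angles$ankle[idx])
      calib <- calibrate_mtu(env100[idx, ], cal_angles, torque_id$nm[idx],
                             geometry, init, trial$rate,
                             length_bound_frac = config$calibration$length_bound_frac,
                             strength_bounds = config$calibration$strength_bounds,
                             shape_bounds = config$calibration$shape_bounds,
                             seed = config$seed,
                             control = list(pop = config$calibration$pop,
                                            gens = config$calibration$gens))
      torque_emg <- estimate_torque(calib, env100, angles, geometry,
                                    trial$rate, body$mass)$torque
    }

    stage <- "report"
    covered <- !is.na(loads$share)
    m <- list(
      knee_angle = agreement_metrics(truth$knee_angle, angles$knee),
      ankle_angle = agreement_metrics(truth$ankle_angle, angles$ankle),
      grf_vertical = agreement_metrics(truth$grf$total[covered, 2], total[covered, 2]),
      grf_anterior = agreement_metrics(truth$grf$total[covered, 1], total[covered, 1]),
      grf_imp_vertical = agreement_metrics(truth$grf$imp[covered, 2],
                                           loads$imp[covered, 2]),
      cop_imp_anterior = agreement_metrics(truth$cop$imp[, 1], cop$imp[, 1]),
      torque_id = agreement_metrics(truth$ankle_torque[covered],
                                    torque_id$nm[covered], mass = body$mass)
    )
    if (!is.null(torque_emg))
      m$torque_emg_vs_id <- agreement_metrics(torque_id$nm[covered],
                                              torque_emg$nm[covered],
                                              mass = body$mass)
    metrics <- data.frame(
      quantity = names(m),
      r2 = vapply(m, `[[`, 0, "r2"),
      rmse = vapply(m, `[[`, 0, "rmse"),
      row.names = NULL)

    list(config = config, poses = poses, trial = trial, truth = truth,
         body = body, emg = emg_proc, events = events, phases = phases,
         total_grf = total, loads = loads, cop = cop, angles = angles,
         torque_id = torque_id, calibration = calib, torque_emg = torque_emg,
         metrics = metrics)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_imu_table(res$trial, file.path(out_dir, "imu.csv"))
    ev <- res$events
    jsonlite::write_json(list(
      impaired = list(ic = ev$impaired$ic, tc = ev$impaired$tc,
                      ic_time = ev$impaired$ic_time, tc_time = ev$impaired$tc_time),
      contralateral = list(ic = ev$contralateral$ic, tc = ev$contralateral$tc,
                           ic_time = ev$contralateral$ic_time,
                           tc_time = ev$contralateral$tc_time)),
      file.path(out_dir, "events.json"), digits = NA, pretty = TRUE)
    write_external_loads(res$trial$time, res$loads, res$cop,
                         file.path(out_dir, "external_loads.sto"))
    write_sto(data.frame(time = res$trial$time,
                         knee = res$angles$knee * 180 / pi,
                         ankle = res$angles$ankle * 180 / pi),
              file.path(out_dir, "joint_angles.sto"), name = "joint_angles",
              in_degrees = TRUE)
    tq <- data.frame(time = res$trial$time, ankle_torque_id = res$torque_id$nm)
    if (!is.null(res$torque_emg)) tq$ankle_torque_emg <- res$torque_emg$nm
    write_sto(tq, file.path(out_dir, "ankle_torque.sto"), name = "ankle_torque")
    utils::write.csv(within(res$metrics, {
      r2 <- .fmt_num(r2); rmse <- .fmt_num(rmse)
    }), file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(res$calibration)) {
      cal <- res$calibration
      jsonlite::write_json(list(
        params = cal$params, objective_init = cal$objective_init,
        objective_final = cal$objective_final, seed = cal$seed,
        r2 = cal$metrics$r2, rmse = cal$metrics$rmse),
        file.path(out_dir, "calibration.json"), digits = NA, pretty = TRUE,
        dataframe = "columns")
    }
    log_lines <- c(
      "wearlab pipeline log",
      paste0("seed=", res$config$seed),
      paste0("participant.height_m=", res$config$participant$height),
      paste0("participant.mass_kg=", res$config$participant$mass),
      paste0("filters.imu_lowpass_hz=", res$config$filters$imu_lowpass_hz),
      paste0("filters.lab_lowpass_hz=", res$config$filters$lab_lowpass_hz),
      paste0("emg.highpass_hz=", res$config$emg$highpass_hz),
      paste0("emg.median_window_s=", res$config$emg$median_window_s),
      paste0("emg.noise_mult=", res$config$emg$noise_mult),
      paste0("events.k=", res$config$events$k),
      paste0("events.min_ff_duration_s=", res$config$events$min_ff_duration_s),
      paste0("calibration.length_bound_frac=",
             res$config$calibration$length_bound_frac),
      paste0("noisy_channels=", if (is.null(res$emg)) "NA" else
        paste(which(res$emg$noisy_mask), collapse = ",")),
      paste0("cycles_detected=", nrow(res$phases)),
      paste0("emg_driven_sections=", if (is.null(res$torque_emg)) "absent" else "present")
    )
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    return(invisible(res))
  }
  res
}
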
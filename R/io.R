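RAD2DEG <- 180 / pi
DEG2RAD <- pi / 180

#' Write a trial ensemble to long-format CSV
#'
#' One row per trial per sample: `trial`, `time_s`, tip position `x_mm`,
#' `y_mm`, `z_mm`, and the nine joint angles in degrees (columns named after
#' [JOINT_NAMES] with a `_deg` suffix). Angles are stored in degrees at the
#' file boundary; the package works in radians internally.
#'
#' @param ensemble a `trial_ensemble`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trials_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  k <- dim(ensemble$angles)[3]
  n <- dim(ensemble$angles)[1]
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    ang <- ensemble$angles[, , j] * RAD2DEG
    colnames(ang) <- paste0(JOINT_NAMES, "_deg")
    tip <- ensemble$tips[, , j]
    colnames(tip) <- c("x_mm", "y_mm", "z_mm")
    rows[[j]] <- data.frame(trial = j, time_s = ensemble$time, tip, ang)
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trial CSV back into a trial ensemble
#'
#' Inverse of [write_trials_csv()]. The returned ensemble has no generative
#' reference (it may be measured data), so it supports [analyze_ensemble()]
#' but not [ensemble_ucm()].
#'
#' @param path CSV path
#' @param cond a [condition_spec()] describing the trials (start/target points
#'   are needed for bounds detection)
#' @param geometry an [arm_geometry()] for the condition
#' @return object of class `trial_ensemble`
#' @export
read_trials_csv <- function(path, cond, geometry = NULL) {
  stopifnot(inherits(cond, "condition_spec"))
  if (is.null(geometry)) geometry <- default_geometry(cond$rod_length)
  df <- utils::read.csv(path)
  need <- c("trial", "time_s", "x_mm", "y_mm", "z_mm",
            paste0(JOINT_NAMES, "_deg"))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trial CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  trials <- sort(unique(df$trial))
  k <- length(trials)
  n <- sum(df$trial == trials[1L])
  time <- df$time_s[df$trial == trials[1L]]
  angles <- array(NA_real_, c(n, 9L, k),
                  dimnames = list(NULL, JOINT_NAMES, NULL))
  tips <- array(NA_real_, c(n, 3L, k),
                dimnames = list(NULL, c("x", "y", "z"), NULL))
  for (j in seq_len(k)) {
    sub <- df[df$trial == trials[j], ]
    if (nrow(sub) != n)
      stop("trial ", trials[j], " has a different number of samples",
           call. = FALSE)
    angles[, , j] <- as.matrix(sub[, paste0(JOINT_NAMES, "_deg")]) * DEG2RAD
    tips[, , j] <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
  }
  structure(list(time = time, angles = angles, tips = tips, reference = NULL,
                 cond = cond, geometry = geometry, model = NULL),
            class = "trial_ensemble")
}

#' Read a pipeline configuration file
#'
#' YAML configuration with keys: `geometry` (the five [arm_geometry()] field
#' names, mm; `rod_length` is set per condition), `conditions` (list of
#' `rod_length`, `displaced`, optional `n_trials`), `movement_time` (s),
#' `sample_rate` (Hz), `variability` (`sigma_gev_deg`, `sigma_ngev_deg`,
#' `temporal_smoothness_s`), `seed`, and `thresholds` (`speed_mm_s`,
#' `radius_mm`). Missing keys fall back to study defaults except the listed
#' required ones.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- c("geometry", "conditions", "variability", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config error: missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  gkeys <- c("upper_arm_length", "forearm_length", "hand_length",
             "finger_length")
  gmiss <- setdiff(gkeys, names(cfg$geometry))
  if (length(gmiss))
    stop("config error: geometry missing keys: ",
         paste(gmiss, collapse = ", "), call. = FALSE)
  vkeys <- c("sigma_gev_deg", "sigma_ngev_deg")
  vmiss <- setdiff(vkeys, names(cfg$variability))
  if (length(vmiss))
    stop("config error: variability missing keys: ",
         paste(vmiss, collapse = ", "), call. = FALSE)
  cfg$movement_time <- cfg$movement_time %||% 0.6
  cfg$sample_rate <- cfg$sample_rate %||% 100
  cfg$variability$temporal_smoothness_s <-
    cfg$variability$temporal_smoothness_s %||% 0.4
  cfg$thresholds <- cfg$thresholds %||% list()
  cfg$thresholds$speed_mm_s <- cfg$thresholds$speed_mm_s %||% 25
  cfg$thresholds$radius_mm <- cfg$thresholds$radius_mm %||% 10
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default study configuration
#'
#' Emits a YAML config for the full eight-condition design with the package's
#' default geometry, movement parameters and variability model, ready for
#' [run_pipeline()] or the command-line interface.
#'
#' @param path output YAML path
#' @param seed base RNG seed recorded in the config
#' @return `path`, invisibly
#' @export
write_default_config <- function(path, seed = 1L) {
  cfg <- list(
    geometry = list(upper_arm_length = 300, forearm_length = 250,
                    hand_length = 80, finger_length = 70),
    conditions = unname(lapply(study_design(), function(cs)
      list(rod_length = cs$rod_length, displaced = cs$displaced,
           n_trials = cs$n_trials))),
    movement_time = 0.6,
    sample_rate = 100,
    variability = list(sigma_gev_deg = 2, sigma_ngev_deg = 0.5,
                       temporal_smoothness_s = 0.4),
    thresholds = list(speed_mm_s = 25, radius_mm = 10),
    seed = as.integer(seed)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
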
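#' Declare source units for trial files
#'
#' Trial files may store accelerometer data in g or m/s^2 and gyroscope data
#' in deg/s or rad/s, depending on how the logger was configured; the native
#' export units of wrist-worn research loggers vary by firmware. The
#' declaration is applied at read time and everything downstream works in SI
#' (m/s^2, rad/s, uT).
#'
#' @param acc `"ms2"` or `"g"`.
#' @param gyro `"rad_s"` or `"deg_s"`.
#' @param mag `"uT"` (the only supported magnetometer unit).
#' @return a unit-declaration object used by [read_trial()] / [write_trial()].
#' @export
imu_units <- function(acc = c("ms2", "g"), gyro = c("rad_s", "deg_s"),
                      mag = "uT") {
  structure(list(acc = match.arg(acc), gyro = match.arg(gyro),
                 mag = match.arg(mag)),
            class = "imu_units")
}

.acc_factor <- function(u) if (u == "g") .GRAVITY else 1
.gyro_factor <- function(u) if (u == "deg_s") pi / 180 else 1

.TRIAL_COLS <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Read one trial file
#'
#' Reads a delimited trial table (header `t,ax,ay,az,gx,gy,gz,mx,my,mz`, one
#' row per sample) and converts the declared source units to the internal SI
#' units. Metadata is supplied by the caller, normally from a session
#' manifest entry.
#'
#' @param path CSV file path.
#' @param units an [imu_units()] declaration for the file's source units.
#' @inheritParams imu_trial
#' @return an [imu_trial()].
#' @export
read_trial <- function(path, units = imu_units(), participant_id = "unknown",
                       task_id = "1", setting = "home", movement_type = "",
                       quality = "unknown", fs_nominal = 100,
                       trial_id = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(.TRIAL_COLS, names(tab))
  if (length(missing))
    stop("trial file ", path, " lacks columns: ",
         paste(missing, collapse = ","), call. = FALSE)
  if (nrow(tab) < 2)
    stop("trial file ", path, " has fewer than 2 rows", call. = FALSE)
  if (any(diff(tab$t) <= 0))
    stop("trial file ", path, " has non-monotone timestamps", call. = FALSE)
  fa <- .acc_factor(units$acc)
  fg <- .gyro_factor(units$gyro)
  tab[c("ax", "ay", "az")] <- tab[c("ax", "ay", "az")] * fa
  tab[c("gx", "gy", "gz")] <- tab[c("gx", "gy", "gz")] * fg
  if (is.null(trial_id))
    trial_id <- tools::file_path_sans_ext(basename(path))
  imu_trial(tab[.TRIAL_COLS], participant_id = participant_id,
            task_id = task_id, setting = setting,
            movement_type = movement_type, quality = quality,
            fs_nominal = fs_nominal, trial_id = trial_id)
}

#' Write one trial file
#'
#' Inverse of [read_trial()]: converts the trial's internal SI channels to
#' the declared target units and writes the 10-column table.
#'
#' @inheritParams read_trial
#' @param trial an [imu_trial()].
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, units = imu_units()) {
  tab <- trial$samples
  tab[c("ax", "ay", "az")] <- tab[c("ax", "ay", "az")] / .acc_factor(units$acc)
  tab[c("gx", "gy", "gz")] <- tab[c("gx", "gy", "gz")] / .gyro_factor(units$gyro)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a session from a manifest
#'
#' The manifest is a JSON file listing the session's trial files with their
#' metadata:
#' \preformatted{
#' {"participant_id": "p01", "setting": "lab", "fs_nominal": 100,
#'  "units": {"acc": "ms2", "gyro": "rad_s"},
#'  "trials": [{"file": "t01.csv", "task_id": "1",
#'              "movement_type": "correct", "quality": "correct"}, ...]}
#' }
#' Trial file paths are resolved relative to the manifest's directory.
#' Trials with quality `"unknown"` are only accepted for home sessions.
#'
#' @param manifest_path path to the manifest JSON.
#' @return an [imu_session()].
#' @export
read_session <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  for (f in c("participant_id", "setting", "trials"))
    if (is.null(man[[f]])) stop("manifest lacks field ", f, call. = FALSE)
  units <- if (is.null(man$units)) imu_units() else
    imu_units(acc = man$units$acc %||% "ms2",
              gyro = man$units$gyro %||% "rad_s")
  fs <- man$fs_nominal %||% 100
  base <- dirname(manifest_path)
  trials <- lapply(man$trials, function(e) {
    read_trial(file.path(base, e$file), units = units,
               participant_id = man$participant_id, task_id = e$task_id,
               setting = man$setting, movement_type = e$movement_type %||% "",
               quality = e$quality %||% "unknown", fs_nominal = fs,
               trial_id = e$trial_id %||% NULL)
  })
  imu_session(trials)
}

#' Write a session as trial files plus manifest
#'
#' @param session an [imu_session()].
#' @param dir output directory (created if needed).
#' @param units target units for the trial files.
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir, units = imu_units()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(session$trials, function(tr) {
    file <- paste0(tr$trial_id, ".csv")
    write_trial(tr, file.path(dir, file), units = units)
    list(file = file, trial_id = tr$trial_id, task_id = tr$task_id,
         movement_type = tr$movement_type, quality = tr$quality)
  })
  man <- list(participant_id = session$participant_id,
              setting = session$setting,
              fs_nominal = session$trials[[1]]$fs_nominal,
              units = list(acc = units$acc, gyro = units$gyro),
              trials = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
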
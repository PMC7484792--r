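# Trial input/output: delimited-text marker and force files with YAML
# metadata sidecars. Readers never filter, resample or gap-fill -- they hand
# the raw arrays to the preprocessing stage unchanged.

#' Subject metadata record
#'
#' @param subject_id character identifier.
#' @param age age in years.
#' @param age_group `"young"` or `"older"`; if missing it is derived from
#'   `age` using the study cutoffs (young 18--40 y, older >= 55 y).
#' @param height stature, m.
#' @param mass body mass, kg.
#' @param leg_length leg length, m.
#' @param comfortable_speed self-selected walking speed, m/s.
#' @return an object of class `subject_info`.
#' @export
subject_info <- function(subject_id, age, age_group = NULL, height, mass,
                         leg_length = NA_real_, comfortable_speed = NA_real_) {
  stopifnot(mass > 0, height > 0)
  derived <- if (age >= 55) "older" else if (age >= 18 && age <= 40) "young" else NA_character_
  if (is.null(age_group)) {
    if (is.na(derived))
      stop("age ", age, " falls outside both group definitions (young 18-40, older >= 55); ",
           "pass age_group explicitly")
    age_group <- derived
  }
  age_group <- match.arg(age_group, c("young", "older"))
  if (!is.na(derived) && age_group != derived)
    stop("age_group '", age_group, "' inconsistent with age ", age,
         " under cutoffs young 18-40 / older >= 55")
  structure(list(subject_id = as.character(subject_id), age = age,
                 age_group = age_group, height = height, mass = mass,
                 leg_length = leg_length, comfortable_speed = comfortable_speed),
            class = "subject_info")
}

#' Marker trajectory container
#'
#' @param positions time x marker x 3 array of lab-frame positions, metres.
#' @param labels marker names (length = dim 2 of `positions`).
#' @param sample_rate nominal sampling rate, Hz.
#' @param time optional time vector, s; defaults to `(0:(T-1))/sample_rate`.
#' @param gaps optional time x marker logical mask, TRUE where the marker is
#'   missing. Gap samples carry NA positions and are never interpolated here.
#' @export
marker_trajectories <- function(positions, labels, sample_rate, time = NULL,
                                gaps = NULL) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 3L,
            dim(positions)[2] == length(labels), sample_rate > 0)
  n <- dim(positions)[1]
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (is.null(gaps)) gaps <- apply(is.na(positions), c(1, 2), any)
  dimnames(positions)[[2]] <- labels
  structure(list(positions = positions, labels = labels,
                 sample_rate = sample_rate, time = time,
                 gaps = matrix(gaps, n, length(labels))),
            class = "marker_trajectories")
}

#' Force-plate record container
#'
#' Forces in N and moments in N.m about `plate_origin`, all in the lab
#' frame. `plate_origin` is a point in the plate's surface plane, so the
#' centre of pressure can be recovered directly from the moments.
#'
#' @param force,moment time x 3 matrices.
#' @param plate_origin length-3 lab-frame position of the plate origin, m.
#' @param sample_rate Hz.
#' @param time optional time vector, s.
#' @export
force_plate_record <- function(force, moment, plate_origin = c(0, 0, 0),
                               sample_rate = 300, time = NULL) {
  force <- as.matrix(force); moment <- as.matrix(moment)
  dimnames(force) <- NULL; dimnames(moment) <- NULL
  stopifnot(ncol(force) == 3L, ncol(moment) == 3L,
            nrow(force) == nrow(moment), sample_rate > 0)
  n <- nrow(force)
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  structure(list(force = force, moment = moment,
                 plate_origin = as.numeric(plate_origin),
                 sample_rate = sample_rate, time = time),
            class = "force_plate_record")
}

#' One walking pass: markers + force plate + metadata
#'
#' @param subject a [subject_info()] record.
#' @param condition `"slow"`, `"comfortable"` or `"fast"`.
#' @param measured_speed gait speed of the pass, m/s.
#' @param markers a [marker_trajectories()] object.
#' @param forceplate a [force_plate_record()] object. Marker and force clocks
#'   share t = 0.
#' @export
gait_trial <- function(subject, condition, measured_speed, markers, forceplate) {
  condition <- match.arg(condition, c("slow", "comfortable", "fast"))
  stopifnot(inherits(markers, "marker_trajectories"),
            inherits(forceplate, "force_plate_record"))
  structure(list(subject = subject, condition = condition,
                 measured_speed = measured_speed, markers = markers,
                 forceplate = forceplate),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s (%s), %s condition, %.2f m/s\n",
              x$subject$subject_id, x$subject$age_group, x$condition,
              x$measured_speed))
  cat(sprintf("  markers: %d labels x %d samples @ %g Hz\n",
              length(x$markers$labels), dim(x$markers$positions)[1],
              x$markers$sample_rate))
  cat(sprintf("  forces:  %d samples @ %g Hz\n",
              nrow(x$forceplate$force), x$forceplate$sample_rate))
  invisible(x)
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, fill = FALSE,
                          colClasses = "numeric", na.strings = c("NA", "NaN", ""))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  df
}

#' Read a marker trajectory file
#'
#' Expects a tab- or comma-separated file with a header row of
#' `time, <label>_X, <label>_Y, <label>_Z, ...` columns. Missing samples
#' (`NA`/`NaN` cells) are flagged in the gap mask, never interpolated.
#'
#' @param path file path.
#' @param labels optional character vector of required marker names; an error
#'   listing the missing names is raised if any is absent from the header.
#' @param units `"m"` or `"mm"`; positions are converted to metres.
#' @param sample_rate sampling rate, Hz (default 150). Overridden by the time
#'   column spacing only for the returned `time` vector.
#' @return a [marker_trajectories()] object.
#' @export
read_marker_file <- function(path, labels = NULL, units = c("m", "mm"),
                             sample_rate = 150) {
  units <- match.arg(units)
  df <- read_delim_table(path)
  cols <- names(df)
  has_time <- cols[1] == "time"
  xyz <- grep("_(X|Y|Z)$", cols, value = TRUE)
  found <- unique(sub("_(X|Y|Z)$", "", xyz))
  if (!is.null(labels)) {
    missing <- setdiff(labels, found)
    if (length(missing))
      stop("marker file ", path, " is missing labels: ",
           paste(missing, collapse = ", "))
    found <- labels
  }
  n <- nrow(df)
  pos <- array(NA_real_, c(n, length(found), 3L))
  for (j in seq_along(found)) {
    for (k in 1:3) {
      cn <- paste0(found[j], "_", c("X", "Y", "Z")[k])
      if (!cn %in% cols) stop("marker file ", path, " lacks column ", cn)
      pos[, j, k] <- df[[cn]]
    }
  }
  if (units == "mm") pos <- pos / 1000
  time <- if (has_time) df$time else NULL
  marker_trajectories(pos, found, sample_rate, time = time)
}

#' Read a force-plate file
#'
#' Two dialects are supported. The moment dialect has columns
#' `time, Fx, Fy, Fz, Mx, My, Mz` with moments about the configured plate
#' origin. The COP dialect has `time, Fx, Fy, Fz, COPx, COPy` (optionally
#' `Tz` for the free moment); moments about the plate origin are then
#' reconstructed as `M = (cop - origin) x F + (0, 0, Tz)` with the COP given
#' relative to the plate origin in its surface plane.
#'
#' @param path file path.
#' @param plate_origin lab-frame position of the plate origin (a point in
#'   the plate surface plane), m.
#' @param sample_rate Hz (default 300).
#' @return a [force_plate_record()] object.
#' @export
read_force_file <- function(path, plate_origin = c(0, 0, 0), sample_rate = 300) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  df <- read_delim_table(path)
  cols <- names(df)
  need_f <- c("Fx", "Fy", "Fz")
  if (!all(need_f %in% cols))
    stop("force file ", path, " is missing channels: ",
         paste(setdiff(need_f, cols), collapse = ", "))
  force <- as.matrix(df[, need_f])
  if (all(c("Mx", "My", "Mz") %in% cols)) {
    moment <- as.matrix(df[, c("Mx", "My", "Mz")])
  } else if (all(c("COPx", "COPy") %in% cols)) {
    tz <- if ("Tz" %in% cols) df$Tz else 0
    cop_rel <- cbind(df$COPx, df$COPy, 0)
    moment <- row_cross(cop_rel, force) + cbind(0, 0, tz)
  } else {
    stop("force file ", path,
         " has neither Mx/My/Mz nor COPx/COPy channels")
  }
  time <- if ("time" %in% cols) df$time else NULL
  force_plate_record(force, moment, plate_origin, sample_rate, time = time)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a marker trajectory file (TSV)
#' @param markers a [marker_trajectories()] object.
#' @param path output path.
#' @export
write_marker_file <- function(markers, path) {
  df <- data.frame(time = markers$time, check.names = FALSE)
  for (j in seq_along(markers$labels)) {
    for (k in 1:3) {
      df[[paste0(markers$labels[j], "_", c("X", "Y", "Z")[k])]] <-
        markers$positions[, j, k]
    }
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a force-plate file (TSV, moment dialect)
#' @param record a [force_plate_record()] object.
#' @param path output path.
#' @export
write_force_file <- function(record, path) {
  df <- data.frame(time = record$time,
                   Fx = record$force[, 1], Fy = record$force[, 2],
                   Fz = record$force[, 3],
                   Mx = record$moment[, 1], My = record$moment[, 2],
                   Mz = record$moment[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a trial from the documented dataset layout
#'
#' Layout: `<root>/subjects.yaml` holds a list of subject records keyed by
#' `subject_id`; trial files live at
#' `<root>/<subject_id>/<condition>/trial<k>_{markers,forces,meta}.{tsv,yaml}`.
#' The meta sidecar supplies `measured_speed`, sampling rates, marker units
#' and the plate origin. Marker and force clocks are assumed to share t = 0;
#' a duration mismatch beyond `sync_tol` seconds raises a sync error.
#'
#' @param root dataset root directory.
#' @param subject_id subject identifier present in `subjects.yaml`.
#' @param condition speed condition.
#' @param trial trial number within the condition (default 1).
#' @param sync_tol tolerated marker/force duration mismatch, s.
#' @return a [gait_trial()] object.
#' @export
load_trial <- function(root, subject_id, condition, trial = 1, sync_tol = 0.02) {
  subs <- yaml::read_yaml(file.path(root, "subjects.yaml"))
  rec <- NULL
  for (s in subs) if (identical(as.character(s$subject_id), as.character(subject_id))) rec <- s
  if (is.null(rec)) stop("unknown subject_id '", subject_id, "' in ", root)
  subject <- subject_info(rec$subject_id, rec$age, rec$age_group, rec$height,
                          rec$mass, rec$leg_length %||% NA_real_,
                          rec$comfortable_speed %||% NA_real_)
  dir <- file.path(root, subject_id, condition)
  stem <- file.path(dir, sprintf("trial%02d", trial))
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  markers <- read_marker_file(paste0(stem, "_markers.tsv"),
                              units = meta$marker_units %||% "m",
                              sample_rate = meta$marker_rate %||% 150)
  forces <- read_force_file(paste0(stem, "_forces.tsv"),
                            plate_origin = unlist(meta$plate_origin %||% c(0, 0, 0)),
                            sample_rate = meta$force_rate %||% 300)
  d_m <- max(markers$time); d_f <- max(forces$time)
  if (abs(d_m - d_f) > sync_tol)
    stop(sprintf("marker/force duration mismatch (%.3f vs %.3f s) exceeds sync tolerance",
                 d_m, d_f))
  gait_trial(subject, condition, meta$measured_speed, markers, forces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
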
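## Waveform ingestion, breath segmentation, and per-PEEP-step summaries.
##
## Internal unit convention: time s, pressure cmH2O, volume L, flow L/s.
## CSV files declare their source units on a second header row; the reader
## converts on the way in and the writer always emits canonical units.

.canonical_units <- c(time = "s", pressure = "cmH2O", flow = "L/s")

## Conversion factors into canonical units, keyed by column then unit tag.
.unit_factors <- list(
  time     = c("s" = 1, "ms" = 1e-3, "min" = 60),
  pressure = c("cmH2O" = 1, "hPa" = 1.0197162129779283, "mbar" = 1.0197162129779283,
               "kPa" = 10.197162129779283),
  flow     = c("L/s" = 1, "mL/s" = 1e-3, "L/min" = 1 / 60, "mL/min" = 1e-3 / 60)
)

#' Read a ventilator waveform CSV
#'
#' Reads a continuous pressure--flow recording written in the package's
#' waveform dialect: one header row naming the columns `time`, `pressure`,
#' `flow`; one units row declaring the source units of each column; then
#' numeric samples. All series are converted to the internal units
#' (s, cmH2O, L/s) on reading.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named list overriding the units row, e.g.
#'   `list(flow = "mL/s")`. Entries here take precedence over the file's
#'   units row, for files whose embedded tags are known to be wrong.
#' @return A data frame with columns `time`, `pressure`, `flow` in internal
#'   units, of class `vent_series`.
#' @seealso [write_waveform_csv()], [segment_breaths()]
#' @export
read_waveform_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop("waveform file not found: ", path, call. = FALSE)
  }
  header <- utils::read.csv(path, nrows = 2, header = FALSE,
                            colClasses = "character", strip.white = TRUE)
  cols <- tolower(trimws(as.character(header[1, ])))
  required <- c("time", "pressure", "flow")
  missing <- setdiff(required, cols)
  if (length(missing) > 0) {
    stop("waveform file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- trimws(as.character(header[2, ]))
  names(units) <- cols
  ## second row must be a units row, not data
  if (suppressWarnings(!all(is.na(as.numeric(units[required]))))) {
    stop("waveform file ", path,
         " has no units row (second line must declare units, e.g. s,cmH2O,L/s)",
         call. = FALSE)
  }
  if (!is.null(dialect)) {
    for (nm in names(dialect)) units[[nm]] <- dialect[[nm]]
  }

  dat <- utils::read.csv(path, skip = 2, header = FALSE)
  names(dat) <- cols
  dat <- dat[required]

  for (col in required) {
    fac <- .unit_factors[[col]][units[[col]]]
    if (is.na(fac) || length(fac) == 0) {
      stop("unknown unit tag '", units[[col]], "' for column '", col,
           "' in ", path, call. = FALSE)
    }
    x <- dat[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      bad <- which(!is.finite(x))[1]
      stop("non-numeric or missing value in column '", col, "', data row ",
           if (is.na(bad)) "?" else bad, " of ", path, call. = FALSE)
    }
    dat[[col]] <- x * unname(fac)
  }
  if (any(dat$time < 0)) {
    stop("negative time value at data row ", which(dat$time < 0)[1],
         " of ", path, call. = FALSE)
  }
  dt <- diff(dat$time)
  if (any(dt <= 0)) {
    stop("non-monotone time at data row ", which(dt <= 0)[1] + 1,
         " of ", path, call. = FALSE)
  }
  class(dat) <- c("vent_series", "data.frame")
  dat
}

#' Write a ventilator waveform CSV
#'
#' Writes a series in the same dialect [read_waveform_csv()] reads, always
#' in canonical units (s, cmH2O, L/s). Numeric values are written with
#' enough digits that a read-back reproduces the series to better than six
#' significant digits.
#'
#' @param series Data frame with columns `time`, `pressure`, `flow` in
#'   internal units.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(series, path) {
  stopifnot(all(c("time", "pressure", "flow") %in% names(series)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("time,pressure,flow", "s,cmH2O,L/s"), con)
  lines <- sprintf("%.10g,%.10g,%.10g",
                   series$time, series$pressure, series$flow)
  writeLines(lines, con)
  invisible(path)
}

#' Construct a breath record
#'
#' A breath is one respiratory cycle: sampled time, airway pressure, flow,
#' and the running inspired volume (re-zeroed at inspiration onset), with
#' the end-inspiratory zero-flow sample marked. Volume is required to be
#' the trapezoidal running integral of flow.
#'
#' @param time Sample times, s, strictly increasing.
#' @param pressure Airway pressure, cmH2O.
#' @param flow Airway flow, L/s.
#' @param volume Inspired volume above onset, L; defaults to the trapezoidal
#'   integral of `flow`.
#' @param insp_end_index Index of the end-inspiratory zero-flow sample.
#' @param set_peep Ventilator PEEP setting, cmH2O.
#' @return An object of class `breath`.
#' @export
breath <- function(time, pressure, flow, volume = NULL,
                   insp_end_index = NULL, set_peep = NA_real_) {
  n <- length(time)
  if (is.null(volume)) volume <- pracma::cumtrapz(time, flow)[, 1]
  if (n < 8 || length(pressure) != n || length(flow) != n ||
      length(volume) != n) {
    stop("breath series must have equal length >= 8", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("breath time must be strictly increasing",
                                 call. = FALSE)
  if (abs(volume[1]) > 1e-9) stop("breath volume must start at zero",
                                  call. = FALSE)
  vint <- pracma::cumtrapz(time, flow)[, 1]
  tol <- 1e-6 + 1e-3 * max(abs(vint))
  if (max(abs(volume - vint)) > tol) {
    stop("breath volume is not the running integral of flow", call. = FALSE)
  }
  if (is.null(insp_end_index)) {
    insp_end_index <- detect_zero_flow(
      structure(list(time = time, pressure = pressure, flow = flow,
                     volume = volume, insp_end_index = n - 1L,
                     set_peep = set_peep), class = "breath"))$insp_end_index
  }
  insp_end_index <- as.integer(insp_end_index)
  if (insp_end_index <= 1L || insp_end_index >= n) {
    stop("insp_end_index must lie strictly inside the breath", call. = FALSE)
  }
  structure(list(time = time, pressure = pressure, flow = flow,
                 volume = volume, insp_end_index = insp_end_index,
                 set_peep = set_peep),
            class = "breath")
}

#' @export
print.breath <- function(x, ...) {
  cat(sprintf(
    "<breath> %d samples, %.2f s, Vt(insp) %.3f L, set PEEP %s cmH2O\n",
    length(x$time), diff(range(x$time)), x$volume[x$insp_end_index],
    format(x$set_peep)))
  invisible(x)
}

#' Segment a continuous recording into breaths
#'
#' Splits a validated series at inspiration onsets, defined as
#' negative-to-positive zero crossings of flow. The volume channel of each
#' breath is re-zeroed at its onset. Fragments shorter than
#' `min_breath_duration` are discarded, as are the leading partial cycle
#' before the first onset and the trailing partial cycle when it contains
#' no expiration.
#'
#' @param series A `vent_series` (or data frame with `time`, `pressure`,
#'   `flow` in internal units).
#' @param min_breath_duration Minimum breath length to keep, s.
#' @param set_peep PEEP setting attached to each breath, cmH2O.
#' @return A list of [breath()] objects.
#' @export
segment_breaths <- function(series, min_breath_duration = 1, set_peep = NA_real_) {
  flow <- series$flow
  n <- length(flow)
  ## onset = first sample of a positive run that follows a non-positive sample
  onsets <- which(flow[-1] > 0 & flow[-n] <= 0) + 1L
  if (length(onsets) == 0) {
    stop("no inspiration onset (negative-to-positive flow crossing) found",
         call. = FALSE)
  }
  bounds <- c(onsets, n + 1L)
  out <- list()
  for (k in seq_along(onsets)) {
    idx <- bounds[k]:(bounds[k + 1L] - 1L)
    if (length(idx) < 8) next
    if (series$time[idx[length(idx)]] - series$time[idx[1]] <
        min_breath_duration) next
    if (all(flow[idx] >= 0) && k == length(onsets)) next  # trailing partial
    out[[length(out) + 1L]] <- breath(
      time = series$time[idx], pressure = series$pressure[idx],
      flow = flow[idx], set_peep = set_peep)
  }
  if (length(out) == 0) {
    stop("no breath longer than min_breath_duration found", call. = FALSE)
  }
  out
}

#' Locate end-inspiratory and end-expiratory zero-flow samples
#'
#' End-inspiratory zero flow is the last sample of the inspiratory phase
#' with `|flow| <= flow_tolerance` (the fall through zero after the
#' inspiratory pause); end-expiratory zero flow is the analogous sample at
#' the end of the breath. When no sample of a phase is inside tolerance the
#' sample of minimum `|flow|` in that phase is returned with a warning:
#' plateau pressures read there are then approximations.
#'
#' @param breath A [breath()] object (the stored `insp_end_index` is
#'   ignored; indices are recomputed).
#' @param flow_tolerance Magnitude below which flow counts as zero, L/s.
#' @return List with `insp_end_index` and `exp_end_index`.
#' @export
detect_zero_flow <- function(breath, flow_tolerance = 0.005) {
  flow <- breath$flow
  n <- length(flow)
  ## inspiratory phase: up to the last sample before flow turns negative
  first_neg <- which(flow < -flow_tolerance)[1]
  if (is.na(first_neg)) {
    warning("breath has no expiratory flow beyond tolerance; ",
            "phase boundaries are degenerate", call. = FALSE)
  }
  insp_last <- if (is.na(first_neg)) n else first_neg - 1L
  insp_idx <- seq_len(max(insp_last, 1L))
  in_tol <- which(abs(flow[insp_idx]) <= flow_tolerance)
  if (length(in_tol) > 0) {
    insp_end <- max(in_tol)
  } else {
    insp_end <- insp_idx[which.min(abs(flow[insp_idx]))]
    warning("no inspiratory sample within flow tolerance; using minimum-|flow| sample",
            call. = FALSE)
  }
  ## expiratory phase: from end of inspiration to breath end
  exp_idx <- seq.int(min(insp_last + 1L, n), n)
  in_tol_e <- exp_idx[abs(flow[exp_idx]) <= flow_tolerance]
  if (length(in_tol_e) > 0) {
    exp_end <- max(in_tol_e)
  } else {
    exp_end <- exp_idx[which.min(abs(flow[exp_idx]))]
    warning("no expiratory sample within flow tolerance; using minimum-|flow| sample",
            call. = FALSE)
  }
  list(insp_end_index = as.integer(insp_end),
       exp_end_index = as.integer(exp_end))
}

## Plateau read: mean pressure over the contiguous zero-flow window around
## the detected index (noise on a single sample would otherwise propagate
## straight into the plateau).
.plateau_read <- function(b, idx, flow_tolerance) {
  lo <- idx
  while (lo > 1 && abs(b$flow[lo - 1]) <= flow_tolerance) lo <- lo - 1
  mean(b$pressure[lo:idx])
}

#' Summarise breaths at one PEEP setting
#'
#' Aggregates one or more breaths recorded at a single PEEP setting into a
#' PEEP-step record. Plateau pressure is the median over breaths of airway
#' pressure averaged across the end-inspiratory zero-flow window; PEEP is
#' the corresponding read at end-expiratory zero flow (both are plateau
#' pressures, read where the resistive term vanishes); tidal volume is the
#' median trapezoidal integral of inspiratory flow. The inspiratory
#' driving pressure `delta_paw` is `plateau_pressure - peep`.
#'
#' @param breaths List of [breath()] objects.
#' @param set_peep Ventilator PEEP setting, cmH2O (carried as metadata).
#' @param measured_dfrc Optional clinically measured dFRC at this PEEP, L.
#' @param flow_tolerance Zero-flow tolerance passed to [detect_zero_flow()].
#' @return An object of class `peep_step` with fields `peep`,
#'   `plateau_pressure`, `tidal_volume`, `delta_paw`, `measured_dfrc`,
#'   `set_peep`, `breaths`.
#' @export
summarize_step <- function(breaths, set_peep = NA_real_,
                           measured_dfrc = NULL, flow_tolerance = 0.005) {
  stopifnot(length(breaths) >= 1)
  plateau <- numeric(length(breaths))
  peep <- numeric(length(breaths))
  vt <- numeric(length(breaths))
  for (i in seq_along(breaths)) {
    b <- breaths[[i]]
    zf <- detect_zero_flow(b, flow_tolerance)
    plateau[i] <- .plateau_read(b, zf$insp_end_index, flow_tolerance)
    peep[i] <- .plateau_read(b, zf$exp_end_index, flow_tolerance)
    insp <- seq_len(zf$insp_end_index)
    vt[i] <- pracma::trapz(b$time[insp], b$flow[insp])
  }
  step <- list(peep = stats::median(peep),
               plateau_pressure = stats::median(plateau),
               tidal_volume = stats::median(vt),
               delta_paw = stats::median(plateau) - stats::median(peep),
               measured_dfrc = if (is.null(measured_dfrc)) NA_real_
                               else measured_dfrc,
               set_peep = set_peep,
               breaths = breaths)
  if (step$plateau_pressure <= step$peep) {
    stop("inconsistent step: plateau pressure (", signif(step$plateau_pressure, 4),
         ") not above PEEP (", signif(step$peep, 4), ")", call. = FALSE)
  }
  if (step$tidal_volume <= 0) {
    stop("inconsistent step: non-positive tidal volume", call. = FALSE)
  }
  if (!is.na(step$measured_dfrc) && step$measured_dfrc < 0) {
    stop("measured dFRC must be non-negative", call. = FALSE)
  }
  class(step) <- "peep_step"
  step
}

#' @export
print.peep_step <- function(x, ...) {
  cat(sprintf(
    "<peep_step> PEEP %.1f, plateau %.1f, dPaw %.1f cmH2O; Vt %.3f L; %d breath(s)%s\n",
    x$peep, x$plateau_pressure, x$delta_paw, x$tidal_volume,
    length(x$breaths),
    if (is.na(x$measured_dfrc)) "" else
      sprintf("; measured dFRC %.3f L", x$measured_dfrc)))
  invisible(x)
}

#' Assemble a patient dataset from PEEP steps
#'
#' Orders steps by PEEP and validates the stepwise-PEEP structure (strictly
#' increasing, no duplicates). Consecutive-step dFRC differences are
#' computed where both steps carry a measured dFRC.
#'
#' @param steps List of `peep_step` objects.
#' @param patient_id,cohort Opaque labels.
#' @return An object of class `patient_dataset`.
#' @export
patient_dataset <- function(steps, patient_id = "patient", cohort = NA_character_) {
  stopifnot(length(steps) >= 1)
  peeps <- vapply(steps, .step_key, numeric(1))
  steps <- steps[order(peeps)]
  peeps <- sort(peeps)
  if (any(diff(peeps) <= 0)) {
    stop("PEEP levels must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  dfrc <- vapply(steps, function(s) s$measured_dfrc, numeric(1))
  ddfrc <- rep(NA_real_, length(steps))
  if (length(steps) > 1) {
    for (k in 2:length(steps)) {
      if (!is.na(dfrc[k]) && !is.na(dfrc[k - 1])) {
        ddfrc[k] <- dfrc[k] - dfrc[k - 1]
      }
    }
  }
  structure(list(patient_id = patient_id, cohort = cohort, steps = steps,
                 measured_delta_dfrc = ddfrc),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  peeps <- vapply(x$steps, function(s) s$peep, numeric(1))
  cat(sprintf("<patient_dataset> %s (cohort %s): %d PEEP step(s) at %s cmH2O\n",
              x$patient_id, format(x$cohort), length(x$steps),
              paste(sprintf("%.1f", peeps), collapse = ", ")))
  invisible(x)
}

## Per-step accessors used throughout the package.
##
## PEEP *levels* (the keys that group steps across patients for
## calibration and lookup) are the nominal set PEEPs when known, falling
## back to the measured end-expiratory plateau: the set value is the
## controlled protocol variable, while the measured plateau carries
## patient-specific offsets (intrinsic PEEP, sensor noise) that would
## splinter population grouping.
.step_key <- function(s) {
  if (!is.na(s$set_peep)) s$set_peep else s$peep
}
step_peeps <- function(patient) {
  vapply(patient$steps, .step_key, numeric(1))
}
step_dfrc <- function(patient) {
  vapply(patient$steps, function(s) s$measured_dfrc, numeric(1))
}

#' Read a patient manifest
#'
#' A manifest is a YAML file describing one patient's stepwise-PEEP
#' recordings: `patient_id`, `cohort`, and a list of `steps`, each with
#' `peep` (the set PEEP, cmH2O), `file` (waveform CSV path relative to the
#' manifest), and optionally `measured_dfrc` (L). Waveforms are read,
#' segmented into breaths and summarised into PEEP steps.
#'
#' @param path Manifest path.
#' @param min_breath_duration,flow_tolerance Passed to the segmentation and
#'   zero-flow detection stages.
#' @return A [patient_dataset()].
#' @export
read_manifest <- function(path, min_breath_duration = 1, flow_tolerance = 0.005) {
  man <- yaml::read_yaml(path)
  if (is.null(man$steps) || length(man$steps) == 0) {
    stop("manifest has no steps: ", path, call. = FALSE)
  }
  base <- dirname(path)
  steps <- lapply(man$steps, function(st) {
    f <- st$file
    if (!file.exists(f)) f <- file.path(base, st$file)
    series <- read_waveform_csv(f)
    brs <- segment_breaths(series, min_breath_duration, set_peep = st$peep)
    summarize_step(brs, set_peep = st$peep,
                   measured_dfrc = st$measured_dfrc,
                   flow_tolerance = flow_tolerance)
  })
  patient_dataset(steps,
                  patient_id = if (is.null(man$patient_id)) "patient" else man$patient_id,
                  cohort = if (is.null(man$cohort)) NA_character_ else man$cohort)
}
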
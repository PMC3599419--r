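## Population-constant calibration for the stress-strain dFRC estimators.
##
## Both stress-strain methods fold the specific lung elastance, the
## lung/chest-wall elastance ratio and the PEEP-dependent scaling into a
## single per-PEEP constant, assumed common across patients:
##   multiple-breath:  dFRC = (ddFRC/dPEEP) * beta       [beta: cmH2O]
##   single-breath:    dFRC = (Vt/dPaw) * beta, beta1 = beta/Vt
##                                                  [beta1: cmH2O/L]
## Calibration solves these identities for each patient and PEEP on a
## cohort with measured dFRC, then stores the per-PEEP median across
## patients as the population constant, with min/max/IQR dispersion.

#' Construct a beta table
#'
#' @param method `"SSMB"` (per-PEEP `beta`, cmH2O) or `"SSSB"` (per-PEEP
#'   `beta1`, cmH2O/L).
#' @param table Data frame with columns `peep`, `median_value`,
#'   `n_patients`, `min`, `max`, `iqr`.
#' @param provenance Free-text provenance (cohort labels etc.).
#' @return An object of class `beta_table`.
#' @export
beta_table <- function(method = c("SSMB", "SSSB"), table, provenance = "") {
  method <- match.arg(method)
  req <- c("peep", "median_value", "n_patients", "min", "max", "iqr")
  stopifnot(all(req %in% names(table)))
  table <- table[order(table$peep), req]
  rownames(table) <- NULL
  if (nrow(table) == 0) stop("beta table has no PEEP levels", call. = FALSE)
  if (anyDuplicated(table$peep)) stop("duplicate PEEP levels in beta table",
                                      call. = FALSE)
  with(table, stopifnot(all(min <= median_value + 1e-12),
                        all(median_value <= max + 1e-12),
                        all(n_patients >= 1)))
  structure(list(method = method, table = table,
                 units = if (method == "SSMB") "cmH2O" else "cmH2O/L",
                 provenance = provenance),
            class = "beta_table")
}

#' @export
print.beta_table <- function(x, ...) {
  cat(sprintf("<beta_table %s> %s per PEEP [%s]\n", x$method,
              if (x$method == "SSMB") "beta" else "beta1", x$units))
  print(x$table, row.names = FALSE)
  invisible(x)
}

## Per-patient, per-PEEP constants underlying both calibrations.
## pairing = "consecutive": ddFRC/dPEEP over the immediately preceding step
## (matches a stepwise PEEP-increase protocol); "baseline": first step as
## the common reference, for sensitivity analysis.
.ssmb_patient_betas <- function(patient, pairing = c("consecutive", "baseline")) {
  pairing <- match.arg(pairing)
  peeps <- step_peeps(patient)
  dfrc <- step_dfrc(patient)
  out <- data.frame(peep = numeric(0), beta = numeric(0))
  if (length(peeps) < 2) return(out)
  for (k in 2:length(peeps)) {
    ref <- if (pairing == "consecutive") k - 1L else 1L
    if (is.na(dfrc[k]) || is.na(dfrc[ref])) next
    ddfrc <- dfrc[k] - dfrc[ref]
    dpeep <- peeps[k] - peeps[ref]
    if (abs(ddfrc) < .Machine$double.eps * 100) {
      warning("zero dFRC change for patient ", patient$patient_id,
              " at PEEP ", peeps[k], "; pair excluded from calibration",
              call. = FALSE)
      next
    }
    out <- rbind(out, data.frame(peep = peeps[k],
                                 beta = dfrc[k] * dpeep / ddfrc))
  }
  out
}

## PEEP levels are grouped at 1e-6 cmH2O resolution: waveform-derived
## plateau pressures carry floating-point jitter far below any clinical
## resolution, and exact-equality grouping would splinter levels.
.round_peep <- function(p) round(p, 6)

.dispersion_table <- function(values_by_peep) {
  values_by_peep$peep <- .round_peep(values_by_peep$peep)
  peeps <- sort(unique(values_by_peep$peep))
  rows <- lapply(peeps, function(p) {
    v <- values_by_peep$value[values_by_peep$peep == p]
    data.frame(peep = p, median_value = stats::median(v),
               n_patients = length(v), min = min(v), max = max(v),
               iqr = stats::IQR(v))
  })
  do.call(rbind, rows)
}

#' Calibrate the multiple-breath population constant
#'
#' For each patient and each PEEP level above that patient's first, solves
#' the multiple-breath identity for `beta`:
#' `beta = dFRC(PEEP) * dPEEP / ddFRC`, where `ddFRC` and `dPEEP` are the
#' changes from the immediately preceding PEEP step. The per-PEEP median
#' across patients is the population constant. A patient's lowest PEEP
#' step has no preceding step and cannot contribute; that PEEP level is
#' calibrated by the other patients or absent from the table.
#'
#' @param cohort List of [patient_dataset()] objects, each with measured
#'   dFRC at two or more PEEP steps.
#' @param pairing `"consecutive"` (default) or `"baseline"` step pairing.
#' @return A [beta_table()] with `method = "SSMB"`.
#' @export
calibrate_beta_ssmb <- function(cohort, pairing = c("consecutive", "baseline")) {
  pairing <- match.arg(pairing)
  rows <- list()
  for (p in cohort) {
    b <- .ssmb_patient_betas(p, pairing)
    if (nrow(b) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(peep = b$peep, value = b$beta)
    }
  }
  if (length(rows) == 0) {
    stop("no patient contributes a calibratable PEEP step ",
         "(need measured dFRC at >= 2 PEEP levels)", call. = FALSE)
  }
  tab <- .dispersion_table(do.call(rbind, rows))
  beta_table("SSMB", tab,
             provenance = sprintf("calibrated from %d patient(s), %s pairing",
                                  length(cohort), pairing))
}

#' Calibrate the single-breath population constant
#'
#' For each patient step with measured dFRC, solves the single-breath
#' identity for `beta = dFRC * dPaw / Vt`, then normalises by tidal volume
#' (`beta1 = beta / Vt`) because the raw constant scales with the applied
#' tidal volume. The per-PEEP median of `beta1` across patients is stored.
#'
#' @param cohort List of [patient_dataset()] objects.
#' @return A [beta_table()] with `method = "SSSB"`.
#' @export
calibrate_beta1_sssb <- function(cohort) {
  rows <- list()
  for (p in cohort) {
    for (s in p$steps) {
      if (is.na(s$measured_dfrc)) next
      if (s$delta_paw <= 0 || s$tidal_volume <= 0) {
        warning("degenerate step (dPaw or Vt non-positive) for patient ",
                p$patient_id, " at PEEP ", s$peep, "; excluded",
                call. = FALSE)
        next
      }
      beta <- s$measured_dfrc * s$delta_paw / s$tidal_volume
      rows[[length(rows) + 1L]] <-
        data.frame(peep = .step_key(s), value = beta / s$tidal_volume)
    }
  }
  if (length(rows) == 0) {
    stop("no step with measured dFRC available for calibration",
         call. = FALSE)
  }
  tab <- .dispersion_table(do.call(rbind, rows))
  beta_table("SSSB", tab,
             provenance = sprintf("calibrated from %d patient(s)",
                                  length(cohort)))
}

#' Look up a population constant at a PEEP level
#'
#' Exact calibrated PEEPs return the stored median; PEEPs inside the
#' calibrated range are linearly interpolated between the bracketing
#' levels; outside the range the `policy` decides: `"refuse"` (default)
#' raises an error naming the calibrated span, `"clamp"` returns the
#' nearest calibrated value with a warning.
#'
#' @param table A [beta_table()].
#' @param peep Query PEEP, cmH2O.
#' @param policy Out-of-range policy, `"refuse"` or `"clamp"`.
#' @return The constant in table units (cmH2O for SSMB, cmH2O/L for SSSB).
#' @export
lookup_beta <- function(table, peep, policy = c("refuse", "clamp")) {
  policy <- match.arg(policy)
  tab <- table$table
  ## snap to a calibrated level within grouping resolution
  nearest <- which.min(abs(tab$peep - peep))
  if (abs(tab$peep[nearest] - peep) < 1e-6) {
    return(tab$median_value[nearest])
  }
  if (peep < min(tab$peep) || peep > max(tab$peep)) {
    if (policy == "refuse") {
      stop(sprintf("PEEP %.3g cmH2O outside calibrated range [%.3g, %.3g]",
                   peep, min(tab$peep), max(tab$peep)), call. = FALSE)
    }
    warning(sprintf("PEEP %.3g outside calibrated range; clamping to nearest",
                    peep), call. = FALSE)
    return(tab$median_value[which.min(abs(tab$peep - peep))])
  }
  stats::approx(tab$peep, tab$median_value, xout = peep, rule = 1)$y
}

#' Leave-one-out calibration and estimation
#'
#' Guards against the in-sample optimism of calibrating and evaluating
#' population medians on the same cohort: each patient's dFRC is estimated
#' with a table calibrated on the remaining patients only.
#'
#' @param cohort List of [patient_dataset()] objects (at least 3).
#' @param method `"SSMB"` or `"SSSB"`.
#' @param policy Beta lookup policy forwarded to the estimators.
#' @return Data frame of pairs (`patient_id`, `peep`, `measured`,
#'   `estimated`), suitable for [compute_agreement()].
#' @export
loo_evaluate <- function(cohort, method = c("SSMB", "SSSB"),
                         policy = c("refuse", "clamp")) {
  method <- match.arg(method)
  policy <- match.arg(policy)
  if (length(cohort) < 3) stop("leave-one-out needs >= 3 patients",
                               call. = FALSE)
  rows <- list()
  for (i in seq_along(cohort)) {
    rest <- cohort[-i]
    tab <- if (method == "SSMB") calibrate_beta_ssmb(rest)
           else calibrate_beta1_sssb(rest)
    rows[[i]] <- .estimate_patient_pairs(cohort[[i]], tab, method, policy)
  }
  do.call(rbind, rows)
}

## Shared pair-builder: estimates every eligible step of one patient with
## one table; returns measured/estimated pairs.
.estimate_patient_pairs <- function(patient, table, method, policy = "refuse") {
  peeps <- step_peeps(patient)
  dfrc <- step_dfrc(patient)
  rows <- list()
  for (k in seq_along(peeps)) {
    est <- tryCatch({
      if (method == "SSMB") {
        if (k == 1) NULL
        else estimate_ssmb(patient, table, peeps[k], policy = policy)
      } else {
        estimate_sssb(patient$steps[[k]], table, policy = policy)
      }
    }, error = function(e) NULL)
    if (is.null(est) || is.na(dfrc[k])) next
    rows[[length(rows) + 1L]] <-
      data.frame(patient_id = patient$patient_id, peep = peeps[k],
                 measured = dfrc[k], estimated = est$value)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Write a beta table to a structured text file
#'
#' Header lines (`#key: value`) carry the method, units and provenance;
#' the body is tab-separated with full-precision numbers, so a read-back
#' with [read_beta_table()] is bit-exact.
#'
#' @param table A [beta_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#method: ", table$method),
    paste0("#units: ", table$units),
    paste0("#provenance: ", table$provenance),
    "peep\tmedian_value\tn_patients\tmin\tmax\tiqr"), con)
  t <- table$table
  writeLines(sprintf("%.17g\t%.17g\t%d\t%.17g\t%.17g\t%.17g",
                     t$peep, t$median_value, as.integer(t$n_patients),
                     t$min, t$max, t$iqr), con)
  invisible(path)
}

#' Read a beta table written by [write_beta_table()]
#'
#' @param path File path.
#' @return A [beta_table()].
#' @export
read_beta_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) stop("beta table file missing header '", key, "'",
                             call. = FALSE)
    sub(paste0("^#", key, ": "), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"))
  for (col in c("peep", "median_value", "min", "max", "iqr")) {
    tab[[col]] <- as.double(tab[[col]])
  }
  tab$n_patients <- as.integer(tab$n_patients)
  beta_table(get("method"), tab, provenance = get("provenance"))
}
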
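## The four dFRC estimators.
##
##   SSMB  dFRC = (ddFRC/dPEEP) * beta(PEEP)      needs >= 2 PEEP steps
##   SSSB  dFRC = (Vt/dPaw) * beta,  beta = beta1(PEEP) * Vt
##   SCSB  V_Po = PEEP / Ers                      no population constant
##   CM    SSSB while one PEEP level is known, SSMB once two are
##
## SSSB's output is the single-breath stress-strain volume at the step's
## PEEP and is reported as the dFRC estimate there; SCSB's output is the
## PEEP-induced volume V_Po, a dFRC proxy proportional to (not equal to)
## dFRC, reported unscaled.

LOW_PEEP_CAUTION <- 5  # cmH2O; estimates below this carry large errors

.dfrc_estimate <- function(method, peep, value, beta_applied = NULL,
                           inputs_used = list(), flags = character(0)) {
  if (peep < LOW_PEEP_CAUTION) flags <- c(flags, "low_peep")
  if (is.na(value) || value < 0) flags <- c(flags, "negative_value")
  structure(list(method = method, peep = peep, value = value,
                 beta_applied = beta_applied, inputs_used = inputs_used,
                 flags = unique(flags)),
            class = "dfrc_estimate")
}

#' @export
print.dfrc_estimate <- function(x, ...) {
  cat(sprintf("<dfrc_estimate %s> %.4g L at PEEP %.1f cmH2O%s%s\n",
              x$method, x$value, x$peep,
              if (is.null(x$beta_applied)) "" else
                sprintf(" (beta %.4g %s)", x$beta_applied$value,
                        x$beta_applied$units),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Multiple-breath stress-strain dFRC estimate
#'
#' Estimates dFRC at `target_peep` as the patient's volume responsiveness
#' over the step ending there — measured dFRC change divided by PEEP
#' change from the immediately preceding step — scaled by the population
#' constant `beta` at that PEEP.
#'
#' @param patient A [patient_dataset()] with measured dFRC at the target
#'   step and the one before it.
#' @param table A [beta_table()] with `method = "SSMB"`.
#' @param target_peep PEEP at which to estimate, cmH2O; must be one of the
#'   patient's step PEEPs (not the first).
#' @param policy Beta lookup policy, see [lookup_beta()].
#' @return A `dfrc_estimate`.
#' @export
estimate_ssmb <- function(patient, table, target_peep,
                          policy = c("refuse", "clamp")) {
  policy <- match.arg(policy)
  if (table$method != "SSMB") stop("table method must be SSMB", call. = FALSE)
  peeps <- step_peeps(patient)
  k <- which(abs(peeps - target_peep) < 1e-9)
  if (length(k) != 1 || k == 1) {
    stop("insufficient data for the multiple-breath method at PEEP ",
         target_peep, ": need a measured step at this PEEP with a ",
         "preceding step (consider the single-breath or combined method)",
         call. = FALSE)
  }
  dfrc <- step_dfrc(patient)
  if (is.na(dfrc[k]) || is.na(dfrc[k - 1])) {
    stop("insufficient data: measured dFRC required at PEEP ",
         peeps[k - 1], " and ", peeps[k],
         " (consider the single-breath or combined method)", call. = FALSE)
  }
  responsiveness <- (dfrc[k] - dfrc[k - 1]) / (peeps[k] - peeps[k - 1])
  beta <- lookup_beta(table, target_peep, policy)
  .dfrc_estimate("SSMB", target_peep, responsiveness * beta,
                 beta_applied = list(value = beta, units = "cmH2O"),
                 inputs_used = list(responsiveness = responsiveness))
}

#' Single-breath stress-strain dFRC estimate
#'
#' Estimates dFRC at a single PEEP step from that step's inspiratory
#' compliance `Vt/dPaw` and the tidal-volume-normalised population
#' constant: `dFRC = beta1(PEEP) * Vt^2 / dPaw`.
#'
#' @param step A `peep_step` with `tidal_volume` and `delta_paw`.
#' @param table A [beta_table()] with `method = "SSSB"`.
#' @param policy Beta lookup policy, see [lookup_beta()].
#' @return A `dfrc_estimate`.
#' @export
estimate_sssb <- function(step, table, policy = c("refuse", "clamp")) {
  policy <- match.arg(policy)
  if (table$method != "SSSB") stop("table method must be SSSB", call. = FALSE)
  if (is.na(step$delta_paw) || step$delta_paw <= 0) {
    stop("invalid step: inspiratory driving pressure must be positive",
         call. = FALSE)
  }
  key <- .step_key(step)
  beta1 <- lookup_beta(table, key, policy)
  beta <- beta1 * step$tidal_volume
  .dfrc_estimate("SSSB", key,
                 (step$tidal_volume / step$delta_paw) * beta,
                 beta_applied = list(value = beta1, units = "cmH2O/L"),
                 inputs_used = list(compliance = step$tidal_volume / step$delta_paw,
                                    tidal_volume = step$tidal_volume))
}

#' Single-compartment dFRC proxy from fitted elastance
#'
#' Under the single-compartment model, the set PEEP inflates the lung by
#' `V_Po = PEEP / Ers` above its zero-PEEP resting volume; `V_Po` is
#' proportional to dFRC and needs no population constant. Elastance comes
#' from the integral-based fit of the breath's inspiratory portion.
#'
#' @param breath A [breath()] object.
#' @param set_peep PEEP at which to evaluate, cmH2O; defaults to the
#'   breath's own setting.
#' @return A `dfrc_estimate` whose `value` is `V_Po` (L).
#' @export
estimate_scsb <- function(breath, set_peep = breath$set_peep) {
  if (is.na(set_peep)) stop("set PEEP required", call. = FALSE)
  fit <- fit_single_compartment(breath, "free")
  if (fit$flagged) {
    stop("single-compartment fit is non-physiological (Ers = ",
         signif(fit$ers, 4), ", Rrs = ", signif(fit$rrs, 4),
         "); refusing to estimate", call. = FALSE)
  }
  .dfrc_estimate("SCSB", set_peep, set_peep / fit$ers,
                 inputs_used = list(ers = fit$ers, fit = fit))
}

#' Combined real-time dFRC estimate
#'
#' The combined method follows the data available so far in a stepwise
#' PEEP protocol: with a single PEEP level it is exactly the single-breath
#' stress-strain estimate; once measured dFRC is available at two or more
#' levels it converts to the multiple-breath estimate and stays there.
#' There is no blending — the returned estimate is bit-identical to the
#' delegated method's, with the branch recorded.
#'
#' @param patient_so_far A [patient_dataset()] holding the steps observed
#'   so far.
#' @param ssmb_table,sssb_table Calibrated [beta_table()]s for the two
#'   delegated methods.
#' @param target_peep PEEP at which to estimate, cmH2O; defaults to the
#'   highest observed.
#' @param policy Beta lookup policy.
#' @return A `dfrc_estimate` with `method = "CM"` and a `branch` field
#'   naming the delegated method.
#' @export
estimate_cm <- function(patient_so_far, ssmb_table, sssb_table,
                        target_peep = NULL, policy = c("refuse", "clamp")) {
  policy <- match.arg(policy)
  peeps <- step_peeps(patient_so_far)
  dfrc <- step_dfrc(patient_so_far)
  if (is.null(target_peep)) target_peep <- max(peeps)
  k <- which(abs(peeps - target_peep) < 1e-9)
  ssmb_ready <- length(k) == 1 && k > 1 &&
    !is.na(dfrc[k]) && !is.na(dfrc[k - 1])
  est <- if (ssmb_ready) {
    estimate_ssmb(patient_so_far, ssmb_table, target_peep, policy)
  } else {
    if (length(k) != 1) stop("no observed step at PEEP ", target_peep,
                             call. = FALSE)
    estimate_sssb(patient_so_far$steps[[k]], sssb_table, policy)
  }
  est$branch <- est$method
  est$method <- "CM"
  est
}
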
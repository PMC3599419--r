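## Integral-based identification of the single-compartment equation of
## motion, Paw(t) = Ers*V(t) + Rrs*Q(t) + Po, over the inspiratory portion
## of a breath.
##
## Both sides are integrated cumulatively from inspiration onset, which
## turns the pointwise relation into a regression on smooth cumulative
## integrals: int P dt = Ers*int V dt + Rrs*int Q dt + Po*t. Integration
## acts as a low-pass filter, so the least-squares solution is far less
## sensitive to sample-level pressure noise than a direct fit.

#' Fit the single-compartment lung model to a breath
#'
#' Estimates respiratory elastance `Ers` (cmH2O/L), resistance `Rrs`
#' (cmH2O.s/L) and offset pressure `Po` (cmH2O; set PEEP plus any
#' intrinsic PEEP) from the inspiratory portion of a breath, by linear
#' least squares on cumulative trapezoidal integrals of the equation of
#' motion. In `"fixed"` intercept mode `Po` is pinned to the ventilator's
#' set PEEP and only `Ers` and `Rrs` are estimated; this is the form in
#' which the PEEP-induced volume `V_Po = PEEP/Ers` is absorbed into the
#' volume axis.
#'
#' @param breath A [breath()] object.
#' @param intercept_mode `"free"` (estimate `Po`) or `"fixed"` (pin `Po`
#'   to `breath$set_peep`).
#' @param condition_threshold Condition number of the regressor matrix
#'   above which the breath is declared unidentifiable.
#' @return An object of class `sc_fit` with fields `ers`, `rrs`, `po`,
#'   `rms_residual` (pressure space, cmH2O), `n_samples`,
#'   `intercept_mode`, and `flagged` (TRUE when a fitted parameter is
#'   non-physiological: `ers <= 0` or `rrs < 0`).
#' @export
fit_single_compartment <- function(breath, intercept_mode = c("free", "fixed"),
                                   condition_threshold = 1e8) {
  intercept_mode <- match.arg(intercept_mode)
  insp <- seq_len(breath$insp_end_index)
  if (length(insp) < 8) {
    stop("inspiratory portion too short to fit (need >= 8 samples)",
         call. = FALSE)
  }
  t <- breath$time[insp] - breath$time[1]
  P <- breath$pressure[insp]
  V <- breath$volume[insp]
  Q <- breath$flow[insp]
  if (max(abs(V)) <= 0 || max(abs(Q)) <= 0) {
    stop("degenerate inspiratory portion: volume or flow identically zero",
         call. = FALSE)
  }

  iP <- pracma::cumtrapz(t, P)[, 1]
  iV <- pracma::cumtrapz(t, V)[, 1]
  iQ <- pracma::cumtrapz(t, Q)[, 1]

  if (intercept_mode == "free") {
    X <- cbind(iV, iQ, t)
    y <- iP
  } else {
    po_fixed <- breath$set_peep
    if (is.na(po_fixed)) {
      stop("fixed intercept mode requires a set PEEP on the breath",
           call. = FALSE)
    }
    X <- cbind(iV, iQ)
    y <- iP - po_fixed * t
  }
  ## drop the all-zero first row (integrals start at 0)
  X <- X[-1, , drop = FALSE]
  y <- y[-1]

  ## column-scaled condition number: collinearity of regressor shapes
  sc <- apply(X, 2, function(col) max(abs(col)))
  kappa_val <- kappa(sweep(X, 2, sc, "/"), exact = TRUE)
  if (!is.finite(kappa_val) || kappa_val > condition_threshold) {
    stop("unidentifiable breath: cumulative-integral regressors are ",
         "collinear (condition number ", format(kappa_val, digits = 3), ")",
         call. = FALSE)
  }

  coefs <- qr.coef(qr(X), y)
  ers <- coefs[[1]]
  rrs <- coefs[[2]]
  po <- if (intercept_mode == "free") coefs[[3]] else breath$set_peep

  resid_p <- P - (ers * V + rrs * Q + po)
  fit <- structure(list(
    ers = ers, rrs = rrs, po = po,
    rms_residual = sqrt(mean(resid_p^2)),
    n_samples = length(insp),
    intercept_mode = intercept_mode,
    flagged = (ers <= 0 || rrs < 0)),
    class = "sc_fit")
  if (fit$flagged) {
    warning("non-physiological fit (Ers = ", signif(ers, 4), ", Rrs = ",
            signif(rrs, 4), "); fit flagged", call. = FALSE)
  }
  fit
}

#' @export
print.sc_fit <- function(x, ...) {
  cat(sprintf(
    "<sc_fit %s> Ers %.3f cmH2O/L, Rrs %.3f cmH2O.s/L, Po %.3f cmH2O; RMS %.4f cmH2O over %d samples%s\n",
    x$intercept_mode, x$ers, x$rrs, x$po, x$rms_residual, x$n_samples,
    if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Compare elastance under free and PEEP-pinned intercepts
#'
#' Fits the same breath with the offset pressure free and with it pinned
#' to the set PEEP, returning both elastances. When intrinsic PEEP is zero
#' the two models coincide and the elastances agree; auto-PEEP (true
#' offset above set PEEP) forces the pinned fit to absorb the unmodelled
#' offset into its slope terms, separating the pair. The scatter of the
#' two elastances over a cohort is the standard diagnostic for this
#' assumption.
#'
#' @param breath A [breath()] object.
#' @param set_peep Set PEEP used for the pinned fit, cmH2O; defaults to
#'   the breath's own.
#' @return List with `ers_free`, `ers_fixed`, and both full fits
#'   (`fit_free`, `fit_fixed`).
#' @export
compare_elastance_modes <- function(breath, set_peep = breath$set_peep) {
  b <- breath
  b$set_peep <- set_peep
  fit_free <- fit_single_compartment(b, "free")
  fit_fixed <- fit_single_compartment(b, "fixed")
  list(ers_free = fit_free$ers, ers_fixed = fit_fixed$ers,
       fit_free = fit_free, fit_fixed = fit_fixed)
}
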
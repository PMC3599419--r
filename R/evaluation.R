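## Measured-versus-estimated agreement, reported the way PEEP-titration
## studies report it: a pooled linear trend with its R^2, and
## non-parametric error statistics (median, IQR, min, max) pooled and per
## PEEP level. Errors are estimated - measured, so overestimation is
## positive.

#' Agreement between measured and estimated dFRC
#'
#' @param pairs Data frame with columns `measured` (L), `estimated` (L)
#'   and optionally `peep` (cmH2O) and `patient_id`.
#' @param method Label carried into the report.
#' @return An object of class `agreement_report` with `r_squared` (squared
#'   Pearson correlation of measured and estimated; `NA` with a reason
#'   when the measured values have zero variance), `slope` and `intercept`
#'   of the ordinary least-squares trend of estimated on measured, and
#'   error statistics pooled and per exact PEEP level.
#' @export
compute_agreement <- function(pairs, method = "estimate") {
  stopifnot(all(c("measured", "estimated") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[c("measured", "estimated")]), ]
  n <- nrow(pairs)
  if (n < 1) stop("no measured/estimated pairs", call. = FALSE)
  err <- pairs$estimated - pairs$measured

  r2 <- NA_real_
  slope <- NA_real_
  intercept <- NA_real_
  r2_reason <- NULL
  if (n >= 2 && stats::var(pairs$measured) > 0) {
    if (stats::var(pairs$estimated) > 0) {
      r2 <- stats::cor(pairs$measured, pairs$estimated)^2
    } else {
      r2 <- 0  # constant estimate has no trend agreement
    }
    fit <- stats::lm(estimated ~ measured, data = pairs)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    r2_reason <- if (n < 2) "fewer than 2 pairs"
                 else "zero variance in measured values"
  }

  err_stats <- function(e) {
    c(median = stats::median(e), iqr = stats::IQR(e),
      min = min(e), max = max(e), n = length(e))
  }
  per_peep <- NULL
  if ("peep" %in% names(pairs)) {
    per_peep <- do.call(rbind, lapply(sort(unique(pairs$peep)), function(p) {
      data.frame(peep = p, t(err_stats(err[pairs$peep == p])))
    }))
  }
  structure(list(method = method, n_pairs = n, r_squared = r2,
                 r_squared_reason = r2_reason,
                 slope = slope, intercept = intercept,
                 errors = as.list(err_stats(err)),
                 errors_per_peep = per_peep,
                 pairs = pairs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report %s> n = %d pairs\n", x$method, x$n_pairs))
  if (is.na(x$r_squared)) {
    cat("  R^2: undefined (", x$r_squared_reason, ")\n", sep = "")
  } else {
    cat(sprintf("  R^2 = %.3f; trend estimated = %.3f * measured + %.3f\n",
                x$r_squared, x$slope, x$intercept))
  }
  cat(sprintf("  error (est - meas, L): median %.3f, IQR %.3f, range [%.3f, %.3f]\n",
              x$errors$median, x$errors$iqr, x$errors$min, x$errors$max))
  invisible(x)
}

#' Rank estimators by pooled trend agreement
#'
#' @param reports List of [compute_agreement()] reports, one per method.
#' @return Data frame sorted by `r_squared` descending (ties broken by
#'   method name), with per-cohort columns when the underlying pairs carry
#'   a `cohort` column.
#' @export
rank_methods <- function(reports) {
  stopifnot(length(reports) >= 2)
  rows <- lapply(reports, function(r) {
    row <- data.frame(method = r$method, n_pairs = r$n_pairs,
                      r_squared = r$r_squared,
                      median_error = r$errors$median,
                      iqr_error = r$errors$iqr)
    if (!is.null(r$pairs$cohort)) {
      for (co in sort(unique(r$pairs$cohort))) {
        sub <- r$pairs[r$pairs$cohort == co, ]
        rc <- if (nrow(sub) >= 2 && stats::var(sub$measured) > 0 &&
                  stats::var(sub$estimated) > 0) {
          stats::cor(sub$measured, sub$estimated)^2
        } else NA_real_
        row[[paste0("r_squared_", co)]] <- rc
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared, out$method), ]
  rownames(out) <- NULL
  out
}

#' Run every estimator over a cohort and collect measured/estimated pairs
#'
#' Calibrates both population-constant tables on the cohort (in-sample, or
#' leave-one-out for the stress-strain methods when `loo = TRUE`), then
#' estimates dFRC at every eligible (patient, PEEP) with each requested
#' method. The multiple-breath method contributes from each patient's
#' second step up; the single-breath methods at every step; the combined
#' method replays the protocol step by step.
#'
#' @param cohort List of [patient_dataset()] objects with measured dFRC.
#' @param methods Character vector among `"SSMB"`, `"SSSB"`, `"SCSB"`,
#'   `"CM"`.
#' @param loo Use leave-one-out calibration instead of in-sample.
#' @param policy Beta lookup policy.
#' @return Named list of pair data frames (columns `patient_id`, `peep`,
#'   `measured`, `estimated`), one per method.
#' @export
evaluate_cohort <- function(cohort,
                            methods = c("SSMB", "SSSB", "SCSB", "CM"),
                            loo = FALSE, policy = c("refuse", "clamp")) {
  policy <- match.arg(policy)
  methods <- match.arg(methods, several.ok = TRUE)
  need_ssmb <- any(c("SSMB", "CM") %in% methods)
  need_sssb <- any(c("SSSB", "CM") %in% methods)
  ssmb_tab <- if (need_ssmb) calibrate_beta_ssmb(cohort) else NULL
  sssb_tab <- if (need_sssb) calibrate_beta1_sssb(cohort) else NULL

  out <- list()
  for (m in methods) {
    rows <- list()
    for (p in cohort) {
      peeps <- step_peeps(p)
      dfrc <- step_dfrc(p)
      for (k in seq_along(peeps)) {
        if (is.na(dfrc[k])) next
        est <- tryCatch(switch(m,
          SSMB = if (k > 1) estimate_ssmb(p, ssmb_tab, peeps[k], policy),
          SSSB = estimate_sssb(p$steps[[k]], sssb_tab, policy),
          SCSB = estimate_scsb(p$steps[[k]]$breaths[[1]],
                               set_peep = p$steps[[k]]$peep),
          CM = {
            sofar <- patient_dataset(p$steps[seq_len(k)],
                                     patient_id = p$patient_id,
                                     cohort = p$cohort)
            estimate_cm(sofar, ssmb_tab, sssb_tab, peeps[k], policy)
          }), error = function(e) NULL)
        if (is.null(est)) next
        rows[[length(rows) + 1L]] <-
          data.frame(patient_id = p$patient_id, peep = peeps[k],
                     measured = dfrc[k], estimated = est$value,
                     cohort = p$cohort)
      }
    }
    out[[m]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (loo) {
    for (m in intersect(c("SSMB", "SSSB"), methods)) {
      out[[m]] <- loo_evaluate(cohort, m, policy)
    }
  }
  out
}

#' Plot measured versus estimated dFRC with the fitted trend
#'
#' Scatter of estimated against measured dFRC with the ordinary
#' least-squares trend line and identity line, plus a per-PEEP box plot of
#' errors. Display only: errors beyond `truncate_at` are clipped in the
#' box-plot panel but never in computed statistics.
#'
#' @param report An [compute_agreement()] report.
#' @param truncate_at Display clip for the error panel, L.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_agreement <- function(report, truncate_at = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_agreement requires the ggplot2 package", call. = FALSE)
  }
  p <- report$pairs
  ggplot2::ggplot(p, ggplot2::aes(x = measured, y = estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "measured dFRC [L]", y = "estimated dFRC [L]",
      title = sprintf("%s: R^2 = %s", report$method,
                      ifelse(is.na(report$r_squared), "undefined",
                             sprintf("%.3f", report$r_squared))))
}
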
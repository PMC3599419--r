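## Virtual ventilated patients with known ground-truth dFRC.
##
## Breaths follow the single-compartment equation of motion forward:
## a half-sine inspiratory flow scaled to the set tidal volume, an
## end-inspiratory zero-flow pause, a half-sine expiration scaled so the
## trapezoidal volume returns exactly to zero, and an end-expiratory
## zero-flow pause where airway pressure sits exactly at the offset
## pressure (the ventilator holding PEEP). Volume is the trapezoidal
## running integral of flow by construction, and pressure =
## Ers*V + Rrs*Q + Po (+ noise), so the waveform-side pipeline sees data
## exactly of the form it models, with both plateaus readable at zero
## flow.
##
## Ground-truth dFRC(PEEP) is a logistic sigmoid in PEEP — volume
## responsiveness to PEEP saturates at both ends — optionally held flat
## below an auto-PEEP level: set PEEP below the intrinsic PEEP recruits
## nothing, producing the characteristic compliance-trend break once PEEP
## crosses the auto-PEEP.

#' Virtual patient parameters
#'
#' @param ers_true Respiratory elastance, cmH2O/L.
#' @param rrs_true Respiratory resistance, cmH2O.s/L.
#' @param vt_set Set tidal volume, L.
#' @param resp_rate Respiratory rate, breaths/min.
#' @param v_max Recruitment capacity: upper asymptote of dFRC(PEEP), L.
#' @param peep_mid PEEP at half recruitment, cmH2O.
#' @param slope Sigmoid width parameter, cmH2O (smaller = steeper).
#' @param auto_peep Intrinsic PEEP, cmH2O (0 = none). Acts as a floor on
#'   the offset pressure and a hold on recruitment below it, so a set PEEP
#'   under the intrinsic PEEP recruits nothing.
#' @param noise_sd_pressure Additive Gaussian noise on the pressure
#'   channel, cmH2O.
#' @param noise_sd_dfrc Additive Gaussian noise on measured dFRC, L
#'   (floored at 0).
#' @param sample_rate Waveform sampling rate, Hz.
#' @param seed Integer seed making the patient reproducible.
#' @return A `virtual_patient_params` list.
#' @export
virtual_patient_params <- function(ers_true = 28, rrs_true = 10, vt_set = 0.5,
                                   resp_rate = 15, v_max = 2, peep_mid = 10,
                                   slope = 4, auto_peep = 0,
                                   noise_sd_pressure = 0, noise_sd_dfrc = 0,
                                   sample_rate = 50, seed = 1L) {
  p <- list(ers_true = ers_true, rrs_true = rrs_true, vt_set = vt_set,
            resp_rate = resp_rate, v_max = v_max, peep_mid = peep_mid,
            slope = slope, auto_peep = auto_peep,
            noise_sd_pressure = noise_sd_pressure,
            noise_sd_dfrc = noise_sd_dfrc,
            sample_rate = sample_rate, seed = as.integer(seed))
  pos <- c("ers_true", "rrs_true", "vt_set", "resp_rate", "peep_mid",
           "slope", "sample_rate")
  for (nm in pos) if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  nonneg <- c("v_max", "auto_peep", "noise_sd_pressure", "noise_sd_dfrc")
  for (nm in nonneg) if (p[[nm]] < 0) stop(nm, " must be non-negative",
                                           call. = FALSE)
  structure(p, class = "virtual_patient_params")
}

#' Ground-truth dFRC of a virtual patient
#'
#' Logistic sigmoid in PEEP, held at its auto-PEEP value for PEEP below
#' the auto-PEEP level (no recruitment until set PEEP exceeds intrinsic
#' PEEP). Non-decreasing in PEEP.
#'
#' @param params A [virtual_patient_params()].
#' @param peep PEEP level(s), cmH2O.
#' @return Ground-truth dFRC, L.
#' @export
true_dfrc <- function(params, peep) {
  sig <- function(p) params$v_max / (1 + exp(-(p - params$peep_mid) / params$slope))
  ifelse(peep > params$auto_peep, sig(peep), sig(params$auto_peep))
}

## One noise-free breath at a given offset pressure; returns a vent_series
## slice (time from t0). Both half-sine lobes are rescaled after sampling
## so the trapezoidal volume reaches exactly vt_set at end-inspiration and
## exactly zero at end-expiration: plateau pressures read at the zero-flow
## pauses are then exact on the sampled grid. The rescaling is exact
## because every flow sample outside a lobe is identically zero, making
## the trapezoidal integral linear in the lobe's scale factor.
.simulate_breath_series <- function(params, po, t0 = 0) {
  period <- 60 / params$resp_rate
  ti <- period / 3            # inspiratory time
  tpause <- period / 10       # end-inspiratory pause
  te <- period * 0.4          # active expiration
  dt <- 1 / params$sample_rate
  time <- seq(0, period - dt / 2, by = dt)
  flow <- numeric(length(time))

  insp <- time <= ti
  flow[insp] <- sin(pi * time[insp] / ti)
  vt_raw <- pracma::trapz(time, flow)
  flow <- flow * (params$vt_set / vt_raw)

  texp0 <- ti + tpause
  expi <- time > texp0 & time <= texp0 + te
  raw <- -sin(pi * (time[expi] - texp0) / te)
  fexp <- flow
  fexp[expi] <- raw
  e_raw <- pracma::trapz(time, fexp) - params$vt_set  # expiratory lobe only
  flow[expi] <- raw * (params$vt_set / -e_raw)

  volume <- pracma::cumtrapz(time, flow)[, 1]
  pressure <- params$ers_true * volume + params$rrs_true * flow + po
  data.frame(time = time + t0, pressure = pressure, flow = flow)
}

#' Simulate a stepwise-PEEP protocol for one virtual patient
#'
#' Generates `n_breaths` single-compartment breaths at each protocol PEEP
#' (offset pressure `max(set PEEP, auto_peep)` plus pressure noise),
#' segments and summarises them through the standard waveform pipeline,
#' and attaches the measured dFRC (ground truth plus measurement noise,
#' floored at 0). The same seed gives a bit-identical dataset.
#'
#' @param params A [virtual_patient_params()].
#' @param peep_protocol Ordered PEEP levels, cmH2O, all non-negative.
#' @param n_breaths Breaths generated per PEEP level.
#' @param patient_id,cohort Labels for the resulting dataset.
#' @return A [patient_dataset()]; ground truth is attached as attribute
#'   `true_dfrc` (named by PEEP) and per-step field `true_dfrc`.
#' @export
simulate_patient <- function(params, peep_protocol = c(5, 10, 15),
                             n_breaths = 3, patient_id = "sim",
                             cohort = "synthetic") {
  if (any(peep_protocol < 0)) stop("invalid protocol: PEEP below 0 cmH2O",
                                   call. = FALSE)
  if (any(diff(peep_protocol) <= 0)) stop("invalid protocol: PEEP levels ",
                                          "must be strictly increasing",
                                          call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  truth <- true_dfrc(params, peep_protocol)
  steps <- vector("list", length(peep_protocol))
  for (j in seq_along(peep_protocol)) {
    peep <- peep_protocol[j]
    po <- max(peep, params$auto_peep)
    series <- do.call(rbind, lapply(seq_len(n_breaths), function(b) {
      .simulate_breath_series(params, po,
                              t0 = (b - 1) * 60 / params$resp_rate)
    }))
    if (params$noise_sd_pressure > 0) {
      series$pressure <- series$pressure +
        stats::rnorm(nrow(series), 0, params$noise_sd_pressure)
    }
    measured <- truth[j]
    if (params$noise_sd_dfrc > 0) {
      measured <- max(0, measured + stats::rnorm(1, 0, params$noise_sd_dfrc))
    }
    breaths <- lapply(split(series, rep(seq_len(n_breaths),
                                        each = nrow(series) / n_breaths)),
                      function(s) breath(s$time - s$time[1], s$pressure,
                                         s$flow, set_peep = peep))
    st <- summarize_step(breaths, set_peep = peep, measured_dfrc = measured)
    st$true_dfrc <- truth[j]
    steps[[j]] <- st
  }
  ds <- patient_dataset(steps, patient_id = patient_id, cohort = cohort)
  attr(ds, "true_dfrc") <- stats::setNames(truth, peep_protocol)
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cohort specification
#'
#' Inter-patient heterogeneity: each numeric field of
#' [virtual_patient_params()] is drawn log-normally around its stated mean
#' with its stated coefficient of variation (CV 0 = identical across
#' patients). By default the recruitment capacity `v_max` is partially
#' coupled to tidal strain — multiplied per patient by
#' `((vt/mean(vt)) * (mean(ers)/ers))^strain_coupling` on top of its own
#' draw — reflecting the stress-strain premise that recruited volume
#' correlates with the tidal strain a patient receives relative to their
#' elastance, without being determined by it; the patient's own `v_max`
#' draw (its CV) remains as recruitment heterogeneity independent of
#' tidal mechanics. The default exponent 0.5 was calibrated, together
#' with the mean recruitment capacity, so that cohorts drawn from the
#' defaults reproduce the relative measured-versus-estimated agreement
#' the four estimators attain on real stepwise-PEEP cohorts. Set
#' `couple_vmax = FALSE` for fully independent draws.
#'
#' @param n_patients Number of patients.
#' @param means Named list of mean parameter values (defaults:
#'   [virtual_patient_params()] defaults).
#' @param cvs Named list of coefficients of variation (fields omitted
#'   default to 0).
#' @param peep_protocol Ordered PEEP levels shared by the cohort, cmH2O.
#' @param couple_vmax Couple recruitment capacity to tidal strain (default
#'   TRUE).
#' @param strain_coupling Coupling exponent between recruitment capacity
#'   and per-patient tidal strain (0 = none, 1 = proportional).
#' @param master_seed Integer seed; per-patient seeds derive from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10, means = list(), cvs = list(),
                        peep_protocol = c(5, 10, 15), couple_vmax = TRUE,
                        strain_coupling = 0.5, master_seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (any(diff(peep_protocol) <= 0)) stop("protocol must be strictly increasing",
                                          call. = FALSE)
  base <- virtual_patient_params()
  drawable <- c("ers_true", "rrs_true", "vt_set", "resp_rate", "v_max",
                "peep_mid", "slope", "auto_peep", "noise_sd_pressure",
                "noise_sd_dfrc")
  m <- utils::modifyList(base[drawable], means)
  cv <- utils::modifyList(stats::setNames(as.list(rep(0, length(drawable))),
                                          drawable), cvs)
  structure(list(n_patients = n_patients, means = m, cvs = cv,
                 peep_protocol = peep_protocol, couple_vmax = couple_vmax,
                 strain_coupling = strain_coupling,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Reference synthetic stepwise-PEEP cohort specification
#'
#' The package's standing emulation of a clinical stepwise-PEEP ARDS
#' cohort: 10 patients at PEEP 5/10/15 cmH2O, mechanics heterogeneity of
#' 20% (elastance, resistance) with 30% on tidal volume, recruitment-curve
#' heterogeneity of 50% on capacity and 20% on shape, intrinsic PEEP
#' around 3 cmH2O, pressure-sensor noise 0.5 cmH2O and dFRC measurement
#' noise 0.05 L. The recruitment-side distributions were calibrated so
#' that the four estimators' pooled measured-versus-estimated agreement on
#' cohorts drawn from this spec reproduces the relative pattern observed
#' on real stepwise-PEEP cohorts (multiple-breath and combined methods
#' strong, single-breath stress-strain moderate, single-compartment proxy
#' weakest); the mechanics-side values are standard adult-ICU figures.
#'
#' @param master_seed Integer seed.
#' @param n_patients Number of patients.
#' @param peep_protocol Ordered PEEP levels, cmH2O.
#' @return A [cohort_spec()].
#' @export
reference_cohort_spec <- function(master_seed = 1L, n_patients = 10,
                                  peep_protocol = c(5, 10, 15)) {
  cohort_spec(
    n_patients = n_patients,
    means = list(ers_true = 28, rrs_true = 10, vt_set = 0.5, resp_rate = 15,
                 v_max = 2.5, peep_mid = 10, slope = 5, auto_peep = 3,
                 noise_sd_pressure = 0.5, noise_sd_dfrc = 0.05),
    cvs = list(ers_true = 0.2, rrs_true = 0.2, vt_set = 0.3, v_max = 0.5,
               peep_mid = 0.2, slope = 0.2, auto_peep = 0.5),
    peep_protocol = peep_protocol, couple_vmax = TRUE, strain_coupling = 1,
    master_seed = master_seed)
}

## Log-normal draw with given mean and CV (exact moments); CV 0 is exact.
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate a synthetic cohort
#'
#' Draws per-patient parameters from the spec's distributions using
#' per-patient seeds derived deterministically from the master seed, then
#' simulates each patient's stepwise-PEEP protocol.
#'
#' @param spec A [cohort_spec()].
#' @param n_breaths Breaths per PEEP level.
#' @return List of [patient_dataset()] objects.
#' @export
simulate_cohort <- function(spec, n_breaths = 3) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$master_seed)
  n <- spec$n_patients
  draws <- lapply(names(spec$means), function(nm) {
    .rlnorm_mean_cv(n, spec$means[[nm]], spec$cvs[[nm]])
  })
  names(draws) <- names(spec$means)
  if (spec$couple_vmax) {
    strain_ratio <- (draws$vt_set / spec$means$vt_set) *
      (spec$means$ers_true / draws$ers_true)
    draws$v_max <- draws$v_max * strain_ratio^spec$strain_coupling
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    p <- virtual_patient_params(
      ers_true = draws$ers_true[i], rrs_true = draws$rrs_true[i],
      vt_set = draws$vt_set[i], resp_rate = draws$resp_rate[i],
      v_max = draws$v_max[i], peep_mid = draws$peep_mid[i],
      slope = draws$slope[i], auto_peep = draws$auto_peep[i],
      noise_sd_pressure = draws$noise_sd_pressure[i],
      noise_sd_dfrc = draws$noise_sd_dfrc[i],
      seed = seeds[i])
    simulate_patient(p, spec$peep_protocol, n_breaths,
                     patient_id = sprintf("sim%02d", i))
  })
}

#' Build a cohort whose dFRC satisfies the multiple-breath identity exactly
#'
#' Constructs measured dFRC values so every patient satisfies
#' `dFRC(PEEP) = (ddFRC/dPEEP) * beta(PEEP)` exactly under a given
#' per-PEEP beta profile, by solving the implied recurrence
#' `dFRC_k = dFRC_{k-1} * beta_k / (beta_k - dPEEP_k)` from each patient's
#' first-step dFRC. Used for exact-recovery tests of calibration and the
#' multiple-breath estimator: calibrating on such a cohort returns the
#' generating profile, and estimating with it reproduces the constructed
#' dFRC exactly.
#'
#' @param beta_profile Named numeric: beta (cmH2O) at each protocol PEEP
#'   above the first (names are PEEP levels).
#' @param spec A [cohort_spec()]; the waveform side is simulated as usual,
#'   only measured dFRC is overridden.
#' @param dfrc_first Per-patient dFRC at the first protocol PEEP, L
#'   (recycled).
#' @return List of [patient_dataset()] objects.
#' @export
make_eq8_consistent_cohort <- function(beta_profile, spec,
                                       dfrc_first = 0.2) {
  protocol <- spec$peep_protocol
  upper <- protocol[-1]
  if (!all(as.character(upper) %in% names(beta_profile))) {
    stop("beta_profile must cover every protocol PEEP above the first",
         call. = FALSE)
  }
  dpeep <- diff(protocol)
  betas <- as.numeric(beta_profile[as.character(upper)])
  if (any(betas <= dpeep)) {
    stop("infeasible beta profile: beta must exceed the PEEP step ",
         "(otherwise dFRC would be negative or unbounded)", call. = FALSE)
  }
  cohort <- simulate_cohort(spec)
  dfrc_first <- rep_len(dfrc_first, length(cohort))
  for (i in seq_along(cohort)) {
    dfrc <- numeric(length(protocol))
    dfrc[1] <- dfrc_first[i]
    for (k in seq_along(upper)) {
      dfrc[k + 1] <- dfrc[k] * betas[k] / (betas[k] - dpeep[k])
    }
    for (k in seq_along(protocol)) {
      cohort[[i]]$steps[[k]]$measured_dfrc <- dfrc[k]
      cohort[[i]]$steps[[k]]$true_dfrc <- dfrc[k]
    }
    cohort[[i]] <- patient_dataset(cohort[[i]]$steps,
                                   patient_id = cohort[[i]]$patient_id,
                                   cohort = cohort[[i]]$cohort)
    attr(cohort[[i]], "true_dfrc") <- stats::setNames(dfrc, protocol)
  }
  cohort
}

#' Write a simulated cohort as waveform CSVs, manifests and a truth sidecar
#'
#' Emits, under `out_dir`: one waveform CSV per (patient, PEEP), one YAML
#' manifest per patient referencing its files with set PEEP and measured
#' dFRC, and `ground_truth.csv` (patient_id, peep, true_dfrc) for
#' evaluation against known truth.
#'
#' @param cohort List of [patient_dataset()] objects from the simulator.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of manifest paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth_rows <- list()
  manifests <- character(0)
  for (p in cohort) {
    entries <- list()
    for (s in p$steps) {
      fname <- sprintf("%s_peep%02.0f.csv", p$patient_id, s$peep)
      series <- do.call(rbind, lapply(seq_along(s$breaths), function(i) {
        b <- s$breaths[[i]]
        data.frame(time = b$time + (i - 1) * (max(b$time) + diff(b$time)[1]),
                   pressure = b$pressure, flow = b$flow)
      }))
      write_waveform_csv(series, file.path(out_dir, fname))
      e <- list(peep = s$set_peep, file = fname)
      if (!is.na(s$measured_dfrc)) e$measured_dfrc <- s$measured_dfrc
      entries[[length(entries) + 1L]] <- e
      if (!is.null(s$true_dfrc)) {
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(patient_id = p$patient_id, peep = s$peep,
                     true_dfrc = s$true_dfrc)
      }
    }
    man <- file.path(out_dir, paste0(p$patient_id, ".yaml"))
    yaml::write_yaml(list(patient_id = p$patient_id, cohort = p$cohort,
                          steps = entries), man, precision = 15L)
    manifests <- c(manifests, man)
  }
  if (length(truth_rows) > 0) {
    utils::write.csv(do.call(rbind, truth_rows),
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(manifests)
}
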
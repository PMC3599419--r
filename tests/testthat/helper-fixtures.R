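# Shared fixtures: analytic breaths and small cohorts built in code.

# Noise-free single-compartment breath sampled on a uniform grid:
# half-sine inspiration (exact tidal volume on the grid), zero-flow pause,
# half-sine expiration returning volume exactly to zero, final pause.
# Independent of the package's simulator internals so it can serve as an
# oracle for the identification fit.
analytic_breath <- function(ers = 25, rrs = 10, po = 5, vt = 0.5,
                            sample_rate = 50, period = 4, set_peep = po) {
  dt <- 1 / sample_rate
  ti <- period / 3
  tpause <- period / 10
  te <- 0.4 * period
  time <- seq(0, period - dt / 2, by = dt)
  flow <- numeric(length(time))
  insp <- time <= ti
  flow[insp] <- sin(pi * time[insp] / ti)
  flow <- flow * vt / pracma::trapz(time, flow)
  t0 <- ti + tpause
  expi <- time > t0 & time <= t0 + te
  raw <- -sin(pi * (time[expi] - t0) / te)
  tmp <- flow; tmp[expi] <- raw
  scale <- vt / -(pracma::trapz(time, tmp) - vt)
  flow[expi] <- raw * scale
  volume <- pracma::cumtrapz(time, flow)[, 1]
  pressure <- ers * volume + rrs * flow + po
  breath(time, pressure, flow, set_peep = set_peep)
}

# Cohort of fully-specified patients (no distributional draws) whose
# measured dFRC values are set directly.
manual_cohort <- function(dfrc_by_patient, peeps = c(5, 10, 15),
                          vt = 0.5, dpaw = 12) {
  lapply(seq_along(dfrc_by_patient), function(i) {
    dfrc <- dfrc_by_patient[[i]]
    steps <- lapply(seq_along(peeps), function(k) {
      structure(list(peep = peeps[k], plateau_pressure = peeps[k] + dpaw,
                     tidal_volume = vt, delta_paw = dpaw,
                     measured_dfrc = dfrc[k], set_peep = peeps[k],
                     breaths = list()),
                class = "peep_step")
    })
    patient_dataset(steps, patient_id = sprintf("p%02d", i))
  })
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), rel_tol)
}
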
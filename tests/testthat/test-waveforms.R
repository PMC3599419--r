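test_that("waveform CSV round trip is the identity to 6 significant digits", {
  b <- analytic_breath()
  series <- data.frame(time = b$time, pressure = b$pressure, flow = b$flow)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(series, path)
  back <- read_waveform_csv(path)
  expect_equal(nrow(back), nrow(series))
  for (col in c("time", "pressure", "flow")) {
    expect_equal(back[[col]], series[[col]], tolerance = 1e-6)
  }
})

test_that("reader converts declared source units and rejects bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,pressure,flow", "ms,cmH2O,mL/s",
               "0,5,0", "10,6,100", "20,7,200"), path)
  s <- read_waveform_csv(path)
  expect_equal(s$time, c(0, 0.01, 0.02))
  expect_equal(s$flow, c(0, 0.1, 0.2))

  # dialect override takes precedence over the units row
  s2 <- read_waveform_csv(path, dialect = list(flow = "L/s"))
  expect_equal(s2$flow, c(0, 100, 200))

  # duplicate timestamp
  writeLines(c("time,pressure,flow", "s,cmH2O,L/s",
               "0,5,0", "0.01,6,0.1", "0.01,7,0.2"), path)
  expect_error(read_waveform_csv(path), "non-monotone time.*row 3")

  # unknown unit tag
  writeLines(c("time,pressure,flow", "s,psi,L/s", "0,5,0"), path)
  expect_error(read_waveform_csv(path), "unknown unit tag 'psi'")

  # missing column
  writeLines(c("time,pressure", "s,cmH2O", "0,5"), path)
  expect_error(read_waveform_csv(path), "flow")
})

test_that("segmentation splits at inspiration onsets and drops short fragments", {
  # three sinusoidal cycles: the sign-change oracle counts 3 upward crossings
  tt <- seq(0, 6, by = 0.01)
  series <- data.frame(time = tt, pressure = 10 + sin(pi * tt),
                       flow = sin(pi * tt))
  f <- sin(pi * tt)
  crossings <- sum(head(f, -1) <= 0 & tail(f, -1) > 0)
  brs <- segment_breaths(series, min_breath_duration = 1)
  expect_length(brs, crossings)
  expect_length(brs, 3)

  # breaths partition the retained samples: contiguous, non-overlapping
  idx <- unlist(lapply(brs, function(b) b$time))
  expect_true(all(diff(idx) > 0))

  # all-positive flow has no expiration, hence no onset
  series_pos <- data.frame(time = tt, pressure = 10 + tt, flow = 1 + 0 * tt)
  expect_error(segment_breaths(series_pos), "no inspiration onset")

  # a compressed middle cycle shorter than min_breath_duration is discarded
  t1 <- seq(0, 2, by = 0.01)          # full cycle, 2 s
  t2 <- seq(0, 0.2, by = 0.01)        # 10x shorter cycle
  flow3 <- c(sin(pi * t1), sin(pi * t2 / 0.1), sin(pi * t1))
  tt3 <- seq_along(flow3) * 0.01
  series3 <- data.frame(time = tt3, pressure = 10 + flow3, flow = flow3)
  brs3 <- segment_breaths(series3, min_breath_duration = 1)
  expect_length(brs3, 2)
})

test_that("zero-flow detection finds pauses, analytic zeros, and degenerate flows", {
  # square-wave flow with an explicit 0.3 s inspiratory pause
  dt <- 0.01
  flow <- c(rep(1, 100), rep(0, 30), rep(-1, 70), rep(0, 20))
  tt <- seq_along(flow) * dt
  b <- breath(tt, 10 + cumsum(flow) * dt, flow, set_peep = 5)
  zf <- detect_zero_flow(b)
  expect_true(zf$insp_end_index %in% 101:130)   # inside the pause
  expect_equal(zf$insp_end_index, 130L)          # last pause sample
  expect_equal(zf$exp_end_index, length(flow))

  # pure sinusoid: inspiratory zero at the analytic half-period
  tt <- seq(0.01, 2, by = 0.01)
  flow <- sin(pi * tt)
  bs <- breath(tt, 10 + sin(pi * tt), flow, set_peep = 5)
  zfs <- detect_zero_flow(bs, flow_tolerance = 0.001)
  expect_lt(abs(tt[zfs$insp_end_index] - 1), 0.011)

  # identically zero flow resolves to the last sample, with a warning
  bz <- suppressWarnings(breath(tt, rep(10, length(tt)), rep(0, length(tt)),
                                volume = rep(0, length(tt)),
                                insp_end_index = length(tt) - 1L))
  expect_warning(zfz <- detect_zero_flow(bz), "tolerance")
  expect_equal(zfz$exp_end_index, length(tt))
})

test_that("step summary recovers plateau, PEEP and tidal volume from model breaths", {
  # equation-of-motion oracle: at zero flow, pressure = Po + Ers * V
  b <- analytic_breath(ers = 25, rrs = 10, po = 5, vt = 0.5)
  st <- summarize_step(list(b), set_peep = 5)
  expect_rel_equal(st$plateau_pressure, 5 + 25 * 0.5, 1e-3)
  expect_rel_equal(st$peep, 5, 1e-3)
  expect_rel_equal(st$tidal_volume, 0.5, 1e-3)
  expect_equal(st$delta_paw, st$plateau_pressure - st$peep)

  # duplicated breaths change nothing (median of identical values)
  st2 <- summarize_step(list(b, b), set_peep = 5)
  expect_equal(st2$plateau_pressure, st$plateau_pressure)
  expect_equal(st2$tidal_volume, st$tidal_volume)

  # corrupted pressures with end-inspiratory pressure below PEEP
  bad <- analytic_breath()
  bad$pressure <- rev(bad$pressure)
  expect_error(summarize_step(list(bad), set_peep = 5),
               "plateau pressure.*not above PEEP")
})

test_that("patient datasets validate PEEP ordering and derive dFRC differences", {
  co <- manual_cohort(list(c(0.2, 0.5, 0.9)))
  p <- co[[1]]
  expect_equal(p$measured_delta_dfrc, c(NA, 0.3, 0.4))

  dup <- manual_cohort(list(c(0.2, 0.5)), peeps = c(5, 10))[[1]]
  dup$steps[[2]]$set_peep <- 5
  expect_error(patient_dataset(dup$steps), "strictly increasing")
})

test_that("manifest round trip reproduces steps written by the simulator", {
  params <- virtual_patient_params(seed = 11)
  ds <- simulate_patient(params, c(5, 10), patient_id = "rt01")
  dir <- withr::local_tempdir()
  manifests <- write_cohort(list(ds), dir)
  back <- read_manifest(manifests[[1]])
  expect_equal(back$patient_id, "rt01")
  expect_length(back$steps, 2)
  # re-segmentation re-anchors each inspiration at the first positive-flow
  # sample, so step quantities agree to ~0.1%, not bit-exactly
  for (k in 1:2) {
    expect_equal(back$steps[[k]]$peep, ds$steps[[k]]$peep, tolerance = 1e-3)
    expect_equal(back$steps[[k]]$tidal_volume, ds$steps[[k]]$tidal_volume,
                 tolerance = 1e-3)
    expect_equal(back$steps[[k]]$measured_dfrc, ds$steps[[k]]$measured_dfrc,
                 tolerance = 1e-9)
  }
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(truth$true_dfrc,
               unname(attr(ds, "true_dfrc")), tolerance = 1e-9)
})
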
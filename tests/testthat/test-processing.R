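test_that("a decaying complex exponential transforms to a peak at its shift", {
  p <- default_params()
  sw_hz <- p$spectral_width * p$spectrometer_frequency
  t <- (0:(p$n_complex_points - 1)) / sw_hz
  f0 <- (3.2 - p$transmitter_offset) * p$spectrometer_frequency
  fid <- raw_fid(exp((2i * pi * f0 - pi * 1) * t), p)
  s <- nmr_transform(fid)
  expect_equal(s$ppm[which.max(s$real)], 3.2, tolerance = 0.01)
  # linearity
  fid2 <- raw_fid(3 * fid$signal, p)
  expect_equal(nmr_transform(fid2)$real, 3 * s$real, tolerance = 1e-12)
})

test_that("transform honours zero filling rules and degenerate input", {
  p <- small_params(1024L)
  fid <- raw_fid(complex(1024), p)
  s <- nmr_transform(fid, zero_fill_to = 2048L)
  expect_length(s$real, 2048L)
  expect_true(all(s$real == 0))
  expect_error(nmr_transform(fid, zero_fill_to = 512L), "smaller")
  # axis spans offset +/- sw/2
  expect_equal(max(s$ppm), p$transmitter_offset + p$spectral_width / 2,
               tolerance = 0.01)
  expect_equal(min(s$ppm), p$transmitter_offset - p$spectral_width / 2,
               tolerance = 0.01)
})

test_that("auto-phase recovers a known dephasing within one degree", {
  p <- default_params()
  sp <- oil_spec(0.15, 0.75, 0.09, 0.01)
  s0 <- nmr_transform(synthesize_fid(sp, p))
  dephased <- apply_phase(s0, -30, -10)
  rec <- auto_phase(dephased)
  pr <- rec$proc[[length(rec$proc)]]
  expect_lt(abs(pr$phi0 - 30), 1)
  expect_lt(abs(pr$phi1 - 10), 1)
  # >= 99 % of the total area positive after correction
  expect_gt(sum(pmax(rec$real, 0)) / sum(abs(rec$real)), 0.99)
})

test_that("auto-phase is near identity on a phased spectrum and idempotent", {
  p <- default_params()
  s0 <- nmr_transform(synthesize_fid(oil_spec(0.15, 0.75, 0.09, 0.01), p))
  once <- auto_phase(s0)
  pr1 <- once$proc[[length(once$proc)]]
  expect_lt(abs(pr1$phi0), 1)
  expect_lt(abs(pr1$phi1), 1)
  twice <- auto_phase(once)
  pr2 <- twice$proc[[length(twice$proc)]]
  expect_lt(abs(pr2$phi0), 0.5)
  expect_lt(abs(pr2$phi1), 0.5)
})

test_that("pure-noise input does not break the phaser", {
  p <- small_params(4096L)
  set.seed(3)
  fid <- raw_fid(complex(real = rnorm(4096), imaginary = rnorm(4096)), p)
  s <- auto_phase(nmr_transform(fid, zero_fill_to = 4096L))
  expect_s3_class(s, "nmr_spectrum")
  expect_true("phase_fallback_magnitude" %in% s$flags)
  expect_true(all(s$real >= 0))  # magnitude mode
})

test_that("baseline correction removes offsets and ramps without touching signal", {
  p <- default_params()
  sp <- oil_spec(0.15, 0.75, 0.09, 0.01)
  s0 <- synthesize_spectrum(sp, p)
  reg <- default_regions()
  ref_tab <- integrate_regions(baseline_correct(s0), reg)

  # constant offset: removed, noise region centred on zero
  s_off <- s0
  s_off$real <- s_off$real + 0.1 * max(s0$real)
  s_corr <- baseline_correct(s_off)
  sel <- s_corr$ppm >= 9.5 & s_corr$ppm <= 10.5
  expect_lt(max(abs(s_corr$real[sel])), 1e-4 * max(s0$real))

  # linear ramp across the axis: region integrals within 0.5 % of the
  # ramp-free reference pushed through the same correction
  s_ramp <- s0
  s_ramp$real <- s_ramp$real + seq(0, 0.2 * max(s0$real), length.out =
                                     length(s0$real))
  tab <- integrate_regions(baseline_correct(s_ramp), reg)
  for (sig in c("A", "C", "E", "F", "H", "J"))
    expect_equal(tab$areas[[sig]], ref_tab$areas[[sig]],
                 tolerance = 5e-3)

  # already-flat spectrum: peaks are left standing (apexes within 3 %) and
  # area ratios are preserved within 1.5 % — the correction subtracts only
  # the near-uniform far-wing pedestal
  s_flat <- baseline_correct(s0)
  for (center in c(0.88, 2.30, 5.35)) {
    near <- abs(s0$ppm - center) < 0.02
    expect_equal(max(s_flat$real[near]), max(s0$real[near]),
                 tolerance = 0.03)
  }
  tab0 <- integrate_regions(s0, reg)
  for (sig in c("A", "E", "H", "J"))
    expect_equal(ref_tab$areas[[sig]] / ref_tab$areas[["F"]],
                 tab0$areas[[sig]] / tab0$areas[["F"]], tolerance = 0.015)
})

test_that("TMS referencing shifts the axis by the injected offset", {
  p <- default_params()
  sp <- oil_spec(0.15, 0.75, 0.09, 0.01)
  s0 <- synthesize_spectrum(sp, p)
  s_shift <- s0
  s_shift$ppm <- s_shift$ppm + 0.05   # TMS now sits at +0.05 ppm
  s_ref <- reference_to_tms(s_shift)
  pr <- s_ref$proc[[length(s_ref$proc)]]
  expect_true(pr$found)
  expect_equal(pr$shift, -0.05, tolerance = 1e-3)
  expect_equal(s_ref$ppm[which.max(s_ref$real * (abs(s_ref$ppm) < 0.3))], 0,
               tolerance = 1e-3)

  # idempotence: a second referencing moves the axis by ~0
  s_ref2 <- reference_to_tms(s_ref)
  pr2 <- s_ref2$proc[[length(s_ref2$proc)]]
  expect_lt(abs(pr2$shift), 1e-6)
})

test_that("absent TMS raises a flag and leaves the axis unchanged", {
  p <- default_params()
  sp <- oil_spec(0.15, 0.75, 0.09, 0.01, tms_amplitude = 0,
                 noise_sigma = 2e-3, seed = 4)
  s <- nmr_transform(synthesize_fid(sp, p))
  s_ref <- reference_to_tms(s)
  expect_true("tms_missing" %in% s_ref$flags)
  expect_identical(s_ref$ppm, s$ppm)
})

test_that("quality metrics report S/N, linewidth and resolution", {
  p <- default_params()
  sp <- oil_spec(0.124, 0.851, 0.018, 0.007, seed = 8)
  sp$noise_sigma <- noise_sigma_for_snr(sp, p, snr = 500)
  q <- quality_metrics(nmr_transform(synthesize_fid(sp, p)))
  expect_equal(q$snr_B, 500, tolerance = 0.1)
  expect_equal(q$linewidth_tms, 0.68, tolerance = 0.05)
  expect_equal(round(q$digital_resolution, 2), 0.11)
  expect_true(q$passed[["snr"]])
  expect_true(q$passed[["resolution"]])

  # noiseless: unbounded S/N, still passing
  sp$noise_sigma <- 0
  q0 <- quality_metrics(nmr_transform(synthesize_fid(sp, p)))
  expect_true(is.infinite(q0$snr_B) || q0$snr_B > 1e4)
  expect_true(q0$passed[["snr"]])

  # a window outside the axis is an error
  expect_error(quality_metrics(nmr_transform(synthesize_fid(sp, p)),
                               noise_window = c(20, 21)), "noise window")
})

test_that("experiment duration follows (NS+DS)*(AQ+D1) rounded to seconds", {
  expect_equal(experiment_duration(acq_params()), 86)
  expect_equal(experiment_duration(
    acq_params(n_scans = 1, n_dummy_scans = 0, acquisition_time = 1,
               recycle_delay = 0, n_complex_points = 3600)), 1)
  expect_equal(experiment_duration(acq_params(n_scans = 16)), 154)
})
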
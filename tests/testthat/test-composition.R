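test_that("composition equations reproduce pure and mixed triglycerides", {
  r1 <- compute_fac(count_table(oil_spec(1, 0, 0, 0)))
  expect_equal(c(r1$sfa, r1$mufa, r1$pufa), c(100, 0, 0), tolerance = 1e-9)

  r2 <- compute_fac(count_table(oil_spec(0, 0, 0, 1)))
  expect_equal(c(r2$sfa, r2$mufa, r2$pufa), c(0, 0, 100), tolerance = 1e-9)

  r3 <- compute_fac(count_table(oil_spec(0.2, 0.6, 0.15, 0.05)))
  expect_equal(c(r3$sfa, r3$mufa, r3$pufa), c(20, 60, 20), tolerance = 1e-9)

  # the as-printed mono-unsaturated equation (glycerol H in place of the
  # bis-allylic G) does not close the balance: pure 18:1 comes out at 33 %
  r4 <- compute_fac(count_table(oil_spec(0, 1, 0, 0)), eq2 = "as_printed")
  expect_equal(r4$mufa, 100 / 3, tolerance = 1e-9)
})

test_that("equations invert the forward proton-count model on a grid", {
  grid <- composition_grid(0.05)
  expect_gt(nrow(grid), 1000)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tab <- count_table(oil_spec(g$x, g$y, g$z, g$w))
    r <- compute_fac(tab)
    expect_equal(r$sfa, 100 * g$x, tolerance = 1e-9)
    expect_equal(r$mufa, 100 * g$y, tolerance = 1e-9)
    expect_equal(r$pufa, 100 * (g$z + g$w), tolerance = 1e-9)
    expect_equal(r$sfa + r$mufa + r$pufa, 100, tolerance = 1e-9)
  }
})

test_that("scale invariance propagates to all composition outputs", {
  tab <- count_table(oil_spec(0.15, 0.75, 0.09, 0.01))
  tabk <- tab
  tabk$areas <- tabk$areas * 123.4
  expect_equal(compute_fac(tab), compute_fac(tabk), tolerance = 1e-12)
  expect_equal(compute_op_percent(tab), compute_op_percent(tabk),
               tolerance = 1e-12)
  expect_equal(compute_fh(tab), compute_fh(tabk), tolerance = 1e-12)
})

test_that("implausible integrals are rejected, small negatives clamped", {
  tab <- count_table(oil_spec(1, 0, 0, 0))
  tab$areas[["E"]] <- 40  # drives SFA far below -2 %
  expect_error(compute_fac(tab), "implausible")

  tab2 <- count_table(oil_spec(1, 0, 0, 0))
  tab2$areas[["G"]] <- -0.02  # small negative from noise: PUFA slightly < 0
  r <- compute_fac(tab2)
  expect_equal(r$pufa, 0)
  expect_true("negative_fraction_clamped" %in% r$qc_flags)

  tab3 <- count_table(oil_spec(1, 0, 0, 0))
  tab3$areas[["F"]] <- 0
  expect_error(compute_fac(tab3), "F")
})

test_that("olefinic proton percentage and iodine value follow the regression", {
  tri <- count_table(oil_spec(0, 1, 0, 0))
  op <- compute_op_percent(tri)
  expect_equal(op, 100 * 6 / 104, tolerance = 1e-9)
  expect_equal(compute_iv(op), 10.54 + 13.39 * 600 / 104, tolerance = 1e-6)

  expect_equal(compute_op_percent(count_table(oil_spec(1, 0, 0, 0))), 0)
  expect_equal(compute_iv(0), 10.54)
  expect_equal(compute_iv(1), 23.93)
  expect_error(compute_iv(-1), ">= 0")
})

test_that("unsaturation measures increase with the linolenic fraction", {
  w_grid <- seq(0, 0.5, by = 0.05)
  ops <- vapply(w_grid, function(w)
    compute_op_percent(count_table(oil_spec(0.3 - 0.0, 0.7 - w, 0, w))),
    numeric(1))
  expect_true(all(diff(ops) > 0))
  expect_true(all(diff(compute_iv(ops)) > 0))
})

test_that("F/H flags free fatty acids and rejects degenerate input", {
  pure <- compute_fh(count_table(oil_spec(0, 1, 0, 0)))
  expect_equal(pure$fh_ratio, 1.5)
  expect_length(pure$qc_flags, 0)

  ffa <- compute_fh(count_table(
    oil_spec(0, 1, 0, 0, free_fatty_acid_fraction = 0.10)))
  expect_gt(ffa$fh_ratio, 1.5)
  expect_equal(ffa$fh_ratio, 6 / (4 * 0.9), tolerance = 1e-9)
  expect_true("FH_out_of_range" %in% ffa$qc_flags)

  bad <- count_table(oil_spec(0, 1, 0, 0))
  bad$areas[["H"]] <- 0
  expect_error(compute_fh(bad), "H")
})

test_that("free fatty acids push the measured F/H of a spectrum above 1.50", {
  p <- default_params()
  sp <- oil_spec(0.15, 0.75, 0.09, 0.01, free_fatty_acid_fraction = 0.10,
                 include_satellites = FALSE)
  s <- synthesize_spectrum(sp, p)
  res <- analyze_sample(s, default_regions())
  expect_gt(res$fh_ratio, 1.6)
  expect_true("FH_out_of_range" %in% res$qc_flags)
})

test_that("noiseless pipeline round-trip recovers the composition", {
  p <- default_params()
  truth <- c(sfa = 14.2, mufa = 77.6, pufa = 8.2)
  sp <- oil_spec(0.142, 0.776, 0.075, 0.007, include_satellites = FALSE)
  s <- run_pipeline(synthesize_fid(sp, p))
  res <- analyze_sample(s, default_regions(),
                        quality = quality_metrics(s))
  expect_equal(res$sfa, truth[["sfa"]], tolerance = 0.5 / truth[["sfa"]])
  expect_lt(abs(res$sfa - truth[["sfa"]]), 0.5)
  expect_lt(abs(res$mufa - truth[["mufa"]]), 0.5)
  expect_lt(abs(res$pufa - truth[["pufa"]]), 0.5)
  expect_equal(res$fh_ratio, 1.50, tolerance = 0.01)
  expect_length(setdiff(res$qc_flags, "negative_fraction_clamped"), 0)
})

test_that("quality failures propagate into the result flags", {
  p <- default_params()
  sp <- oil_spec(0.124, 0.851, 0.018, 0.007, seed = 21)
  sp$noise_sigma <- noise_sigma_for_snr(sp, p, snr = 100)  # below the floor
  s <- run_pipeline(synthesize_fid(sp, p))
  q <- quality_metrics(s)
  expect_false(q$passed[["snr"]])
  res <- analyze_sample(s, default_regions(), quality = q)
  expect_true("snr_fail" %in% res$qc_flags)

  # missing TMS flag travels from the spectrum into the result
  sp2 <- oil_spec(0.15, 0.75, 0.09, 0.01, tms_amplitude = 0,
                  noise_sigma = 2e-3, seed = 6)
  s2 <- run_pipeline(synthesize_fid(sp2, p))
  res2 <- analyze_sample(s2, default_regions())
  expect_true("tms_missing" %in% res2$qc_flags)
})
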
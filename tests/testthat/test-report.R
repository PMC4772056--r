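make_batch_root <- function(noise = 0) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  p <- acq_params()
  oils <- list(
    olive = oil_spec(0.15, 0.75, 0.09, 0.01, noise_sigma = noise, seed = 1),
    sunflower = oil_spec(0.11, 0.30, 0.58, 0.01, noise_sigma = noise, seed = 2),
    linseed = oil_spec(0.09, 0.18, 0.15, 0.58, noise_sigma = noise, seed = 3))
  for (nm in names(oils))
    write_bruker_dataset(synthesize_fid(oils[[nm]], p, sample_label = nm),
                         file.path(root, nm))
  root
}

test_that("batch analysis orders oils by their known unsaturation", {
  root <- make_batch_root()
  report <- run_batch(root)
  expect_equal(report$status$status, rep("ok", 3))
  by_label <- setNames(report$results, vapply(report$results, `[[`, "",
                                              "sample_label"))
  pufa <- vapply(by_label[c("linseed", "sunflower", "olive")], `[[`,
                 numeric(1), "pufa")
  expect_true(pufa[["linseed"]] > pufa[["sunflower"]])
  expect_true(pufa[["sunflower"]] > pufa[["olive"]])
  # iodine value ranks the same way
  iv <- vapply(by_label[c("linseed", "sunflower", "olive")], `[[`,
               numeric(1), "iv")
  expect_true(iv[["linseed"]] > iv[["sunflower"]])
  expect_true(iv[["sunflower"]] > iv[["olive"]])
})

test_that("an empty root yields an empty report and a corrupt sample a failed row", {
  empty <- withr::local_tempdir()
  report <- run_batch(empty)
  expect_equal(nrow(report$status), 0)

  root <- make_batch_root()
  con <- file(file.path(root, "sunflower", "fid"), "wb")
  writeBin(integer(10), con, size = 4L)
  close(con)
  report2 <- run_batch(root)
  expect_equal(sum(report2$status$status == "ok"), 2)
  failed <- report2$status[report2$status$status == "failed", ]
  expect_equal(basename(failed$path), "sunflower")
  expect_match(failed$reason, "mismatch")
})

fixed_report <- function() {
  res <- structure(list(
    sample_label = "sample1", sfa = 14.19, mufa = 77.58, pufa = 8.23,
    op_percent = 6.086, iv = 92.03, fh_ratio = 1.47,
    qc_flags = character(), integrals = NULL), class = "fac_result")
  structure(list(
    results = list(res),
    status = data.frame(path = "x/sample1", status = "ok", reason = "",
                        stringsAsFactors = FALSE),
    meta = list(version = "0.1.0", timestamp = "2026-01-01T00:00:00+0000")
  ), class = "batch_report")
}

test_that("csv export writes the documented layout and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  export_report(fixed_report(), f, format = "csv")
  lines <- readLines(f)
  expect_true(all(startsWith(lines[1:2], "#")))
  expect_equal(lines[3], "sample,mufa_pct,pufa_pct,sfa_pct,iv,fh_ratio,flags")
  expect_equal(lines[4], "sample1,77.58,8.23,14.19,92.03,1.47,")

  back <- read_report_csv(f)
  expect_equal(back$mufa_pct, 77.58)
  expect_equal(back$pufa_pct, 8.23)
  expect_equal(back$sfa_pct, 14.19)
  expect_equal(back$iv, 92.03)
  expect_equal(back$fh_ratio, 1.47)
})

test_that("exports are deterministic apart from the timestamp comment", {
  root <- make_batch_root()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_report(run_batch(root), f1)
  export_report(run_batch(root), f2)
  l1 <- grep("^# generated", readLines(f1), invert = TRUE, value = TRUE)
  l2 <- grep("^# generated", readLines(f2), invert = TRUE, value = TRUE)
  expect_identical(l1, l2)

  # txt export carries the same columns
  ft <- withr::local_tempfile(fileext = ".txt")
  export_report(fixed_report(), ft, format = "txt")
  txt <- readLines(ft)
  expect_true(any(grepl("sample1", txt)))
  expect_true(any(grepl("77.58", txt)))

  # empty report: header-only csv
  fe <- withr::local_tempfile(fileext = ".csv")
  empty <- withr::local_tempdir()
  export_report(run_batch(empty), fe)
  expect_equal(tail(readLines(fe), 1),
               "sample,mufa_pct,pufa_pct,sfa_pct,iv,fh_ratio,flags")
})

test_that("yaml configuration overrides defaults and reaches the analysis", {
  cfg_file <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "j_mode: separate",
    "fh_band: [1.40, 1.60]",
    "water:",
    "  delta30: 1.56",
    "  slope: -0.012",
    "  halfwidth: 0.08"
  ), cfg_file)
  cfg <- load_config(cfg_file)
  expect_equal(cfg$j_mode, "separate")
  expect_equal(cfg$fh_band, c(1.40, 1.60))
  expect_true(cfg$auto_phase)  # untouched default

  root <- make_batch_root()
  report <- run_batch(root, cfg_file)
  expect_equal(report$status$status, rep("ok", 3))
  expect_equal(report$results[[1]]$integrals$j_mode, "separate")
})

test_that("one synthetic sample is processed end to end in under ten seconds", {
  root <- withr::local_tempdir()
  p <- acq_params()
  write_bruker_dataset(
    synthesize_fid(oil_spec(0.15, 0.75, 0.09, 0.01), p, "timing"),
    file.path(root, "1"))
  elapsed <- system.time(report <- run_batch(root))[["elapsed"]]
  expect_equal(report$status$status, "ok")
  expect_lt(elapsed, 10)
})
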
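#' Analysis configuration
#'
#' Merges a YAML configuration file over the package defaults. Recognized
#' keys: `auto_phase`, `auto_reference` (logicals mirroring the two
#' processing checkboxes of the interactive workflow), `zero_fill_to`,
#' `j_mode`, `eq2`, `fh_band`, `snr_min`, `water` (list with `delta30`,
#' `slope`, `halfwidth`) and `regions` (named list of two-element ppm
#' windows overriding the defaults).
#'
#' @param path Optional YAML file.
#' @return A named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(
    auto_phase = TRUE,
    auto_reference = TRUE,
    zero_fill_to = 32768L,
    j_mode = "sn2_corrected",
    eq2 = "bis_allylic",
    fh_band = c(1.45, 1.55),
    snr_min = 250,
    water = list(delta30 = 1.56, slope = -0.012, halfwidth = 0.06),
    regions = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  cfg
}

config_regions <- function(cfg, field, temperature) {
  regions <- default_regions(field = field, temperature = temperature,
                             water_halfwidth = cfg$water$halfwidth)
  w <- water_shift(temperature, delta30 = cfg$water$delta30,
                   slope = cfg$water$slope)
  regions$exclusions$water <- c(w - cfg$water$halfwidth,
                                w + cfg$water$halfwidth)
  if (!is.null(cfg$regions))
    for (s in names(cfg$regions))
      regions$windows[[s]] <- as.numeric(cfg$regions[[s]])
  regions
}

#' Process and analyze one dataset directory
#'
#' The single-sample pipeline: read parameters and FID, Fourier transform
#' with zero filling, optional automatic phasing, baseline correction,
#' optional TMS referencing, quality metrics, region integration and
#' composition analysis.
#'
#' @param path Bruker dataset directory.
#' @param config Configuration list from [load_config()].
#' @return A `fac_result` (see [analyze_sample()]) with the
#'   [quality_metrics()] attached as attribute `quality`.
#' @export
process_dataset <- function(path, config = load_config()) {
  params <- read_acqus(path)
  fid <- read_fid(path, params)
  spec <- nmr_transform(fid, zero_fill_to = config$zero_fill_to)
  if (isTRUE(config$auto_phase)) {
    spec <- auto_phase(spec)
    spec <- baseline_correct(spec)
  }
  if (isTRUE(config$auto_reference)) spec <- reference_to_tms(spec)
  qc <- quality_metrics(spec, snr_min = config$snr_min)
  regions <- config_regions(config, params$spectrometer_frequency,
                            params$temperature)
  res <- analyze_sample(spec, regions, quality = qc,
                        j_mode = config$j_mode, eq2 = config$eq2,
                        fh_band = config$fh_band)
  attr(res, "quality") <- qc
  res
}

#' Batch analysis of every dataset under a directory
#'
#' Discovers datasets with [discover_datasets()] and runs [process_dataset()]
#' on each. A failure in one sample is recorded in its status row and never
#' aborts the batch.
#'
#' @param root Directory containing dataset subdirectories.
#' @param config Configuration list or path to a YAML file.
#' @return An object of class `batch_report`: list with `results` (one
#'   `fac_result` or `NULL` per dataset), `status` data.frame (`path`,
#'   `status`, `reason`) and `meta`.
#' @export
run_batch <- function(root, config = load_config()) {
  if (is.character(config)) config <- load_config(config)
  if (!dir.exists(root)) stop(sprintf("cannot read '%s'", root), call. = FALSE)
  paths <- discover_datasets(root)
  results <- vector("list", length(paths))
  status <- character(length(paths))
  reason <- character(length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch(process_dataset(paths[i], config), error = identity)
    if (inherits(res, "error")) {
      status[i] <- "failed"
      reason[i] <- conditionMessage(res)
    } else {
      results[[i]] <- res
      status[i] <- "ok"
      reason[i] <- ""
    }
  }
  structure(list(
    results = results,
    status = data.frame(path = paths, status = status, reason = reason,
                        stringsAsFactors = FALSE),
    meta = list(version = as.character(utils::packageVersion("oilnmr")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config)
  ), class = "batch_report")
}

report_rows <- function(report) {
  ok <- which(report$status$status == "ok")
  do.call(rbind, lapply(ok, function(i) {
    r <- report$results[[i]]
    data.frame(sample = r$sample_label,
               mufa_pct = round(r$mufa, 2), pufa_pct = round(r$pufa, 2),
               sfa_pct = round(r$sfa, 2), iv = round(r$iv, 2),
               fh_ratio = round(r$fh_ratio, 2),
               flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.batch_report <- function(x, ...) {
  rows <- report_rows(x)
  cat(sprintf("oil FAC batch report (%d ok, %d failed)\n",
              sum(x$status$status == "ok"), sum(x$status$status == "failed")))
  if (!is.null(rows)) print(rows, row.names = FALSE)
  failed <- x$status[x$status$status == "failed", , drop = FALSE]
  if (nrow(failed))
    for (i in seq_len(nrow(failed)))
      cat(sprintf("  FAILED %s: %s\n", failed$path[i], failed$reason[i]))
  invisible(x)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Export a batch report
#'
#' `csv` writes a comma-separated file with header
#' `sample,mufa_pct,pufa_pct,sfa_pct,iv,fh_ratio,flags`, all numbers to two
#' decimals and RFC-4180 quoting; run metadata (version, timestamp) lives in
#' leading `#` comment lines so repeated runs on identical inputs differ
#' only there. `txt` writes the same columns as an aligned fixed-width
#' table.
#'
#' @param report A [run_batch()] result.
#' @param path Output file.
#' @param format `"csv"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "txt")) {
  stopifnot(inherits(report, "batch_report"))
  format <- match.arg(format)
  rows <- report_rows(report)
  header <- c("sample", "mufa_pct", "pufa_pct", "sfa_pct", "iv", "fh_ratio",
              "flags")
  meta <- c(sprintf("# oilnmr %s", report$meta$version),
            sprintf("# generated: %s", report$meta$timestamp))

  if (format == "csv") {
    lines <- paste(header, collapse = ",")
    if (!is.null(rows)) {
      for (i in seq_len(nrow(rows))) {
        fields <- c(csv_quote(rows$sample[i]),
                    sprintf("%.2f", rows$mufa_pct[i]),
                    sprintf("%.2f", rows$pufa_pct[i]),
                    sprintf("%.2f", rows$sfa_pct[i]),
                    sprintf("%.2f", rows$iv[i]),
                    sprintf("%.2f", rows$fh_ratio[i]),
                    csv_quote(rows$flags[i]))
        lines <- c(lines, paste(fields, collapse = ","))
      }
    }
    writeLines(c(meta, lines), path)
  } else {
    if (is.null(rows)) {
      writeLines(c(meta, paste(header, collapse = "  ")), path)
    } else {
      txt <- utils::capture.output(print(
        data.frame(sample = rows$sample,
                   `MUFA (%)` = sprintf("%.2f", rows$mufa_pct),
                   `PUFA (%)` = sprintf("%.2f", rows$pufa_pct),
                   `SFA (%)` = sprintf("%.2f", rows$sfa_pct),
                   IV = sprintf("%.2f", rows$iv),
                   `F/H` = sprintf("%.2f", rows$fh_ratio),
                   flags = rows$flags,
                   check.names = FALSE, stringsAsFactors = FALSE),
        row.names = FALSE))
      writeLines(c(meta, txt), path)
    }
  }
  invisible(path)
}

#' Read back an exported csv report
#'
#' Skips the `#` metadata comment lines and parses the numeric columns, so
#' export followed by parse round-trips the reported values.
#'
#' @param path csv file written by [export_report()].
#' @return data.frame with the report columns.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(sample = "character", flags = "character"))
}
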
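#' Raw free induction decay
#'
#' The complex time-domain signal of one 1D experiment together with its
#' acquisition parameters. `length(signal)` must equal
#' `params$n_complex_points` (group delay already handled by the reader).
#'
#' @param signal Complex vector, one element per complex point.
#' @param params An [acq_params] object.
#' @param source_path Directory the data came from ("" for synthetic data).
#' @param sample_label Free-text sample identifier.
#' @return An object of class `raw_fid`.
#' @export
raw_fid <- function(signal, params, source_path = "", sample_label = "") {
  stopifnot(inherits(params, "acq_params"))
  signal <- as.complex(signal)
  if (length(signal) != params$n_complex_points)
    stop(sprintf("FID length %d does not match n_complex_points %d",
                 length(signal), params$n_complex_points), call. = FALSE)
  structure(list(signal = signal, params = params,
                 source_path = source_path, sample_label = sample_label),
            class = "raw_fid")
}

#' @export
print.raw_fid <- function(x, ...) {
  cat(sprintf("raw FID '%s': %d complex points, %.1f Hz sweep\n",
              x$sample_label, length(x$signal),
              x$params$spectral_width * x$params$spectrometer_frequency))
  invisible(x)
}

# Parse a JCAMP-style acqus file into a flat named list. Scalar values are
# returned as character; Bruker array blocks "##$D= (0..63) v0 v1 ..." are
# returned as a character vector of tokens.
parse_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[[2]]
      val <- m[[3]]
      if (grepl("^\\(", val)) {
        # array block: values follow the size declaration, possibly on
        # continuation lines up to the next ## entry
        vals <- sub("^\\([^)]*\\)\\s*", "", val)
        while (i < length(lines) && !grepl("^##", lines[[i + 1L]])) {
          i <- i + 1L
          vals <- paste(vals, lines[[i]])
        }
        out[[key]] <- strsplit(trimws(vals), "\\s+")[[1]]
      } else {
        out[[key]] <- trimws(val)
      }
    }
    i <- i + 1L
  }
  out
}

jcamp_num <- function(kv, key, default = NULL, file = "acqus") {
  if (is.null(kv[[key]])) return(default)
  v <- suppressWarnings(as.numeric(kv[[key]][[1]]))
  if (is.na(v))
    stop(sprintf("%s: cannot parse numeric value for key %s", file, key),
         call. = FALSE)
  v
}

#' Read acquisition parameters from a Bruker dataset directory
#'
#' Parses the JCAMP-style `acqus` file. Required keys are `SFO1` and `TD`
#' plus one of `SW` (ppm) or `SW_h` (Hz). `TD` counts stored real points, so
#' the complex point count is `TD/2`. Optional keys and their defaults:
#' `O1` (carrier Hz; default 5 ppm), `NS` 1, `DS` 0, `D1` 0 s (also accepted
#' as element 1 of a Bruker `D` array), `TE` sample temperature in Kelvin
#' (default 30 degrees C, with a warning), `BYTORDA` 0 = little-endian,
#' `DTYPA` 0 = int32 / 2 = float64, `GRPDLY` 0, `NC` intensity exponent 0.
#'
#' @param path Dataset directory containing `acqus`.
#' @return An [acq_params] object.
#' @export
read_acqus <- function(path) {
  f <- file.path(path, "acqus")
  if (!file.exists(f))
    stop(sprintf("'%s' is not an NMR dataset (no acqus file)", path),
         call. = FALSE)
  kv <- parse_jcamp(f)

  sfo1 <- jcamp_num(kv, "SFO1")
  td <- jcamp_num(kv, "TD")
  if (is.null(sfo1) || is.null(td))
    stop("acqus: required key SFO1 or TD missing", call. = FALSE)

  sw <- jcamp_num(kv, "SW")
  if (is.null(sw)) {
    sw_h <- jcamp_num(kv, "SW_h")
    if (is.null(sw_h)) stop("acqus: neither SW nor SW_h present", call. = FALSE)
    sw <- sw_h / sfo1
  }

  o1 <- jcamp_num(kv, "O1")
  offset <- if (is.null(o1)) 5 else o1 / sfo1

  d1 <- jcamp_num(kv, "D1")
  if (is.null(d1) && !is.null(kv[["D"]]) && length(kv[["D"]]) >= 2L) {
    d1 <- suppressWarnings(as.numeric(kv[["D"]][[2L]]))
    if (is.na(d1)) stop("acqus: cannot parse numeric value for key D",
                        call. = FALSE)
  }
  if (is.null(d1)) d1 <- 0

  te <- jcamp_num(kv, "TE")
  if (is.null(te)) {
    warning("acqus: no TE key; assuming 30 degrees C", call. = FALSE)
    temp <- 30
  } else {
    # TE is in Kelvin on modern instruments; tolerate Celsius values too
    temp <- if (te > 150) te - 273.15 else te
  }

  bytorda <- jcamp_num(kv, "BYTORDA", default = 0)
  dtypa <- jcamp_num(kv, "DTYPA", default = 0)

  acq_params(
    spectrometer_frequency = sfo1,
    spectral_width = sw,
    transmitter_offset = offset,
    n_complex_points = as.integer(td / 2),
    n_scans = as.integer(jcamp_num(kv, "NS", default = 1)),
    n_dummy_scans = as.integer(jcamp_num(kv, "DS", default = 0)),
    acquisition_time = NULL,
    recycle_delay = d1,
    temperature = temp,
    byte_order = if (bytorda == 1) "big" else "little",
    data_type = if (dtypa == 2) "float64" else "int32",
    group_delay = jcamp_num(kv, "GRPDLY", default = 0),
    scale_exponent = jcamp_num(kv, "NC", default = 0)
  )
}

#' Read a binary Bruker fid file
#'
#' Decodes the interleaved real/imaginary words into a complex series,
#' applies the stored intensity exponent (`value = int * 2^NC`) and removes
#' the digital-filter group delay: the first `round(GRPDLY)` complex points
#' are dropped and the series is zero-padded back to `n_complex_points`.
#'
#' @param path Dataset directory containing `fid`.
#' @param params An [acq_params] object, normally from [read_acqus()].
#' @return A [raw_fid] object. The sample label is taken from the first line
#'   of `pdata/1/title` when present, otherwise the directory name.
#' @export
read_fid <- function(path, params) {
  stopifnot(inherits(params, "acq_params"))
  f <- file.path(path, "fid")
  if (!file.exists(f))
    stop(sprintf("'%s' is not an NMR dataset (no fid file)", path),
         call. = FALSE)

  n_reals <- 2L * params$n_complex_points
  word <- if (params$data_type == "float64") 8L else 4L
  n_found <- file.info(f)$size / word
  if (n_found != n_reals)
    stop(sprintf("fid size mismatch: expected %d stored values, found %g",
                 n_reals, n_found), call. = FALSE)

  con <- file(f, "rb")
  on.exit(close(con))
  raw_vals <- if (params$data_type == "float64") {
    readBin(con, "numeric", n = n_reals, size = 8L, endian = params$byte_order)
  } else {
    readBin(con, "integer", n = n_reals, size = 4L, endian = params$byte_order)
  }
  raw_vals <- raw_vals * 2^params$scale_exponent

  sig <- complex(real = raw_vals[c(TRUE, FALSE)],
                 imaginary = raw_vals[c(FALSE, TRUE)])

  gd <- round(params$group_delay)
  if (gd > 0) {
    sig <- c(sig[-seq_len(gd)], complex(gd))
  }

  title_file <- file.path(path, "pdata", "1", "title")
  label <- if (file.exists(title_file)) {
    readLines(title_file, n = 1L, warn = FALSE)
  } else {
    basename(normalizePath(path, mustWork = FALSE))
  }

  raw_fid(sig, params, source_path = path, sample_label = label)
}

#' Write a dataset in Bruker directory layout
#'
#' Writes `fid` (32-bit little-endian integers, interleaved real/imaginary),
#' `acqus` and `pdata/1/title` so that [read_acqus()] / [read_fid()]
#' reproduce the input. Intensities are quantized: the writer picks the
#' smallest power-of-two exponent NC such that the rounded integers fit in
#' 30 bits, stores it in `acqus`, and the reader rescales, so the round-trip
#' error per point is at most `2^(NC-1)` (relative error about 1e-9 of the
#' maximum amplitude).
#'
#' @param fid A [raw_fid] object.
#' @param path Target dataset directory.
#' @param overwrite Overwrite an existing dataset directory?
#' @return `path`, invisibly.
#' @export
write_bruker_dataset <- function(fid, path, overwrite = FALSE) {
  stopifnot(inherits(fid, "raw_fid"))
  if (file.exists(file.path(path, "fid")) && !overwrite)
    stop(sprintf("dataset already exists at '%s' (use overwrite = TRUE)", path),
         call. = FALSE)
  dir.create(file.path(path, "pdata", "1"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create '%s'", path), call. = FALSE)

  p <- fid$params
  reals <- as.vector(rbind(Re(fid$signal), Im(fid$signal)))
  peak <- max(abs(reals))
  nc <- if (peak == 0) 0L else as.integer(ceiling(log2(peak / 2^29)))
  ints <- as.integer(round(reals / 2^nc))

  con <- file(file.path(path, "fid"), "wb")
  writeBin(ints, con, size = 4L, endian = "little")
  close(con)

  sw_hz <- p$spectral_width * p$spectrometer_frequency
  acqus <- c(
    "##TITLE= acquisition parameters",
    "##JCAMPDX= 5.0",
    "##DATATYPE= NMR FID",
    sprintf("##$SFO1= %.6f", p$spectrometer_frequency),
    sprintf("##$O1= %.6f", p$transmitter_offset * p$spectrometer_frequency),
    sprintf("##$SW= %.9g", p$spectral_width),
    sprintf("##$SW_h= %.6f", sw_hz),
    sprintf("##$TD= %d", 2L * p$n_complex_points),
    sprintf("##$NS= %d", p$n_scans),
    sprintf("##$DS= %d", p$n_dummy_scans),
    sprintf("##$D1= %.9g", p$recycle_delay),
    sprintf("##$TE= %.4f", p$temperature + 273.15),
    "##$BYTORDA= 0",
    "##$DTYPA= 0",
    "##$GRPDLY= 0",
    sprintf("##$NC= %d", nc),
    "##END="
  )
  writeLines(acqus, file.path(path, "acqus"))
  writeLines(fid$sample_label, file.path(path, "pdata", "1", "title"))
  invisible(path)
}

#' Find NMR datasets under a directory
#'
#' Returns the lexicographically sorted paths of all directories (the root
#' included) that contain both a `fid` and an `acqus` file. Non-dataset
#' directories are skipped silently; an empty result is not an error.
#'
#' @param root Directory to search.
#' @return Character vector of dataset paths, sorted.
#' @export
discover_datasets <- function(root) {
  if (!dir.exists(root)) return(character(0))
  dirs <- list.dirs(root, recursive = TRUE, full.names = TRUE)
  hit <- vapply(dirs, function(d)
    file.exists(file.path(d, "fid")) && file.exists(file.path(d, "acqus")),
    logical(1))
  sort(dirs[hit])
}
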
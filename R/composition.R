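#' Fatty acid composition from signal integrals
#'
#' The SFA / MUFA / PUFA partition of the acyl chains, computed from the
#' integral table with the proton-count equations (areas in arbitrary common
#' units; F is the alpha-carboxyl CH2, 2 protons per acyl chain):
#'
#' \deqn{SFA = (4A + 4B - 3E) / (6F)}
#' \deqn{MUFA = (4B + 3E - 6G) / (6F)}
#' \deqn{PUFA = (3G - 2B) / (3F)}
#'
#' The mono-unsaturated equation uses the bis-allylic signal G: under the
#' proton-count model this is the form that closes the mass balance
#' (SFA + MUFA + PUFA = 100 identically) and assigns a pure 18:1 oil 100\%
#' MUFA. A variant with the glycerol signal H in its place is available as
#' `eq2 = "as_printed"` for comparison; it does not close the balance.
#'
#' Raw fractions must lie in \[-0.02, 1.02\]; values outside that band abort
#' with an "implausible integrals" error, while small negatives (noise) are
#' clamped to zero and flagged.
#'
#' @param table An [integral_table] (any positive scaling).
#' @param eq2 Which mono-unsaturated equation to use.
#' @return List with `sfa`, `mufa`, `pufa` (percentages) and `qc_flags`.
#' @examples
#' tab <- integral_table(c(A = 9, B = 0, C = 60, D = 6, E = 12, F = 6,
#'                         G = 0, H = 4, I = 1, J = 6), "triolein")
#' compute_fac(tab)  # 100% MUFA
#' @export
compute_fac <- function(table, eq2 = c("bis_allylic", "as_printed")) {
  stopifnot(inherits(table, "integral_table"))
  eq2 <- match.arg(eq2)
  a <- table$areas
  f <- a[["F"]]
  if (!is.finite(f) || f <= 0)
    stop("area of signal F must be positive", call. = FALSE)

  sfa <- (4 * a[["A"]] + 4 * a[["B"]] - 3 * a[["E"]]) / (6 * f)
  mufa <- if (eq2 == "bis_allylic") {
    (4 * a[["B"]] + 3 * a[["E"]] - 6 * a[["G"]]) / (6 * f)
  } else {
    (4 * a[["B"]] + 3 * a[["E"]] - 6 * a[["H"]]) / (6 * f)
  }
  pufa <- (3 * a[["G"]] - 2 * a[["B"]]) / (3 * f)

  vals <- c(sfa = sfa, mufa = mufa, pufa = pufa)
  if (any(vals < -0.02 | vals > 1.02))
    stop(sprintf(
      "implausible integrals: raw fractions (%.3f, %.3f, %.3f) outside [-0.02, 1.02]",
      sfa, mufa, pufa), call. = FALSE)
  flags <- character()
  if (any(vals < 0)) {
    vals[vals < 0] <- 0
    flags <- "negative_fraction_clamped"
  }
  list(sfa = 100 * vals[["sfa"]], mufa = 100 * vals[["mufa"]],
       pufa = 100 * vals[["pufa"]], qc_flags = flags)
}

#' Percentage of olefinic protons
#'
#' `%OP = 100 * J / (A + B + ... + J)`: the olefinic area as a share of all
#' assigned oil signal areas (TMS, water and satellite-only regions are not
#' part of the denominator). J is used as produced by the integration mode
#' (sn-2-corrected or separate). A slightly negative J (up to 2\% of the
#' total, from noise or the sn-2 correction of a saturated oil) is clamped
#' to zero.
#'
#' @param table An [integral_table].
#' @return Olefinic proton percentage (scale 0-100).
#' @export
compute_op_percent <- function(table) {
  stopifnot(inherits(table, "integral_table"))
  a <- table$areas[c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")]
  total <- sum(a)
  if (!is.finite(total) || total <= 0)
    stop("total signal area must be positive", call. = FALSE)
  j <- a[["J"]]
  if (j < 0) {
    if (-j > 0.02 * total)
      stop("implausible integrals: strongly negative olefinic area", call. = FALSE)
    j <- 0
  }
  100 * j / total
}

#' Iodine value from the olefinic proton percentage
#'
#' Linear regression of the iodine value (g I2 per 100 g of oil) on the
#' olefinic proton percentage: `IV = 10.54 + 13.39 * %OP`.
#'
#' @param op_percent Olefinic proton percentage (>= 0).
#' @return Iodine value.
#' @examples
#' compute_iv(0)  # 10.54, a fully saturated fat
#' @export
compute_iv <- function(op_percent) {
  if (any(op_percent < 0)) stop("op_percent must be >= 0", call. = FALSE)
  10.54 + 13.39 * op_percent
}

#' F/H triglyceride validity ratio
#'
#' Ratio of the alpha-carboxyl CH2 area (6 protons per intact triglyceride)
#' to the glycerol sn-1,3 CH2 area (4 protons): 1.50 for intact
#' triglycerides. Higher values indicate free fatty acids or partial
#' glycerides, which make the composition equations unreliable, so values
#' outside `band` raise the `FH_out_of_range` flag.
#'
#' @param table An [integral_table].
#' @param band Acceptance band for the ratio.
#' @return List with `fh_ratio` and `qc_flags`.
#' @export
compute_fh <- function(table, band = c(1.45, 1.55)) {
  stopifnot(inherits(table, "integral_table"))
  h <- table$areas[["H"]]
  if (!is.finite(h) || h <= 0)
    stop("area of signal H must be positive", call. = FALSE)
  ratio <- table$areas[["F"]] / h
  flags <- if (ratio < band[1] || ratio > band[2]) "FH_out_of_range"
  else character()
  list(fh_ratio = ratio, qc_flags = flags)
}

#' Full per-sample analysis of a processed spectrum
#'
#' Composes [integrate_regions()], [normalize_table()] and the composition
#' operations into one result record, merging quality-control flags from the
#' spectrum (e.g. `tms_missing`) and from [quality_metrics()] (`snr_fail`).
#'
#' @param spec A processed, referenced [nmr_spectrum].
#' @param regions A [default_regions()] object.
#' @param quality Optional [quality_metrics()] result.
#' @param j_mode Olefinic integration mode, see [integrate_regions()].
#' @param eq2 Mono-unsaturated equation variant, see [compute_fac()].
#' @param fh_band Acceptance band for the F/H ratio.
#' @return An object of class `fac_result` with fields `sample_label`,
#'   `sfa`, `mufa`, `pufa`, `op_percent`, `iv`, `fh_ratio`, `qc_flags` and
#'   the normalized `integrals`.
#' @export
analyze_sample <- function(spec, regions = default_regions(), quality = NULL,
                           j_mode = c("sn2_corrected", "separate"),
                           eq2 = c("bis_allylic", "as_printed"),
                           fh_band = c(1.45, 1.55)) {
  j_mode <- match.arg(j_mode)
  eq2 <- match.arg(eq2)
  tab <- normalize_table(integrate_regions(spec, regions, j_mode = j_mode))

  fac <- compute_fac(tab, eq2 = eq2)
  op <- compute_op_percent(tab)
  fh <- compute_fh(tab, band = fh_band)

  flags <- c(fac$qc_flags, fh$qc_flags)
  if ("tms_missing" %in% spec$flags) flags <- c(flags, "tms_missing")
  if ("phase_fallback_magnitude" %in% spec$flags)
    flags <- c(flags, "phase_fallback_magnitude")
  if (!is.null(quality) && !quality$passed[["snr"]])
    flags <- c(flags, "snr_fail")

  structure(list(
    sample_label = tab$sample_label,
    sfa = fac$sfa, mufa = fac$mufa, pufa = fac$pufa,
    op_percent = op, iv = compute_iv(op), fh_ratio = fh$fh_ratio,
    qc_flags = unique(flags), integrals = tab
  ), class = "fac_result")
}

#' @export
print.fac_result <- function(x, ...) {
  cat(sprintf("%s\n", x$sample_label))
  cat(sprintf("  MUFA %6.2f %%   PUFA %6.2f %%   SFA %6.2f %%\n",
              x$mufa, x$pufa, x$sfa))
  cat(sprintf("  IV %6.2f   F/H %.2f   (%%OP %.3f)\n",
              x$iv, x$fh_ratio, x$op_percent))
  if (length(x$qc_flags))
    cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}
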
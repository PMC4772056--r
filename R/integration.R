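#' Default integration regions for oil spectra
#'
#' The ten named signal windows (ppm) used for quantitation, the residual
#' water exclusion window centred on [water_shift()] of the sample
#' temperature, and the joint olefinic window used by the sn-2-corrected
#' J mode. The window bounds are standard vegetable-oil values; the
#' linolenic CH3 window B (0.93-1.03 ppm) lies within the 0.82-1.03 ppm
#' span of the terminal-methyl region.
#'
#' A field-dependence check is performed on construction: if a 13C
#' satellite of the terminal CH3 signal A falls inside the B window (which
#' happens at fields above roughly 400 MHz but not at 300 MHz) a warning is
#' emitted and the attribute `satellite_in_B` is set.
#'
#' @param field Spectrometer frequency in MHz.
#' @param temperature Sample temperature in degrees C.
#' @param water_halfwidth Half-width of the water exclusion window, ppm.
#' @param j_ch One-bond CH coupling (Hz) for the satellite check.
#' @param a_center Centre of signal A used for the satellite check, ppm.
#' @return An object of class `signal_regions`: list with `windows` (named
#'   list of `c(lo, hi)`), `exclusions`, `j_sn2_window` and attribute
#'   `satellite_in_B`.
#' @export
default_regions <- function(field = 300.13, temperature = 30,
                            water_halfwidth = 0.06, j_ch = 125,
                            a_center = 0.88) {
  stopifnot(field > 0)
  windows <- list(
    A = c(0.82, 0.93), B = c(0.93, 1.03), C = c(1.03, 1.42),
    D = c(1.42, 1.75), E = c(1.90, 2.15), F = c(2.15, 2.45),
    G = c(2.65, 2.90), H = c(4.05, 4.40), I = c(5.18, 5.28),
    J = c(5.28, 5.50))
  w <- water_shift(temperature)
  exclusions <- list(water = c(w - water_halfwidth, w + water_halfwidth))

  sat <- satellite_positions(a_center, field, j_ch)
  in_b <- any(sat >= windows$B[1] & sat <= windows$B[2])
  if (in_b)
    warning(sprintf(
      "13C satellite of signal A (%.3f ppm) falls inside the B window at %g MHz",
      sat[sat >= windows$B[1] & sat <= windows$B[2]][1], field), call. = FALSE)

  structure(list(windows = windows, exclusions = exclusions,
                 j_sn2_window = c(5.10, 5.50),
                 field = field, temperature = temperature),
            class = "signal_regions", satellite_in_B = in_b)
}

#' @export
print.signal_regions <- function(x, ...) {
  cat(sprintf("signal regions (%g MHz, %g degrees C):\n", x$field, x$temperature))
  for (s in names(x$windows))
    cat(sprintf("  %s: %5.2f - %5.2f ppm\n", s, x$windows[[s]][1],
                x$windows[[s]][2]))
  for (e in names(x$exclusions))
    cat(sprintf("  excluded (%s): %5.2f - %5.2f ppm\n", e,
                x$exclusions[[e]][1], x$exclusions[[e]][2]))
  invisible(x)
}

# Trapezoidal integral of the absorption trace over [lo, hi] ppm, minus any
# exclusion sub-windows.
trapz_window <- function(spec, lo, hi, exclusions = list()) {
  area_of <- function(a, b) {
    sel <- which(spec$ppm >= a & spec$ppm <= b)
    if (length(sel) < 2L) return(0)
    pp <- spec$ppm[sel]
    yy <- spec$real[sel]
    abs(sum(diff(pp) * (yy[-1] + yy[-length(yy)]) / 2))
  }
  total <- area_of(lo, hi)
  for (ex in exclusions) {
    a <- max(lo, ex[1]); b <- min(hi, ex[2])
    if (a < b) total <- total - area_of(a, b)
  }
  total
}

#' Integral table of one sample
#'
#' Raw (or normalized) areas of the ten named signals. In `"F6"`
#' normalization all areas are rescaled so signal F, the alpha-carboxyl CH2
#' of the three acyl chains, equals exactly 6 proton-equivalents per mole of
#' triglyceride.
#'
#' @param areas Named numeric vector over A-J.
#' @param sample_label Sample identifier.
#' @param mode Normalization mode: `"raw"`, `"F6"` or `"per_proton"`.
#' @param j_mode How the olefinic area J was obtained (see
#'   [integrate_regions()]).
#' @return An object of class `integral_table`.
#' @export
integral_table <- function(areas, sample_label = "", mode = "raw",
                           j_mode = "sn2_corrected") {
  stopifnot(all(c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J") %in%
                  names(areas)))
  structure(list(areas = areas, sample_label = sample_label, mode = mode,
                 j_mode = j_mode),
            class = "integral_table")
}

#' @export
print.integral_table <- function(x, ...) {
  cat(sprintf("integrals for '%s' (%s, J: %s)\n", x$sample_label, x$mode,
              x$j_mode))
  print(round(x$areas, 4))
  invisible(x)
}

#' Integrate the named signal regions of a processed spectrum
#'
#' Trapezoidal integration of the absorption trace over each window, with
#' exclusion sub-windows (residual water) removed. Two treatments of the
#' olefinic/sn-2 overlap are available:
#'
#' * `"sn2_corrected"` (default): the olefinic area J is the joint
#'   5.10-5.50 ppm integral minus one proton-equivalent estimated as H/4,
#'   because at 300 MHz the glycerol sn-2 CH multiplet sits under the
#'   olefinic envelope; I is then reported as H/4.
#' * `"separate"`: I and J are integrated over their own windows with no
#'   correction.
#'
#' @param spec A processed, referenced [nmr_spectrum].
#' @param regions A [default_regions()] object.
#' @param j_mode `"sn2_corrected"` or `"separate"`.
#' @param sample_label Label for the resulting table (defaults to the label
#'   recorded by the transform step, if any).
#' @return An [integral_table] in `"raw"` mode.
#' @export
integrate_regions <- function(spec, regions = default_regions(),
                              j_mode = c("sn2_corrected", "separate"),
                              sample_label = NULL) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(regions, "signal_regions"))
  j_mode <- match.arg(j_mode)
  if (is.null(sample_label)) {
    sample_label <- ""
    for (pr in spec$proc)
      if (!is.null(pr$sample_label)) sample_label <- pr$sample_label
  }

  lo_ax <- min(spec$ppm); hi_ax <- max(spec$ppm)
  for (s in names(regions$windows)) {
    win <- regions$windows[[s]]
    if (win[1] < lo_ax || win[2] > hi_ax)
      stop(sprintf("region %s (%g-%g ppm) lies outside the spectral axis", s,
                   win[1], win[2]), call. = FALSE)
  }

  areas <- vapply(regions$windows, function(win)
    trapz_window(spec, win[1], win[2], regions$exclusions), numeric(1))

  if (j_mode == "sn2_corrected") {
    joint <- trapz_window(spec, regions$j_sn2_window[1],
                          regions$j_sn2_window[2], regions$exclusions)
    areas[["I"]] <- areas[["H"]] / 4
    areas[["J"]] <- joint - areas[["H"]] / 4
  }
  integral_table(areas, sample_label = sample_label, mode = "raw",
                 j_mode = j_mode)
}

#' Normalize an integral table
#'
#' `"F6"` rescales all areas so that F equals exactly 6, putting the table in
#' protons-per-mole-of-triglyceride units; downstream composition results are
#' invariant under this rescaling (and under any positive scaling of the raw
#' areas).
#'
#' @param table An [integral_table].
#' @param mode `"F6"` or `"raw"` (no-op).
#' @return The normalized [integral_table].
#' @export
normalize_table <- function(table, mode = c("F6", "raw")) {
  stopifnot(inherits(table, "integral_table"))
  mode <- match.arg(mode)
  if (mode == "raw") return(table)
  f <- table$areas[["F"]]
  if (!is.finite(f) || f <= 0)
    stop("cannot normalize: area of signal F is not positive", call. = FALSE)
  table$areas <- table$areas * (6 / f)
  table$mode <- "F6"
  table
}
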
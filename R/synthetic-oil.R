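#' Residual-water chemical shift as a function of temperature
#'
#' Linear model for the shift of the residual water line of an oil/CDCl3
#' sample: `delta(T) = delta30 + slope * (T - 30)`. The defaults (1.56 ppm at
#' 30 degrees C, -0.012 ppm per degree) are literature-informed configuration
#' values; the direction (upfield with increasing temperature) is the
#' physically expected one.
#'
#' @param temperature Sample temperature in degrees C (0-80).
#' @param delta30 Shift at 30 degrees C, ppm.
#' @param slope Shift change per degree C, ppm.
#' @return Chemical shift in ppm.
#' @examples
#' water_shift(30)  # 1.56
#' water_shift(50)  # 1.32
#' @export
water_shift <- function(temperature, delta30 = 1.56, slope = -0.012) {
  if (any(temperature < 0 | temperature > 80))
    stop("temperature must lie in 0-80 degrees C", call. = FALSE)
  delta30 + slope * (temperature - 30)
}

#' Ground-truth description of a synthetic oil sample
#'
#' The four acyl-chain molar fractions (all chains modelled as C18) must sum
#' to 1. `free_fatty_acid_fraction` emulates hydrolysed material: that
#' fraction of acyl chains lacks a glycerol backbone, which lowers the
#' glycerol sn-1,3 (H) and sn-2 (I) signals relative to the alpha-CH2 signal
#' F and pushes the F/H ratio above 1.50.
#'
#' @param sfa,oleic,linoleic,linolenic Molar fractions of saturated, 18:1,
#'   18:2 and 18:3 acyl chains; must sum to 1 (tolerance 1e-9).
#' @param free_fatty_acid_fraction Fraction of acyl chains present as free
#'   fatty acids (default 0).
#' @param temperature Sample temperature in degrees C; positions the water
#'   line via [water_shift()].
#' @param noise_sigma Gaussian noise s.d. per time-domain point (0 = none);
#'   see [noise_sigma_for_snr()] for setting a target spectral S/N.
#' @param line_width Lorentzian full width at half maximum in Hz. The default
#'   0.68 Hz matches a well-shimmed reference line at 300 MHz.
#' @param water_amplitude Water line area in proton-equivalents per mole TG.
#' @param tms_amplitude TMS reference line area in proton-equivalents.
#' @param include_satellites Add 13C satellites at +/- 1J(CH)/2 with 0.55\%
#'   of the parent area per side?
#' @param j_ch One-bond CH coupling constant in Hz used for satellite
#'   placement.
#' @param seed Integer seed making the time-domain noise reproducible.
#' @return An object of class `oil_spec`.
#' @examples
#' olive <- oil_spec(sfa = 0.15, oleic = 0.75, linoleic = 0.09, linolenic = 0.01)
#' proton_counts(olive)
#' @export
oil_spec <- function(sfa = 0.15, oleic = 0.75, linoleic = 0.09,
                     linolenic = 0.01, free_fatty_acid_fraction = 0,
                     temperature = 30, noise_sigma = 0, line_width = 0.68,
                     water_amplitude = 0.5, tms_amplitude = 2,
                     include_satellites = TRUE, j_ch = 125, seed = 1L) {
  fr <- c(sfa = sfa, oleic = oleic, linoleic = linoleic, linolenic = linolenic)
  if (any(fr < 0 | fr > 1))
    stop("chain fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop(sprintf("chain fractions must sum to 1 (got %.12f)", sum(fr)),
         call. = FALSE)
  if (free_fatty_acid_fraction < 0 || free_fatty_acid_fraction > 1)
    stop("free_fatty_acid_fraction must lie in [0, 1]", call. = FALSE)
  if (line_width <= 0) stop("line_width must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  water_shift(temperature)  # validates the temperature range

  structure(list(
    sfa = sfa, oleic = oleic, linoleic = linoleic, linolenic = linolenic,
    free_fatty_acid_fraction = free_fatty_acid_fraction,
    temperature = temperature, noise_sigma = noise_sigma,
    line_width = line_width, water_amplitude = water_amplitude,
    tms_amplitude = tms_amplitude, include_satellites = include_satellites,
    j_ch = j_ch, seed = as.integer(seed)
  ), class = "oil_spec")
}

#' @export
print.oil_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic oil: SFA %.3f / 18:1 %.3f / 18:2 %.3f / 18:3 %.3f (FFA %.2f)\n",
    x$sfa, x$oleic, x$linoleic, x$linolenic, x$free_fatty_acid_fraction))
  cat(sprintf("  %g degrees C, lw %.2f Hz, noise sd %g, satellites %s, seed %d\n",
              x$temperature, x$line_width, x$noise_sigma,
              if (x$include_satellites) "on" else "off", x$seed))
  invisible(x)
}

#' Default chemical shifts of the oil signal regions
#'
#' Centres (ppm) of the ten assigned oil signals: A terminal CH3 of
#' non-linolenic chains, B terminal CH3 of linolenic chains, C bulk chain
#' CH2, D beta-CH2, E allylic CH2, F alpha-carboxyl CH2, G bis-allylic CH2,
#' H glycerol sn-1,3 CH2 (an AB system modelled as two lines), I glycerol
#' sn-2 CH, J olefinic CH. Standard vegetable-oil values; all configurable.
#'
#' @return Named list of ppm positions (H has two).
#' @export
oil_line_centers <- function() {
  list(A = 0.88, B = 0.97, C = 1.29, D = 1.61, E = 2.02, F = 2.30,
       G = 2.77, H = c(4.14, 4.29), I = 5.26, J = 5.35, TMS = 0)
}

#' Protons per mole of triglyceride contributing to each signal
#'
#' Book-keeping of the C18 chain structures. With chain fractions
#' x (saturated), y (18:1), z (18:2), w (18:3):
#' A = 9(1-w), B = 9w, C = 84x + 60y + 42z + 24w, D = 6,
#' E = 12(y+z+w), F = 6, G = 6z + 12w, H = 4, I = 1, J = 6y + 12z + 18w.
#' The totals reproduce the molecular proton counts (tristearin C57H110O6:
#' 110 H; triolein C57H104O6: 104 H; trilinolenin C57H92O6: 92 H). A
#' non-zero free fatty acid fraction f scales the glycerol signals H and I
#' by (1 - f).
#'
#' @param spec An [oil_spec] object.
#' @return Named numeric vector over signals A-J.
#' @export
proton_counts <- function(spec) {
  stopifnot(inherits(spec, "oil_spec"))
  x <- spec$sfa; y <- spec$oleic; z <- spec$linoleic; w <- spec$linolenic
  f <- spec$free_fatty_acid_fraction
  c(A = 9 * (1 - w),
    B = 9 * w,
    C = 84 * x + 60 * y + 42 * z + 24 * w,
    D = 6,
    E = 12 * (y + z + w),
    F = 6,
    G = 6 * z + 12 * w,
    H = 4 * (1 - f),
    I = 1 * (1 - f),
    J = 6 * y + 12 * z + 18 * w)
}

#' 13C satellite positions of a proton line
#'
#' Satellites of a carbon-bound proton signal sit at
#' `center +/- j_ch / 2 / field` ppm, so their ppm offset shrinks with
#' increasing field: at 300 MHz the satellites of the 0.88 ppm terminal-CH3
#' signal fall outside the 0.93-1.03 ppm window of the linolenic CH3 signal,
#' at 500 MHz the upper one falls inside it.
#'
#' @param center Parent line position, ppm.
#' @param field Spectrometer frequency, MHz.
#' @param j_ch One-bond CH coupling, Hz.
#' @return Numeric vector of the two satellite positions in ppm.
#' @export
satellite_positions <- function(center, field, j_ch = 125) {
  center + c(-1, 1) * j_ch / 2 / field
}

#' Line catalog of a synthetic oil spectrum
#'
#' Expands an [oil_spec] into individual Lorentzian lines: the ten oil
#' signals (H as two lines), the TMS reference at 0 ppm, the residual water
#' line at [water_shift()] of the sample temperature, and, when enabled, two
#' 13C satellites per carbon-bound line with 0.55\% of the parent area each.
#'
#' @param spec An [oil_spec] object.
#' @param field Spectrometer frequency in MHz (places the satellites).
#' @param centers Line positions, as returned by [oil_line_centers()].
#' @return A data.frame with columns `name`, `ppm`, `protons`.
#' @export
line_catalog <- function(spec, field = 300.13, centers = oil_line_centers()) {
  stopifnot(inherits(spec, "oil_spec"))
  counts <- proton_counts(spec)
  name <- character(0); ppm <- numeric(0); protons <- numeric(0); sat <- logical(0)
  for (s in names(counts)) {
    pos <- centers[[s]]
    name <- c(name, rep(s, length(pos)))
    ppm <- c(ppm, pos)
    protons <- c(protons, rep(counts[[s]] / length(pos), length(pos)))
    sat <- c(sat, rep(TRUE, length(pos)))
  }
  name <- c(name, "TMS", "water")
  ppm <- c(ppm, centers$TMS, water_shift(spec$temperature))
  protons <- c(protons, spec$tms_amplitude, spec$water_amplitude)
  sat <- c(sat, TRUE, FALSE)

  cat_df <- data.frame(name = name, ppm = ppm, protons = protons,
                       stringsAsFactors = FALSE)
  if (spec$include_satellites) {
    parents <- cat_df[sat & cat_df$protons > 0, , drop = FALSE]
    if (nrow(parents)) {
      sat_df <- do.call(rbind, lapply(seq_len(nrow(parents)), function(i) {
        data.frame(name = paste0(parents$name[i], "_sat"),
                   ppm = satellite_positions(parents$ppm[i], field, spec$j_ch),
                   protons = 0.0055 * parents$protons[i],
                   stringsAsFactors = FALSE)
      }))
      cat_df <- rbind(cat_df, sat_df)
    }
  }
  cat_df[cat_df$protons > 0, , drop = FALSE]
}

# Restore the caller's RNG state after seeded noise generation.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate the free induction decay of a synthetic oil
#'
#' The time-domain signal is a sum of complex exponentials, one per catalog
#' line: amplitude proportional to its proton count, frequency at its offset
#' from the carrier, decay rate `pi * line_width`. Gaussian noise of s.d.
#' `noise_sigma` is added independently to the real and imaginary parts of
#' every point, seeded by `spec$seed`, so the same spec always yields the
#' same FID. Lines outside the spectral window are dropped with a warning.
#'
#' @param spec An [oil_spec] object.
#' @param params An [acq_params] object.
#' @return A [raw_fid] object with `sample_label = "synthetic"` unless
#'   relabelled.
#' @param sample_label Label stored in the FID.
#' @export
synthesize_fid <- function(spec, params = acq_params(),
                           sample_label = "synthetic") {
  stopifnot(inherits(spec, "oil_spec"), inherits(params, "acq_params"))
  cat_df <- keep_in_window(line_catalog(spec, params$spectrometer_frequency),
                           params)
  sw_hz <- params$spectral_width * params$spectrometer_frequency
  n <- params$n_complex_points
  t <- (0:(n - 1L)) / sw_hz
  sig <- complex(n)
  for (i in seq_len(nrow(cat_df))) {
    f0 <- (cat_df$ppm[i] - params$transmitter_offset) *
      params$spectrometer_frequency
    sig <- sig + cat_df$protons[i] *
      exp((2i * pi * f0 - pi * spec$line_width) * t)
  }
  if (spec$noise_sigma > 0) {
    sig <- sig + with_seed(spec$seed, {
      complex(real = stats::rnorm(n, sd = spec$noise_sigma),
              imaginary = stats::rnorm(n, sd = spec$noise_sigma))
    })
  }
  raw_fid(sig, params, source_path = "", sample_label = sample_label)
}

keep_in_window <- function(cat_df, params) {
  lo <- params$transmitter_offset - params$spectral_width / 2
  hi <- params$transmitter_offset + params$spectral_width / 2
  out <- cat_df$ppm < lo | cat_df$ppm > hi
  if (any(out)) {
    warning(sprintf("%d line(s) fall outside the spectral window and are dropped",
                    sum(out)), call. = FALSE)
    cat_df <- cat_df[!out, , drop = FALSE]
  }
  cat_df
}

#' Synthesize a frequency-domain oil spectrum directly
#'
#' Evaluates the analytic Fourier transform of each catalog line (a complex
#' Lorentzian) on the digital frequency grid, scaled to match
#' [nmr_transform()] applied to [synthesize_fid()], so the two routes agree
#' within discretization error. With `noiseless = FALSE` the spectrum is
#' instead produced by transforming a noisy FID.
#'
#' @param spec An [oil_spec] object.
#' @param params An [acq_params] object.
#' @param n_points Number of real spectral points (default 32768).
#' @param noiseless Skip time-domain noise?
#' @return An [nmr_spectrum] object.
#' @export
synthesize_spectrum <- function(spec, params = acq_params(),
                                n_points = 32768L, noiseless = TRUE) {
  stopifnot(inherits(spec, "oil_spec"), inherits(params, "acq_params"))
  if (!noiseless)
    return(nmr_transform(synthesize_fid(spec, params), zero_fill_to = n_points))

  cat_df <- keep_in_window(line_catalog(spec, params$spectrometer_frequency),
                           params)
  ax <- ppm_axis(params, n_points)
  sw_hz <- params$spectral_width * params$spectrometer_frequency
  f <- (ax - params$transmitter_offset) * params$spectrometer_frequency
  z <- complex(length(f))
  for (i in seq_len(nrow(cat_df))) {
    f0 <- (cat_df$ppm[i] - params$transmitter_offset) *
      params$spectrometer_frequency
    z <- z + cat_df$protons[i] * sw_hz /
      (pi * spec$line_width + 2i * pi * (f - f0))
  }
  nmr_spectrum(Re(z), Im(z), ax, params,
               proc = list(list(step = "synthesize_spectrum",
                                line_width = spec$line_width)))
}

#' Time-domain noise level for a target spectral signal-to-noise ratio
#'
#' Inverts the S/N convention `peak / (2 * sd(noise))`: complex white noise
#' of s.d. `sigma` per time-domain point yields frequency-domain noise of
#' s.d. `sigma * sqrt(n)` after an unnormalized FFT of `n` recorded points,
#' so `sigma = peak_height / (2 * snr * sqrt(n))`. The reference peak is the
#' tallest point of the noiseless spectrum inside `window` (default the
#' linolenic CH3 window B, the smallest routinely integrated signal).
#'
#' @param spec An [oil_spec] object (its `noise_sigma` is ignored).
#' @param params An [acq_params] object.
#' @param snr Target signal-to-noise ratio.
#' @param window ppm window containing the reference peak.
#' @param n_points Spectral points used for the reference synthesis.
#' @return Time-domain noise s.d. achieving approximately the target S/N.
#' @export
noise_sigma_for_snr <- function(spec, params = acq_params(), snr = 250,
                                window = c(0.93, 1.03), n_points = 32768L) {
  clean <- spec
  clean$noise_sigma <- 0
  s <- synthesize_spectrum(clean, params, n_points = n_points)
  sel <- s$ppm >= window[1] & s$ppm <= window[2]
  peak <- max(s$real[sel])
  if (peak <= 0) stop("no reference signal in the S/N window", call. = FALSE)
  peak / (2 * snr * sqrt(params$n_complex_points))
}
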
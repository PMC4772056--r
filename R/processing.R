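#' Frequency-domain spectrum
#'
#' Absorption (real) and dispersion (imaginary) intensities on a descending
#' ppm axis spanning `transmitter_offset +/- spectral_width/2`, together with
#' the acquisition parameters and an ordered provenance list recording every
#' processing step applied.
#'
#' @param real,imag Real and imaginary intensity vectors.
#' @param ppm Strictly descending ppm axis of the same length.
#' @param params An [acq_params] object.
#' @param proc List of provenance entries.
#' @param flags Character vector of quality flags accumulated by processing.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(real, imag, ppm, params, proc = list(),
                         flags = character()) {
  stopifnot(inherits(params, "acq_params"),
            length(real) == length(imag), length(real) == length(ppm))
  if (any(diff(ppm) >= 0))
    stop("ppm axis must be strictly descending", call. = FALSE)
  structure(list(real = real, imag = imag, ppm = ppm, params = params,
                 proc = proc, flags = flags),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("1H spectrum: %d points, %.2f to %.2f ppm at %.2f MHz\n",
              length(x$real), max(x$ppm), min(x$ppm),
              x$params$spectrometer_frequency))
  if (length(x$proc))
    cat("  processing:", paste(vapply(x$proc, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot an absorption spectrum
#'
#' @param x An [nmr_spectrum] object.
#' @param xlim ppm limits (plotted with ppm decreasing left to right).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nmr_spectrum <- function(x, xlim = rev(range(x$ppm)), ...) {
  graphics::plot(x$ppm, x$real, type = "l", xlim = xlim,
                 xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  invisible(x)
}

# Descending ppm axis of an n-point transformed spectrum.
ppm_axis <- function(params, n) {
  sw_hz <- params$spectral_width * params$spectrometer_frequency
  f <- (0:(n - 1L)) / n * sw_hz
  f[f >= sw_hz / 2] <- f[f >= sw_hz / 2] - sw_hz
  sort(params$transmitter_offset + f / params$spectrometer_frequency,
       decreasing = TRUE)
}

add_proc <- function(spec, entry) {
  spec$proc <- c(spec$proc, list(entry))
  spec
}

#' Fourier transform a FID into a spectrum
#'
#' Zero fills the complex series to `zero_fill_to` points, halves the first
#' point (the discrete analogue of the half-sample offset of the FID start),
#' applies the FFT and maps the frequency axis to ppm. No apodization is
#' applied. With the default 16384 complex points zero filled to 32768 the
#' digital resolution at 300 MHz / 12 ppm is 3601.6/32768 = 0.11 Hz.
#'
#' @param fid A [raw_fid] object.
#' @param zero_fill_to Number of spectral points (>= FID length).
#' @return An [nmr_spectrum] object.
#' @export
nmr_transform <- function(fid, zero_fill_to = 32768L) {
  stopifnot(inherits(fid, "raw_fid"))
  x <- fid$signal
  n <- length(x)
  if (n < 1L) stop("empty FID", call. = FALSE)
  if (zero_fill_to < n)
    stop(sprintf("zero_fill_to (%d) is smaller than the FID length (%d)",
                 zero_fill_to, n), call. = FALSE)
  x[1L] <- 0.5 * x[1L]
  x <- c(x, complex(zero_fill_to - n))
  X <- stats::fft(x)

  p <- fid$params
  sw_hz <- p$spectral_width * p$spectrometer_frequency
  f <- (0:(zero_fill_to - 1L)) / zero_fill_to * sw_hz
  f[f >= sw_hz / 2] <- f[f >= sw_hz / 2] - sw_hz
  ppm <- p$transmitter_offset + f / p$spectrometer_frequency
  ord <- order(ppm, decreasing = TRUE)

  nmr_spectrum(Re(X)[ord], Im(X)[ord], ppm[ord], p,
               proc = list(list(step = "fourier_transform",
                                zero_fill_to = as.integer(zero_fill_to),
                                sample_label = fid$sample_label)))
}

#' Apply zero- and first-order phase correction
#'
#' Multiplies the complex spectrum by `exp(i * (phi0 + phi1 * (u - pivot)))`
#' where `u` runs linearly from 0 at the left (high-ppm) end to 1 at the
#' right end and `pivot` defaults to the spectrum centre.
#'
#' @param spec An [nmr_spectrum] object.
#' @param phi0,phi1 Phase angles in degrees.
#' @param pivot First-order pivot as a fraction of the axis (0.5 = centre).
#' @return The phased [nmr_spectrum].
#' @export
apply_phase <- function(spec, phi0, phi1, pivot = 0.5) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  n <- length(spec$real)
  u <- (seq_len(n) - 1) / (n - 1)
  theta <- (phi0 + phi1 * (u - pivot)) * pi / 180
  z <- complex(real = spec$real, imaginary = spec$imag) * exp(1i * theta)
  spec$real <- Re(z)
  spec$imag <- Im(z)
  add_proc(spec, list(step = "apply_phase", phi0 = phi0, phi1 = phi1))
}

# ACME-style objective: Shannon entropy of the normalized first derivative of
# the absorption trace plus a penalty on negative intensity.
phase_objective <- function(z, u, pivot, scale, gamma) {
  function(par) {
    theta <- (par[1] + par[2] * (u - pivot)) * pi / 180
    r <- Re(z * exp(1i * theta))
    h <- abs(diff(r))
    s <- sum(h)
    ent <- if (s > 0) {
      p <- h[h > 0] / s
      -sum(p * log(p))
    } else 0
    neg <- r[r < 0]
    ent + gamma * sum((neg / scale)^2)
  }
}

#' Automatic phase correction by entropy minimization
#'
#' Chooses the zero- and first-order phase that minimize the Shannon entropy
#' of the first derivative of the absorption trace with a quadratic penalty
#' on negative intensity (ACME-style), a criterion suited to all-positive
#' absorption spectra such as oils. The search is a coarse zero-order grid
#' followed by Nelder-Mead refinement of both angles. If the best solution
#' still leaves more than 20\% of the spectral power negative the spectrum
#' falls back to magnitude mode and the flag `phase_fallback_magnitude` is
#' raised.
#'
#' @param spec An [nmr_spectrum] object.
#' @param gamma Weight of the negative-intensity penalty.
#' @param pivot First-order pivot (fraction of the axis).
#' @return The phased [nmr_spectrum]; provenance records `(phi0, phi1)`.
#' @export
auto_phase <- function(spec, gamma = 1e5, pivot = 0.5) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  z <- complex(real = spec$real, imaginary = spec$imag)
  n <- length(z)
  u <- (seq_len(n) - 1) / (n - 1)
  scale <- max(Mod(z))
  if (scale == 0) {
    spec$flags <- union(spec$flags, "phase_unreliable")
    return(add_proc(spec, list(step = "auto_phase", phi0 = 0, phi1 = 0)))
  }
  obj <- phase_objective(z, u, pivot, scale, gamma)

  coarse <- seq(-180, 170, by = 10)
  best0 <- coarse[which.min(vapply(coarse, function(p0) obj(c(p0, 0)),
                                   numeric(1)))]
  fit <- stats::optim(c(best0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  phi <- fit$par

  r <- Re(z * exp(1i * (phi[1] + phi[2] * (u - pivot)) * pi / 180))
  neg_power <- sum(pmin(r, 0)^2) / sum(r^2)
  if (fit$convergence != 0 || neg_power > 0.2) {
    spec$real <- Mod(z)
    spec$imag <- rep(0, n)
    spec$flags <- union(spec$flags, "phase_fallback_magnitude")
    return(add_proc(spec, list(step = "auto_phase", mode = "magnitude")))
  }
  out <- apply_phase(spec, phi[1], phi[2], pivot = pivot)
  out$proc[[length(out$proc)]]$step <- "auto_phase"
  out
}

# Centered moving average with edge padding; smooth = 1 returns y unchanged.
run_mean <- function(y, k) {
  if (k <= 1L) return(y)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  padded <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2L))[
    (half + 1L):(half + length(y))]
}

# Asymmetric least squares (Whittaker) baseline estimate: penalized least
# squares with a second-difference roughness penalty, weights p for points
# above the baseline and 1-p below, iterated to convergence. With p << 1 the
# estimate approaches the lower envelope, which on a noisy trace sits about
# two noise s.d. below the noise centre; estimating on a lightly smoothed
# copy (smooth-point running mean) keeps the baseline centred in the noise
# while leaving the narrow peaks essentially untouched.
als_baseline <- function(y, lambda = 1e5, p = 1e-5, niter = 10, smooth = 9L) {
  y <- run_mean(y, smooth)
  n <- length(y)
  d <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2),
                                           rep(-2, n - 2),
                                           rep(1, n - 2)))
  dtd <- lambda * Matrix::crossprod(d)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(niter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + dtd, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Automatic baseline correction
#'
#' Estimates a slowly varying baseline by asymmetric least squares (Whittaker
#' smoother with asymmetry `p` and roughness penalty `lambda`) and subtracts
#' it from the absorption trace. Constant offsets and linear ramps lie in the
#' null space of the second-difference penalty and are removed exactly at any
#' stiffness. The default `lambda` is deliberately soft: the baseline also
#' follows the low inter-peak shelf formed by the far Lorentzian wings of the
#' intense oil signals, so each region integral afterwards counts only the
#' near-peak area. The wing fraction removed is essentially the same for
#' every signal (identical line widths), so area ratios — and with them the
#' composition results — are preserved, while cross-contamination of small
#' windows (the linolenic CH3 region sits on the foot of the terminal-CH3
#' signal) is strongly reduced.
#'
#' @param spec An [nmr_spectrum] object.
#' @param lambda Roughness penalty (larger = stiffer baseline).
#' @param p Asymmetry: weight of points above the baseline estimate.
#' @param niter Maximum number of reweighting iterations.
#' @param smooth Running-mean width (points) applied to the trace for the
#'   baseline estimate only, keeping the baseline centred in the noise.
#' @return The corrected [nmr_spectrum].
#' @export
baseline_correct <- function(spec, lambda = 1e5, p = 1e-5, niter = 10,
                             smooth = 9L) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  z <- als_baseline(spec$real, lambda = lambda, p = p, niter = niter,
                    smooth = smooth)
  spec$real <- spec$real - z
  add_proc(spec, list(step = "baseline_correct", method = "asls",
                      lambda = lambda, p = p))
}

# sd of the absorption trace in the signal-free noise window.
noise_sd <- function(spec, window = c(9.5, 10.5)) {
  sel <- spec$ppm >= window[1] & spec$ppm <= window[2]
  if (!any(sel)) stop("noise window outside the spectral axis", call. = FALSE)
  stats::sd(spec$real[sel])
}

#' Reference the chemical shift axis to TMS
#'
#' Finds the tallest peak within +/- `search` ppm of 0, refines its position
#' by parabolic interpolation, and translates the axis so the peak sits at
#' exactly 0 ppm. If no point in the search window exceeds 5 times the noise
#' level (sd of the 9.5-10.5 ppm window) the axis is left unchanged and the
#' flag `tms_missing` is raised.
#'
#' @param spec An [nmr_spectrum] object.
#' @param search Half-width of the search window around 0 ppm.
#' @return The referenced [nmr_spectrum].
#' @export
reference_to_tms <- function(spec, search = 0.3) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  sel <- which(abs(spec$ppm) <= search)
  if (!length(sel)) stop("no axis points near 0 ppm", call. = FALSE)
  ns <- noise_sd(spec)
  peak <- max(spec$real[sel])
  threshold <- if (ns > 0) 5 * ns else 0
  if (peak <= threshold) {
    spec$flags <- union(spec$flags, "tms_missing")
    return(add_proc(spec, list(step = "reference_to_tms", found = FALSE)))
  }
  i <- sel[which.max(spec$real[sel])]
  delta <- spec$ppm[i]
  if (i > 1L && i < length(spec$ppm)) {
    y1 <- spec$real[i - 1L]; y2 <- spec$real[i]; y3 <- spec$real[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom != 0) {
      frac <- 0.5 * (y1 - y3) / denom
      delta <- delta + frac * (spec$ppm[i + 1L] - spec$ppm[i])
    }
  }
  spec$ppm <- spec$ppm - delta
  add_proc(spec, list(step = "reference_to_tms", found = TRUE, shift = -delta))
}

#' Spectral quality metrics
#'
#' Computes the acceptance metrics of the screening protocol:
#' * `snr_B`: highest absorption intensity in the linolenic CH3 window
#'   divided by twice the noise s.d. (9.5-10.5 ppm), the common
#'   spectrometer-software S/N convention; `Inf` for a noiseless spectrum.
#' * `linewidth_tms`: full width at half maximum of the 0 ppm reference
#'   peak, in Hz (NA when the peak is absent).
#' * `digital_resolution`: spectral width in Hz divided by the number of
#'   spectral points.
#'
#' Pass flags: S/N at least `snr_min` (default 250, the screening floor),
#' and digital resolution at most half the reference line width.
#'
#' @param spec A processed [nmr_spectrum].
#' @param b_window ppm window of the smallest integrated signal.
#' @param noise_window Signal-free ppm window used for the noise estimate.
#' @param snr_min Acceptance threshold for `snr_B`.
#' @return An object of class `quality_metrics`.
#' @export
quality_metrics <- function(spec, b_window = c(0.93, 1.03),
                            noise_window = c(9.5, 10.5), snr_min = 250) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  ns <- noise_sd(spec, noise_window)
  sel_b <- spec$ppm >= b_window[1] & spec$ppm <= b_window[2]
  if (!any(sel_b)) stop("B window outside the spectral axis", call. = FALSE)
  peak_b <- max(spec$real[sel_b])
  snr_b <- if (ns > 0) peak_b / (2 * ns) else Inf

  n <- length(spec$real)
  sw_hz <- spec$params$spectral_width * spec$params$spectrometer_frequency
  dres <- sw_hz / n

  lw <- fwhm_at(spec, 0, half_window = 0.05)

  structure(list(
    snr_B = snr_b,
    linewidth_tms = lw,
    digital_resolution = dres,
    passed = c(snr = snr_b >= snr_min,
               resolution = !is.na(lw) && dres <= lw / 2)
  ), class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("S/N (B)            : %.1f [%s]\n", x$snr_B,
              if (x$passed[["snr"]]) "pass" else "FAIL"))
  cat(sprintf("TMS line width     : %s Hz\n",
              if (is.na(x$linewidth_tms)) "NA" else
                sprintf("%.2f", x$linewidth_tms)))
  cat(sprintf("digital resolution : %.2f Hz [%s]\n", x$digital_resolution,
              if (x$passed[["resolution"]]) "pass" else "FAIL"))
  invisible(x)
}

# FWHM (Hz) of the tallest peak within center +/- half_window ppm; NA if the
# half-height crossings are not bracketed.
fwhm_at <- function(spec, center, half_window = 0.05) {
  sel <- which(abs(spec$ppm - center) <= half_window)
  if (!length(sel)) return(NA_real_)
  i <- sel[which.max(spec$real[sel])]
  h <- spec$real[i]
  if (h <= 0) return(NA_real_)
  half <- h / 2
  left <- i
  while (left > 1L && spec$real[left] > half) left <- left - 1L
  right <- i
  n <- length(spec$real)
  while (right < n && spec$real[right] > half) right <- right + 1L
  if (spec$real[left] > half || spec$real[right] > half) return(NA_real_)
  interp <- function(i1, i2) {
    y1 <- spec$real[i1]; y2 <- spec$real[i2]
    spec$ppm[i1] + (half - y1) / (y2 - y1) * (spec$ppm[i2] - spec$ppm[i1])
  }
  p_left <- interp(left, left + 1L)
  p_right <- interp(right, right - 1L)
  abs(p_left - p_right) * spec$params$spectrometer_frequency
}
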
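#' Acquisition parameters for a 1D proton experiment
#'
#' Container for the spectrometer and pulse-sequence metadata needed to
#' simulate, read and process a 1D spectrum. Defaults reproduce a routine
#' oil screening experiment on a 300 MHz instrument: 12 ppm sweep centred at
#' 5 ppm, 16384 complex points (32768 stored reals), 8 scans, 2 dummy scans,
#' 4 s recycle delay, 30 degrees C.
#'
#' @param spectrometer_frequency Proton Larmor frequency in MHz.
#' @param spectral_width Sweep width in ppm.
#' @param transmitter_offset Carrier position in ppm; the spectrum spans
#'   `transmitter_offset +/- spectral_width/2`.
#' @param n_complex_points Number of complex time-domain points (half the
#'   stored-real count `TD`).
#' @param n_scans,n_dummy_scans Number of recorded (NS) and dummy (DS) scans.
#' @param acquisition_time Acquisition time in seconds; when `NULL` it is
#'   derived as `n_complex_points / spectral_width_Hz`. A supplied value
#'   inconsistent with the derived one by more than 5\% triggers a warning,
#'   not an error. The default 4.56 s is the nominal AQ of the screening
#'   sequence (derived value 4.55 s).
#' @param recycle_delay Relaxation delay D1 in seconds.
#' @param temperature Sample temperature in degrees C (0-80).
#' @param byte_order Byte order of the raw integer data on disk.
#' @param data_type Raw data word type on disk.
#' @param group_delay Digital-filter group delay in complex points (dropped on
#'   reading; synthetic datasets use 0).
#' @param scale_exponent Power-of-two intensity exponent applied to the stored
#'   integers (`value = int * 2^scale_exponent`).
#'
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params()
#' p$acquisition_time          # 4.56 s
#' experiment_duration(p)      # 86 s
#' @export
acq_params <- function(spectrometer_frequency = 300.13,
                       spectral_width = 12,
                       transmitter_offset = 5,
                       n_complex_points = 16384L,
                       n_scans = 8L,
                       n_dummy_scans = 2L,
                       acquisition_time = 4.56,
                       recycle_delay = 4,
                       temperature = 30,
                       byte_order = c("little", "big"),
                       data_type = c("int32", "float64"),
                       group_delay = 0,
                       scale_exponent = 0) {
  byte_order <- match.arg(byte_order)
  data_type <- match.arg(data_type)
  if (!is.numeric(spectral_width) || spectral_width <= 0)
    stop("spectral_width must be > 0", call. = FALSE)
  if (!is.numeric(n_complex_points) || n_complex_points < 1)
    stop("n_complex_points must be >= 1", call. = FALSE)
  if (n_scans < 1) stop("n_scans must be >= 1", call. = FALSE)
  if (n_dummy_scans < 0) stop("n_dummy_scans must be >= 0", call. = FALSE)
  if (temperature < 0 || temperature > 80)
    stop("temperature must lie in 0-80 degrees C", call. = FALSE)

  sw_hz <- spectral_width * spectrometer_frequency
  aq_derived <- n_complex_points / sw_hz
  if (is.null(acquisition_time)) {
    acquisition_time <- aq_derived
  } else if (abs(acquisition_time - aq_derived) > 0.05 * aq_derived) {
    warning(sprintf(
      "acquisition_time %.3f s differs from n_complex_points/spectral_width (%.3f s) by more than 5%%",
      acquisition_time, aq_derived), call. = FALSE)
  }

  structure(list(
    spectrometer_frequency = spectrometer_frequency,
    spectral_width = spectral_width,
    transmitter_offset = transmitter_offset,
    n_complex_points = as.integer(n_complex_points),
    n_scans = as.integer(n_scans),
    n_dummy_scans = as.integer(n_dummy_scans),
    acquisition_time = acquisition_time,
    recycle_delay = recycle_delay,
    temperature = temperature,
    byte_order = byte_order,
    data_type = data_type,
    group_delay = group_delay,
    scale_exponent = scale_exponent
  ), class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("1D NMR acquisition parameters\n")
  cat(sprintf("  frequency      : %.2f MHz\n", x$spectrometer_frequency))
  cat(sprintf("  spectral width : %g ppm (%.1f Hz)\n",
              x$spectral_width, x$spectral_width * x$spectrometer_frequency))
  cat(sprintf("  offset         : %g ppm\n", x$transmitter_offset))
  cat(sprintf("  complex points : %d (TD = %d)\n",
              x$n_complex_points, 2L * x$n_complex_points))
  cat(sprintf("  NS / DS        : %d / %d\n", x$n_scans, x$n_dummy_scans))
  cat(sprintf("  AQ / D1        : %.2f s / %.2f s\n",
              x$acquisition_time, x$recycle_delay))
  cat(sprintf("  temperature    : %g degrees C\n", x$temperature))
  invisible(x)
}

#' Total wall-clock duration of the experiment
#'
#' `(NS + DS) * (AQ + D1)`, rounded to whole seconds. With the default
#' screening parameters (NS = 8, DS = 2, AQ = 4.56 s, D1 = 4 s) this is 86 s.
#'
#' @param params An [acq_params] object.
#' @return Duration in whole seconds.
#' @export
experiment_duration <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  round((params$n_scans + params$n_dummy_scans) *
          (params$acquisition_time + params$recycle_delay))
}
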
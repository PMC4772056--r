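# Shared fixtures: all synthetic, built in code.

default_params <- function() acq_params()

# Small, fast acquisition for I/O round-trip tests (precision-insensitive).
small_params <- function(nc = 128L) {
  acq_params(n_complex_points = nc, acquisition_time = NULL)
}

# Independent oracle for the molecular proton count of a triglyceride
# mixture: glycerol backbone contributes 5 H (4 sn-1,3 + 1 sn-2), each C18
# acyl chain 2*18 - 1 - 2*d protons for d double bonds.
oracle_total_protons <- function(x, y, z, w) {
  chain <- c(35, 33, 31, 29)
  5 + 3 * sum(c(x, y, z, w) * chain)
}

# Integral table straight from the proton-count model (exact areas).
count_table <- function(spec_oil, label = "model") {
  integral_table(proton_counts(spec_oil), sample_label = label,
                 j_mode = "separate")
}

# Full processing pipeline used across tests.
run_pipeline <- function(fid, zero_fill_to = 32768L, phase = TRUE,
                         reference = TRUE) {
  s <- nmr_transform(fid, zero_fill_to = zero_fill_to)
  if (phase) {
    s <- auto_phase(s)
    s <- baseline_correct(s)
  }
  if (reference) s <- reference_to_tms(s)
  s
}

# Enumerate all compositions on a grid with the given step that sum to 1.
composition_grid <- function(step = 0.05) {
  vals <- seq(0, 1, by = step)
  g <- expand.grid(x = vals, y = vals, z = vals)
  g$w <- pmax(1 - g$x - g$y - g$z, 0)
  g[g$x + g$y + g$z <= 1 + 1e-9, , drop = FALSE]
}
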
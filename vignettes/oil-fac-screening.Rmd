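---
title: "Automated fatty acid composition screening of edible oils by 1H-NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated fatty acid composition screening of edible oils by 1H-NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilnmr)
```

## The measurement

A vegetable oil is, to an excellent approximation, a mixture of
triacylglycerols (TGs): glycerol esterified with three C18 fatty acyl
chains that are saturated (stearic/palmitic-like), mono-unsaturated
(oleic, 18:1), di-unsaturated (linoleic, 18:2) or tri-unsaturated
(linolenic, 18:3). A single 1D proton spectrum of oil in CDCl3 separates
these chains into ten well-known signal groups, labelled A-J from high
field to low field:

| signal | assignment | ppm (default) | protons per mole TG |
|--------|------------|---------------|---------------------|
| A | terminal CH3, non-linolenic chains | 0.88 | 9(1-w) |
| B | terminal CH3, linolenic chains | 0.97 | 9w |
| C | bulk chain CH2 | 1.29 | 84x + 60y + 42z + 24w |
| D | CH2 beta to the carbonyl | 1.61 | 6 |
| E | allylic CH2 | 2.02 | 12(y+z+w) |
| F | CH2 alpha to the carbonyl | 2.30 | 6 |
| G | bis-allylic CH2 | 2.77 | 6z + 12w |
| H | glycerol sn-1,3 CH2 | 4.14/4.29 | 4 |
| I | glycerol sn-2 CH | 5.26 | 1 |
| J | olefinic CH | 5.35 | 6y + 12z + 18w |

with x, y, z, w the molar fractions of saturated, 18:1, 18:2 and 18:3
chains. The totals reproduce the molecular formulae (tristearin C57H110O6
has 110 protons, triolein 104, trilinolenin 92), which is how the package
tests audit the bookkeeping.

Because F carries exactly two protons per acyl chain, ratios of integrals
to F count chains directly. The composition equations implemented by
`compute_fac()` are

$$\mathrm{SFA} = \frac{4A + 4B - 3E}{6F}, \qquad
  \mathrm{MUFA} = \frac{4B + 3E - 6G}{6F}, \qquad
  \mathrm{PUFA} = \frac{3G - 2B}{3F},$$

reported as percentages. Two reading decisions were needed. First, the
flat typesetting of these formulae is ambiguous; full-numerator grouping
is forced by dimensional analysis (every term must be a chain count).
Second, the mono-unsaturated equation is sometimes quoted with the
glycerol signal H in place of the bis-allylic G. Under the proton-count
model above only the G form closes the mass balance: it assigns pure
triolein 100 % MUFA and makes SFA + MUFA + PUFA = 100 an algebraic
identity, while the H form yields 33 % for triolein. We therefore default
to G and expose the H variant as `eq2 = "as_printed"` for comparison. The
identity and the exact inversion of the forward proton-count model are
property-tested over the full composition grid with step 0.05.

Two further quantities complete a sample record:

* the olefinic proton percentage `%OP` = 100 J / (A + ... + J), and from
  it the iodine value via the linear regression IV = 10.54 + 13.39 x %OP
  (grams of I2 per 100 g of oil);
* the F/H validity ratio, 6/4 = 1.50 for intact triglycerides. Free fatty
  acids and partial glycerides lower H relative to F; values outside
  1.45-1.55 flag the sample, because the chain-counting approximation is
  then unreliable.

## The processing pipeline

Raw data come either from a Bruker dataset directory (`read_acqus()`,
`read_fid()`) or from the synthetic generator described below. Processing
is fully automatic, mirroring a routine screening workflow:

1. **Fourier transform** (`nmr_transform()`): zero filling from 16384
   complex points to 32768 real points, first point halved, no
   apodization. At 300.13 MHz and 12 ppm sweep this gives 0.11 Hz digital
   resolution.
2. **Automatic phasing** (`auto_phase()`): zero- and first-order phase by
   minimizing the Shannon entropy of the derivative of the absorption
   trace plus a quadratic penalty on negative intensity, refined by
   Nelder-Mead from a coarse zero-order grid. The penalty weight
   (`gamma = 1e5`) matters: with entropy alone the optimum on a clean
   all-positive oil spectrum is biased by about a degree; the strong
   penalty pulls the identity bias below 0.25 degrees, and a known
   dephasing of (30, 10) degrees is recovered to better than a degree.
   If the best solution still leaves more than 20 % of the spectral power
   negative, the spectrum falls back to magnitude mode and is flagged.
3. **Baseline correction** (`baseline_correct()`): asymmetric least
   squares (Whittaker smoother, second-difference penalty). Offsets and
   linear ramps lie in the penalty's null space and are removed exactly
   at any stiffness. The default stiffness (`lambda = 1e5`,
   `p = 1e-5`) is deliberately soft for a reason specific to
   high-resolution spectra: at 0.11 Hz resolution each Lorentzian's far
   wings form a low shelf that leaks across the narrow integration
   windows — most painfully from the intense terminal-CH3 signal A into
   the adjacent small linolenic window B, which enters the equations with
   weights 4 and -2. A soft baseline treats that inter-peak wing pedestal
   as baseline and removes it. The removed wing fraction is a few per
   cent of each line's area but essentially *uniform* across lines (all
   lines share one width), so area ratios — and with them SFA/MUFA/PUFA,
   %OP and F/H — are preserved, which is what the tests assert. The
   baseline is estimated on a 9-point running mean of the trace so that
   on noisy data it stays centred in the noise instead of hugging its
   lower envelope (which would bias every integral upward).
4. **Referencing** (`reference_to_tms()`): the tallest peak within
   ±0.3 ppm of zero, refined by parabolic interpolation, is translated to
   exactly 0 ppm. If nothing in the window exceeds five times the noise
   level the axis is left alone and `tms_missing` is flagged.
5. **Quality control** (`quality_metrics()`): S/N of the linolenic CH3
   signal B — the smallest routinely integrated peak — with the
   peak/(2 x sd) convention and the noise taken from the signal-free
   9.5-10.5 ppm stretch; the reference linewidth at half height; and the
   digital resolution. Pass thresholds are S/N >= 250 and resolution at
   most half the linewidth.
6. **Integration and composition** (`integrate_regions()`,
   `analyze_sample()`): trapezoidal areas over the window table below,
   with the residual-water exclusion window tracking the water line's
   temperature dependence (1.56 ppm at 30 °C, -0.012 ppm per degree —
   configuration values calibrated only qualitatively), then the
   equations above.

`run_batch()` applies the whole chain to every dataset under a directory,
never letting one failed sample abort the rest, and `export_report()`
writes the per-sample table as csv or fixed-width text.

## Integration windows and their pitfalls

Default windows (ppm): A 0.82-0.93, B 0.93-1.03, C 1.03-1.42, D
1.42-1.75, E 1.90-2.15, F 2.15-2.45, G 2.65-2.90, H 4.05-4.40, I
5.18-5.28, J 5.28-5.50; all configurable through the YAML config. Three
overlap problems shape the defaults:

* **Olefinic / sn-2 overlap.** At 300 MHz the one-proton glycerol sn-2
  multiplet (5.26 ppm) sits essentially under the olefinic envelope. The
  default `j_mode = "sn2_corrected"` therefore integrates 5.10-5.50 ppm
  jointly and subtracts one proton-equivalent estimated as H/4, the
  standard practice. This is also numerically robust for (nearly)
  saturated fats, where a narrow separate J window would integrate pure
  wing leakage from the sn-2 line: with the correction, a noiseless
  tristearin run returns %OP of a few thousandths and an iodine value
  within 0.05 of the regression intercept 10.54. The `"separate"` mode
  (independent I and J windows) is available and tested.
* **Water vs the beta-CH2 signal D.** The water exclusion window
  (±0.06 ppm around the modelled water position) overlaps the D line at
  1.61 ppm at 30 °C, so most of the D signal is excluded along with the
  water. This is a deliberate trade: D appears in no composition
  equation, only in the %OP denominator, where the effect is a small
  systematic common to all samples. What matters — and what the tests
  check across 20-50 °C — is that the excluded D integral is *insensitive*
  to water amplitude and temperature.
* **13C satellites.** Every carbon-bound line carries satellites at
  ±1J(CH)/2 (default 125 Hz) with 0.55 % of the parent area per side.
  Their ppm offset shrinks with field: at 300 MHz the satellites of A
  (0.88 ppm) fall at 0.67/1.09 ppm, outside the B window, whereas at
  500 MHz the upper one lands at 1.005 ppm, inside it —
  `default_regions()` warns in that case. One overlap remains even at
  300 MHz: the allylic satellite at 2.23 ppm sits in the F window,
  inflating F by about 1 % and shifting MUFA by roughly -0.5 points and
  F/H by +0.01 in fully realistic simulations. This is a property of the
  spectra themselves, not of the algorithm; it is consistent with
  observed F/H values of 1.47-1.48 for real intact-TG oils.

## The synthetic generator

`oil_spec()` + `synthesize_fid()` stand in for the spectrometer: a sum of
complex exponentials (one per catalog line, amplitude proportional to its
proton count, decay rate pi x linewidth), with seeded Gaussian noise per
time-domain point. `synthesize_spectrum()` evaluates the same model
analytically in the frequency domain; the two routes agree to within
discretization error, which is itself a test of the transform. Defaults
are the screening study conditions: 300.13 MHz, 12 ppm sweep centred at
5 ppm, 16384 complex points, NS = 8, DS = 2, D1 = 4 s (86 s per sample),
30 °C, 0.68 Hz linewidth (a well-shimmed reference line), satellites on,
a 0.5 proton-equivalent water line, and no noise unless requested —
`noise_sigma_for_snr()` converts a target spectral S/N into the required
time-domain sigma via the FFT noise-gain sqrt(n).

What the generator does **not** emulate: J-coupled multiplet structure
(each signal is a single Lorentzian; areas, which are what integration
uses, are unaffected), field inhomogeneity and lineshape distortion,
solvent impurities other than water, diglyceride/monoglyceride spectra
(only their F/H signature, via `free_fatty_acid_fraction`, which removes
glycerol backbone protons from H and I), and chain-length variation
(all chains are C18; palmitic chains would change C but no equation
input). Passing round-trip tests therefore demonstrates correctness of
the processing and arithmetic under realistic lineshape, overlap,
satellite and noise conditions — not immunity to shimming artefacts or
non-TG impurities in real oils.

## Numerical choices and test conditions

* Recovery accuracy, measured by the test suite on this generator: with
  satellites off a noiseless round trip recovers SFA/MUFA/PUFA within
  0.15 points (asserted at 0.5); with full defaults including satellites
  and noise at the S/N = 250 acceptance floor, 50 seeded replicates of a
  low-PUFA olive-like oil stay within 1.5 points of truth (observed
  worst case about 0.8).
* The S/N = 250 replicate composition is picual-like (saturated 0.124,
  oleic 0.851, linoleic 0.018, linolenic 0.007), the variety whose B
  signal anchors the S/N acceptance criterion; its tiny B peak makes the
  absolute noise level, and hence the test, as demanding as the floor
  allows.
* Problem sizes: all spectral tests run at the full acquisition geometry
  (16384 complex points, 32768 spectral points); I/O round-trip tests use
  64-128 point series, where precision is not at stake.
* Integer quantization on write: the Bruker writer chooses a power-of-two
  exponent so the data fill 30 bits, giving round-trip errors below 1e-9
  of the maximum amplitude.
* Ties and degenerate inputs: an all-zero spectrum integrates to zero
  everywhere and is reported as such; F <= 0 or H <= 0 abort the sample
  (not the batch); raw composition fractions outside [-0.02, 1.02] are
  treated as implausible integrals and abort the sample, while small
  negatives within noise are clamped to zero and flagged.

## Known limitations

The iodine-value regression is taken as given and applied to the %OP of
the synthetic spectra; its absolute calibration against titration for
real oils is outside what desk simulation can check. The %OP denominator
convention (sum of the assigned A-J areas) and the sn-2 correction mode
are config-exposed because usage varies between laboratories. The water
model constants are qualitative placeholders — only the direction of the
temperature dependence is anchored — and real oils at very low field or
poor shim may need manual phasing, for which every automatic step can be
disabled individually (`--no-auto-phase`, `--no-auto-reference` in the
CLI, or the corresponding config keys).
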
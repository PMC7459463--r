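---
title: "Slope-code fingerprinting of sensor noise spectra: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slope-code fingerprinting of sensor noise spectra: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesprint)
```

## The measurement model

Fluctuation-enhanced sensing (FES) reads a chemiresistive gas sensor not
through its mean resistance but through the statistics of the resistance
*fluctuations* superimposed on it. Molecules of different odors interact
differently with the sensing film (adsorption/desorption dynamics, surface
diffusion, trapping), and those microscopic differences reshape the power
density spectrum (PDS) of the pre-amplified noise voltage. The spectrum of
such sensors is 1/f-like: on log-log axes it is close to piecewise linear,
with local slopes near $-\gamma$, $\gamma \approx 0.5\ldots2$. The
information that distinguishes odors sits in *how the slope varies along the
band*, not in the absolute noise level, which depends on gain, temperature
and bias.

`fesprint` codes that slope structure into short symbol strings:

* **Binary fingerprint.** The analysis band $[f_\mathrm{low},
  f_\mathrm{high}]$ is tiled into $n$ sub-bands of equal width in $\log_{10}
  f$. The *global slope* is the chord slope of the log-log spectrum across
  the whole band,
  $$s_\mathrm{glob} = \frac{\log_{10} S(f_\mathrm{high}) - \log_{10} S(f_\mathrm{low})}
                           {\log_{10} f_\mathrm{high} - \log_{10} f_\mathrm{low}},$$
  and each sub-band's *local slope* $s_i$ is the chord slope over that
  sub-band. Symbol $i$ is $-1$ if $s_i < s_\mathrm{glob}$ and $+1$
  otherwise (ties, including the pure-power-law case, code as $+1$).
* **Ternary fingerprint.** The same local slopes are compared with the
  local slopes $r_i$ of a *reference odor* spectrum (laboratory air, sterile
  growth medium, ...) over the same sub-bands: symbol $i$ is
  $\operatorname{sign}(s_i - r_i)$, except that $|s_i - r_i| \le
  \varepsilon$ codes as $0$. The zero symbol makes the alphabet ternary —
  $\log_2 3 \approx 1.585$ bits per symbol instead of 1, a
  $100(\log_2 3 - 1) \approx 58.5\%$ gain — and the reference makes the code
  relative, so one agent yields different fingerprints under different
  references.

Chord slopes (not least-squares fits) are used everywhere: the code is
defined by connecting the endpoints of the band or sub-band, which makes
each symbol depend on exactly two spectrum values and keeps the scheme
cheap, transparent, and scale-free. A least-squares variant would average
interior structure into every symbol and was deliberately not made the
default.

Two structural consequences are worth knowing. Because the sub-bands tile
the band contiguously with equal log width, the local chords telescope:
$\frac{1}{n}\sum_i s_i = s_\mathrm{glob}$ exactly. Hence a binary
fingerprint can never be all $-1$ — at least one local slope is at or above
the mean. And because chord slopes are differences of logs, multiplying a
spectrum by any positive constant changes no symbol: fingerprints are
invariant under gain changes.

## From noise record to spectrum

`estimate_psd()` implements the averaged-periodogram (Welch) estimate:
overlapping segments, per-segment mean removal, a taper, FFT, one-sided
normalisation so that $\sum_k S(f_k)\,\Delta f$ equals the signal variance.
Defaults are segment length 4096, 50% overlap and a Hann window — standard
spectrum-analyzer practice. The DC bin is always dropped: $\log f$ is
undefined at 0 and the fingerprints live entirely in log-log coordinates.

Raw Welch bins scatter with relative standard deviation $\approx
1/\sqrt{n_\mathrm{avg}}$, which would make single-bin chord endpoints
noisy. `log_bin_spectrum()` therefore averages the estimate in bins of
equal log-width (default 12 per decade, anchored at the lowest retained
frequency): each output point is the geometric-mean frequency and
arithmetic-mean density of its bin. Twelve bins per decade is fine enough
that five sub-bands over 1.5–3 decades keep several points per sub-band,
and coarse enough to pool tens of raw bins at the upper end of the band.
On an exact power law the binned spectrum keeps the same slope, so the
smoothing does not bias the code.

Band endpoints are closed everywhere, and `select_band()` refuses bands
with fewer than two surviving points. When no band is given,
`default_band()` uses $[2 f_\mathrm{min},\ 0.8 f_\mathrm{max}]$: the lowest
retained frequencies carry the worst estimator scatter and the top of the
band may be shaped by anti-aliasing roll-off. The meaningful band is
ultimately an operator decision and every function takes it explicitly.

Non-positive densities in user-supplied spectrum files are rejected, not
floored. A proper Welch estimate of real noise is positive everywhere, so a
zero can only come from a corrupted or truncated file, and silently
flooring it would manufacture arbitrary slopes.

## The tie tolerance

Exact equality of two floating-point slopes is a null event, so the ternary
zero needs a resolution: symbols with $|s_i - r_i| \le \varepsilon$ code as
0. The default is $\varepsilon = 0.05$ slope units. Under the packaged
acquisition conditions (below) the slope-difference estimator scatter is
about $0.01$–$0.02$, so $\varepsilon = 0.05$ is a $\ge 2.5\sigma$ window:
designed-equal slopes code as 0 reliably, while designed sign margins of
$0.3$ or more are far outside it. Raising $\varepsilon$ can only turn
$\pm1$ symbols into 0 — it never flips a sign — so the choice trades
sensitivity against reproducibility monotonically.

When agent and reference spectra live on different frequency grids, the
reference is resampled (linearly in log-log coordinates, exact on power
laws) onto the agent's grid augmented with the sub-band edges, so both
chord endpoints are taken at identical frequencies and each side's endpoint
value is interpolated from its own sampling. Resampling the reference
across the coarser agent grid alone was found to bias slope differences by
about $0.01$ near reference spectral breaks, which matters at the scale of
the tie tolerance.

## The noise simulator and what it emulates

No public corpus of Taguchi-sensor noise records exists, so the package
carries its own surrogate generator. `spectrum_model()` specifies an
analytic one-sided PSD as contiguous power-law segments
$S(f) = c_i f^{-\gamma_i}$ with amplitudes chained for continuity;
`simulate_noise()` draws a Gaussian record whose *expected* Welch spectrum
equals that model, by frequency-domain synthesis: independent complex
Gaussian amplitudes scaled by $\sqrt{S(f_k)\,f_s N/2}$, Hermitian symmetry,
zero DC, real Nyquist bin, inverse FFT. This is exact in expectation for
any piecewise law (an AR/filtering approach would only approximate it), and
a seed makes every record bit-reproducible. Frequencies outside the model
support take the nearest segment's law, so the model need not extend to the
lowest FFT bin. `simulate_measurement_pair()` draws two records with seeds
`seed` and `seed + 1` — the in-silico analogue of measuring the same Petri
plate twice.

The generator emulates the *spectral shape and estimator statistics* of
sensor noise. It is Gaussian and stationary: it does not model sensor
drift, temperature fluctuations, adsorption bursts (random-telegraph
components), chamber turbulence, or any non-Gaussian structure real films
produce. Results obtained with it therefore validate the *processing
chain* — that the coding recovers designed slope structure at realistic
averaging — not the chemistry of any particular sensor/odor pairing.

### Study conditions

All simulator-based studies in the tests and the acceptance script use one
fixed set of acquisition conditions, `default_conditions()`: sampling rate
1000 Hz, $2^{20}$ samples per measurement (about 17.5 min of signal), Welch
segments of 2048 samples at 50% overlap (1023 averages), 12 log bins per
decade, analysis band 10–400 Hz in 5 log-equal sub-bands, tie tolerance
0.05. The segment length and record length were chosen together so that
the sub-band slope scatter ($\le 0.02$) sits at least a factor 3 below the
designed sign margins and well inside the tie window; the band keeps one
octave of guard below the 500 Hz Nyquist and a decade above the lowest
Welch bins. The general-purpose default in `fes_config()` keeps the more
conservative 4096-sample segment; longer segments resolve lower
frequencies at the cost of fewer averages.

The packaged example models (`example_models()`) are synthetic design
points, not digitised measurements: agent exponents
$(2.0, 0.5, 0.5, 0.5, 0.5)$ and reference exponents
$(2.4, 0.1, 0.5, 0.9, 1.3)$ over segment edges aligned with the sub-band
edges, giving designed agent-minus-reference slope differences
$(+0.4, -0.4, 0, +0.4, +0.8)$ and hence the designed ternary code
$(+1, -1, 0, +1, +1)$. In the reproducibility study the reference side is
the model's analytic spectrum (a fixed reference), so the comparison
isolates the agent measurement's scatter.

## Classification

`fingerprint_distance()` is the plain Hamming count over symbol positions;
it is a true metric on fingerprint strings. The unweighted count treats
$0 \leftrightarrow \pm1$ and $+1 \leftrightarrow -1$ mismatches equally —
the minimal assumption, and the default everywhere. A weighted variant
(sign flip 2, zero transition 1) is available for callers who consider a
full reversal worse. `classify_fingerprint()` returns the nearest library
entry; equidistant entries are all returned and flagged ambiguous, never
broken by order — the fingerprint-as-address idea presumes exact lookup,
so approximations must be explicit about ties. Reproducibility between
repeated measurements is summarised by `bit_agreement()`, the fraction of
agreeing positions.

## Numerical choices and degenerate inputs

* Base-10 logs throughout; slope values do not depend on the base as long
  as both axes share it.
* Chord endpoints not on the frequency grid are obtained by log-log linear
  interpolation; extrapolation beyond a spectrum's support is always an
  error, never silent.
* Binary ties (local exactly equal to global) go to $+1$; they occur with
  probability zero for estimated spectra but deterministically for exact
  power laws.
* Log binning drops empty bins; an output with fewer than two points is an
  error. The top band edge belongs to the last bin.
* `simulate_noise()` requires an even record length; the Nyquist amplitude
  is drawn real, the DC term is zero, so simulated records have zero mean
  in expectation but not exactly — `estimate_psd()` removes per-segment
  means regardless.
* All file writers format numbers with 12 significant digits and fixed key
  order, so identical objects give byte-identical files.

## Problem sizes used in the packaged studies

The test suite and `scripts/acceptance.R` exercise: slope recovery for
$\gamma \in \{0.5, 1, 1.5, 2\}$ from $2^{19}$-sample records over 10 seeds
each (recovered chord slope within $\pm0.1$); reproducibility over 20
measurement pairs at the study conditions above (median bit agreement
$\ge 0.9$); property suites (self-reference, telescoping,
amplitude-invariance, antisymmetry) over 50–100 randomly generated smooth
spectra; and metric axioms over 1000 random ternary strings. These sizes
give stable pass/fail behaviour across seeds while keeping a full run in
tens of seconds on one core.

## Known limitations

* The tie tolerance, sub-band count and band are operator choices; there
  is no universally correct setting, and fingerprints are only comparable
  when all of them match.
* Chord slopes ignore curvature inside a sub-band; two spectra with equal
  endpoint values but different interior shape share a code. That is a
  feature of the scheme, not a bug of the implementation.
* The simulator's Gaussianity means agreement rates measured here are an
  upper bound on what drifting hardware would show.
* Only alphabets of size 2 and 3 are implemented; the machinery would
  extend, but larger alphabets need correspondingly tighter slope
  resolution to be meaningful.
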
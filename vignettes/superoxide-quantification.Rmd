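---
title: "Quantifying extracellular superoxide from chemiluminescence traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extracellular superoxide from chemiluminescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxylume)
```

## The measurement model

Superoxide at an organism's surface is at a production–decay steady state.
With a production rate $P$ (nM s$^{-1}$) and pseudo-first-order decay
constant $k$ (s$^{-1}$),

$$\frac{dC}{dt} = P(t) - kC, \qquad C_{ss} = P/k,$$

and the half-life is $t_{1/2} = \ln 2 / k$ — tens of seconds in
DTPA-amended seawater, which is why every step of quantification is a race
against decay. The instrument mixes the analyte stream with the MCLA probe
in a flow cell; its response is linear,

$$L(t) = \text{baseline} + s \cdot 1000\,C(t-\tau)\,e^{-k\tau} + \varepsilon,$$

with sensitivity $s$ in counts per pM (hence the factor 1000 on nM
concentrations), a transit delay $\tau$ through the tubing during which the
analyte decays by $e^{-k\tau}$, and noise $\varepsilon$. Field
concentrations are deliberately *not* corrected for transit decay, so they
are conservative (under-) estimates; the simulator makes that bias
measurable — it equals $e^{-k\tau}$ exactly in noiseless runs, and the test
suite asserts it.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_concentration()` + `render_trace()` generate
traces with: piecewise-constant production schedules (solved
piecewise-analytically, so there is no integration error to confound
tests), linear detection, additive homoscedastic Gaussian noise on counts,
a reagent-blank baseline, instantaneous SOD quench events (the biogenic
term is removed from the event time on), transit attenuation as a pure
$e^{-k\tau}$ with no dispersion, decaying standard injections and seeded
replicate blank series.

Real traces additionally contain baseline drift with temperature, MCLA
autooxidation chemistry, flow-cell mixing dispersion, and
moving-the-tubing artefacts; none of these are modelled. A green
end-to-end test therefore establishes that the *processing chain* is
self-consistent (simulate → plateau → blank-correct → calibrate → quantify
recovers known concentrations), not that the kinetic model captures every
instrumental effect. Default choices that the protocol fixes: 0.5 Hz
sampling (the field acquisition rate), SOD quench modelled as instantaneous
(sub-second dynamics are unobservable at 0.5 Hz). The noise magnitude in
counts is not fixed by the protocol — only a 4% CV acceptance rule is —
so `noise_sd` has no meaningful default and must be set by the user
(tests use 2% of the peak biogenic signal as a realistic mid-range value).

## Plateau detection and blanks

A segment counts as a steady-state reading when the rolling coefficient of
variation (sd/mean over a trailing window) stays below 4% for a minimum
duration. Parameters, with defaults:

* `window_length_s = 30` — the protocol states only the threshold, not the
  window; 30 s is ~15 points at 0.5 Hz, enough for a stable sd.
* `cv_threshold = 0.04` — the field acceptance rule; computed on raw
  (uncorrected) counts, since that is what "stable baseline" refers to.
* `min_duration_s = 60` for biological plateaus, 120 s for reagent blanks
  (the ~2 min blank acquisition).

The *latest* qualifying run is returned, not the first: the field protocol
reads the final steady state before the tubing moves. Windows with
non-positive mean are ineligible (CV undefined) rather than errors.
Blank correction is tiered: `coral_minus_sw` subtracts the background
seawater signal taken 5–15 cm away (removing seawater and reagent blanks at
once); `raw_minus_reagent_blank` subtracts only the reagent blank and is
used for the seawater backgrounds themselves. The scheme is linear —
$(\text{coral}-\text{sw}) + (\text{sw}-\text{blank}) =
\text{coral}-\text{blank}$ holds exactly — and negative corrected values
are propagated, never clipped: some surfaces genuinely sit below their
background, and that result depends on not clipping.

## Calibration

Primary KO2 standards are quantified by Beer–Lambert from the drop in A240
on SOD addition, with $\varepsilon = 2{,}183$ L mol$^{-1}$ cm$^{-1}$
(pH 12.5). That value is taken as already corrected for the hydrogen
peroxide formed during decay; no separate H2O2 term is computed. Secondary
standards (3–38 nM) decay while being read, so their signals are fitted by
ordinary least squares on $\ln(L - \text{baseline})$ versus time — the
log-linear route rather than nonlinear least squares, because log-linearity
is itself the diagnostic for first-order behaviour ($R^2$ of the log fit is
the lack-of-fit statistic) — and extrapolated backwards
($L_0 = e^{\text{intercept} - k t_q}$) to the quantification time. Spans
beyond 120 s warn rather than fail.

The calibration regression keeps a free intercept: with perfect blank
correction it should be ~0, and reporting it lets users detect correction
failures. Sensitivity is $1000/\text{slope}$ (pM per count; the identity
$\text{sensitivity} \times \text{slope} = 1000$ is asserted in tests), the
detection limit is $3\times$ the sample sd (n−1 denominator, appropriate to
a small series) of replicate blanks, and curves with Pearson $r$ below 0.93
are flagged, not discarded. Concentrations are held in nM internally;
conversions to pM/amol/fmol happen only at reporting boundaries.

## Quantification conventions

The curve intercept is applied only under `raw_minus_reagent_blank`; the
`coral_minus_sw` difference cancels any common intercept, so only the slope
is used there. Whether field protocols used the intercept is not
documented, so this scheme-dependent rule is this package's own convention.
Temporal sd converts to nM by dividing by the slope; calibration-fit
uncertainty is not folded in, since only temporal scatter is conventionally
reported. Rates: $\text{rate} = C_{ss} \times \text{flow}$
(mol h$^{-1}$ after unit conversion), divided by the organism count on the
filter, reported in amol (cell-scale) or fmol (larva-scale) per organism
per hour, chosen by magnitude at 1 fmol.

## Statistics

* **Two-way ANOVA, Type-II sums of squares.** Field species × health
  designs are unbalanced (2–16 per cell); Type-II tests each main effect
  adjusted for the other, and reduces exactly to the classical
  decomposition when balanced (asserted to 1e-10). A diel
  repeated-measures design would need a mixed model; it is approximated
  here, as in the original analysis scope, by fixed effects with a
  blocking factor.
* **Tukey–Kramer HSD** against the studentized range with
  $SE = \sqrt{\tfrac{MSE}{2}(1/n_i + 1/n_j)}$ for unbalanced groups.
* **Welch or pooled t-tests**, with the convention $t = 0, p = 1$ when both
  samples are constant and equal.
* **Bray–Curtis** from definition,
  $d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$; community matrices are
  converted to relative abundance before dissimilarity in the ANOSIM
  pipeline (the original normalization is unstated; relative abundance is
  the common Primer-E default).
* **ANOSIM**: all $M = n(n-1)/2$ pairwise dissimilarities are ranked (ties
  → average rank) and $R = (\bar r_B - \bar r_W) / (n(n-1)/4)$. The
  divisor $n(n-1)/4$ is Clarke's: it is the unique scaling under which
  perfect separation gives $R = 1$ for any group sizes (since
  $\bar r_B - \bar r_W = M/2$ there) and $R$ is bounded in $[-1, 1]$.
  Permutation $p = (\#\{R^* \ge R\} + 1)/(n_\text{perm} + 1)$ with a
  seeded generator, default 999 permutations (so $p$ floors at 1/1000;
  99 permutations produce the familiar $P = 0.01$); `exact = TRUE`
  enumerates all distinct label assignments for small $n$ and is tested
  against an independently coded enumeration.

## Numerical choices and degenerate inputs

* The kinetic solver floors concentrations at 0; negative values can arise
  only downstream of blank subtraction, by design.
* A decay fit whose slope is numerically ~0 (|k| ≤ 1e-10 s$^{-1}$) is
  rejected as non-decaying rather than returned as a near-infinite
  half-life.
* Rolling-CV windows need ≥ 2 points; plateau stats are computed over the
  full returned run, which includes the tail of the approach transient —
  the reason end-to-end recovery is asserted to 0.5% rather than to
  machine precision when the plateau detector is in the loop, and exactly
  when it is not.
* Transit delays that are integer multiples of the sampling interval shift
  the grid exactly; other delays are linearly interpolated.
* Plateau search scans qualifying runs from latest to earliest and takes
  the first whose span — extended back to the start of its first
  qualifying window — meets the minimum duration.

## Known limitations

The simulator's homoscedastic noise understates shot-noise scaling at high
count rates; no changepoint detection is attempted (segments must be
annotated); peak (as opposed to plateau) readings are reported as the
maximum single corrected value in a segment and are convention-dependent;
and the statistics module consumes community matrices as given — no
sequence processing of any kind.
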
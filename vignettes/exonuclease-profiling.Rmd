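---
title: "Exonuclease-protection profiling: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exonuclease-protection profiling: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoprofiler)
```

## The assay and its statistic

Exonuclease-protection profiling characterises aptamer-small-molecule
binding through digestion kinetics. A single-stranded DNA aptamer incubated
with its ligand is exposed to a 5'-to-3' exonuclease mix; digestion of the
free aptamer proceeds to completion, while a ligand-bound aptamer stalls
the enzyme at an internal position, leaving a truncated protected product
(typically a few tens of nucleotides). An intercalating dye reports the
amount of retained DNA, so a fluorescence time course read from
destructively sampled aliquots tracks digestion. Protection is quantified
by the **resistance value**

$$R = \frac{\mathrm{AUC}_1 - \mathrm{AUC}_0}{\mathrm{AUC}_0},$$

the relative excess area under the fluorescence time course with ligand
(AUC$_1$) over the ligand-free control (AUC$_0$). $R = 0$ means the ligand
changes nothing; higher values mean stronger protection and hence tighter
binding. Specificity panels are summarised by the **cross-reactivity**

$$\mathrm{CR} = 100\,\frac{\mathrm{AUC}_L - \mathrm{AUC}_0}
                          {\mathrm{AUC}_T - \mathrm{AUC}_0}\,\%$$

of each test ligand $L$ relative to the main target $T$; with a shared
control this is algebraically $100\,R_L/R_T$, an identity the test suite
asserts to machine precision. The strand-displacement comparison uses the
**signal gain** $S = (F - F_0)/F_0$ of a fluorophore-labelled aptamer
released from a quencher-labelled complement, and its own cross-reactivity
$100\,S_L/S_T$.

## The digestion model

The simulator is phenomenological: it models the fluorescence signal, not
per-nucleotide enzymology. For occupancy $\theta$ (fraction of aptamer
ligand-bound at mixing time), protected-length fraction
$\omega = P/N$, background $B$ and amplitude $A$:

**Slow exchange** (default): each molecule keeps its initial bound/free
state over the digestion,

$$F(t) = B + A\left[(1-\theta)e^{-k_u t} +
  \theta\,(\omega + (1-\omega)e^{-k_u t})\,e^{-k_{leak} t}\right].$$

The free channel decays at $k_u$; the bound channel is digested down to its
protected product (decay from 1 to $\omega$ at $k_u$) and the product
itself leaks away slowly at $k_{leak}$. This reproduces the persistent
truncated products seen on gels.

**Fast exchange**: bound and free states interconvert quickly relative to
digestion, so a single effective rate applies,
$F(t) = B + A e^{-[(1-\theta)k_u + \theta k_{leak}]t}$. Both modes coincide
exactly at $\theta = 0$. The mechanism underlying protection (the enzyme's
lower affinity for the ligand-bound aptamer) does not fix which regime
holds; we default to slow exchange and expose the other.

Occupancy comes from the single-site isotherm under ligand excess,
$\theta = c/(K_{d,app} + c)$: the assay uses about 1 uM aptamer against at
least 25 uM ligand, so free ligand is taken equal to total ligand. The
simulator warns when a requested concentration is below ten times the
aptamer concentration, the validity bound of that approximation. Ligand
depletion, two-site binding and endonucleolytic side products are not
modelled; the latter are absorbed into $k_u$, which is harmless because the
plate statistic depends only on total stainable signal.

Noise is multiplicative Gaussian with constant coefficient of variation
(plate-reader behaviour), independent per read because each time point is a
destructively sampled aliquot; negative excursions are clipped at zero.

## Default parameters and their calibration

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k_unprotected` | 0.05 | /min | control digested to baseline within ~1.5 h |
| `k_leak` | 0.012 | /min | see below |
| `amplitude` | 100 | a.u. | arbitrary signal scale ($R$ is scale-free) |
| `background` | 5 | a.u. | 5% of amplitude; persists in both AUCs |
| `noise_cv` | 0.02 | — | typical plate-reader replicate scatter |
| schedule | 0–240 by 15 | min | the longest recording window in use (4 h) |
| screening conc. | 200 | uM | standard single-concentration screen |

`k_leak` is the one genuinely free constant. With the defaults above and a
4-h window, noiseless $R$ as a function of occupancy is almost exactly
$R \approx \theta$, so a saturated binder reaches $R \approx 0.97$ and the
empirically reported binder range 0.8–1 corresponds to apparent $K_d$
values of roughly 0.6–50 uM at the 200 uM screening concentration. A much
smaller `k_leak` would push saturated binders to $R \approx 3$ or more over
the same window; the calibrated value encodes the observation that
protected products are retained but not immortal. Whether digestion
inhibition saturates below full protection is left open by exposing
`k_leak` rather than asserting one behaviour.

One regularity condition is worth recording: expected fluorescence is
monotonically non-decreasing in $\theta$ at every $t$ (the property that
makes $R$ a binding monotone) for the slow-exchange model only when
$k_{leak} \le \omega k_u$ — slightly stronger than the structural
requirement $k_{leak} < k_u$. The defaults satisfy it with a threefold
margin ($0.012 < 0.029$).

The bundled 29-candidate screen (`mephedrone_screen_panel()`) encodes the
canonical screening scenario: four true binders (apparent $K_d$ 6.6, 15,
30 and 40 uM — the first two are experimentally reported affinities for
the mephedrone aptamer and its truncation, the others fill the
moderate-affinity range) among 25 non-binders, all 73-nt candidates with a
42-nt protected product. At the screening concentration their noiseless
resistance values are 0.80–0.97, matching the reported binder range, while
non-binders sit at 0.

## Replicates, grid alignment and the AUC

AUCs are composite trapezoids over the recorded grid (irregular grids
supported). When ligand and control wells were read on different grids,
the control is linearly interpolated onto the ligand grid and both areas
are taken over the overlap only — never extrapolated. Because a digestion
curve is convex, linear interpolation biases the interpolated AUC up by at
most $k_u^2 h^2/8$ relative (about 3% at a 10-min step), which the tests
bound explicitly.

Replicates are aggregated with a common denominator: AUC$_0$ is the mean
over control replicates, each ligand replicate's $R_i$ uses that shared
denominator, and the condition is reported as mean ± SD over ligand
replicates. Published figure legends do not specify replicate pairing, so
the common-denominator scheme is the least-assumptive choice. No
baseline/blank subtraction is applied (none is used in practice);
`background` therefore persists in both AUCs and partially cancels in $R$,
a known small bias toward zero. The $t = 0$ read is included by default
(`include_t0 = FALSE` excludes it). Negative $R$ and CR are reported raw
with a quality flag rather than clipped, so artifact-like behaviour stays
visible.

One wording subtlety: the resistance value is defined as the AUC ratio
minus one; the looser phrase "ratio of the integrals" describes the same
quantity only up to that offset. The formula implemented is
$(\mathrm{AUC}_1 - \mathrm{AUC}_0)/\mathrm{AUC}_0$.

## Screening, profiling and dose-response

`call_binders()` thresholds replicate-mean resistance at $\tau = 0.1$ by
default: observed screens separate binders ($R$ 0.8–1) from non-binders
(near zero) so cleanly that any $\tau$ far from both clusters gives the
same calls; ties call binder. A z-score companion
($R_{mean}/R_{sd} \ge 3$) is reported but deliberately not used for the
call, keeping the headline rule identical to the qualitative one. Mixed
screening concentrations are refused — the screen assumes one shared
concentration.

`build_profile()` converts per-ligand resistance into CR% and annotates
entries under 10% as not significant, the conventional reporting bound.

`fit_dose_response()` fits the rectangular hyperbola
$R(c) = R_{max}\,c/(k_{half} + c)$ by Levenberg–Marquardt least squares
with non-negativity bounds. This is the minimal model consistent with
fraction-bound occupancy driving protection; nothing deeper is claimed,
and $k_{half}$ is an *apparent* half-saturation constant, not a
calorimetric $K_d$. Initialisation: $R_{max}$ from the maximum observed
resistance, $k_{half}$ from the linearly interpolated concentration at
half-maximum. Confidence intervals come from a seeded 200-resample
residual bootstrap, chosen because replicate counts are far too small for
asymptotic standard errors. An all-non-positive resistance vector returns
a non-binder sentinel (`converged = FALSE`, `k_half = Inf`) rather than an
error. The estimator is concentration-scale equivariant and exact on
noiseless model data, both asserted in the tests.

## The strand-displacement comparison

`simulate_sd_readout()` models the displacement assay with quenched
baseline $F_q = (1 - q)F_{max}$ (default quench efficiency $q = 0.92$,
reflecting the >90% optimisation target), displacement fraction
$\delta = d_{max}\,c/(K_{d,SD} + c)$ with $d_{max} = 0.6$ by default, and
observed signal $m \cdot [F_q + (F_{max} - F_q)\delta]$ where $m$ is the
ligand's dye-artifact factor. Because the artifact scales the whole
readout while the reference $F_0$ is always ligand-free and artifact-free,
a tight binder whose ligand attenuates the fluorophore ($m \approx 0.1$)
produces a *negative* apparent gain (false negative), and a non-binder
whose ligand enhances it ($m = 1.3$) produces a spurious $+30\%$ gain
(false positive). The exonuclease statistic is immune by construction: its
dye is added after the reaction is quenched. The `analysis/05` driver
tabulates the paired readouts and marks discordant ligands.

## What the generator does and does not emulate

The simulator reproduces the features the statistics rely on: exponential
control digestion, concentration-dependent retention of a protected
product, replicate structure (2–3 wells), destructive per-read sampling,
realistic sampling windows (1.5–4 h), the calibration concentration series
(0–800 uM), and ligand-specific fluorophore artifacts. It does not emulate
sequence-dependent digestion patterns, enzyme batch effects, temperature
drift, pipetting covariance between wells, or spectrally resolved
emission (only the single analysis wavelength is modelled). Passing tests
therefore validate the statistical machinery and its calibration on data
with the assumed structure; they cannot certify behaviour on instrument
exports with unmodelled systematics.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the sizes the
analyses themselves use: 1000 simulated condition/control pairs for the
null calibration, 100 seeded repeats of the 29-candidate screen, 50
Monte-Carlo dose-response fits, and a 200-resample bootstrap — a few
minutes end to end on one CPU. All randomness flows from explicit master
seeds; per-well sub-seeds are derived by a fixed counter scheme
(`seed + index * 10007 mod 2^31 - 1`), so a full plate is bit-reproducible
and any single well can be regenerated in isolation. Identical seeds give
byte-identical output files.

## Known limitations

- $R$ inherits a small downward bias from the unsubtracted background and
  from trapezoid integration on coarse grids; both are quantified in the
  tests and negligible at the default settings.
- `k_half` from resistance dose-response tracks, but is not equal to,
  thermodynamic affinity; with `k_leak > 0` the mapping from occupancy to
  resistance is mildly window-dependent.
- The screen refuses mixed concentrations rather than normalising across
  them, because cross-concentration comparability of $R$ is not
  established.
- Fast-exchange simulations decay to background at saturation rather than
  to the protected plateau; the plateau is a slow-exchange prediction.
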
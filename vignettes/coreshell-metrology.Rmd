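---
title: "Methods: core-shell nanoparticle metrology from correlated AFM and DLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-shell nanoparticle metrology from correlated AFM and DLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoshell)
```

## The measurement problem

Self-assembled nucleic-acid delivery nanoparticles (polyplexes) have a dense
core of nucleic acid condensed by polyethylenimine (PEI) and a diffuse
poly(ethylene glycol) (PEG) shell. No single instrument sees both parts:
atomic force microscopy (AFM) images the rigid core (the brush-like PEG
shell collapses under the imaging force), while dynamic light scattering
(DLS) reports the hydrodynamic diameter of core plus shell. Combining the
two measurements per sample,

$$ L = \tfrac{1}{2}\,(d_\mathrm{DLS} - d_\mathrm{AFM}), $$

gives the shell thickness — but only after dealing with three confounders
this package models explicitly: the two methods' opposite responses to
polydispersity, brush thinning on strongly curved (small) cores, and
particle deformation on the substrate.

`nanoshell` implements the full chain in both directions: a seeded
synthetic-data generator that emulates the study design (an 11-member gold
nanoparticle reference series, 5–250 nm nominal, plus polyplex populations),
and the analysis chain that recovers core size, shell thickness, grafting
density, and payload from AFM and DLS observables.

## Synthetic populations

All size distributions are log-normal, parameterized by median $m$ and
log-scale SD $\sigma$; this matches the distribution family used for AFM
size histograms throughout. A target relative SD maps to
$\sigma = \sqrt{\ln(1 + \mathrm{relSD}^2)}$ by the log-normal moment
identity, and the generator's sample median and relative SD converge to the
requested values. The gold series uses a constant relative SD of 0.05 across
all 11 nominal sizes — the defining property of the commercial series it
emulates (narrow, with constant relative width); the exact value is not
reported by any source, so 0.05 was fixed once as typical of citrate-gold
size standards.

Functionalization adds a uniform shell deterministically,
$d_2 = d_1 + 2L$: it shifts the distribution without broadening it, which is
the experimentally observed behavior of the intensity-weighted DLS
distributions before and after PEGylation.

Seeds are mandatory for every stochastic operation; an unseeded call is an
error. All draws are bit-reproducible under `withr::with_seed`.

## AFM forward model and analysis

`gen_afm_topograph()` renders each particle as a rigid spheroid resting on
the substrate plane, so the maximum pixel height equals the particle height.
Oblateness (attachment-induced deformation) enters only through
`shape_aspect` (lateral width / height): a particle of equivalent-sphere
diameter $d$ is rendered with height $h = d / a^{2/3}$ and width $w = a\,h$,
preserving its volume. Placement is by rejection sampling with a no-overlap
constraint; the background is a tilted plane plus Gaussian pixel noise. Tip
convolution, drift, and fluid-imaging artifacts are deliberately out of
scope, so end-to-end recovery tests validate the analysis chain, not AFM
physics.

The analysis chain mirrors standard practice:

* **Flattening** fits one first-order (plane) background per image by least
  squares over non-particle pixels and subtracts it. It is a projection
  (idempotent), exact on noise-free planes, and leaves the background at
  zero mean. `measure_topograph()` runs two passes: a first flatten/detect
  pass builds the particle exclusion mask, then the background is re-fitted
  with particles masked out — the automated counterpart of excluding
  particles by eye before computing a global background.
* **Detection** thresholds the flattened image and labels connected
  components (EBImage); regions smaller than `min_area_px` are dropped.
* **Measurement** takes the peak height $h$ and the two full widths at
  half-maximum height along perpendicular axes through the peak. Half-max
  was chosen as the width criterion because for a rendered spheroid the
  half-height contour sits exactly at the true lateral extent, and it is
  insensitive to the detection threshold.
* **Exclusions** are per-particle with reasons, never silent: border
  contact; and fused particles, flagged when the region's moment
  eccentricity exceeds 0.85. The 0.85 default is set from geometry: two
  fused equal disks reach eccentricity ≈ 0.89 at most (tangent), while
  isolated rendered particles with realistic noise stay far below 0.5, so
  0.85 separates the two cases with margin on both sides.

The equivalent-sphere diameter uses the volume-preserving spheroid
convention $d_\mathrm{eq} = (h\,w_1 w_2)^{1/3}$. When only heights are
usable (soft particles imaged at scale), the empirical shape correction
factor $f = \mathrm{median}(d_\mathrm{eq}/h)$ from a measured subset is
applied elementwise; $f$ is exactly 1 for spheres and scale-invariant. The
field-standard factors 1.2 (oligo-DNA polyplexes) and 1.7 (siRNA
polyplexes) are accepted as configuration overrides rather than derived,
since their derivation depends on imaging conditions the forward model does
not simulate.

Size distributions are fitted by maximum likelihood on log-diameters; the
reported mode is $m\,e^{-\sigma^2}$. The modal diameter is the AFM size
reporter throughout, matching the repeatability statements that are phrased
on modal heights.

## DLS forward model and inversions

The forward model is standard homodyne DLS physics: scattering vector
$q = 4\pi n \sin(\theta/2)/\lambda$, Stokes–Einstein diffusion
$D_t = k_B T / (3\pi\eta d)$, Rayleigh intensity weights $w_i \propto
d_i^6$, field correlation $g_1(\tau) = \sum_i w_i e^{-q^2 D_i \tau}$, and
$g_2 = 1 + \beta g_1^2$ with additive Gaussian noise. Defaults: 25 °C water,
633 nm, 173° backscatter, $\beta = 0.9$. The $d^6$ weighting is the Rayleigh
approximation and degrades above roughly $\lambda/10$ — the 200–250 nm
series members violate it — so every weighting consumer accepts a
substitute weight vector; Mie form factors are out of scope.

Two inversions are implemented:

* **Cumulant analysis** fits $\tfrac12\ln[(g_2-1)/\beta] = -\bar\Gamma\tau +
  \tfrac{\mu_2}{2}\tau^2$ over lags down to 10 % of the initial
  $g_2 - 1$ (a common instrument default; the choice was verified to be
  uncritical between 5 % and 30 %). The z-average is the Stokes–Einstein
  diameter at $\bar\Gamma/q^2$; $\mathrm{PDI} = \mu_2/\bar\Gamma^2$.
* **NNLS size distribution** solves a non-negative least-squares problem on
  a log-spaced diameter grid, with optional Tikhonov (second-difference)
  smoothing. The default is $\lambda = 0$: on noise-free or low-noise data
  plain NNLS resolves sharp modes exactly, while any visible smoothing
  spreads an exact spectral line over neighboring bins. The ladder
  $\lambda \in \{10^{-4},\dots,10^{-1}\}$ is an escalation path used only
  when the solver fails, trading resolution for stability with a warning.

The cumulant result is validated against an independent closed-form oracle,
the harmonic intensity-weighted mean $d_z = \sum w_i / \sum (w_i/d_i)$. For
a log-normal number distribution the intensity weighting shifts the log-mean
by $6\sigma^2$, so $d_z = m\,e^{5.5\sigma^2}$ and
$\mathrm{PDI} = e^{\sigma^2} - 1$; both identities were re-derived and
checked by numerical integration before being frozen into tests. Agreement
is within 2 % (z-average) and 10 % (PDI) for $\sigma \le 0.2$.

The same identities explain the DLS/AFM divergence on broad distributions:
`polydispersity_gap()` returns
$d_z - \mathrm{mode} = m\,(e^{5.5\sigma^2} - e^{-\sigma^2})$, zero only for
monodisperse samples and strictly increasing in $\sigma$. At $\sigma = 0.2$
and $m = 100$ nm the gap is already ≈ 28 nm — larger than the shells being
measured, which is why screening matters.

## Shell-thickness inference

`build_series_pair()` joins per-sample AFM modes and DLS z-averages;
unmatched labels are reported, duplicates rejected. `screen_rows()` flags —
never deletes — members below 50 nm ("curvature": on strongly curved cores
the same adsorbed PEG occupies more volume, thinning the brush; handled as
a cutoff rather than a correction formula) and members with
$\sigma > 0.15$ ("polydispersity"; 0.15 is this package's operational
definition of "narrow", chosen so the resulting z-average-vs-mode bias
stays below the measurement noise of the screened series).

`estimate_shell_thickness()` fits $d_\mathrm{DLS} = d_\mathrm{AFM} +
\Delta$ with the slope fixed at 1 — the bare reference series is 1:1 to
within noise, and freeing the slope would let polydispersity leverage the
large members; the free-slope fit is reported as a diagnostic only. $L =
\Delta/2$ with the (inverse-variance weighted, if weights are given)
standard error of the mean offset, halved. Negative fitted shells are
returned with a warning flag, never clamped.

The end-to-end study (`run_synthetic_study()`) estimates $L$ as the *shift
between trendlines*: the functionalized-series offset minus the
bare-series offset. Both offsets share the z-average-vs-mode polydispersity
bias, so differencing cancels it; this is also why the protocol measures a
bare reference series at all. On the default study (11 members, relative SD
0.05, DLS noise $10^{-4}$) the recovered shell is within 1 nm of truth for
both the 8 nm and 17 nm shell scales.

Monte-Carlo calibration (200 seeds, 7 members ≥ 50 nm, 2.8 % AFM and 1.6 %
DLS relative noise — the two methods' expanded uncertainty levels) shows
the estimator unbiased to ≪ 1 nm with ± 2·se coverage ≈ 94 %.

Uncertainty components combine in quadrature
($u_c = \sqrt{\sum u_i^2}$, the root-sum-of-squares rule) and expand with
coverage factor $k$; $k = 2$ is labeled as the 95 % confidence interval.

## Shell chemistry

The brush model $L = N a^{5/3} D^{1/3}$ links shell thickness to grafting
density $D$ (chains/nm²), with $N = 114$ monomers and $a = 0.35$ nm for
5-kDa PEG ($N$ = molar mass / 44.05 rounded). Its exact inverse recovers
$D$ from a measured $L$; round-trips are exact to $10^{-12}$ relative. At
the equilibrium density $D^* = 0.5$ PEG/nm² the model gives
$L = 15.7$ nm, consistent with the 17 nm shell measured by the
trendline method (within 10 %).

Titrations are mass-balanced exactly at every step
(uptake + supernatant = added). The default is hard saturation —
complete uptake until the surface capacity is reached, matching the
observed sharp concurrent plateau of uptake and shell thickness — with a
Langmuir-like `softness` option for robustness studies. `analyze_titration()`
flags saturation at the first step whose marginal uptake falls below 1 % of
the marginal addition, and recovers the generative plateau density within
2 % (hard) / 5 % (softness 0.2).

Payload per particle is volumetric bookkeeping:
$(\pi/6)d^3 \rho f / M_w \cdot N_A$, with core density $\rho = 1370$ µg/µL
(converted internally at 1 µg/µL = $10^{-24}$ g/nm³) and DNA mass fraction
$f$ from N/P stoichiometry, $f = 330/(330 + r\cdot 43.1)$ at molar ratio
$r$ (330 g/mol per phosphate, 43.1 g/mol per PEI nitrogen); $f = 0.657$ at
the fixed working ratio N/P = 4. This stoichiometric $f$ is a declared
default, configurable, since the core's exact PEI content is not measured
directly. Per-population payloads conserve total DNA mass to machine
precision.

The growth model closes the loop: if condensation proceeds until the PEG
grafting density over the total core surface relaxes to $D^*$, then at
fixed total core volume $V$ the equilibrium diameter is
$d = 6 V D^* / P$ with $P$ the total PEG count. Two consequences are
testable: core diameter is inversely proportional to the degree of
conjugation, and the total surface-area ratio of systems formulated at 7 %
vs 10 % conjugation equals $7/10 = 0.7$, independent of every other
parameter. When $P$ is derived from the blend's amine count, only the
PEGylated fraction $1/(1 + \mathrm{PEI/(R)PP})$ of amines can carry PEG;
with that bookkeeping a 50:1 blend at 7–10 % conjugation yields ~230–330 nm
cores, the observed scale for that formulation. Whether "percentage of PEI
amines conjugated" counts all amines or only primary ones is not settled;
the default amine count (581 per 25-kDa PEI, one nitrogen per 43 g/mol)
takes the all-amines reading and is exposed in configuration — every ratio
result, including 0.7, is unaffected by this choice.

The polydispersity-vs-blend-ratio trend is reported only qualitatively in
the source system (broadest near 10:1, narrowing again by 50:1), so the
generator's schedule is a declared stand-in: a Gaussian bump in
$\log(\mathrm{ratio})$ centered at 10:1 (baseline $\sigma = 0.05$, peak
0.25, width 0.6 log-units), user-replaceable wherever it is consumed.

## Problem sizes and numerical choices

Simulated campaigns are sized for desk-scale reproducibility: 400 particles
per gold population for the study summary; four 1600 nm fields at 2 nm/px
(320 analyzable particles) for the end-to-end AFM chain; 5000-particle
populations for cumulant-oracle comparisons; 200 seeds for estimator
calibration. Degenerate inputs are rejected with messages rather than
propagated: non-positive sizes, unseeded stochastic calls, all-masked
images, all-zero correlograms, empty label intersections, sub-minimal
screened series.

What passing these tests shows — and does not show: the synthetic data
share the real system's distribution family, noise magnitudes, and design
(reference series, titration, paired formulations), but not tip-sample
physics, Mie optics, aggregation, or instrument-specific regularization.
Agreement with the generative truth validates the inference chain; absolute
agreement with any real instrument still requires the usual reference
materials.
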
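# nanoshell

Dimensional and chemical metrology of self-assembled core–shell
nanoparticles from correlated AFM and DLS measurements.

Nucleic-acid delivery nanoparticles (polyplexes) are built from a dense
core — nucleic acid condensed by polyethylenimine (PEI) — wrapped in a
poly(ethylene glycol) (PEG) brush shell. Neither standard sizing method
sees the whole particle: AFM measures the rigid core (the brush collapses
under the tip), DLS measures the hydrodynamic size of core plus shell.
`nanoshell` is for researchers characterizing such particles: it combines
the two measurements into a shell-thickness estimate with an uncertainty
budget, and links the result to the shell's chemistry.

The core relations:

- shell thickness from paired sizes: `L = (d_DLS − d_AFM) / 2`, estimated
  from the systematic shift between DLS-vs-AFM trendlines over a particle
  series, after screening members < 50 nm (brush curvature) and broad
  distributions (the z-average and the AFM mode diverge as
  `m·(exp(5.5σ²) − exp(−σ²))` for a log-normal of median `m`, log-sd `σ`);
- DLS inversion: cumulant fit `ln g1 = −Γ̄τ + (μ₂/2)τ²` giving the
  z-average and PDI, and an NNLS size distribution on a diameter grid;
- AFM chain: first-order flattening, particle detection, height/width
  measurement, equivalent-sphere diameter `d_eq = (h·w1·w2)^(1/3)` with
  shape correction factor `f = median(d_eq/h)`;
- polymer-brush model `L = N·a^(5/3)·D^(1/3)` connecting shell thickness to
  PEG grafting density `D`;
- equilibrium growth model `d = 6·V·D*/P`: core growth arrests when the
  grafting density relaxes to the equilibrium value `D*`, which forces the
  total core surface-area ratio of formulations at 7% vs 10% PEG
  conjugation to 0.7;
- uncertainty combination `u_c = sqrt(Σ u_i²)`, expanded with coverage
  factor `k = 2` (95% confidence).

A seeded synthetic-data module generates every input the pipeline consumes
(gold reference series, AFM topographs, DLS correlograms, PEGylation
titrations, polyplex core populations), so the whole chain is testable end
to end.

## Worked example

Estimate a 17-nm PEG shell from a synthetic gold reference study:

```r
library(nanoshell)
st <- run_synthetic_study(default_config(seed = 42))
st$estimate
#> <shell_estimate> L = 16.86 nm (se 0.28 nm, n = 6, 5 excluded)
st$budget
#> <uncertainty_budget> u_c = 1.61%, U = 3.22% (k = 2, 95% confidence interval)
```

Six series members survive screening (the sub-50-nm members are flagged for
curvature; at this seed the 50-nm member's measured mode falls just below
the cutoff and is screened too). The recovered
shell thickness (trendline shift between the functionalized and bare
series, halved) is within the combined AFM/DLS uncertainty of the
generative 17 nm. The brush model ties this to the shell's grafting
density:

```r
brush_thickness(n_monomers = 114, monomer_nm = 0.35, density_per_nm2 = 0.5)
#> [1] 15.72805   # nm, consistent with the measured 17-nm shell
payload_count(30)  # oligos in a 30-nm core at N/P = 4
#> [1] 596.2042
surface_area_ratio(7, 10)
#> [1] 0.7
```

The numbered drivers under `analysis/` run the same chain as a file-based
workflow (simulate → AFM analysis → DLS analysis → shell inference → shell
chemistry), writing CSV tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

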
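# condensinhic

Quantifying how condensin II levels reshape interphase chromosome
organisation, from binned Hi-C contact matrices and 3D FISH
observations.

Condensin II activity compacts whole chromosomes during interphase:
raising it (e.g. by depleting the SLMB adaptor that degrades its Cap-H2
subunit) strengthens long-range and pericentric interactions, while
depleting Cap-H2 relaxes them. The package implements the full
quantification stack for this phenotype and a forward simulator with a
planted condensin-activity parameter λ (1 = control, >1 = elevated,
<1 = depleted) so that every estimator is validated against ground
truth:

- **Hi-C IO and normalisation** — bin-table/triplet text matrices,
  iterative-correction balancing to equal per-bin marginals,
  observed/expected transforms, coarsening.
- **Compartments** — arm-wise eigenvectors of the O/E correlation
  matrix; A/B calls as same-sign PC1 runs ≥ 20 kb; pericentric (P)
  compartments by seeded k-means on the first three eigenvectors.
- **Distance metrics** — P(s) decay curves with slope fits and curve
  crossovers; short/long contact ratio (1 Mb cutoff, ≥ 1 Mb counts
  long); per-chromosome trans-contact proportions; chromatin-state
  stratified interaction strengths; numbered compartment-pair scores
  with fold changes; HiCRep-style stratum-adjusted correlation (SCC).
- **Differential structure** — antisymmetric log2 differential maps;
  insulation-score TAD boundaries with a Same / Shift (15–70 kb) /
  Lost / Gained / Split / Merge taxonomy (≤ 10 kb = Same); virtual 4C
  with size-matched random control anchors.
- **FISH metrics** — 3D connected-component domain counts, voxel-face
  surface areas, channel overlap fractions, probe-pair contact and
  minimum distance, and power-law fits of 3D distance versus genomic
  separation, d = A·s^β.

At its core the simulator gives cis pairs
`B[c_i,c_j] · s^-α(λ) · (1 + σ(λ−1))^[one end in P]` with
`α(λ) = α0 − κ·log2 λ`, a trans background `τ0·λ^-γ` away from P, and
joint row scaling to constant coverage — so the short-to-long shift,
trans depletion and pericentric stripe all emerge from the single
parameter λ. See `vignettes/condensin-hic-methods.Rmd` for the model,
estimator definitions, and numerical choices.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → compartments → distance metrics → differential/v4c → FISH),
each writing tables under `results/`. Running them in order prints,
among other things:

```
$ Rscript analysis/02_compartments.R
balanced control map: 2000/2000 bins unmasked
chr2L: 28 compartments, A/B sign agreement with truth 100.0%
chr2R: 32 compartments, A/B sign agreement with truth 99.8%
k-means P cluster: purity 97.5%, recall 99.5%

$ Rscript analysis/03_distance_metrics.R
  condition   ps_slope short_long   trans_prop
 lambda_0.5 -1.3288627  16.476912 0.6929486836
   lambda_1 -1.0284948   4.544535 0.0519626971
   lambda_2 -0.7242137   1.476594 0.0009651314
SCC control vs replicate (h=20, <=20Mb): 0.936
```

Reading this: the eigenvector analysis recovers the planted A/B
checkerboard nearly perfectly and the k-means P cluster isolates the
planted pericentric domain; the fitted P(s) slopes track the planted
exponents (α = 1.3, 1.0, 0.7 at λ = 0.5, 1, 2), and both the
short/long contact ratio and the trans proportion fall monotonically as
condensin activity rises — the directional signature of condensin II
gain. `analysis/04_differential_v4c.R` additionally shows the
compartment-pair fold change at ≥ 1 Mb rising above 1 under λ = 2 (and
falling below 1 under λ = 0.5), and the P-anchor virtual-4C gain
exceeding every size-matched control anchor.

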
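---
title: "Quantifying condensin II-dependent chromosome folding from Hi-C and FISH"
author: "condensinhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensin II-dependent chromosome folding from Hi-C and FISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Condensin II is an SMC complex whose interphase activity compacts whole
chromosomes. Depleting its kleisin subunit (Cap-H2) lowers activity;
depleting the F-box adaptor SLMB, which targets Cap-H2 for degradation,
raises it. Titrating condensin II this way changes *long-range*
chromosome organisation — the balance of short- versus long-range
contacts, inter-chromosomal (trans) contact levels, interactions between
distant A/B compartments, and the behaviour of the pericentric
heterochromatin ("P") compartment at the centromeric end of each
chromosome arm — while leaving TADs and compartment identity largely
intact. This package implements the quantification stack needed to
measure those effects from binned Hi-C contact matrices and from 3D FISH
observations, together with a forward simulator that plants all of the
relevant structure so every estimator can be validated against ground
truth.

Throughout, condensin II activity is a single positive parameter
$\lambda$: $\lambda = 1$ is the control, $\lambda > 1$ emulates elevated
condensin II (SLMB knockdown), $\lambda < 1$ emulates depletion (Cap-H2
knockdown).

## The forward model

The simulator defines a genome of chromosome arms tiled by alternating
A/B blocks with a terminal P domain at each arm's centromeric end
(defaults: two 10 Mb arms, 10 kb bins — 2,000 bins; 500 kb blocks; 1 Mb
P domains). The deterministic expected contact between bins $i,j$ is

- cis, separation $s$:
  $B_{c_i c_j}\, s^{-\alpha(\lambda)} \cdot
  \big(1 + \sigma(\lambda - 1)\big)^{[\text{exactly one of } i,j \in P]}$
- trans, at least one end in P:
  $\tau_0\, B_{c_i c_j} \cdot \big(1 + \sigma(\lambda - 1)\big)$
- trans otherwise: $\tau_0\, \lambda^{-\gamma} B_{c_i c_j}$

with $\alpha(\lambda) = \alpha_0 - \kappa \log_2 \lambda$. Rows are then
jointly rescaled (symmetric iterative proportional fitting) so the
expected coverage per bin is constant, exactly as balancing would
enforce on real data; the short-range/long-range trade-off therefore
emerges from the single exponent change rather than a hand-tuned
crossover. Sampled matrices add independent Poisson noise per pair,
scaled to a target depth — the standard shot-noise model for contact
counts.

The trans terms deserve a note. Elevated condensin II *reduces* global
inter-arm contacts while *specifically enhancing* contacts emanating
from the P compartment across the centromere (the "pericentric
stripe"). We model this by exempting P-involving trans pairs from the
global $\lambda^{-\gamma}$ depletion and giving them the stripe factor
instead. Because joint balancing forces every bin to the same coverage,
only *compositional* changes within a bin's contact profile survive
normalisation: the stripe is therefore detectable in absolute units in
cis, but in trans it manifests as the P anchor's enrichment *relative
to size-matched control anchors* (which the directionality tests use),
not as an absolute rise of every trans entry.

Default parameters: $\alpha_0 = 1$, $\kappa = 0.3$, $\sigma = 1$,
$\gamma = 1$, $\tau_0 = 0.05 \times$ the cis level at 1 Mb, affinities
$B_{AA} = B_{BB} = 1.5$, $B_{AB} = 0.7$, $B_{PP} = 3.0$,
$B_{PA} = B_{PB} = 1.0$. These produce visible checkerboarding, a
strongly self-interacting P domain, and monotone responses of every
directional metric over $\lambda \in \{0.5, 1, 2\}$. FISH distances for
a probe pair at genomic separation $s$ follow
$d = A_f\, s^{\beta(\lambda)} e^{\varepsilon}$ with
$\beta(\lambda) = \beta_0 - \kappa_f \log_2 \lambda$
($A_f = 4.2\times10^{-3}$ µm, $\beta_0 = 0.33$, $\kappa_f = 0.05$,
$\varepsilon \sim N(0, 0.3^2)$) — about 0.4 µm at 1 Mb, shrinking with
condensin level.

What the generator does *not* emulate: polymer dynamics or
loop-extrusion mechanics, homolog pairing (one copy per locus), genomic
distance-dependent trans structure, mappability/GC bias, and the
specific crossover scale real data shows near 285 kb. A passing test
suite therefore demonstrates that the estimators recover planted
structure of the right *kind* and direction, not that real data would
yield any particular numeric value.

## The estimators

**Balancing.** Iterative correction (proportional fitting) to unit
per-bin marginals, with a sparsity mask (bins below 2% of the densest
bin's nonzero count). KR normalisation and iterative correction enforce
the same balanced-marginal property, which is the contract every
downstream metric relies on and which the tests assert directly
(marginal deviation < 1e-6); iterative correction is preferred here for
its simple, directly testable post-condition.

**Compartments.** Per arm: observed/expected of the cis map (per-diagonal
means over unmasked pairs; empty diagonals stay missing), a light 2D
mean-filter smooth (half-window 2 bins — the analogue of computing
eigenvectors at a super-resolution window above the bin size), Pearson
correlation matrix, eigendecomposition. PC1 is oriented so active-state
bins average positive, so positive PC1 = A. Contiguous same-sign runs of
at least 20 kb become compartments; shorter runs are absorbed into the
larger flanking run (ties upstream) so the calls partition the arm, and
compartments are numbered consecutively along the genome.

**P compartments.** k-means (k = 3, 20 restarts, seeded) on the first
three eigenvectors, run *arm-wise* because eigenvector sign and
component order are arbitrary per decomposition — pooling arms would mix
incompatible sign conventions. Components are standardised before
clustering; without this a pure-noise component (eigenvector entries all
at the same scale regardless of eigenvalue) dominates the Euclidean
metric. The cluster lying closest on average to the declared centromeric
arm end is designated P; the arm's P interval is the largest consecutive
run of P-cluster bins; an inertia-versus-k table supports scree
inspection.

**Distance metrics.** P(s) uses log-spaced shells (8 per decade), shell
means over all unmasked pairs with implicit zeros, normalised to unit
mass. The slope is fitted over 100 kb–5 Mb on the euchromatic arm body
(P domain excluded): the checkerboard makes per-shell mean affinity
oscillate with the block period, and a window spanning several periods
away from the P domain keeps that oscillation from biasing the fit —
with these defaults the planted exponent is recovered to within ±0.05
without sampling noise and ±0.15 at 10^6 sampled contacts.
Short/long contact ratios use a 1 Mb cutoff with pairs at exactly the
cutoff counted long. Trans proportions are computed on raw matrices
(500 kb bins in the workflow) and normalised per source chromosome so
each row sums to one. Compartment-pair scores average balanced values
over all bin pairs of two control-numbered compartments, filtered by
midpoint separation (defaults 500 kb–5 Mb; both this window and the
300 kb variant are parameters), and fold changes are taken per pair
against the control condition. SCC follows the stratum-adjusted
correlation definition: 2D mean-filter smoothing (half-window h = 20
bins by default), per-separation-stratum Pearson correlations up to
20 Mb, combined with $N_d \sqrt{\operatorname{var}(\text{rank}\,x)\,
\operatorname{var}(\text{rank}\,y)}$ weights.

**Differential structure.** Differential maps are per-pair
log2 ratios of depth-matched balanced values with a shared pseudocount
(1e-3 of the pooled mean), making the map exactly antisymmetric under
condition swap. TAD boundaries come from diamond insulation-score minima
(window 100 kb, log2 prominence 0.1; plateau minima collapse to their
centre). The boundary-change taxonomy matches control and knockdown
boundaries greedily by distance, one-to-one: ≤ 10 kb is "Same",
15–70 kb is "Shift", matches in the 10–15 kb gap are reported
explicitly as "Unclassified" rather than silently binned (at 5–10 kb
bins this gap is off-grid), matches beyond 70 kb dissolve into
Lost + Gained, and whole-domain containment (≥ 2 domains inside one)
defines Split/Merge. Virtual 4C averages balanced contacts from all
unmasked anchor bins to each target bin, flags anchor self-bins, and
excludes them from profile differences; size-matched control anchors are
placed uniformly on the bin grid avoiding the anchor and declared
exclusion intervals.

**FISH metrics.** Domain counts are 3D connected components
(26-connectivity by default, configurable to 6); surface areas count
exposed voxel faces with anisotropic voxel dimensions; intermixing is
the directional overlap fraction of one channel's voxels with another;
probe-pair contact is "overlap of at least one voxel" (or a centroid
distance threshold); minimum distances scan all focus combinations
(diploid homologs allowed). Power-law scaling fits are least squares in
log-log space, by default on per-separation medians, exact on noiseless
input.

## Numerical choices and degenerate inputs

Balancing converges geometrically; matrices whose structure admits no
equal-marginal scaling (for example a bin whose only contact partner
also carries a diagonal) abort with the final marginal deviation after
the iteration cap. Bins with empty or constant O/E rows are masked from
the eigenanalysis. All-masked arms yield empty segmentations rather than
errors. P(s) shells and O/E diagonals with no unmasked pairs are flagged
missing and excluded from fits, never zero-filled. Curve crossovers
interpolate linearly in log-log space and return a none-result when the
log-ratio never changes sign (identical curves, constant offsets).
The single global seed derives per-stage seeds by stage-name hashing, so
adding a stage never shifts another stage's randomness.

## Problem sizes

The validation suite and the reproduction script use the default
synthetic genome (2,000 bins at 10 kb, two arms) at 10^6 sampled
contacts per condition, 500 FISH observations for interval estimates and
100 seeded replicates for ordering checks; oracle-equivalence checks run
on ≤ 50-bin instances against dense brute-force recomputation at 1e-10.

## Known limitations

Real Hi-C data carry mappability structure, translocations and
copy-number effects the mask model does not represent; the X-chromosome
half-arm splitting used on real data generalises here to per-arm
sub-regions supplied by the caller. The insulation-based TAD caller is a
deliberate stand-in for FDR-based multi-window callers — the reusable
contribution is the boundary-change taxonomy, which is implemented
verbatim and is caller-agnostic. Whether per-pair percent changes are
averaged before or after the ratio is a genuine reporting ambiguity;
`fold_change` returns per-pair values so either aggregation can be
formed. The pipeline starts from label masks and centroids; raw
microscopy segmentation and spot calling are out of scope.
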
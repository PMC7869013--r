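---
title: "Backbone-geometry PLI scoring: model, assumptions and numerical choices"
author: "ssnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone-geometry PLI scoring: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: what is computed,
under which assumptions, which knobs matter, and where the design was
genuinely open.

## 1. The protein representation

A chain is reduced to its ordered Cα coordinates and interpolated by a
cubic spline space curve, one spline per coordinate against the cumulative
chord-length parameter. Per residue we report the curve's scalar curvature
κ (Å⁻¹, ≥ 0) and torsion τ (Å⁻¹, signed), computed with the general
non-unit-speed formulas

$$\kappa = \frac{|r' \times r''|}{|r'|^3},\qquad
\tau = \frac{(r' \times r'')\cdot r'''}{|r' \times r''|^2},$$

which coincide with the arc-length forms $\kappa = |r''(s)|$ and
$\tau = [r',r'',r''']/|r''|^2$ when $|r'| = 1$. Together with arc length,
(κ, τ) determine the curve up to rigid motion, so the representation is
exactly rotation/translation invariant, mirror-antisymmetric in τ, and
scales as 1/c when coordinates scale by c — all three symmetries are
asserted to 10⁻⁶ in the tests.

**Why cell averages rather than point values.** A Cα trace samples an
α-helix at ~100° of turn per residue — 3.6 points per period. At that
density an interpolating cubic spline is systematically *smoother than the
underlying curve at its knots*: for an ideal helix (a = 2.3 Å,
b = 0.8594 Å/rad) the spline's pointwise curvature at the anchors
underestimates the true a/(a²+b²) = 0.3815 Å⁻¹ by ~49%, and no
parameterization fixes this (for uniform sampling, chord and arc-length
parameters are affinely identical). The curvature the spline *does* carry
is distributed along the segments between anchors. The default estimator
therefore reports, for residue i, the average of the spline's profile over
the residue's arc cell (from the midpoint toward residue i−1 to the
midpoint toward i+1): curvature weighted by spline speed (an arc-length
average), torsion weighted by |r′ × r″|, the magnitude that defines where
torsion is well-conditioned. This recovers ideal-helix κ within 1.9% and τ
within 3.9% at 100°/anchor, is exact on circles and lines, and preserves
all three symmetries exactly. Pointwise anchor evaluation remains available
as `method = "anchor"`.

Numerical details:

* **Quadrature.** 32 midpoint-rule nodes per cell. Midpoint nodes never
  coincide with spline knots, where the third derivative is discontinuous;
  node-on-knot evaluation would make τ sensitive to last-bit rounding and
  break the 10⁻⁶ symmetry contracts.
* **End conditions.** `stats::splinefun(method = "fmm")`: an exact cubic
  through the four end points supplies the boundary derivatives. Natural
  splines would force κ = 0 at the termini. Terminal residues are
  extrapolation-sensitive either way; tests treat residues ≥ 3 from an end
  as interior.
* **Degenerate torsion.** τ is undefined where κ ≈ 0; wherever
  |r′ × r″| < 10⁻⁸ the torsion integrand is set to 0 (straight-segment
  limit), and a whole cell with no binormal signal reports τ = 0.
* **Chain breaks.** Gaps (Cα–Cα > 6 Å) are splined through with a warning
  rather than splitting the chain; the resulting κ spike is localized to
  the gap.

The network input is a fixed 2 × 9000 matrix: 6 chain slots × 1500
residues per slot (curvature row, torsion row), chains in file order, with
a validity mask; larger structures error unless truncation is requested.
The padded size follows the architecture's design envelope — most PDB
entries fit within 6 chains × 1500 residues. Values are fed raw (Å⁻¹, no
normalization): the physical scale is shared across proteins, and the
first-layer filters learn on it directly.

PDB handling is deliberately minimal and explicit: `ATOM`/`CA` records of
the first `MODEL` only, HETATM excluded, alternate locations resolved to
highest occupancy (ties to altloc `A`), insertion codes kept in file
order. The fixed-width reader/writer are authored here because these
resolution rules and line-numbered parse errors are part of the contract;
`bio3d` serves as an independent cross-check oracle in the tests.

## 2. The ligand representation

Ligands are extended-connectivity circular-substructure fingerprints:
atom-centered environments of radius 0..2 are iteratively hashed
(neighbor tuples sorted, duplicate environments covering the same atom set
removed) and folded into 1024 bits. SMILES parsing, canonicalization and
hydrogen handling go through OpenBabel (ChemmineR/ChemmineOB); the hashing
is implemented in the package with exact double-precision integer
arithmetic, so fingerprints depend only on the molecular graph — any
SMILES of the same molecule yields identical bits, and growing the radius
only adds bits. Radius 2 with 1024 bits are the field's customary
ECFP4-equivalent defaults; both are configurable, and no claim is made
that they match any particular trained model's settings. OpenBabel
silently repairs some malformed SMILES, so a syntax pre-check (balanced
brackets, paired ring closures, legal characters) enforces the
invalid-ligand error contract.

## 3. The scoring network

Per branch κ ∈ {5, 10, 15, 20} (window size in residues), N stacked 1D
convolutions of R filters (ReLU, 'same' padding, 2 input channels at the
first layer) run along the residue axis of each chain's valid segment.
'Same' padding keeps latent column i aligned with residue i at every
depth — this is what makes Grad-CAM's position-to-residue mapping the
identity. Chains are convolved independently over their valid columns
(equivalent to convolving the zero-padded tensor, since padding is zero
and pooling is masked), so perturbing masked positions provably never
changes the score — asserted bit-exactly in the tests.

The variable-length latent space is collapsed per branch into the global
max vector $d_\kappa$ and the total-variation vector
$v_\kappa = d_\kappa - \min$ (so $v_\kappa \ge 0$ always), concatenated in
the order $[d_5, v_5, d_{10}, v_{10}, d_{15}, v_{15}, d_{20}, v_{20}]$,
and embedded by a dense ReLU layer; the fingerprint is embedded likewise;
the concatenated embeddings pass through one hidden ReLU layer and a
sigmoid output. The loss is mean binary cross-entropy with scores clipped
to [10⁻⁷, 1 − 10⁻⁷].

One published description lists branch sizes {5, 10, 15, 30}, while the
embedding equation and the surrounding text use {5, 10, 15, 20}; this
package defaults to {5, 10, 15, 20} (the majority and internally
consistent reading) and leaves the sizes configurable.

**Configurations.** Hidden sizes of the original architecture were not
published with it; the defaults here are the package's own and are stated
explicitly so results are reproducible: `full` uses N = 3 layers × R = 128
filters, 128-unit embeddings, 64-unit hidden layer, Adam at 10⁻⁴. The
`small` preset (N = 2, R = 16, 32-unit embeddings, Adam at 10⁻³) is the
desk-scale configuration used by the synthetic benchmark; it trains in
minutes on one CPU while retaining every architectural element. No
dropout or weight decay is applied in either configuration.

**Training.** Every epoch uses all positives plus an equal-sized fresh
random resample of the negatives (balanced dynamic negative sampling);
minibatch Adam with He initialization. All randomness flows from one
integer seed, and two runs with the same seed produce bit-identical
weights (asserted in tests). Gradients are computed by authored
backpropagation through the entire graph — including the max/min pooling,
which routes gradients to the (first) arg-max/arg-min columns — and the
convolution kernels are RcppArmadillo; analytic gradients match central
finite differences to < 10⁻⁴ relative error on a small model.

Affinity-labeled data are binarized by the two-threshold rule: active
below 100 nM, inactive above 10,000 nM, records in between discarded.
The active/inactive decision threshold on scores is 0.5 (configurable).

## 4. Grad-CAM attribution

For each branch, the channel weight is the gradient of the sigmoid score
averaged over valid positions,
$\alpha_k = \tfrac1Z \sum_i \partial \hat y / \partial X^{(N)}_{k,i}$, and
the raw map $\sum_k \alpha_k X^{(N)}_{k,i}$ is rectified and normalized to
max 1. Two open choices, both exposed as arguments:

* **Gradient sign.** The method is sometimes printed with a negated
  gradient; the standard positive-gradient convention is the default
  (binding-relevant regions must score *highest*), `negate_gradient = TRUE`
  negates.
* **Branch aggregation.** Whether heatmaps should come from one branch or
  all is not fixed by the method; the default aggregates per-branch
  normalized maps by elementwise mean and renormalizes, and per-branch
  maps are returned alongside.

With max pooling, $\partial \hat y / \partial X^{(N)}$ is nonzero only at
arg-max/arg-min columns; the weighted *activation* sum still spreads the
map over all positions. The invariant max(S) = 1 (or S ≡ 0, with a warning
when the gradients themselves vanish) holds for every computed heatmap.
Heatmaps are exported as CA-only PDBs with B-factor = 100·S for rainbow
rendering, and `proximity_hit_rate()` scores highlighted residues (top
decile of S by default) against annotated reference residues at distance
cutoffs — a fraction that is provably non-decreasing in the cutoff.

## 5. Screening metrics

AUROC is the tie-corrected Mann–Whitney statistic (midranks), invariant
under monotone transforms; `pROC` is used in the tests as an independent
cross-check, never as the implementation. The enrichment factor at X%
takes the top ⌈X·N/100⌉ of the stable descending ranking (ceiling and
stable tie order: deterministic and conservative), giving EF = 1 for the
whole list and a maximum of min(N/N_X%, N/n_actives). Early-recognition
alternatives (e.g. BEDROC) are deliberately omitted: EF is the comparison
statistic used throughout, and adding a second early-recognition metric
would not change any decision the package supports. The
conformation-consistency report counts predicted actives per conformation
at the 0.5 threshold, the percent error 100·|A − B|/A, and the Pearson
correlation of raw scores.

## 6. The synthetic benchmark: what it shows and what it does not

`make_synthetic_dataset()` defines the package's study conditions: 200
proteins × 50 ligands (10,000 pairs, full cross), single chains of 100
residues, a 30-residue ideal-helix motif spliced (as rotated step vectors,
keeping the trace connected) into a random half of the proteins at a
random interior position, ligands as random 1024-bit vectors at 5%
density with one key bit forced on in a random half, and label =
(motif AND key bit) flipped with probability ε = 0.02. The conjunction is
deliberate: a protein-only or ligand-only shortcut caps well below the
achievable AUROC, so only the joint embedding can recover the rule — the
benchmark exercises the concatenation pathway, not just one tower.

Default ε: label noise is kept mild but nonzero, as in curated binary
activity data. The ceiling analysis fixes the scale: with pair-level
holdout, even a *perfect* rule scorer has expected AUROC
≈ P₁(1−Q₁) + ½(P₁Q₁ + (1−P₁)(1−Q₁)) where P₁/Q₁ are the rule-positive
fractions inside the noisy label classes — ≈ 0.97 at ε = 0.02 and already
≈ 0.92 at ε = 0.05. A trained small model reaches ≈ 0.96 held-out AUROC at
ε = 0.02 within 20 epochs.

The coil background is a direction-correlated random walk (persistence
0.5) with 1-2-1 position smoothing, rescaled to 3.8 Å steps — it emulates
the *geometric texture* of irregular backbone, not real coil statistics.
What the generator does **not** emulate: real secondary-structure
mixtures (sheets, turns), multi-chain complexes, chemically realistic
ligands or property-matched decoys, affinity distributions, or any
structure–ligand physical compatibility beyond the planted rule. Passing
the benchmark therefore demonstrates that the implementation can extract
a localized backbone motif and couple it with a fingerprint bit through
the full pipeline — it is an implementation validation, not evidence of
screening accuracy on real targets, which would require the large public
benchmarks and full-scale training.

Benchmark problem sizes (the package's choices, stated for
reproducibility): small preset, 80/20 pair holdout, 20 epochs, Grad-CAM
localization averaged over 20 positive pairs, conformation consistency via
0.1 Å Gaussian jitter of one motif protein rescored against all 50
ligands.

## 7. Known limitations

* Backbone geometry is conformation-*robust* by construction, which also
  means mutations preserving the fold are invisible: the scorer is a
  screening filter, not an affinity predictor.
* Terminal residues (±3 from chain ends) carry extrapolation-sensitive
  κ/τ; chains shorter than ~8 residues are mostly "ends".
* The full-scale configuration is provided but untrained weights are not
  distributed; training it to published-benchmark quality requires
  GPU-scale data and compute outside this package's scope.
* Fingerprint hashing collisions are possible at 1024 bits (standard for
  folded ECFP); raise `n_bits` when collision-free bits matter.
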
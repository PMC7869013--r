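# ssnet

Secondary-structure-driven scoring of protein–ligand interactions (PLI) in R.

Virtual screening needs a fast first-pass scorer that ranks millions of
candidate ligands against a protein target before any docking is attempted.
`ssnet` implements a structure-based deep scoring approach in which the
protein is not represented by atoms or pockets but by the differential
geometry of its backbone: each chain's Cα trace is interpolated by a cubic
spline **r**(s) and summarized per residue by its scalar curvature and
torsion,

    κ(s) = |r′ × r″| / |r′|³ ,   τ(s) = (r′ × r″)·r‴ / |r′ × r″|² ,

which reduce to the classical Frenet–Serret quantities |r″(s)| and
[r′, r″, r‴]/|r″|² under arc-length parameterization. Helices, strands,
turns and coils each leave a distinctive (κ, τ) signature, so the pair of
per-residue profiles is a compact, rotation- and conformation-robust
encoding of the fold. Ligands enter as extended-connectivity (ECFP-style)
circular-substructure fingerprints hashed from SMILES.

A multi-branch 1D convolutional network scores the pair:

* four convolution branches with window sizes K = 5, 10, 15, 20 residues
  (N stacked ReLU convolutions of R filters each, 'same' padding) slide
  along the padded 2 × 9000 curvature/torsion input (6 chain slots × 1500
  residues, masked);
* each branch is collapsed by masked global-max pooling **d**κ and a
  total-variation vector **v**κ = max − min per filter;
* `[d₅, v₅, d₁₀, v₁₀, d₁₅, v₁₅, d₂₀, v₂₀]` feeds a dense protein embedding,
  the fingerprint a dense ligand embedding, and two final dense layers end
  in a sigmoid score ŷ ∈ [0, 1];
* training minimizes binary cross-entropy with Adam, re-sampling an
  equal-sized fresh set of negatives every epoch so abundant decoys never
  swamp the positives.

Grad-CAM attribution maps the score's gradient back through the final
convolution layer to per-residue importances S ∈ [0, 1], exported as a
B-factor-colored CA-only PDB so any viewer highlights the residues driving
a prediction. Screening quality is measured by tie-corrected AUROC and
enrichment factors EF X% = (actives in top X% / N_X%) / (actives / N), and
conformation robustness by rescoring the same ligand list against a second
conformation of the target.

Because published PLI benchmarks require multi-GB downloads and GPU
training, the package ships a fully synthetic, desk-scale validation
instead: ideal helices/circles/lines with closed-form κ/τ oracles, and a
planted-rule dataset (label = helix motif present AND key fingerprint bit
set, plus label noise) on which the whole stack — featurization, training,
screening metrics, Grad-CAM localization — is exercised end to end.

## Worked example

```r
library(ssnet)

# ideal alpha-helix: 50 residues, radius 2.3 A, rise 1.5 A, 100 deg/residue
h <- make_helix_trace(50)
prof <- decompose_chain(h)
round(c(kappa = mean(prof$curvature[4:47]), tau = mean(prof$torsion[4:47])), 4)
#>  kappa    tau
#> 0.3883 0.1452
# closed form: kappa = a/(a^2+b^2) = 0.3815, tau = b/(a^2+b^2) = 0.1426 (1/A)

pt <- build_protein_tensor(prof)
pt
#> protein tensor: 2 x 9000 (6 chain slots x 1500), 50 valid positions in 1 chains

fp <- ecfp_fingerprint("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
fp
#> ligand fingerprint: CC(=O)Oc1ccccc1C(=O)O | 24/1024 bits set (radius 2, 25 environments)
tanimoto(fp, ecfp_fingerprint("OC(=O)c1ccccc1OC(C)=O"))
#> [1] 1     # same molecule, different SMILES

# end-to-end planted-signal benchmark (small model, ~5 min on one CPU)
bench <- planted_benchmark(seed = 0)
round(c(auroc = bench$auroc, ef10 = bench$ef10, gradcam = bench$gradcam_overlap), 3)
#>   auroc    ef10 gradcam
#>   0.959   3.726   0.994
```

`auroc` is held-out ranking quality for the planted binding rule (0.5 =
chance; the label-noise ceiling is ≈ 0.97), `ef10` the enrichment of true
actives in the top 10% of the ranked screen (bounded by N/n_actives ≈ 3.8
at the planted ~26% active rate, so 3.73 is near-perfect early
recognition), and `gradcam` the fraction of
top-decile heatmap mass falling inside the planted helix motif (1 = all
attribution on the true signal).

A command-line front end (`inst/cli/ssnet`) exposes `featurize`,
`fingerprint`, `train`, `predict`, `gradcam`, `eval`,
`compare-conformations` and `synth` subcommands over the same functions.

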
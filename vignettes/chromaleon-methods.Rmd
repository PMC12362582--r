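---
title: "Methods: chromatographic chameleonicity, conformer property space and oral bioavailability"
author: "chromaleon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatographic chameleonicity, conformer property space and oral bioavailability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaleon)
```

## The problem

Heterobifunctional degraders (PROTACs) live far beyond the Rule of 5:
molecular weights around 1000 Da, topological polar surface areas well
above 200 Å², a dozen rotatable bonds. Classical property rules predict
they should not be orally bioavailable, yet some are. The working
explanation is *chameleonicity*: the ability to expose polarity in water
while folding into a compact, low-polarity conformation inside membranes.
`chromaleon` implements the measurement-and-analysis layer of that
hypothesis: chromatographic descriptors that quantify lipophilicity,
polarity and chameleonicity from retention data; noncompartmental oral
bioavailability from plasma curves; geometric descriptors of conformer
ensembles; and the relation layer linking descriptors to efflux and F%.

## Chromatographic descriptors

All capacity factors are base-10 logarithms of k' = (t_R − t_0)/t_0, the
chromatographic convention.

* **BRlogD** — surrogate of log D(octanol/water). From log k' at 60%
  acetonitrile on an XBridge Shield RP18 column, via the calibration line
  BRlogD = 3.31·log k'60 + 2.79.
* **log k'80 PLRP-S** — retention at 80% MeCN on a polymeric reversed
  phase; a surrogate of toluene/water partitioning, i.e. of the membrane
  core environment.
* **log k\_w^IAM** — lipophilicity on an immobilized-artificial-membrane
  column. Retention is measured at several organic fractions (10–50%),
  the linear trend is extrapolated to the fully aqueous eluent. The
  source method description contains an internal contradiction here ("the
  extrapolated value at 100% ACN (0% aqueous buffer)"): the w subscript
  denotes water, and the 10–50% measurement range extrapolates naturally
  to 0% organic, so the package extrapolates to 0% by default and exposes
  `target_fraction` for users who want the other convention.
* **Δlog k\_w^IAM** — measured log k\_w^IAM minus the baseline expected
  from lipophilicity alone, clog k\_w^IAM = 0.92·BRlogD − 1.03. Values
  above 1.5 are flagged as excessive polarity.
* **Chamelogk** — the chameleonicity index. On the PLRP-S phase log k'
  is linear in organic fraction over 50/60/70% MeCN; a chameleon folds in
  nearly pure organic eluent and retains more than the linear trend
  predicts at 100%. Chamelogk = measured log k'100 − extrapolated
  log k'100; values above 0.6 class as strong chameleons. The fit uses
  exactly the 50/60/70 points; other compositions are ignored with a
  warning, because the linear regime is part of the method definition.
* **ETR** — EPSA/TPSA, a polarity-masking index (EPSA and TPSA are input
  metadata; the package never predicts them). Missing inputs propagate
  as missing, never imputed.

The calibration coefficients ship in `chromatographic_calibration()` so a
laboratory that recalibrates against its own standards can swap them
without code changes.

**Ionization classing.** Retention of the neutral species on PLRP-S is
pH-independent, so comparing log k'80 at pH 2, 7 and 12 reveals
ionization: depression of more than 0.3 log units relative to the maximum
marks the ionized condition. The 0.3 threshold is a design choice, set
clearly above retention-time reproducibility noise, and is configurable.
The precedence is: depression at both extremes → AMPHOTERIC; at pH 2 →
BASE_IONIZED (a base ionized at gastric pH is reported as such even when
neutral at pH 7, because that is the pharmacokinetically decisive
behavior); otherwise, pH 7 retention within 0.3 of the maximum → NEUTRAL;
depression at pH 12 with pH 7 also depressed → ACID_IONIZED. A profile
depressed only at pH 7 has no consistent reading and returns
UNDETERMINED with a warning.

## Noncompartmental bioavailability

F% = (AUC_oral/dose_oral)/(AUC_IV/dose_IV) × 100, with AUC from the
linear trapezoid between the first and last observed timepoints. No
extrapolation to infinity is performed: the source protocol's proprietary
NCA settings are undisclosed, and truncation at the last observation is
the conservative, assumption-free default. A linear-up/log-down variant
(`method = "linear-log"`), exact on mono-exponential decay segments, is
available for sparse late sampling. Concentrations below the limit of
quantification are treated as missing and dropped with a warning. Classes
follow F < 1% (very low), F < 5% (low), F > 5% (medium/high); the
boundary values themselves take the milder class, since the published
strict inequalities on both sides leave the boundaries unassigned.

## Conformer descriptors

* **R_gyr** — mass-weighted by default (unweighted available); the
  source does not state a weighting, and mass weighting is the common
  trajectory-analysis convention.
* **SASA** — Shrake–Rupley with a deterministic golden-spiral lattice
  (default 960 points per atom) instead of random sampling, so areas are
  bit-reproducible. The lattice is expressed in the molecule's
  principal-axis frame, which makes areas exactly invariant under rigid
  rotation and translation. Bondi van der Waals radii are the default
  radii table. Accuracy: for isolated atoms the lattice is exact; on
  overlapping-sphere test molecules the 960-point lattice agrees with a
  dense Monte-Carlo occlusion estimate to well within 2%, and error
  decreases as points increase.
* **3D PSA (probe 0 / 1.4 Å)** — SASA summed over polar atoms: N, O and
  H bonded to N/O. Sulfur is excluded, following the classical PSA
  convention; the exact polar-atom definition of the original analysis
  software is not published, so this is a documented assumption. When
  bond topology is absent (XYZ input), H–heavy bonding is inferred by a
  1.2 Å distance cutoff.
* **IMHB** — donor–H···acceptor triples with H···A ≤ 2.5 Å and D–H···A
  angle ≥ 120°, donor and acceptor not covalently bonded. The upstream
  tool's "default method" is not numerically specified; these relaxed
  geometric criteria are configurable.

## Ensemble property space

Ensembles are summarized by the medians of R_gyr and 3D PSA 1.4 Å —
medians rather than means because conformer populations are multimodal
and skewed. Density maps are plain 2D histograms (default bins 0.25 Å ×
5 Å²): unlike kernel estimates they conserve frame counts exactly and
give a deterministic density maximum. Ties for the maximum bin break
toward lower PSA, then lower R_gyr; the representative conformer of the
maximum bin is the frame nearest the bin center in z-scored coordinates,
ties to the lowest frame id. The folded/low-polarity region (R_gyr < 7 Å
and 3D PSA 1.4 < 200 Å²) uses guide thresholds taken from manually placed
reference lines in the source analysis — visualization aids, not
validated cutoffs — and both are parameters. `chameleon_contrast()`
reports polar-minus-nonpolar deltas of the medians; positive ΔPSA is the
chameleonic signature, and negative ΔR_gyr the water-folding signature.

## Relation layer

`linear_relation()` is simple OLS with r² reported as the squared Pearson
correlation (identical to the coefficient of determination for a simple
fit; the source uses r² and R² interchangeably). Outlier exclusion is
declarative — compounds are excluded by id, mirroring the published
exclusion of one compound from the efflux–lipophilicity fit — never
automatic. The efflux ratio enters untransformed; whether the published
fit used ER or log ER is not stated, and the untransformed default is
recorded here as the package's choice.

## Synthetic data: what it emulates and what it does not

The generators produce inputs with the statistical structure each stage
assumes, so the full pipeline is testable without any external data.
Defaults are the study conditions the pipeline targets: 11 compounds;
five plasma timepoints per route at 30 mg/kg oral and 5 mg/kg IV; the
50/60/70/100% MeCN retention design with IAM measurements at 10–50%;
retention noise 0.02 log units (typical replicate reproducibility);
planted Chamelogk 0.8 (a strong chameleon, as the compounds of interest
are); ensembles of 200 frames.

* `gen_retention()` builds linear log k' trends and adds the planted
  chameleonic deviation at 100% MeCN, then converts to retention times
  with a 1-minute dead time. At zero noise the descriptor pipeline
  inverts it exactly.
* `gen_ensemble()` grows self-avoiding bead chains whose growth steps are
  biased back toward the chain start by a solvent-dependent compactness
  parameter; excluded volume always wins over the bias, and the dial is
  mapped onto the bias range in which median R_gyr still responds
  (stronger pulls saturate against packing). Beads are C or, with
  probability `polar_fraction`, N/O; the element sequence depends only on
  the compound label so a compound keeps its composition across
  solvents. Chains are geometric stand-ins, not chemically valid
  degraders: the descriptors under test are purely geometric, so chemical
  realism would add cost without adding coverage. Consequently, passing
  tests demonstrate correctness of the geometry/statistics machinery, not
  that any real compound folds.
* `gen_pk()` simulates one-compartment disposition (IV bolus, first-order
  oral absorption) with multiplicative lognormal noise, which keeps
  concentrations positive.
* `gen_property_table()` plants ER = −2·log k'80 + 5 + ε with ε chosen in
  closed form (σ = √(8/9)) so the population r² is 0.6, ER floored at
  0.05, and F% = 50·exp(−0.6·ER), a stated decreasing function.

Every generator is a pure function of its configuration: the master seed
is hashed with a per-generator label into independent streams, so adding
a generator never perturbs the draws of another, and repeat runs are
byte-identical.

## Numerical choices and degenerate inputs

* Measurements with t_R ≤ t_0 are rejected (non-retained solute), not
  clamped.
* Retention-line fits need ≥ 2 distinct organic fractions; collinear
  input reproduces slope and intercept to machine precision.
* SASA neighbor tests use squared distances and a pairwise cutoff at
  r_i + r_j; a fully enclosed atom reports exactly zero area.
* Degenerate principal axes (single atoms, exact symmetry) fall back to
  the identity frame or sign rules on the largest component; areas for
  such symmetric inputs are orientation-independent anyway.
* Density-map edges snap to multiples of the bin width, so binning does
  not depend on data order; Σ counts = n frames always.
* The verification suite runs at deliberately modest problem sizes
  (ensembles of 40–200 frames of 50-bead chains, 960-point SASA lattices,
  Monte-Carlo oracles of about 10⁶ points, 500–1000 replicate
  regressions), chosen so the whole suite completes in a few minutes on
  one core while keeping sampling error far below the asserted
  tolerances.

## Known limitations

* The published per-compound experimental table is not distributed in
  machine-readable form; `transcribed_compound_table()` refuses to load
  until a user with access to the publication transcribes it. The
  published correlation anchors (r² = 0.58 efflux vs log k'80 with one
  declared outlier excluded; r² = 0.53 EPSA vs Δlog k\_w^IAM; 11/11
  strong chameleons; 5 medium/high-F% compounds) can only be reproduced
  after that transcription.
* The package consumes conformer geometries; it does not generate them
  (no force fields, no dynamics) and does not predict EPSA or pKa.
* SASA is O(n² · points) in pure R — adequate for drug-sized molecules
  and bead chains, not for proteins.
* The ionization classes describe retention behavior, not measured pKa.
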
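---
title: "Decoy-learned, mass-calibrated FDR for peptide-spectrum matches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy-learned, mass-calibrated FDR for peptide-spectrum matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FlexiFDR)
```

## The problem

A shotgun proteomics database search assigns every MS/MS spectrum a
best-matching peptide with a score, and the standard way to control the
error of the resulting peptide-spectrum matches (PSMs) is the
target-decoy strategy: the same spectra are searched against reversed
("decoy") protein sequences, and the decoy hits act as a null model for
random matching. With `T(t)` targets and `D(t)` decoys scoring at or
above a threshold `t`, this package uses the two standard estimators

* separate search: `FDR_s(t) = D(t) / T(t)`,
* concatenated search: `FDR_c(t) = 2 D(t) / (T(t) + D(t))`,

and accepts target PSMs by q-value (the minimum estimated FDR over all
thresholds at or below a PSM's score) at a level `alpha`, conventionally
1%.

Many search-engine scores, however, are not exchangeable across peptide
mass: the null (decoy) score drifts with mass, and the drift differs by
precursor charge state — for some engines it rises with mass, for others
it falls. A single flat score threshold then discards correct low-mass
PSMs while admitting random high-mass ones (or vice versa for a negative
drift).

## The rescoring model

The calibration implemented here learns that drift from the decoys
alone. Per charge state `z`, ordinary least squares is fitted on the
decoy PSMs with peptide neutral mass `x` as the independent variable and
score `y` as the dependent one:

```
y = m_z x + c_z .
```

Every PSM — target and decoy alike — is then replaced by the y-axis
intercept of the line through its own point `(x, y')` parallel to its
charge's decoy line:

```
c' = y' - m_z x   (the FlexiScore).
```

q-values and acceptance are computed on the pooled FlexiScores exactly as
for raw scores, so a flat threshold `tau` on the FlexiScore scale is the
family of lines `y = m_z x + tau` in the original (mass, score) plane:
one mass-dependent threshold per charge, parallel to that charge's null
drift. Nothing in the construction requires `m_z > 0`; negative and mixed
slopes work identically, and when every `m_z = 0` the transform is the
identity and the method coincides with classical FDR PSM-for-PSM (this
equivalence is asserted in the test suite).

Two preprocessing rules are applied before estimation:

* **Decoy filtering.** A decoy peptide identical to some target peptide
  is not a valid null draw. Identity is judged after stripping bracketed
  modification masses and merging isoleucine with leucine
  (`normalizePeptide()`), since I/L are isobaric. Filtered decoys are
  excluded from both the regression and the FDR counts.
* **Score orientation.** E-value-like scores are negated on ingest so
  that all internal logic is higher-is-better.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | — | FDR level of acceptance |
| `mode` | from data | — | separate vs concatenated estimator |
| `nMin` | 10 | decoys | minimum decoys per charge for a dedicated fit |
| `scoreDirection` | higher_is_better | — | orientation of the input score |

`nMin` exists because sparse, skewed high-charge strata (often z ≥ 5)
cannot support a stable line. The fallback chain is deterministic: a
charge with fewer than `nMin` filtered decoys borrows the pooled
all-charge slope; if the pooled fit itself has fewer than `nMin` decoys
(or no mass spread), the slope is 0 and the method degenerates gracefully
to classical FDR for that charge. Every fallback is flagged in the
returned `ChargeRegressionModel` for audit.

## Numerical and design choices

* **Candidate thresholds.** FDR is evaluated at every distinct observed
  score (a superset of the decoy scores), and q-values are the running
  minimum from the lowest threshold upward. The raw per-threshold FDR is
  also reported by `computeQvalues()`, but acceptance always uses the
  monotonized q-value: a raw FDR that dips below `alpha` at a lower
  threshold makes every higher score acceptable, which is the only
  self-consistent reading of "FDR at or below alpha".
* **Ties.** Ties at the threshold are accepted (`score >= t` counting),
  and in concatenated best-hit competition an exact target/decoy score
  tie retains the decoy — the conservative choice.
* **Regression.** Unweighted simple OLS via `stats::lm()`, decoys only;
  targets never influence the fit. No score floor is applied to the
  decoys entering the regression.
* **Intercepts are retained.** The transform subtracts only `m_z x`;
  per-charge intercept differences `c_z` deliberately survive into the
  pooled FlexiScores, because acceptance thresholds parallel to each
  charge's own line — not a per-charge re-centering — is what the
  construction calls for. A centering variant was considered and
  rejected: it would change the relative ranking of charges in a way the
  decoy lines alone cannot justify.
* **Mass derivation.** When only a precursor m/z column is available,
  neutral mass is `z * mz - z * 1.007276` Da with the proton mass fixed
  to that constant for bit-exact reproducibility.
* **Theoretical vs observed mass.** Either may be supplied in the `mass`
  column; the method is agnostic and the choice is the caller's.
* **Text round-trips.** Tables are written with 17 significant digits,
  so write/read cycles preserve doubles exactly.

## Entrapment-based evaluation

To compare two FDR procedures without ground truth, the package follows
the entrapment design: the target database holds *true* proteins
(standard-mix proteins plus known contaminants) and *entrapment*
proteins from an unrelated organism. An accepted identification sharing
any protein with the true set is labelled true; it is labelled false
only if all its proteins are entrapment accessions; anything else is
unlabelable and excluded from counts (but reported).

Because a rescoring method shares most identifications with its
baseline, raw totals hide the difference. `compareMethods()` therefore
counts the confusion matrix on *method-unique* identifications: TP/FP
are the true/false identifications found only by the rescored method,
TN/FN the false/true ones found only by the baseline. The single-number
summary is the net positive gain

```
NPG = 100 * ((TP - FP) - (FN - TN)) / (baseline acceptance count) ,
```

i.e. net true identifications gained minus net true identifications
lost, as a percentage of what the baseline accepted. This formula is a
package definition (several near-equivalent forms exist in the
literature); it is reported alongside the full counts so any alternative
can be recomputed. The entrapment false discovery proportion (FDP) of a
full acceptance set — the false fraction among its labelled
identifications — is the "actual FDR" readout.

## What the synthetic generator emulates

`generatePsmData()` produces datasets with exactly the structure the
method assumes, so every pipeline property is testable without raw
mass-spectrometry data. Per spectrum of charge `z` with mass `x` drawn
from a truncated lognormal law:

* decoy score ~ `Normal(a_z + b_z x, sd_d)`;
* a *correct* target (probability `correctFraction`) scores
  `Normal(a_z + b_z x + offset, sd_c)`;
* an *incorrect* target scores an independent draw from the decoy law —
  incorrect targets and decoys are exchangeable by construction, the
  assumption under which target-decoy FDR is valid;
* incorrect targets carry entrapment accessions with probability
  `entrapmentFraction`, otherwise a true-set accession — the latter is
  the entrapment evaluator's unavoidable blind spot, kept in the truth
  table so tests can quantify it;
* a fixed fraction of decoy peptides are I/L twins of their spectrum's
  target peptide, and all other decoy peptides are guaranteed distinct
  from every target after normalization, so the decoy filter's expected
  removals are known exactly.

The committed defaults (also at `inst/extdata/synthgen-default.yaml`)
are 2000 spectra per charge for z in {2, 3}; decoy slopes 0.008 and
0.012 score/Da with intercepts 20 and 25 and s.d. 5; correct fraction
0.5 with offset 25 and s.d. 6; entrapment fraction 0.3; twin fraction
0.05; masses lognormal(median 1400 Da, sdlog 0.3) truncated to
[600, 4600] Da; seed 42; Mersenne-Twister RNG with inversion normals,
recorded in the output metadata. With these values the decoy drift
across the mass range (~13–19 score units) is a substantial fraction of
the target-decoy separation (25), so the flat-threshold baseline and the
rescored method share a large common core of acceptances while differing
at the borderline — the regime the method is designed for. A wider mass
law or smaller offset pushes the baseline into degenerate, near-empty
acceptance, which is a different (and less informative) regime.

What the generator does **not** emulate: engine-specific score shapes
(only a linear conditional mean with Gaussian noise), score dependence on
peptide length or ΔCn-like features, homology between entrapment and
true proteins, shared peptides across proteins, retention-time or
fragmentation structure. Passing tests therefore demonstrate
correctness of the estimators and of the calibration under the model's
own assumptions — not performance on any particular instrument's data.

## Problem sizes and observed behaviour

The test suite and the reproduction script run 50 replicates of the
default 4000-spectrum dataset for the FDP-control checks and single
seed-42 fixtures elsewhere; the whole suite completes in well under a
minute. On those replicates both classical concatenated FDR and the
rescored pipeline hold the realized FDP near 0.5% at a nominal 1% — the
factor-of-two conservatism expected from the concatenated estimator when
half the null competition winners are decoys.

One comparative caveat the tests surface deliberately: under the
generator's exchangeable null, each method's *absolute* number of false
acceptances scales with its acceptance total (roughly `alpha/2 * T`).
When the calibration yields a large sensitivity gain, the rescored
method can therefore carry a few more unique false identifications in
absolute count than the much smaller baseline acceptance, even though
its FDP remains controlled well below `alpha`. The direction "fewer
unique false hits for the rescored method" seen on real benchmark data
requires the baseline to *waste* its FDR budget on mass-biased false
hits at near-equal acceptance totals — a regime an exchangeable-null
simulation reproduces only when the sensitivity gap is small.

## Known limitations

* Only a linear conditional mean in mass is corrected; curvature or
  heteroscedasticity in the decoy drift is out of scope, as are
  multivariate calibrations (mass + length + ΔCn) and iterative
  semi-supervised rescoring.
* No pi0 estimation, posterior error probabilities, or protein-level
  FDR.
* Very small datasets cannot support FDR estimation at all, with or
  without rescoring; the fallback chain keeps the method total but
  cannot create information that is not there.
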
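---
title: "Methods: spike-in DIA absolute quantification, QC, screening and classification"
author: "spikequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in DIA absolute quantification, QC, screening and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The measurement model

spikequant post-processes transition-level quantification reports from
data-independent acquisition (DIA) targeted proteomics of blood plasma in
which every sample is spiked, before digestion, with a panel of heavy
stable-isotope-labeled recombinant protein standards at known
concentrations $S_p$ (pmol per µL raw plasma). For each peptide $p$ in
sample $s$ the exported report carries one integrated chromatographic peak
area per fragment-ion transition and isotope channel. The estimator at the
core of the package is the summed-area ratio to standard over the
transitions present in both channels,

$$ r_{sp} \;=\; \frac{\sum_{t \in \mathrm{paired}} A^{\mathrm{light}}_{spt}}
                  {\sum_{t \in \mathrm{paired}} A^{\mathrm{heavy}}_{spt}},
\qquad
C_{sp} \;=\; r_{sp} \cdot S_p \quad [\mathrm{pmol}/\mu\mathrm{L}], $$

where "paired" means the (fragment, product charge) key has a present,
positive area in *both* channels. Because light (endogenous) and heavy
(standard) species co-elute and are measured in the same injection,
injection-scale intensity fluctuations cancel in $r$; what remains is
channel-specific noise, which is the quantity the intra-assay CV measures.

### Quality filters

A peptide observation is *quantified* iff all of the following hold
(strict inequalities, thresholds configurable):

| filter | default | meaning |
|---|---|---|
| rdotp > 0.7 | cosine of light vs heavy paired-area vectors, recomputed from the report | fragmentation patterns of endogenous peptide and standard agree |
| dotp > 0.5 | library dot product, trusted from the input | measured pattern matches the spectral library (its computation needs the upstream library, so it is not recomputed) |
| 0.01 < r < 1000 | ratio to standard | signal within the assay's usable ratio range |

Every rejection carries machine-readable reason codes
(`no_pairs`, `low_rdotp`, `low_dotp`, `ratio_out_of_bounds`), and stage
counts are additive by construction (inputs = kept + dropped, per stage).

Sample-level QC uses two gates: an ordinary-least-squares regression of
measured retention time on reference iRT over anchor peptides (the twelve
most intense APOA1 peptides in the emulated assay) must succeed with
$R^2 \ge 0.99$ and at least 6 detected anchors (both unstated upstream and
therefore configurable; RT-vs-iRT fits are expected to be near-perfectly
linear, so the gate is deliberately tight), and the sample must have at
least 120 distinct quantified proteins ("fewer than 120" is read strictly,
so exactly 120 is retained). After sample QC, peptides quantified in fewer
than 50% of the *retained* samples are excluded (again strict, so a rate
of exactly 0.5 survives; the denominator is retained samples because
sample exclusion is specified first).

### Ratio orientation

The upstream description names a "heavy to light ratio" while the filter
bounds are phrased on a "ratio to standards". We define $r$ = light/heavy,
because only that orientation makes $C = r \cdot S_p$ an endogenous
concentration; the 0.01–1000 bounds are symmetric, so the filter is
identical either way — only the reported $r$ values differ by inversion.

### Pool-based median normalization

Each plate carries replicate injections of one fixed pooled-plasma sample.
For every peptide × plate the normalization factor is

$$ f_{p,\mathrm{plate}} = \frac{\operatorname{median}(\text{all pool injections of } p)}
                               {\operatorname{median}(\text{this plate's pool injections of } p)}, $$

applied to all of the plate's values (patients and pools alike). The
granularity (per peptide × plate) is our choice: it corrects
analyte-specific batch effects and makes pool medians exactly concordant
across plates. The operation is idempotent — a second application computes
factors of exactly 1 — which the tests assert. Peptides with no pool value
on a plate keep factor 1 and are logged. Protein concentrations are the
median over the protein's quantified peptides (robust to a single aberrant
peptide, e.g. one overlapping a copy-number-variable kringle domain).

## QC statistics

* **Intra-assay CV** — per peptide × plate, $\mathrm{sd}/\mathrm{mean}
  \times 100$ over the plate's pool injections (sample sd, $n-1$); the
  per-plate summary is the median over peptides. The *overall* CV pools
  all pool injections across plates into one CV per peptide before taking
  the median — the cross-plate computation is what makes the overall value
  exceed every per-plate median whenever plate effects exist.
* **Pool correlation** — Pearson r between every pair of pool injections
  over log10 concentrations of shared quantified peptides (pairs sharing
  fewer than 3 are skipped).
* **Normalized IQR** — per protein over patient samples only,
  $\mathrm{nIQR} = Q_3/Q_1$ with quartiles by linear interpolation
  (R quantile type 7). The fold-scale definition was chosen because the
  upstream gloss reads the statistic against "less than two-fold"
  variation; the alternative $(Q_3-Q_1)/\mathrm{median}$ sits behind
  `method = "relative"`. $Q_3/Q_1$ is scale-free and $\ge 1$ by
  construction.

A calibration subtlety: the pipeline computes CVs on the **un-normalized**
concentration matrix by default (`cv_on = "raw"`). Dividing a plate's
three pool replicates by their own median removes part of the very
replicate scatter the CV is supposed to measure (with $n = 3$ the median
replicate becomes exactly the global median), deflating the estimate; the
lognormal closed form below applies to the raw matrix.

## The synthetic cohort: what it emulates

The generator produces a ground-truthed study with the statistical
structure the analysis assumes:

* **Design** — patients of 15 cancer types randomized over 96-well plates,
  each plate carrying a pooled-plasma sample (3 male + 2 female donors,
  blended once and reused on every plate) in triplicate. The default
  desk scale is 350 patients proportional to the emulated cohort's
  per-cancer ratios on 4 plates with 60 proteins × 2 peptides × 5
  transitions; the full 1800-patient roster is one flag away.
* **Concentrations** — protein baselines log-uniform over 6 decades
  (1e-4 to 1e2 pmol/µL; plasma proteins span at least this range);
  patient values multiply the baseline by $2^{\epsilon}$ with
  $\epsilon \sim N(0, \sigma_{bio})$, a planted cancer × protein log2
  effect, and a sex factor. $\sigma_{bio} = 0.5$ log2 units by default
  (typical inter-individual plasma protein variation is below two-fold,
  matching a median fold-IQR near 1.6).
* **Noise** — multiplicative lognormal at three levels, all in natural-log
  units: injection scale (shared by the two channels of a co-measured
  peptide, cancels in the ratio), channel-specific ratio noise
  $\sigma_{intra} = 0.1$ (≈ 10% CV, the per-plate regime of a
  well-behaved assay), and a plate effect $\sigma_{plate} = 0.1$ drawn per
  plate × peptide and applied to the light channel only, so it survives
  into the ratio and is exactly what pool normalization corrects. The
  noise placement is deliberate: with independent channel noise the
  ratio CV would be $\sqrt{e^{2\sigma^2}-1}$, not the
  $\sqrt{e^{\sigma^2}-1}$ the calibration tests assert; sharing the
  injection factor reconciles the generative equations with the
  closed-form CV and with how paired-channel assays actually behave.
* **Pathologies** — per-transition and per-channel dropout; a configurable
  fraction of sample × peptide observations with the library dot product
  planted below the 0.5 threshold; designed QC-fail samples, half with
  randomly permuted anchor retention times (a *reversal* would famously
  still pass an $R^2$ gate, so the scramble is a random permutation) and
  half with ~90% of panel peptides removed so they fall under the
  protein-count gate.
* **Planted biology** — a 10-fold female/male PZP effect, and a
  multiple-myeloma signature: C1QB, C1QC, C1R, C1S, JCHAIN, CD5L and CPN1
  down (log2FC −1), TGFBI, CFD and MGP up (log2FC +0.7). The magnitudes
  are *synthetic defaults* — the emulated study prints no fold changes for
  these proteins — and are labeled as such wherever they surface.

What the generator does **not** emulate: raw spectra or chromatograms,
interference, limit-of-detection censoring, non-lognormal heavy-tailed
biology, or correlated peptide missingness. A green test therefore
establishes the correctness of the *post-processing pipeline* under its
stated assumptions, not the performance of the wet-lab assay.

## Differential abundance

Each cancer is compared against all other patients per peptide with a
two-sided t test on log2 concentrations; for sex-specific cancers
(prostate male-only; breast, ovarian, endometrial, cervical female-only)
the rest group is restricted to the relevant sex. Welch's unequal-variance
t is the default although the upstream caption says "Student's t-test":
one-vs-rest groups are severely unbalanced (e.g. 55 vs 1745) and the
classic pooled test is anti-conservative when the small group has the
larger variance; the pooled test is one flag away (`var_equal = TRUE`)
and the choice is logged in provenance. Bonferroni adjustment multiplies
each raw p by the number of peptides tested *within the comparison*
(each volcano panel stands alone; a global family across comparisons is
the configurable alternative), capped at 1, with significance at adjusted
p < 0.0005. Pools never enter; peptides with fewer than two non-missing
values in either group are skipped and logged.

## Classification

The multiple-myeloma-vs-rest classifier follows the upstream recipe:
kNN imputation, stratified 70/30 split, random forest tuned by 5-fold
cross-validation on the training split, evaluation on the untouched
holdout. Since no random-forest package is part of the supported
dependency stack, the forest is implemented in compiled code inside this
package: CART trees on the Gini criterion, bootstrap resampling, `mtry`
feature subsampling, class-probability predictions as the average of
per-tree leaf frequencies, and mean impurity-decrease importances,
reproducible under `set.seed()`. Defaults left unstated upstream are ours
and documented: 500 trees, minimum node size 5, `mtry` grid
{⌊√p⌋, ⌊p/3⌋}, probability threshold 0.5 for sensitivity/specificity.

Imputation fills a missing (sample, peptide) cell with the mean of the
sample's values over the k = 10 peptides nearest the target peptide
(root-mean-square distance over shared samples, on log2 values);
peptides missing in over half the samples fall back to their column mean.
Two orders are exposed: `paper_faithful` imputes the full matrix before
splitting (reproducing the upstream order), while the default
`within_split` derives neighbour sets and column means from the training
split only — the package reproduces the upstream order on request without
endorsing it silently. ROC points are the standard threshold sweep (ties
form diagonal segments), so the trapezoid AUC equals the normalized
Mann–Whitney U; the tests assert this equality against an independent
rank-based oracle. Feature relevance is the impurity importance linearly
rescaled so the maximum is 100.

## Numerical choices and degenerate inputs

* All threshold comparisons are strict, following the printed
  inequalities verbatim; boundary behavior (rdotp = 0.7, exactly 120
  proteins, exactly 50% quantification rate) is pinned by tests.
* rdotp of a zero vector is 0; a peptide whose paired heavy sum is 0
  cannot occur after pairing (pairing requires positive areas), and the
  standalone ratio operation raises an explicit undefined-ratio error.
* Quartiles use type-7 linear interpolation so documented examples are
  bit-reproducible.
* Missing values are empty fields, never 0: a 0 area is an integrated but
  empty peak and fails the positive-area pairing requirement anyway.
* Seeds: the generator derives its manifest/truth/report streams from one
  master seed with fixed offsets; identical config + seed gives
  byte-identical reports. The classifier seeds split, folds and forests
  from its own seed argument.

## Known limitations

* Desk-scale cohorts (11 MM patients) put only ~3 positives in the
  holdout, so sensitivity/specificity at the 0.5 threshold are coarse and
  the probability threshold matters more than at full scale.
* The synthetic effect magnitudes make the MM classification task easier
  than the real one; holdout AUC ≈ 1 at desk scale establishes recovery
  of planted structure, not clinical performance.
* The quantified-protein reduction of the emulated assay (253 targeted →
  146 absolutely quantified) depends on raw-data properties the generator
  does not model; the pipeline exposes all counts but hard-codes no such
  reduction.
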
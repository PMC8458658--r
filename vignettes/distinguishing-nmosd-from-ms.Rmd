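---
title: "Distinguishing AQP4-seropositive NMOSD from MS on MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing AQP4-seropositive NMOSD from MS on MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmosdmri)
```

## The problem

Neuromyelitis optica spectrum disorder (NMOSD) with aquaporin-4 (AQP4)
antibodies and multiple sclerosis (MS) are both inflammatory demyelinating
diseases of the CNS, but they demand different treatment: several MS
disease-modifying therapies can worsen NMOSD. Their MRI appearances overlap,
yet individual lesion types differ sharply in frequency between the two
conditions — longitudinally extensive spinal cord lesions, bright spotty
cord lesions and bilateral optic nerve lesions point to NMOSD; ovoid
periventricular lesions, Dawson's fingers and T1 black holes point to MS.
This package implements a complete analysis pipeline over such per-patient
lesion-feature records: association statistics, rule- and score-based
classifiers, a score-model search, a weighted evaluation suite, and a
spinal-cord lesion topography map, together with a calibrated synthetic
cohort generator so that every stage is testable without patient data.

## Data model

The unit of input is the adjudicated lesion record, not the image. A cohort
is three tidy tables (patients, scans, cord lesions). Each scan carries
binary presence columns keyed by the feature catalogue
(`nmo_feature_catalog()`, 77 features across optic pathway, brain and
spinal cord, with their prior disease associations) plus lesion counts.
Spinal cord lesions are spans on a 44-level hemi-vertebral coordinate
system: level 1 is the superior half of C1 and level 44 the inferior half
of L3, so a vertebral body is two levels and span length is
`end - start + 1`.

Aggregation to the patient level distinguishes **first** imaging (the
earliest scan of the relevant region — resolved per region, because brain
and spine scans occur on different dates) from **ever** imaging (the OR
over all scans). Three criterion features — normal brain, Paty and Barkhof
— are evaluated on first imaging only. When a patient has no scan covering
a feature's region, the entry is missing and every downstream denominator
shrinks accordingly; association uses the ever data, classifier comparison
the first data, mirroring the clinical situation of a patient under
diagnostic evaluation. A feature column absent from a scans table is read
as *absent wherever the region was imaged* — missingness encodes absent
imaging, never an unrecorded column.

Two geometry rules matter repeatedly. A cord lesion is *long*
(longitudinally extensive) iff it spans at least 6 adjacent hemi-levels
(3 vertebral bodies); long/short partition the lesions. White-matter
lesions meeting several topographic definitions resolve to a single class
by the preference order tumefactive, then periventricular, cortical,
juxtacortical, subcortical. Scans are relapse-associated when a documented
relapse falls within the window 90 days before to 30 days after the scan,
inclusive at both ends (dates have day resolution).

## Association statistics

Each feature yields a 2x2 table of presence against diagnosis after
missing-scan reduction. The odds ratio (NMOSD-favouring above 1) uses the
Haldane-Anscombe continuity correction — 0.5 added to all four cells — if
and only if some cell is zero, and the 95% interval is the Woolf log-normal
interval computed on the same (possibly corrected) cells. The source
analysis names only the correction, not its interval method; Woolf is the
standard companion, and we apply the correction to both the point estimate
and the interval, which keeps `ci_low <= OR <= ci_high` algebraically.
Significance is an interval excluding 1. Deliberately, no multiple-testing
adjustment is applied (the features were pre-specified candidates from a
literature review), and the result table carries no adjusted-p column at
all. Zero-total tables are dropped from the batch scan rather than raising,
so sparse synthetic cohorts never abort an analysis. Lesion-count
comparisons are routine Mann-Whitney tests delegated to
`stats::wilcox.test()`.

## Classifiers and the score rule

`paty()` and `barkhof()` implement the two classical brain-MRI rules from
lesion counts; as diagnosis rules, criteria met imply MS. External criteria
sets are *configuration*, not code: declarative boolean expressions over
feature ids (`ruleset()`), because their published definitions live in
their own references. A decision-tree engine (`decision_tree()`) evaluates
config-defined trees; the example tree shipped in `inst/extdata/` is
synthetic and clearly non-canonical, since the published tree's full
structure is not reproducible from text.

The weighted score model sums integer weights over present features,
separately for NMOSD and MS feature sets, and classifies NMOSD exactly when

\[ \mathrm{score}_{\mathrm{NMOSD}} \times r > \mathrm{score}_{\mathrm{MS}},
\qquad r = 3.5 \text{ by default.} \]

The inequality is strict: a tie goes to MS ("if not, the diagnosis is MS").
Missing features evaluate as absent inside every classifier, but a patient
for whom *all* features a classifier consults are missing is unclassifiable
and is dropped from that classifier's denominator. The default feature
lists and weights (weight 2 on longitudinally extensive cord and bilateral
optic nerve lesions, and on ovoid lesions for MS; weight 1 elsewhere) are a
documented *reconstruction* — the source model's exact weights are
unpublished — and are fully overridable through YAML configs. A regional
mode (optic nerve / brain / spinal cord sub-scores with per-region
cut-offs) is provided but off by default, since summative scoring is
reported to perform best.

## The score search

The original model exploration was manual spreadsheet work; we formalise it
as a deterministic greedy procedure. For one class score: walk the cut-off
grid upward until specificity reaches 1.00 or sensitivity falls below 0.50
(`escalate_cutoffs()`, trajectory retained for audit); then repeatedly
propose every single-feature removal and single-step weight increment,
evaluate each at its best admissible cut-off, and accept the
lexicographically best proposal — specificity first, then sensitivity,
aiming above 0.90 specificity — until nothing improves
(`refine_model()`). Proposals are enumerated in candidate order, removals
before increments, so ties break deterministically. `search_combined()`
refines both class scores on the ever data and then picks the combination
ratio from a 0.5-step grid over (0, 10] maximising weighted precision
(smallest ratio on ties). The whole search is a pure function of data and
configuration: identical inputs give byte-identical serialised models.

Two honest caveats. First, the search is **in-sample by design**, as in the
original analysis; the test suite demonstrates the resulting optimism by
comparing in-sample precision against the same model's precision on a
freshly generated cohort. Second, on label-permuted data the *searched*
in-sample precision does not collapse all the way to chance — an
in-sample-optimised search over ~30 candidate features at n = 166 always
fits some noise. The permutation null proper — the searched classifier held
fixed and evaluated against permuted labels — does collapse to the
prevalence baseline \(2 n_1 n_2 / (n_1+n_2)^2\), and that is what the test
suite asserts. When a degenerate score admits no cut-off meeting the
sensitivity floor (possible on permuted labels), the search falls back to
the most sensitive cut-off rather than erroring, and such operating points
are always dominated by floor-meeting ones.

## The weighted evaluation suite

Confusion matrices take NMOSD as the positive state. For each metric
(TP rate, FP rate, precision, F-measure) the per-class values — each
diagnosis in turn treated as positive — are combined into a single weighted
mean. The weighting convention is **opposite-class**: metric *m* combines
as

\[ \bar m = \frac{m_{\mathrm{NMOSD}} \, n_{\mathrm{MS}} +
                 m_{\mathrm{MS}} \, n_{\mathrm{NMOSD}}}
                {n_{\mathrm{NMOSD}} + n_{\mathrm{MS}}}. \]

The published summary table states "weighted means" without a formula; we
enumerated the conventional candidates (macro, prevalence-weighted,
prediction-count-weighted, opposite-class) and exactly one — the
opposite-class scheme — reproduces every published row; the test suite
performs this enumeration and freezes the winner. Under it the weighted FP
rate satisfies the identity \((fp + fn)/\mathrm{total}\), asserted on
random matrices. The "ROC area" column is the single-operating-point
balanced accuracy, \((TPR_{\mathrm{NMOSD}} + TPR_{\mathrm{MS}})/2\) — the
source table uses that name for single-threshold rules and we keep the
column name with this glossary note; no threshold-sweep ROC curves exist
here because every classifier is a single-operating-point rule. Undefined
cells (zero predicted positives) propagate as `NaN`, never silently zero.
Metrics print at 3 decimals, half-up, matching the published precision.

Two cells of the published table are internally inconsistent and are
asserted against their convention-consistent values: the Liao FP rate
prints 4.352 (an FPR cannot exceed 1; the identity gives 0.352) and the
Matthews/Juryńczyk/Hyun FP rate prints 0.324 (the identity gives
53/162 = 0.327, and the Bensi row with the identical fp+fn sum prints
exactly 0.327). The other 33 cells reproduce verbatim to ±0.001.

## The cord heat map

`build_heatmap()` pools each patient's spine scans ("ever"), marks every
hemi-level covered by a lesion, and summarises per-level frequencies as the
proportion of spine-imaged patients in the group with any lesion at that
level. Where long and short lesions overlap a level, *long* wins — chosen
so the extent of a long lesion is never visually truncated — and Gd
enhancement is an independent overlay rather than a competing category.
Column occupancy always equals the union length of the patient's spans
(inclusion-exclusion over overlaps), an invariant the tests enforce on
random lesion sets. Whether levels enhancing without any T2 category should
count toward the summary is unknowable from the source; the default counts
any lesion category, and the Gd overlay is reported separately.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, calibrated to the printed study marginals: 66 NMOSD and
100 MS patients; per-region scan availability (brain 94%/100%, spine
92%/86%, orbits 27%/6%); among spine-imaged NMOSD patients 11% lesion-free,
70% with a longitudinally extensive lesion and 31% with cord Gd enhancement
(30% of MS spines persistently normal); brain T2 totals negative-binomial
with NMOSD mu = 6, size = 1 (median 4, extreme quantiles near the printed
maximum of 47) and MS mu = 16, size = 2.6 (median 14). Per-feature binary
prevalences are *back-solved* from published odds ratios plus printed
marginals — the source's full per-feature frequency table is unpublished —
and are therefore approximate by construction; they reproduce the direction
of every published association and, loosely, its magnitude. Cord lesions
are spans: NMOSD lesion centres mix cervical C2–C6 and mid-thoracic T2–T8
bands with triangular weights, MS short lesions centre on C2–C7; per-level
frequencies of the published figure are figure-only and not numeric
targets. Derived cord features, criterion features and "normal brain"
emerge from the generated geometry and counts rather than being sampled
directly, so the generator exercises the same derivation code as real data
would.

What the generator does **not** emulate: between-feature covariance
(features are independent within class — adequate for testing every
downstream operation, but real lesions co-occur), reviewer disagreement and
adjudication, image voxels, and longitudinal lesion evolution beyond a
simple two-scan persistence model (an ever-present feature shows on the
first of two scans with probability 0.8). Passing tests therefore certify
the pipeline's arithmetic and contracts, not clinical performance on real
cohorts. One design choice deviates from a per-patient RNG substream
layout: the generator uses a single seeded stream with fully vectorised
sampling, trading extend-a-cohort-without-reshuffling for speed at the
calibration scale; regenerating with a different n is a different cohort.

## Problem sizes and numerical choices

The test suite verifies generator calibration at n = 3300/5000 over ten
seeds (prevalence tolerance three binomial standard errors or the stated
±0.03 band) and runs the score search at the study scale n = 66/100 over
ten seeds; the truth-table oracles enumerate all count combinations up to
10 and the tree-vs-score equivalence all 2^12 feature combinations. Other
explicit choices: window arithmetic inclusive at both ends; integer
weights with a 1..3 grid; strict inequality at the score boundary; the
catalogue's dual-listed cerebral peduncle lesion resolved to a neutral
association (its raw listings are retained in `listed_nmosd`/`listed_ms`);
optic-pathway features readable from brain MRI by default
(`optic_from_brain = FALSE` restricts them to dedicated orbit imaging).

## Limitations

The pipeline inherits the source design's limitations: in-sample model
selection without cross-validation (quantified, not removed), no modelling
of pre-test probability, and a reconstruction — not a reproduction — of
the unpublished model weights and decision tree. The synthetic cohorts are
a testing instrument; conclusions about real NMOSD/MS discrimination
require real, independent cohorts.
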
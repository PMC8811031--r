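---
title: "Identifying and predicting a unifying diagnosis from coded records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and predicting a unifying diagnosis from coded records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unidiag)
```

## The problem

ICU admissions routinely carry ten to forty ICD-9 diagnosis codes.  Many of
those codes are near-duplicates at different granularity (acidosis,
hyperosmolality and hyperpotassemia are all `276.x`), and the list mixes the
diseases that brought the patient in (*primary diseases*) with the
conditions that followed from them (*complications*).  A **unifying
diagnosis (UD)** is the minimal set of primary diseases that explains a
patient group's clinical picture.  `unidiag` identifies the UD of patient
groups from their coded diagnostic records and predicts it for new patients
from admission-time features.

The pipeline has five stages, each exposed as ordinary functions over S4
containers:

1. **Ontology-embedded similarity** (`buildOntology`, `codeSimilarity`,
   `setSimilarity`, `similarityMatrix`),
2. **affinity propagation clustering** (`apPreference`, `apCluster`),
3. **typical-code pattern extraction** (`coreZone`, `buildTDCCoP`),
4. **UD identification** (`groupLCoP`, `conditionalCoOccurrence`,
   `identifyUD`),
5. **UD prediction** (`fuseFeatures`, `selectFeatures`,
   `trainAndEvaluate`).

## The similarity model

ICD-9-CM is a five-level hierarchy: a virtual root, 19 chapters, a
section/subchapter layer, 3-digit categories, 4-digit subcategories and
5-digit extensions.  The package rebuilds this hierarchy over the codes
actually present in a cohort (`buildOntology`); chapter and section ranges
ship as packaged plain-text tables.  The packaged section table is a
standard ICD-9-CM subchapter list whose ranges are tiled so that every
category stem maps to exactly one section; published section counts vary
slightly between ICD-9-CM releases, and only chapter membership affects the
headline groupings.

The information content of a code is its depth: IC(root) = 0 up to IC = 5
at extensions.  Two codes are compared through their least common ancestor
(LCA):

$$s(a, b) = \frac{2\,\mathrm{IC}(\mathrm{LCA}(a,b))}{\mathrm{IC}(a) + \mathrm{IC}(b)}$$

so sibling extensions under one subcategory score
$2 \cdot 4 / (5 + 5) = 0.8$, while codes sharing only the root score 0:

```{r}
ont <- buildOntology(c("550.12", "550.13", "541"))
codeSimilarity(ont, "550.12", "550.13")
icd9LCA(ont, "541", "550.13")
```

One structural note: range nodes such as `520–579` are chapters (level 1)
in ICD-9-CM and in this package, so two codes in different sections of the
same chapter score $2\cdot 1/(\mathrm{IC}(a)+\mathrm{IC}(b))$.  Virtual
sibling padding used in textbook drawings of the hierarchy is never
materialised; it cannot change any LCA.

Patient-level similarity is the best-match average over deduplicated code
sets (diagnosis order is deliberately ignored here):
each code is matched with its most similar counterpart in the other set,
in both directions, and the matched similarities are averaged.  The four
classical exact-match measures (Dice, Jaccard, cosine, overlap) are
available as baselines through the same matrix builder.  The printed form
of the set cosine without the square root is available as
`cosineVariant = "printed"`; the default uses
$|A\cap B|/\sqrt{|A||B|}$, which is bounded consistently with the other
measures.

## Clustering

Affinity propagation (responsibility/availability message passing) is used
because it does not fix the cluster count in advance and returns a real
patient as each cluster's exemplar.  The shared preference placed on the
similarity diagonal follows the median rule
$p = \mathrm{median}(S) - p_{coe} \cdot N$, with the median taken over
off-diagonal entries (the diagonal is a placeholder, not data).  Numerical
choices: damping 0.9, at most 1000 iterations, convergence declared after
50 iterations of an unchanged exemplar set, and a seeded jitter of relative
magnitude $10^{-12}$ to break exactly tied similarities that would
otherwise oscillate.  Ties in member assignment go to the lowest exemplar
index, so results are deterministic given a seed.  `sweepPreference`
reproduces the usual granularity sweep over $p_{coe}$; on our fixtures the
cluster count is non-increasing as the preference falls.

## Typical codes, LCoP and the UD split

Pattern extraction runs on each cluster's **core zone**: the patients most
similar to the exemplar.  Both selection rules are provided — a similarity
threshold $\tau$, and top-*n* (the default, since published experiments fix
patient counts; *n* = 800 by default, clamped to the cluster size).
**Typical diagnosis codes (TDCs)** are codes whose core-zone occurrence
probability strictly exceeds $\delta_1 = 0.3$; each gets the mean of its
diagnosis orders over the core patients containing it, and codes are
re-ranked by ascending average order (ties: higher probability, then code —
a determinism choice).

TDCs are then grouped under least common ancestors (**LCoP**).  The
published grouping was done by visual inspection of the ontology; the
package formalises it as connected components of the relation "pairwise
LCA is not the root", each multi-member component represented by the LCA
of its members.  This rule exactly reproduces the published seven-entry
grouping for the larger sepsis cluster (chapter-mates merge, singletons
stay themselves).  Each entry's order is the minimum re-rank of its
members.

The **conditional co-occurrence matrix (CCoM)** over LCoP entries holds
$p(d_j \mid d_i)$ off the diagonal and each entry's core-zone frequency on
the diagonal; a patient "has" a range entry when any of their codes
descends from it.  Co-occurrence counting is symmetric by default; an
order-directed mode (numerator restricted to patients whose earliest
$d_i$ code precedes their earliest $d_j$ code) is provided because the
clinical reading of the asymmetry is causal.  Which counting the original
experiments used is not stated; neither is asserted as "the" published
variant.

The primary/complication split formalises the published "much greater
than" comparison with a configurable dominance ratio $\rho = 1.5$:
$d_i$ dominates $d_j$ when $CCoM_{ij} \ge \rho\, CCoM_{ji}$ or
$CCoM_{ii} \ge \rho\, CCoM_{jj}$.  The split point in the order-sorted
LCoP maximises prefix-over-suffix dominance wins minus the reverse; ties
favour the smallest prefix, and the prefix (the UD) is never empty.  The
full per-pair dominance ledger is exported so the split can be audited.

## Prediction

Admission features follow the standard schema: demographics, sixteen
text-derived symptom flags, nineteen laboratory indicators summarised as
five-tuples (min, max, median, mean, variance — population variance, as a
descriptive within-stay summary), and six severity indicators (consumed as
given; the package does not compute SOFA/SAPS).  The symptom extractor is
a deliberately lightweight dictionary matcher with token-window negation
(window 3, scope broken at punctuation and adversative conjunctions); it
is a surrogate for a full clinical NLP pipeline and documented as such.

Fusion one-hot encodes categoricals with more than two levels and min-max
normalises numeric columns.  Feature selection keeps features whose
information gain for the UD label strictly exceeds $\delta_2 = 0.005$;
numeric features are discretised into 10 equal-frequency right-closed bins
first.  Evaluation is stratified Z-fold cross-validation (Z = 10 by
default, 5 supported) over five classifier families (multinomial logistic,
decision tree, random forest, SVM, XGBoost).  Inside each training fold
only: median imputation (with missingness indicators), information-gain
selection, and seeded random oversampling of minority classes to the
majority count — the held-out fold never influences any of these, and a
label-permutation canary test asserts it.  Precision, recall, F1 and
one-vs-rest AUC are support-weighted (weighted recall then equals
accuracy, an identity the tests assert); the CV error treats labels as
nominal, so the squared error reduces to the 0/1 mismatch rate.

## The synthetic cohort generator

Real critical-care diagnostic data are access-restricted, so the package
ships a first-class generator (`cohortConfig`, `generateDiagnoses`,
`generateAdmissionFeatures`, `groundTruth`) with known group structure.
The defaults encode a well-separated three-group cohort: four-code
signatures in disjoint chapters (circulatory, respiratory, genitourinary)
included with probability 0.9, order means 1/3/5/7 with spread 0.8, a
shared cross-chapter noise pool at rate 0.1 with late mean order 8, and
group-dependent laboratory shifts.  These values were chosen once as a
plausible high-signal regime — signature probability well above
$\delta_1$, noise well below it — and are deliberately not tuned.

What the generator emulates: multi-code admissions with order structure,
chapter-coherent group signatures, shared comorbidity noise, and the
120-column admission feature schema.  What it does not: realistic code
marginals and co-occurrence from billing practice, longitudinal stays,
free-text notes (symptom snippets are template-level), or inter-feature
correlation in labs.  Passing recovery tests therefore demonstrates the
machinery is correct, not that real cohorts are this separable.

On these defaults the pipeline recovers the planted structure: with
N = 200 the clustering attains adjusted Rand index ≥ 0.9 and the extracted
TDC sets equal the configured ground truth in at least 9 of 10 seeds (the
test suite runs exactly this check).  Problem sizes in the tests (cohorts
of 30–200, similarity matrices up to 200×200, 10-seed sweeps) were chosen
as the smallest sizes at which these properties are stable.

## Degenerate inputs and edge policies

* Duplicate codes within one admission collapse to the smallest order;
  raw order values are preserved (average orders depend on them) and
  re-ranked only if collapsing leaves clashing orders.
* The root node is rejected as a patient code (its IC of 0 would sit in
  the similarity denominator).
* An all-identical similarity matrix clusters to a single exemplar; AP
  non-convergence returns a flagged result with a warning rather than an
  error.
* A core zone with no code above $\delta_1$ yields an empty pattern with
  a warning; an LCoP entry matching no core patient gets a zero
  conditional row with a warning.
* Requesting more core patients than the cluster holds clamps with a
  warning; classes smaller than Z, empty code sets and mismatched feature
  ids are rejected with informative errors.

## Limitations

Diagnosis order is ignored by the similarity measure (order-weighted
similarity is a natural extension); the LCoP connected-component rule and
the dominance split are one formalisation of a published procedure that
mixed visual analysis with matrix inspection; and the symptom extractor is
intentionally minimal.  Published headline results on restricted clinical
data are out of scope for the test suite, which instead pins the in-text
worked examples exactly and validates everything else against brute-force
oracles and generator ground truth.
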
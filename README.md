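# unidiag

Identification and prediction of a **unifying diagnosis (UD)** — the
minimal set of primary diseases, separated from complications — from
multi-code patient diagnostic records.

ICU admissions typically carry 10–40 ICD-9 diagnosis codes mixing primary
diseases with their downstream complications. `unidiag` groups patients by
an ontology-embedded similarity over their diagnosis-code sets, extracts
each group's typical diagnosis-code co-occurrence pattern, splits it into
primary diseases and complications, and trains classifiers to predict the
UD of new patients from admission-time features. Audiences: clinical
informaticians working with coded EMR extracts (e.g. the MIMIC
`DIAGNOSES_ICD` dialect) and methodologists studying diagnosis-code
phenotyping.

## Method at its core

* **Code similarity.** The five-level ICD-9-CM hierarchy (root, 19
  chapters, sections, categories, subcategories, extensions) is rebuilt
  over the cohort's codes. With information content IC(·) = level depth
  and LCA the least common ancestor,

      s(a, b) = 2·IC(LCA(a, b)) / (IC(a) + IC(b))

  e.g. s(550.12, 550.13) = 2·4/(5+5) = **0.8**.
* **Patient similarity.** Best-match average over deduplicated code sets
  in both directions; classical Dice/Jaccard/cosine/overlap baselines are
  built in.
* **Clustering.** Affinity propagation with preference
  p = median(S) − p_coe·N on the similarity diagonal; supports and the
  sum of member-to-exemplar similarities (SS) score the result.
* **Pattern extraction.** In each cluster's core zone (top-n most
  exemplar-similar patients), typical diagnosis codes (TDCs) are those
  with occurrence probability > δ₁ = 0.3, re-ranked by ascending average
  diagnosis order.
* **UD identification.** TDCs merge under least common ancestors (LCoP);
  a conditional co-occurrence matrix (CCoM) over LCoP entries drives a
  dominance split (ratio ρ = 1.5) of the order-sorted entries into
  primary diseases (the UD) and complications.
* **UD prediction.** Fused admission features (demographics, 16 symptom
  flags from text, 19 laboratory five-tuples, severity scores) →
  information-gain selection (δ₂ = 0.005) → five classifier families
  under stratified 10-fold CV with in-fold oversampling, reporting
  accuracy, weighted precision/recall/F1, one-vs-rest AUC and CV error.

A seeded synthetic cohort generator with known group structure makes the
whole pipeline testable without restricted clinical data.

## Worked example

```r
library(unidiag)

ont <- buildOntology(c("550.12", "550.13", "541"))
codeSimilarity(ont, "550.12", "550.13")
#> [1] 0.8

cfg <- cohortConfig(nPatients = 200, seed = 7)   # 3 planted groups
gen <- generateDiagnoses(cfg)
ont <- buildOntology(unique(unlist(codeSets(gen$records))))
S   <- similarityMatrix(gen$records, ont)
cl  <- apCluster(S, apPreference(S, 0.025), seed = 7)
cl
#> APClustering: 200 patients in 3 cluster(s)
#>   preference -5.0000, SS 173.392, 116 iterations, converged: TRUE
#>   supports: 0.335, 0.330, 0.335

core <- coreZone(cl, S, 1, mode = "top-n", n = 50)
td   <- buildTDCCoP(core, gen$records)
td
#> TDCCoP for cluster 1 - 4 typical code(s), delta1 = 0.3
#>    code probability avg_order rank
#>  518.81        0.96  1.020833    1
#>     486        0.92  2.000000    2
#>  493.90        0.96  2.916667    3
#>   511.9        0.92  3.978261    4

lc <- lcopOrder(groupLCoP(td, ont), td)
cc <- conditionalCoOccurrence(lc, core, gen$records, ont)
identifyUD(lc, cc, cluster = 1L)
#> UDResult: unifying diagnosis = 460–519
#>   dominance ratio rho = 1.5 | split after position 1
```

Reading the output: the cluster's four typical codes (acute respiratory
failure, pneumonia, asthma, pleural effusion — the planted respiratory
signature) all fall in chapter 460–519, so the LCoP collapses to a single
chapter-level entry, which is the cluster's unifying diagnosis. Against
the generator's ground truth this run recovers the planted groups with
adjusted Rand index 1.0.

`runPipeline(pipelineConfig(...))` executes all five stages and writes the
similarity matrix CSV, cluster CSV, TDCCoP JSON, UD JSON and metrics JSON
with the resolved parameters embedded; `inst/scripts/unidiag.R` is a thin
CLI over the same functions (`simulate`, `run-all`, `sweep-p`).

## Repository layout

* `R/` — implementation (S4 classes + camelCase stage functions)
* `inst/extdata/` — packaged ICD-9-CM chapter/section range tables and a
  small code-title dictionary
* `tests/testthat/` — unit, property and end-to-end recovery tests with
  brute-force oracles
* `vignettes/unifying-diagnosis.Rmd` — the methods vignette (model,
  parameters, numerical choices, limitations)
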
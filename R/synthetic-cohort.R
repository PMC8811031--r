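# Seeded synthetic EMR cohort generator with known group structure, so
# every pipeline stage (similarity, clustering, pattern extraction, UD
# identification, prediction) can be validated end to end without any
# restricted clinical data.

#' Synthetic cohort configuration
#'
#' @slot nPatients integer cohort size.
#' @slot proportions numeric group mixing proportions (sum to 1).
#' @slot signatures list, one data.frame per group with columns `code`
#'   (ICD-9 leaf), `prob` (inclusion probability), `orderMean`,
#'   `orderSd` (diagnosis-order distribution before re-ranking).
#' @slot noisePool character codes shared across groups.
#' @slot noiseRate numeric per-code inclusion probability of noise codes.
#' @slot noiseOrderMean numeric mean sampled order of noise codes.
#' @slot labEffect numeric scale of per-group laboratory mean shifts.
#' @slot symptomEffect numeric per-group shift of symptom flag
#'   probabilities.
#' @slot seed integer; fixed seed gives byte-identical cohorts.
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", proportions = "numeric",
                 signatures = "list", noisePool = "character",
                 noiseRate = "numeric", noiseOrderMean = "numeric",
                 labEffect = "numeric", symptomEffect = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nPatients < 2L) msgs <- c(msgs, "need at least 2 patients")
  if (abs(sum(object@proportions) - 1) > 1e-8)
    msgs <- c(msgs, "group proportions must sum to 1")
  if (length(object@signatures) != length(object@proportions))
    msgs <- c(msgs, "one signature per group required")
  for (sg in object@signatures) {
    if (!nrow(sg)) { msgs <- c(msgs, "empty group signature"); next }
    if (any(sg$prob < 0 | sg$prob > 1))
      msgs <- c(msgs, "signature probabilities must lie in [0, 1]")
    lv <- icd9Canonicalize(sg$code)$level
    if (any(lv < 3L))
      msgs <- c(msgs, "signature codes must be leaf-level (category or deeper)")
  }
  if (object@noiseRate < 0 || object@noiseRate > 1)
    msgs <- c(msgs, "noise rate must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Build a synthetic cohort configuration
#'
#' Defaults emulate a well-separated three-group ICU-style cohort:
#' disjoint-chapter diagnosis signatures (circulatory, respiratory,
#' genitourinary; four codes each at inclusion probability 0.9 with
#' increasing typical diagnosis order), a shared cross-chapter noise code
#' pool at rate 0.1, and admission features (Table-style schema: 3
#' demographic columns, 16 symptom flags, 19 laboratory five-tuples, 6
#' severity indicators) with group-dependent laboratory shifts.
#'
#' @param nPatients cohort size (default 200).
#' @param proportions group mixing proportions.
#' @param signatures list of per-group signature data.frames (see
#'   [CohortConfig-class]); the defaults are used when `NULL`.
#' @param noisePool shared noise codes.
#' @param noiseRate per-code noise inclusion probability.
#' @param noiseOrderMean mean sampled order of noise codes (noise tends
#'   to be coded late).
#' @param labEffect scale of group-specific laboratory mean shifts.
#' @param symptomEffect group shift of symptom probabilities.
#' @param seed integer seed.
#' @return a [CohortConfig-class] object.
#' @export
cohortConfig <- function(nPatients = 200L,
                         proportions = c(1, 1, 1) / 3,
                         signatures = NULL,
                         noisePool = c("276.2", "285.9", "305.1", "311",
                                       "530.81", "715.90", "780.60",
                                       "E878.8", "V58.61"),
                         noiseRate = 0.1,
                         noiseOrderMean = 8,
                         labEffect = 1.5,
                         symptomEffect = 0.25,
                         seed = 1L) {
  if (is.null(signatures)) {
    sig <- function(codes) data.frame(code = codes,
                                      prob = 0.9,
                                      orderMean = seq_along(codes) * 2 - 1,
                                      orderSd = 0.8,
                                      stringsAsFactors = FALSE)
    signatures <- list(
      circulatory = sig(c("428.0", "427.31", "401.9", "414.01")),
      respiratory = sig(c("518.81", "486", "493.90", "511.9")),
      genitourinary = sig(c("584.9", "599.0", "585.9", "593.9")))
    signatures <- signatures[seq_along(proportions)]
  }
  new("CohortConfig", nPatients = as.integer(nPatients),
      proportions = proportions, signatures = signatures,
      noisePool = icd9Canonicalize(noisePool)$canonical,
      noiseRate = noiseRate, noiseOrderMean = noiseOrderMean,
      labEffect = labEffect, symptomEffect = symptomEffect,
      seed = as.integer(seed))
}

#' Generate synthetic patient diagnoses
#'
#' Each patient is drawn from its group: every signature code is included
#' independently with its configured probability with a diagnosis-order
#' value sampled from the group's order distribution; shared noise codes
#' are appended at the noise rate with late mean order; sampled order
#' values are then re-ranked 1..m so orders are unique within a patient.
#' A patient that would end up empty receives the group's first signature
#' code.
#'
#' @param config a [CohortConfig-class] object.
#' @return list with `records` (a [DiagnosisRecords-class]) and `labels`
#'   (integer true group per patient, named by patient id).
#' @export
generateDiagnoses <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  K <- length(config@proportions)
  n <- config@nPatients
  labels <- sample(rep_len(seq_len(K), n))  # balanced up to rounding
  if (any(abs(config@proportions - 1 / K) > 1e-8))
    labels <- sample(seq_len(K), n, replace = TRUE,
                     prob = config@proportions)
  sigs <- lapply(config@signatures, function(sg) {
    sg$code <- icd9Canonicalize(sg$code)$canonical
    sg
  })
  ids <- sprintf("P%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sg <- sigs[[labels[i]]]
    keep <- stats::runif(nrow(sg)) < sg$prob
    codes <- sg$code[keep]
    ordval <- stats::rnorm(sum(keep), sg$orderMean[keep], sg$orderSd[keep])
    nz <- stats::runif(length(config@noisePool)) < config@noiseRate
    if (any(nz)) {
      codes <- c(codes, config@noisePool[nz])
      ordval <- c(ordval, stats::rnorm(sum(nz), config@noiseOrderMean, 2))
    }
    if (!length(codes)) {
      codes <- sg$code[1L]
      ordval <- sg$orderMean[1L]
    }
    dup <- duplicated(codes)
    codes <- codes[!dup]; ordval <- ordval[!dup]
    rows[[i]] <- data.frame(patient_id = ids[i], code = codes,
                            order = rank(ordval, ties.method = "first"),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  list(records = DiagnosisRecords(df), labels = stats::setNames(labels, ids))
}

.LAB_NAMES <- c("potassium", "po2", "bicarbonate", "temperature", "sodium",
                "urine_out", "urea_n", "wbc", "bilirubin", "gcs_motor",
                "gcs_eyes", "hr", "gcs_verbal", "nbp", "rr", "spo2",
                "hemoglobin", "platelet", "creatinine")

#' Generate synthetic admission features
#'
#' Emits the raw admission-feature schema: a demographic block (age,
#' gender, 3-level admission type), 16 symptom flags, 19 laboratory
#' indicators summarised as five-tuples (min/max/median/mean/variance of
#' a short simulated in-stay series), and 6 severity indicators - 120 raw
#' feature columns in total.  Group effects shift a subset of laboratory
#' means (scale `labEffect`) and symptom probabilities
#' (`symptomEffect`); with both effects 0 the features are independent
#' of the group labels.
#'
#' @param config a [CohortConfig-class] object.
#' @param labels integer group labels named by patient id, from
#'   [generateDiagnoses()].
#' @return list of data.frames `de`, `sy`, `le`, `sev`, all with patient
#'   ids as rownames (widths 3 + 16 + 95 + 6).
#' @export
generateAdmissionFeatures <- function(config, labels) {
  stopifnot(is(config, "CohortConfig"), length(labels) >= 2L)
  set.seed(config@seed + 77L)
  n <- length(labels)
  ids <- names(labels)
  K <- length(config@proportions)
  # fixed per-group lab shift pattern derived from the config seed
  shift <- matrix(stats::rnorm(length(.LAB_NAMES) * K), length(.LAB_NAMES),
                  K) * config@labEffect
  de <- data.frame(
    age = round(stats::runif(n, 18, 89)),
    gender = factor(sample(c("F", "M"), n, replace = TRUE)),
    admission_type = factor(sample(c("emergency", "elective", "urgent"), n,
                                   replace = TRUE, prob = c(0.7, 0.1, 0.2))),
    row.names = ids)
  syms <- names(symptomDictionary())
  baseP <- 0.15
  sy <- vapply(seq_along(syms), function(s) {
    # each group elevates a different third of the symptoms
    up <- (s %% K) + 1L
    p <- ifelse(unname(labels) == up, baseP + config@symptomEffect, baseP)
    as.integer(stats::runif(n) < p)
  }, integer(n))
  sy <- as.data.frame(sy, row.names = ids)
  names(sy) <- syms
  le <- matrix(NA_real_, n, length(.LAB_NAMES) * 5L)
  cn <- as.vector(t(outer(.LAB_NAMES, c("min", "max", "median", "mean",
                                        "var"), paste, sep = "_")))
  for (i in seq_len(n)) {
    for (l in seq_along(.LAB_NAMES)) {
      series <- stats::rnorm(5L, mean = shift[l, labels[i]], sd = 1)
      le[i, (l - 1L) * 5L + 1:5] <- labFiveTuple(series)
    }
  }
  le <- as.data.frame(le, row.names = ids)
  names(le) <- cn
  sev <- data.frame(
    aids = as.integer(stats::runif(n) < 0.03),
    hematologic_malignancy = as.integer(stats::runif(n) < 0.05),
    metastatic_cancer = as.integer(stats::runif(n) < 0.05),
    sofa = stats::rpois(n, 6 + unname(labels)),
    saps = stats::rpois(n, 14 + 2 * unname(labels)),
    saps_ii = stats::rpois(n, 32 + 3 * unname(labels)),
    row.names = ids)
  list(de = de, sy = sy, le = le, sev = sev)
}

#' Expected patterns implied by a cohort configuration
#'
#' Ground truth for generator-based tests: per group, the codes whose
#' configured inclusion probability exceeds `delta1` (the expected
#' typical codes), their least-common-ancestor grouping under the
#' packaged ontology, and the code with the lowest configured order mean
#' (the expected lead primary disease).
#'
#' @param config a [CohortConfig-class] object.
#' @param delta1 frequency threshold.
#' @return list per group: `tdcs`, `lcopNodes`, `primary`.
#' @export
groundTruth <- function(config, delta1 = 0.3) {
  stopifnot(is(config, "CohortConfig"))
  lapply(config@signatures, function(sg) {
    can <- icd9Canonicalize(sg$code)$canonical
    tdcs <- can[sg$prob > delta1]
    ont <- buildOntology(tdcs)
    n <- length(tdcs)
    comp <- seq_len(n)
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
      if (icd9LCA(ont, tdcs[i], tdcs[j]) != .ROOT) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    nodes <- vapply(split(tdcs, comp), function(g) {
      if (length(g) == 1L) g else Reduce(function(a, b) icd9LCA(ont, a, b), g)
    }, character(1))
    list(tdcs = sort(tdcs), lcopNodes = sort(unname(nodes)),
         primary = can[which.min(sg$orderMean)])
  })
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      length(object@proportions), "groups, seed", object@seed, "\n")
  cat("  signature sizes:",
      paste(vapply(object@signatures, nrow, integer(1)), collapse = "/"),
      "| noise rate", object@noiseRate, "\n")
})
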
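# Core-zone selection, typical diagnosis code detection, average-order
# computation and TDCCoP ranking.

#' Core zone of a cluster
#'
#' Selects the most exemplar-similar patients of one cluster, either by a
#' similarity threshold (members with similarity to the exemplar at least
#' tau) or as the top-n most similar members.  The exemplar is always a
#' member (similarity 1).
#'
#' @param result an [APClustering-class] object.
#' @param S the [PatientSimilarity-class] the clustering was run on.
#' @param k cluster index.
#' @param mode `"top-n"` (default; experiments typically fix a patient
#'   count, e.g. 800) or `"threshold"`.
#' @param n number of core patients for `"top-n"`; clamped to the cluster
#'   size with a warning if larger.
#' @param tau similarity threshold in [0, 1] for `"threshold"`.
#' @return a [CoreZone-class] object; members ordered by descending
#'   similarity to the exemplar (ties by patient order in `S`).
#' @export
coreZone <- function(result, S, k, mode = c("top-n", "threshold"),
                     n = 800L, tau = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(result, "APClustering"), is(S, "PatientSimilarity"),
            length(k) == 1L, k %in% seq_len(result@K))
  ids <- patientIDs(S)
  memb <- ids[result@labels[ids] == k]
  exemplar <- result@exemplars[k]
  sim <- simValues(S)[memb, exemplar]
  memb <- memb[order(-sim, match(memb, ids))]
  sim <- sort(sim, decreasing = TRUE)
  if (mode == "threshold") {
    stopifnot(is.numeric(tau), tau >= 0, tau <= 1)
    keep <- memb[sim >= tau]
    if (!(exemplar %in% keep)) keep <- c(exemplar, keep)
    param <- tau
  } else {
    n <- as.integer(n)
    stopifnot(n >= 1L)
    if (n > length(memb)) {
      warning("requested ", n, " core patients but cluster ", k, " has only ",
              length(memb), "; clamping", call. = FALSE)
      n <- length(memb)
    }
    keep <- memb[seq_len(n)]
    param <- n
  }
  new("CoreZone", cluster = as.integer(k), exemplar = exemplar,
      members = keep, mode = mode, param = as.numeric(param))
}

#' Core zone members
#'
#' @param core a [CoreZone-class] object.
#' @return character vector of member patient ids, exemplar-similarity
#'   ordered.
#' @export
coreMembers <- function(core) {
  stopifnot(is(core, "CoreZone"))
  core@members
}

#' Occurrence probability of a code in a core zone
#'
#' Fraction of core patients whose deduplicated code set contains the
#' code (a code repeated within one admission counts once).
#'
#' @param core a [CoreZone-class] object.
#' @param records the [DiagnosisRecords-class] the cohort came from.
#' @param code character vector of canonical codes.
#' @return numeric vector of probabilities in [0, 1].
#' @export
codeProbability <- function(core, records, code) {
  stopifnot(is(core, "CoreZone"), is(records, "DiagnosisRecords"))
  sets <- codeSets(records)[coreMembers(core)]
  vapply(as.character(code), function(cd)
    mean(vapply(sets, function(s) cd %in% s, logical(1))), numeric(1))
}

#' Typical diagnosis codes of a core zone
#'
#' Codes whose core-zone occurrence probability strictly exceeds the
#' frequency threshold `delta1` (default 0.3).
#'
#' @inheritParams codeProbability
#' @param delta1 threshold in [0, 1); strictly-greater comparison.
#' @return data.frame with columns `code`, `probability`, sorted by
#'   descending probability; zero rows when no code qualifies.
#' @export
typicalCodes <- function(core, records, delta1 = 0.3) {
  stopifnot(delta1 >= 0, delta1 < 1)
  sets <- codeSets(records)[coreMembers(core)]
  tab <- table(unlist(lapply(sets, unique), use.names = FALSE))
  prob <- as.numeric(tab) / length(sets)
  keep <- prob > delta1
  out <- data.frame(code = names(tab)[keep], probability = prob[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$probability, out$code), , drop = FALSE]
}

#' Average diagnosis order of a code over core patients
#'
#' Mean of the code's within-admission rank over exactly the core
#' patients whose records contain it; patients lacking the code
#' contribute nothing.
#'
#' @inheritParams codeProbability
#' @return numeric vector of average orders; an error if a code occurs in
#'   no core patient.
#' @export
averageOrder <- function(core, records, code) {
  stopifnot(is(core, "CoreZone"), is(records, "DiagnosisRecords"))
  ords <- codeOrders(records)[coreMembers(core)]
  vapply(as.character(code), function(cd) {
    vals <- unlist(lapply(ords, function(o) o[cd]), use.names = FALSE)
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      stop("code ", cd, " occurs in no core patient", call. = FALSE)
    mean(vals)
  }, numeric(1))
}

# rank average orders ascending; ties broken by higher occurrence
# probability, then lexicographic code
.rankAOrd <- function(avg_order, probability, code) {
  ord <- order(avg_order, -probability, code)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  rank
}

#' Re-rank typical codes by average order
#'
#' The TDCCoP sorting function: assigns new orders 1..H' by ascending
#' average diagnosis order.  Ties are broken by higher occurrence
#' probability, then lexicographically by code, for determinism.
#'
#' @param avgOrder numeric average orders.
#' @param probability optional occurrence probabilities (tie-break).
#' @param code optional code strings (final tie-break).
#' @return integer vector of new ranks (a permutation of 1..H').
#' @examples
#' rankByAvgOrder(c(5.3, 7.8, 3.8))  # 2 3 1
#' @export
rankByAvgOrder <- function(avgOrder, probability = NULL, code = NULL) {
  if (is.null(probability)) probability <- numeric(length(avgOrder))
  if (is.null(code)) code <- sprintf("%06d", seq_along(avgOrder))
  stopifnot(length(probability) == length(avgOrder),
            length(code) == length(avgOrder))
  .rankAOrd(avgOrder, probability, code)
}

#' Build the typical diagnosis code co-occurrence pattern
#'
#' Detects typical codes in the core zone, computes their average
#' diagnosis orders, and re-ranks them 1..H' by ascending average order
#' (ties: higher occurrence probability, then code).  Smaller ranks point
#' at likelier primary diseases.
#'
#' @inheritParams typicalCodes
#' @return a [TDCCoP-class] object; empty (with a warning) when no code
#'   exceeds `delta1`.
#' @export
buildTDCCoP <- function(core, records, delta1 = 0.3) {
  td <- typicalCodes(core, records, delta1)
  if (!nrow(td)) {
    warning("no typical diagnosis codes above delta1 = ", delta1,
            " in cluster ", core@cluster, call. = FALSE)
    entries <- data.frame(code = character(), probability = numeric(),
                          avg_order = numeric(), rank = integer(),
                          stringsAsFactors = FALSE)
    return(new("TDCCoP", cluster = core@cluster, entries = entries,
               delta1 = delta1))
  }
  td$avg_order <- averageOrder(core, records, td$code)
  td$rank <- rankByAvgOrder(td$avg_order, td$probability, td$code)
  td <- td[order(td$rank), , drop = FALSE]
  rownames(td) <- NULL
  new("TDCCoP", cluster = core@cluster,
      entries = td[, c("code", "probability", "avg_order", "rank")],
      delta1 = delta1)
}

#' TDCCoP entry table
#'
#' @param x a [TDCCoP-class] object.
#' @return data.frame with columns `code`, `probability`, `avg_order`,
#'   `rank`, sorted by rank.
#' @export
tdccopEntries <- function(x) {
  stopifnot(is(x, "TDCCoP"))
  x@entries
}

#' Stability of typical diagnosis codes across core sizes
#'
#' Re-extracts the typical code set for a list of core-zone sizes and
#' reports whether consecutive sizes agree, the usual check that the
#' chosen core size sits in a stable range.
#'
#' @param result an [APClustering-class] object.
#' @param S the [PatientSimilarity-class] used for clustering.
#' @param records the cohort [DiagnosisRecords-class].
#' @param k cluster index.
#' @param coreSizes integer vector of core sizes to try (clamped to the
#'   cluster size).
#' @param delta1 frequency threshold.
#' @return list with `sets` (named list of code vectors per size) and
#'   `agreement` (logical matrix of pairwise set equality).
#' @export
tdcStability <- function(result, S, records, k, coreSizes, delta1 = 0.3) {
  coreSizes <- sort(unique(as.integer(coreSizes)))
  sets <- lapply(coreSizes, function(nn) {
    core <- suppressWarnings(coreZone(result, S, k, mode = "top-n", n = nn))
    sort(typicalCodes(core, records, delta1)$code)
  })
  names(sets) <- as.character(coreSizes)
  agree <- outer(seq_along(sets), seq_along(sets),
                 Vectorize(function(i, j) setequal(sets[[i]], sets[[j]])))
  dimnames(agree) <- list(names(sets), names(sets))
  list(sets = sets, agreement = agree)
}

setMethod("show", "TDCCoP", function(object) {
  cat("TDCCoP for cluster", object@cluster, "-", nrow(object@entries),
      "typical code(s), delta1 =", object@delta1, "\n")
  if (nrow(object@entries)) print(object@entries, row.names = FALSE)
})
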
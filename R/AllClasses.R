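#' @import methods
NULL

#' Five-level ICD-9-CM ontology
#'
#' Holds the reconstructed ICD-9-CM hierarchy: a virtual root (level 0),
#' 19 chapters (level 1), the section/subchapter layer (level 2), 3-digit
#' categories (level 3), 4-digit subcategories (level 4) and 5-digit
#' extensions (level 5).  Only codes actually present in the input universe
#' (plus their ancestors) are materialised; no virtual sibling padding is
#' created, which is observationally equivalent for least-common-ancestor
#' queries.
#'
#' @slot nodes data.frame with columns `canonical`, `level`, `kind`,
#'   `parent`; one row per materialised node, including the root sentinel.
#' @slot chapters data.frame of chapter ranges (`start`, `end`, `label`).
#' @slot sections data.frame of section ranges (`start`, `end`, `label`).
#'
#' @seealso [buildOntology()], [icd9LCA()], [informationContent()]
#' @export
setClass("ICD9Ontology",
  representation(nodes = "data.frame",
                 chapters = "data.frame",
                 sections = "data.frame"))

setValidity("ICD9Ontology", function(object) {
  nd <- object@nodes
  msgs <- character()
  if (!all(c("canonical", "level", "kind", "parent") %in% names(nd)))
    msgs <- c(msgs, "nodes must have canonical/level/kind/parent columns")
  else {
    if (anyDuplicated(nd$canonical))
      msgs <- c(msgs, "duplicate node canonical forms")
    if (!any(nd$level == 0L))
      msgs <- c(msgs, "root node missing")
    if (!all(nd$level %in% 0:5))
      msgs <- c(msgs, "node levels must be in 0..5")
    nonroot <- nd[nd$level > 0L, , drop = FALSE]
    if (nrow(nonroot) && !all(nonroot$parent %in% nd$canonical))
      msgs <- c(msgs, "every non-root node needs a materialised parent")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ordered patient diagnostic records
#'
#' Per-admission lists of (ICD-9 code, diagnosis order) pairs.  Codes are
#' stored in canonical dotted form; within a patient, duplicate codes are
#' collapsed keeping the smallest order, and orders are unique.
#'
#' @slot records data.frame with columns `patient_id`, `code` (canonical),
#'   `order` (positive integer rank within the admission).
#' @slot ids character vector of patient identifiers (row order of any
#'   derived matrix).
#'
#' @seealso [DiagnosisRecords()], [codeSets()], [similarityMatrix()]
#' @export
setClass("DiagnosisRecords",
  representation(records = "data.frame", ids = "character"))

setValidity("DiagnosisRecords", function(object) {
  r <- object@records
  msgs <- character()
  if (!all(c("patient_id", "code", "order") %in% names(r)))
    return("records must have patient_id/code/order columns")
  if (!length(object@ids)) msgs <- c(msgs, "no patients")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate patient ids")
  if (!all(r$patient_id %in% object@ids))
    msgs <- c(msgs, "records reference unknown patient ids")
  if (!all(object@ids %in% r$patient_id))
    msgs <- c(msgs, "patient with zero diagnosis codes")
  if (any(r$order < 1L)) msgs <- c(msgs, "orders must be positive")
  key <- paste(r$patient_id, r$code)
  if (anyDuplicated(key)) msgs <- c(msgs, "duplicate (patient, code) pairs")
  keyo <- paste(r$patient_id, r$order)
  if (anyDuplicated(keyo)) msgs <- c(msgs, "duplicate orders within a patient")
  if (length(msgs)) msgs else TRUE
})

#' Patient similarity matrix
#'
#' Symmetric N x N matrix of pairwise patient similarities in [0, 1] with a
#' unit diagonal, as produced by the ontology-embedded set similarity
#' measure or one of the exact-match baseline measures.
#'
#' @slot ids character vector of patient identifiers.
#' @slot values numeric matrix, `dimnames` equal to `ids`.
#'
#' @seealso [similarityMatrix()], [apCluster()]
#' @export
setClass("PatientSimilarity",
  representation(ids = "character", values = "matrix"))

setValidity("PatientSimilarity", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != length(object@ids) || ncol(v) != length(object@ids))
    return("matrix dimensions must match ids")
  if (!all(is.finite(v))) msgs <- c(msgs, "non-finite similarities")
  else {
    if (max(abs(v - t(v))) > 1e-12) msgs <- c(msgs, "matrix must be symmetric")
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      msgs <- c(msgs, "similarities must lie in [0, 1]")
    if (max(abs(diag(v) - 1)) > 1e-12)
      msgs <- c(msgs, "diagonal must be 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Affinity propagation clustering result
#'
#' @slot labels integer cluster index per patient, named by patient id.
#' @slot exemplars character vector of exemplar patient ids, one per
#'   cluster, indexed by cluster.
#' @slot K integer number of clusters.
#' @slot supports numeric per-cluster cohort fractions (sum to 1).
#' @slot SS numeric sum of member-to-exemplar similarities.
#' @slot preference numeric preference p used on the similarity diagonal.
#' @slot iterations integer message-passing iterations run.
#' @slot converged logical, whether the exemplar set stabilised.
#'
#' @seealso [apCluster()], [apPreference()], [sumOfSimilarities()]
#' @export
setClass("APClustering",
  representation(labels = "integer", exemplars = "character", K = "integer",
                 supports = "numeric", SS = "numeric", preference = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("APClustering", function(object) {
  msgs <- character()
  if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (length(object@exemplars) != object@K)
    msgs <- c(msgs, "one exemplar per cluster required")
  if (length(object@supports) != object@K)
    msgs <- c(msgs, "one support per cluster required")
  else if (abs(sum(object@supports) - 1) > 1e-8)
    msgs <- c(msgs, "supports must sum to 1")
  ex <- object@exemplars
  if (all(ex %in% names(object@labels))) {
    if (!all(object@labels[ex] == seq_along(ex)))
      msgs <- c(msgs, "each exemplar must carry its own cluster label")
  } else msgs <- c(msgs, "exemplars must be labelled patients")
  if (length(msgs)) msgs else TRUE
})

#' Cluster core zone
#'
#' The most exemplar-similar patients of one cluster, used for typical
#' diagnosis code extraction.  Members are ordered by descending similarity
#' to the exemplar (exemplar first, similarity 1).
#'
#' @slot cluster integer cluster index.
#' @slot exemplar character exemplar patient id.
#' @slot members character member patient ids, ordered.
#' @slot mode `"threshold"` (similarity >= tau) or `"top-n"`.
#' @slot param numeric, the tau or n actually applied.
#'
#' @seealso [coreZone()], [buildTDCCoP()]
#' @export
setClass("CoreZone",
  representation(cluster = "integer", exemplar = "character",
                 members = "character", mode = "character", param = "numeric"))

setValidity("CoreZone", function(object) {
  msgs <- character()
  if (!length(object@members)) msgs <- c(msgs, "empty core zone")
  if (!(object@exemplar %in% object@members))
    msgs <- c(msgs, "exemplar must belong to its core zone")
  if (!object@mode %in% c("threshold", "top-n"))
    msgs <- c(msgs, "mode must be 'threshold' or 'top-n'")
  if (length(msgs)) msgs else TRUE
})

#' Typical diagnosis code co-occurrence pattern (TDCCoP)
#'
#' Ranked list of a cluster's typical diagnosis codes: codes whose
#' occurrence probability in the core zone exceeds the frequency threshold,
#' re-ranked 1..H' by ascending average diagnosis order.
#'
#' @slot cluster integer cluster index.
#' @slot entries data.frame with columns `code`, `probability`,
#'   `avg_order`, `rank`.
#' @slot delta1 numeric occurrence-probability threshold used.
#'
#' @seealso [buildTDCCoP()], [groupLCoP()]
#' @export
setClass("TDCCoP",
  representation(cluster = "integer", entries = "data.frame",
                 delta1 = "numeric"))

setValidity("TDCCoP", function(object) {
  e <- object@entries
  if (!all(c("code", "probability", "avg_order", "rank") %in% names(e)))
    return("entries must have code/probability/avg_order/rank columns")
  msgs <- character()
  if (nrow(e)) {
    if (!identical(sort(e$rank), seq_len(nrow(e))))
      msgs <- c(msgs, "ranks must be a 1..H' permutation")
    if (any(e$probability <= object@delta1))
      msgs <- c(msgs, "all probabilities must exceed delta1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Conditional co-occurrence matrix (CCoM)
#'
#' Square matrix over LCA co-occurrence pattern (LCoP) entries.
#' Off-diagonal (i, j) holds the conditional probability of entry j given
#' entry i among core patients; the diagonal holds each entry's marginal
#' core-zone frequency.
#'
#' @slot nodes character LCoP node tokens (row/column order).
#' @slot members list of member TDC codes per node.
#' @slot values numeric matrix of conditional probabilities.
#' @slot coreSize integer number of core patients counted.
#' @slot direction `"symmetric"` or `"order-directed"` co-occurrence
#'   counting.
#'
#' @seealso [conditionalCoOccurrence()], [identifyUD()]
#' @export
setClass("CCoM",
  representation(nodes = "character", members = "list", values = "matrix",
                 coreSize = "integer", direction = "character"))

setValidity("CCoM", function(object) {
  msgs <- character()
  v <- object@values
  if (nrow(v) != length(object@nodes) || ncol(v) != length(object@nodes))
    msgs <- c(msgs, "matrix dimensions must match nodes")
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    msgs <- c(msgs, "conditional probabilities must lie in [0, 1]")
  if (length(object@members) != length(object@nodes))
    msgs <- c(msgs, "one member set per node required")
  if (length(msgs)) msgs else TRUE
})

#' Unifying diagnosis split of an LCoP
#'
#' Result of splitting an order-sorted LCoP into primary diseases (the
#' unifying diagnosis) and complications by pairwise conditional
#' co-occurrence dominance.
#'
#' @slot cluster integer cluster index.
#' @slot lcop data.frame of LCoP entries (`node`, `order`), order-sorted.
#' @slot members list of member TDC codes per LCoP entry.
#' @slot primaries character nodes designated as the unifying diagnosis.
#' @slot complications character remaining nodes.
#' @slot rho numeric dominance ratio used.
#' @slot dominance data.frame ledger of per-pair dominance decisions.
#' @slot splitIndex integer position of the last primary in the sorted
#'   LCoP.
#'
#' @seealso [identifyUD()]
#' @export
setClass("UDResult",
  representation(cluster = "integer", lcop = "data.frame", members = "list",
                 primaries = "character", complications = "character",
                 rho = "numeric", dominance = "data.frame",
                 splitIndex = "integer"))

setValidity("UDResult", function(object) {
  msgs <- character()
  all_nodes <- object@lcop$node
  if (!setequal(c(object@primaries, object@complications), all_nodes))
    msgs <- c(msgs, "primaries and complications must partition the LCoP")
  if (length(all_nodes) && !length(object@primaries))
    msgs <- c(msgs, "primaries must be non-empty for a non-empty LCoP")
  if (length(msgs)) msgs else TRUE
})
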
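# Container construction and accessors for ordered per-admission
# diagnosis code lists.

#' Construct ordered patient diagnostic records
#'
#' Builds a [DiagnosisRecords-class] object from a long-format table of
#' (patient id, diagnosis order, ICD-9 code) rows.  Codes are
#' canonicalized (dotless MIMIC forms accepted); duplicate (patient, code)
#' rows are collapsed keeping the smallest order; entries are sorted by
#' order within patient.
#'
#' @param data data.frame with at least the three columns named below.
#' @param id,order,code column names holding the patient identifier, the
#'   1-based diagnosis rank and the ICD-9 code string.
#' @return a [DiagnosisRecords-class] object.
#' @examples
#' df <- data.frame(hadm_id = c(1, 1, 2), seq_num = c(1, 2, 1),
#'                  icd9_code = c("0389", "5849", "486"))
#' DiagnosisRecords(df, id = "hadm_id", order = "seq_num", code = "icd9_code")
#' @export
DiagnosisRecords <- function(data, id = "patient_id", order = "order",
                             code = "code") {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(id, order, code), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  rec <- data.frame(patient_id = as.character(data[[id]]),
                    code = icd9Canonicalize(as.character(data[[code]]))$canonical,
                    order = as.integer(data[[order]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(rec$order)) || any(rec$order < 1L))
    stop("diagnosis orders must be positive integers", call. = FALSE)
  # collapse duplicated codes within a patient, keeping the smallest order
  rec <- rec[order(rec$patient_id, rec$order), , drop = FALSE]
  rec <- rec[!duplicated(rec[c("patient_id", "code")]), , drop = FALSE]
  # original order values are kept (average orders depend on them); only
  # patients with clashing orders are re-ranked to restore uniqueness
  rec <- do.call(rbind, lapply(split(rec, rec$patient_id), function(d) {
    d <- d[order(d$order), , drop = FALSE]
    if (anyDuplicated(d$order))
      d$order <- seq_len(nrow(d))
    d
  }))
  rownames(rec) <- NULL
  ids <- unique(as.character(data[[id]]))
  new("DiagnosisRecords", records = rec, ids = ids)
}

#' Patient identifiers of an object
#'
#' @param x a [DiagnosisRecords-class], [PatientSimilarity-class] or
#'   [APClustering-class] object.
#' @return character vector of patient ids.
#' @export
setMethod("patientIDs", "DiagnosisRecords", function(x) x@ids)

#' Deduplicated per-patient code sets
#'
#' The unordered view of each patient's diagnosis codes, used by the set
#' similarity measure (diagnosis order is deliberately ignored there).
#'
#' @param x a [DiagnosisRecords-class] object.
#' @return named list of character vectors of canonical codes.
#' @export
codeSets <- function(x) {
  stopifnot(is(x, "DiagnosisRecords"))
  out <- split(x@records$code, x@records$patient_id)[x@ids]
  names(out) <- x@ids
  out
}

#' Per-patient diagnosis orders
#'
#' @param x a [DiagnosisRecords-class] object.
#' @return named list; each element a numeric vector of orders named by
#'   canonical code.
#' @export
codeOrders <- function(x) {
  stopifnot(is(x, "DiagnosisRecords"))
  out <- lapply(split(x@records, x@records$patient_id)[x@ids], function(d)
    stats::setNames(d$order, d$code))
  names(out) <- x@ids
  out
}

setMethod("show", "DiagnosisRecords", function(object) {
  sizes <- lengths(codeSets(object))
  cat("DiagnosisRecords:", length(object@ids), "patients,",
      nrow(object@records), "coded diagnoses\n")
  cat("  codes per patient: min", min(sizes), "/ median",
      stats::median(sizes), "/ max", max(sizes), "\n")
})
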
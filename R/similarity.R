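# Ontology-embedded semantic similarity between diagnosis codes and
# between patients' diagnosis-code sets, plus the exact-match baseline
# set measures (Dice, Jaccard, cosine, overlap).

#' Semantic similarity between two diagnosis codes
#'
#' Wu-Palmer-style level-depth similarity: twice the information content
#' of the least common ancestor over the summed information contents of
#' the two codes.  Equals 1 for identical codes and 0 when the codes share
#' only the root (different chapters).
#'
#' @param ontology an [ICD9Ontology-class].
#' @param a,b character vectors of codes (recycled); the root sentinel is
#'   rejected, since patient records never carry it.
#' @return numeric vector of similarities in [0, 1].
#' @examples
#' ont <- buildOntology(c("550.12", "550.13", "541"))
#' codeSimilarity(ont, "550.12", "550.13")  # 2*4/(5+5) = 0.8
#' @export
codeSimilarity <- function(ontology, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ica <- informationContent(ontology, a)
  icb <- informationContent(ontology, b)
  if (any(ica == 0L) || any(icb == 0L))
    stop("the root node is not a valid patient diagnosis code", call. = FALSE)
  lca <- icd9LCA(ontology, a, b)
  2 * informationContent(ontology, lca) / (ica + icb)
}

# code-by-code similarity matrix over a set of leaf codes, computed from
# precomputed ancestor chains (one chain per unique code)
.codeSimMatrix <- function(codes) {
  chains <- lapply(codes, .ancestorChain)
  ic <- lengths(chains) - 1L  # chain is root-first, so IC = length - 1
  if (any(ic == 0L))
    stop("the root node is not a valid patient diagnosis code", call. = FALSE)
  n <- length(codes)
  m <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    common <- intersect(chains[[i]], chains[[j]])
    m[i, j] <- m[j, i] <- 2 * (length(common) - 1L) / (ic[i] + ic[j])
  }
  dimnames(m) <- list(codes, codes)
  m
}

#' Set-level similarity between two diagnosis-code sets
#'
#' Best-match average: each code of one set is matched to its most similar
#' code in the other set, in both directions, and the matched similarities
#' are averaged over the total number of codes.  Symmetric, bounded in
#' [0, 1], and 1 exactly for identical sets.
#'
#' @param ontology an [ICD9Ontology-class].
#' @param di,dj non-empty character vectors of codes (deduplicated
#'   internally).
#' @return numeric scalar in [0, 1].
#' @examples
#' ont <- buildOntology(c("550.12", "550.13"))
#' setSimilarity(ont, "550.12", "550.13")  # 0.8
#' @export
setSimilarity <- function(ontology, di, dj) {
  di <- unique(as.character(di)); dj <- unique(as.character(dj))
  if (!length(di) || !length(dj))
    stop("diagnosis code sets must be non-empty", call. = FALSE)
  di <- .requireNode(ontology, di); dj <- .requireNode(ontology, dj)
  cs <- .codeSimMatrix(union(di, dj))
  sub <- cs[di, dj, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
    (length(di) + length(dj))
}

#' Exact-match baseline set similarities
#'
#' Classical set-overlap measures used as baselines for the
#' ontology-embedded measure; intersection is exact code equality, with no
#' semantic credit for near-sibling codes.
#'
#' @param di,dj non-empty character vectors of codes.
#' @param method one of `"dice"`, `"jaccard"`, `"cosine"`, `"overlap"`.
#' @param cosineVariant `"sqrt"` (standard set cosine,
#'   `|A∩B|/sqrt(|A||B|)`) or `"printed"` (`|A∩B|/(|A||B|)`, not bounded
#'   consistently with the other measures; kept for comparison).
#' @return numeric scalar.
#' @export
baselineSetSimilarity <- function(di, dj,
                                  method = c("dice", "jaccard", "cosine",
                                             "overlap"),
                                  cosineVariant = c("sqrt", "printed")) {
  method <- match.arg(method)
  cosineVariant <- match.arg(cosineVariant)
  di <- unique(as.character(di)); dj <- unique(as.character(dj))
  if (!length(di) || !length(dj))
    stop("diagnosis code sets must be non-empty", call. = FALSE)
  nab <- length(intersect(di, dj)); na <- length(di); nb <- length(dj)
  switch(method,
    dice = 2 * nab / (na + nb),
    jaccard = nab / length(union(di, dj)),
    overlap = nab / min(na, nb),
    cosine = if (cosineVariant == "sqrt") nab / sqrt(na * nb)
             else nab / (na * nb))
}

#' Patient similarity matrix
#'
#' Computes the full symmetric patient-by-patient similarity matrix over
#' deduplicated code sets.  With `method = "ontology"` the
#' ontology-embedded best-match measure is used; the remaining methods are
#' the exact-match baselines.  Each unordered pair is evaluated once
#' (patients with identical code sets share their computed values).
#'
#' @param records a [DiagnosisRecords-class] object with at least two
#'   patients.
#' @param ontology an [ICD9Ontology-class]; required for
#'   `method = "ontology"`, ignored otherwise.
#' @param method similarity measure; see [setSimilarity()] and
#'   [baselineSetSimilarity()].
#' @param cosineVariant passed to [baselineSetSimilarity()].
#' @return a [PatientSimilarity-class] object.
#' @export
similarityMatrix <- function(records, ontology = NULL,
                             method = c("ontology", "dice", "jaccard",
                                        "cosine", "overlap"),
                             cosineVariant = c("sqrt", "printed")) {
  method <- match.arg(method)
  cosineVariant <- match.arg(cosineVariant)
  stopifnot(is(records, "DiagnosisRecords"))
  ids <- patientIDs(records)
  if (length(ids) < 2L) stop("need at least two patients", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  sets <- codeSets(records)
  if (method == "ontology") {
    stopifnot(is(ontology, "ICD9Ontology"))
    allCodes <- unique(unlist(sets, use.names = FALSE))
    .requireNode(ontology, allCodes)
    cs <- .codeSimMatrix(allCodes)
  }
  # patients sharing a code-set signature share all pairwise values
  sig <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
  usig <- unique(sig)
  grp <- match(sig, usig)
  usets <- sets[match(usig, sig)]
  m <- length(usig)
  um <- diag(1, m)
  pairSim <- if (method == "ontology") {
    function(si, sj) {
      sub <- cs[si, sj, drop = FALSE]
      (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(si) + length(sj))
    }
  } else {
    function(si, sj) baselineSetSimilarity(si, sj, method, cosineVariant)
  }
  if (m > 1L) for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    um[i, j] <- um[j, i] <- pairSim(usets[[i]], usets[[j]])
  }
  v <- um[grp, grp, drop = FALSE]
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  new("PatientSimilarity", ids = ids, values = v)
}

#' Similarity matrix values
#'
#' @param x a [PatientSimilarity-class] object.
#' @return the numeric matrix, dimnames set to patient ids.
#' @export
simValues <- function(x) {
  stopifnot(is(x, "PatientSimilarity"))
  x@values
}

#' @rdname patientIDs
#' @export
setMethod("patientIDs", "PatientSimilarity", function(x) x@ids)

setMethod("show", "PatientSimilarity", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat("PatientSimilarity:", length(object@ids), "x", length(object@ids),
      "symmetric matrix\n")
  if (length(off))
    cat(sprintf("  off-diagonal range [%.3f, %.3f], median %.3f\n",
                min(off), max(off), stats::median(off)))
})
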
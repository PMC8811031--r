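# Unifying-diagnosis identification: grouping typical codes under least
# common ancestors (LCoP), the conditional co-occurrence matrix over LCoP
# entries, and the primary-disease / complication split.

#' Group typical codes under least common ancestors
#'
#' Partitions the TDCCoP's codes into connected components of the
#' relation "pairwise LCA is not the root" (i.e. codes sharing any
#' chapter).  Each multi-member component is represented by the LCA of
#' all its members; singletons keep their own code.  Component
#' representatives are never the root.
#'
#' @param tdccop a non-empty [TDCCoP-class] object.
#' @param ontology an [ICD9Ontology-class] containing all TDCCoP codes.
#' @return list with `node` (character representative per entry) and
#'   `members` (list of member codes per entry).
#' @export
groupLCoP <- function(tdccop, ontology) {
  stopifnot(is(tdccop, "TDCCoP"), is(ontology, "ICD9Ontology"))
  codes <- tdccopEntries(tdccop)$code
  if (!length(codes)) stop("empty TDCCoP", call. = FALSE)
  n <- length(codes)
  comp <- seq_len(n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (icd9LCA(ontology, codes[i], codes[j]) != .ROOT) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  groups <- split(codes, comp)
  node <- vapply(groups, function(g) {
    if (length(g) == 1L) return(.requireNode(ontology, g))
    Reduce(function(a, b) icd9LCA(ontology, a, b), g)
  }, character(1))
  list(node = unname(node), members = unname(groups))
}

#' Order LCoP entries from member ranks
#'
#' Assigns each LCoP entry the minimum TDCCoP re-rank among its member
#' codes and sorts entries ascending by that order.
#'
#' @param lcop result of [groupLCoP()].
#' @param tdccop the [TDCCoP-class] the grouping came from.
#' @return data.frame with columns `node`, `order`, plus the member list
#'   attached as the `members` attribute-free list column `members`.
#' @export
lcopOrder <- function(lcop, tdccop) {
  entries <- tdccopEntries(tdccop)
  ranks <- stats::setNames(entries$rank, entries$code)
  if (!all(unlist(lcop$members) %in% entries$code))
    stop("LCoP members must all appear in the TDCCoP", call. = FALSE)
  ord <- vapply(lcop$members, function(m) min(ranks[m]), numeric(1))
  ix <- order(ord)
  out <- data.frame(node = lcop$node[ix], order = as.integer(ord[ix]),
                    stringsAsFactors = FALSE)
  out$members <- lcop$members[ix]
  out
}

# does each core patient "have" an LCoP node?  true when any of the
# patient's codes equals the node or descends from it in the ontology
.entryPresence <- function(nodes, sets, ontology) {
  allCodes <- unique(unlist(sets, use.names = FALSE))
  chains <- lapply(allCodes, .ancestorChain)
  names(chains) <- allCodes
  covered <- lapply(nodes, function(nd)
    allCodes[vapply(chains, function(ch) nd %in% ch, logical(1))])
  out <- vapply(seq_along(nodes), function(i)
    vapply(sets, function(s) any(s %in% covered[[i]]), logical(1)),
    logical(length(sets)))
  matrix(out, nrow = length(sets), dimnames = list(names(sets), nodes))
}

#' Conditional co-occurrence matrix over LCoP entries
#'
#' Off-diagonal entry (i, j) is the conditional probability of entry j
#' given entry i among core patients; the diagonal holds each entry's
#' marginal core-zone frequency.  A patient "has" an entry when any of
#' its codes equals the entry's node or descends from it (sections and
#' chapters act as range predicates over leaf codes).
#'
#' With `direction = "symmetric"` (default) the numerator counts patients
#' having both entries; with `"order-directed"` it counts, among patients
#' having both, those whose earliest d_i code precedes their earliest d_j
#' code in the diagnosis order, reflecting the causal reading that
#' complications are coded after primary diseases.
#'
#' @param lcop an ordered LCoP data.frame from [lcopOrder()].
#' @param core a [CoreZone-class].
#' @param records the cohort [DiagnosisRecords-class].
#' @param ontology an [ICD9Ontology-class].
#' @param direction co-occurrence counting mode.
#' @return a [CCoM-class] object.
#' @export
conditionalCoOccurrence <- function(lcop, core, records, ontology,
                                    direction = c("symmetric",
                                                  "order-directed")) {
  direction <- match.arg(direction)
  stopifnot(is(core, "CoreZone"), is(records, "DiagnosisRecords"))
  nodes <- lcop$node
  sets <- codeSets(records)[coreMembers(core)]
  pres <- .entryPresence(nodes, sets, ontology)
  ncore <- length(sets)
  freq <- colSums(pres)
  m <- length(nodes)
  v <- matrix(0, m, m, dimnames = list(nodes, nodes))
  if (direction == "order-directed") {
    ords <- codeOrders(records)[coreMembers(core)]
    minOrd <- vapply(seq_len(m), function(i) {
      nd <- nodes[i]
      vapply(ords, function(o) {
        cds <- names(o)
        inNode <- vapply(cds, function(cd) nd %in% .ancestorChain(cd),
                         logical(1))
        if (any(inNode)) min(o[inNode]) else NA_real_
      }, numeric(1))
    }, numeric(ncore))
    minOrd <- matrix(minOrd, nrow = ncore)
  }
  for (i in seq_len(m)) {
    if (freq[i] == 0) {
      warning("LCoP entry ", nodes[i], " occurs in no core patient; ",
              "its conditional row is zero", call. = FALSE)
      next
    }
    for (j in seq_len(m)) {
      if (i == j) { v[i, i] <- freq[i] / ncore; next }
      both <- pres[, i] & pres[, j]
      num <- if (direction == "symmetric") sum(both)
             else sum(both & minOrd[, i] < minOrd[, j], na.rm = TRUE)
      v[i, j] <- num / freq[i]
    }
  }
  new("CCoM", nodes = nodes, members = lcop$members, values = v,
      coreSize = as.integer(ncore), direction = direction)
}

#' CCoM values
#'
#' @param x a [CCoM-class] object.
#' @return numeric matrix with LCoP node dimnames.
#' @export
ccomValues <- function(x) {
  stopifnot(is(x, "CCoM"))
  x@values
}

#' Identify the unifying diagnosis
#'
#' Splits the order-sorted LCoP into primary diseases (the unifying
#' diagnosis) and complications.  Entry d_i dominates d_j when its
#' conditional co-occurrence probability is at least `rho` times the
#' reverse one, or its marginal frequency is at least `rho` times d_j's.
#' The split point maximises (dominance wins of the prefix over the
#' suffix) minus (wins of the suffix over the prefix); ties favour the
#' smaller prefix, and the prefix is never empty.
#'
#' @param lcop an ordered LCoP data.frame from [lcopOrder()].
#' @param ccom a [CCoM-class] over the same entries.
#' @param rho dominance ratio, > 1 (default 1.5).
#' @param cluster cluster index recorded in the result.
#' @return a [UDResult-class] object with the full per-pair dominance
#'   ledger.
#' @export
identifyUD <- function(lcop, ccom, rho = 1.5, cluster = 1L) {
  stopifnot(is(ccom, "CCoM"), rho > 1)
  nodes <- lcop$node
  if (!identical(nodes, ccom@nodes))
    stop("LCoP and CCoM entries disagree", call. = FALSE)
  m <- length(nodes)
  v <- ccomValues(ccom)
  dom <- matrix(FALSE, m, m)
  ledger <- NULL
  if (m > 1L) {
    pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    ledger <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      dij <- v[i, j] >= rho * v[j, i] || v[i, i] >= rho * v[j, j]
      dji <- v[j, i] >= rho * v[i, j] || v[j, j] >= rho * v[i, i]
      dom[i, j] <<- dij; dom[j, i] <<- dji
      data.frame(d_i = nodes[i], d_j = nodes[j],
                 cc_ij = v[i, j], cc_ji = v[j, i],
                 freq_i = v[i, i], freq_j = v[j, j],
                 i_dominates_j = dij, j_dominates_i = dji,
                 stringsAsFactors = FALSE)
    }))
  } else {
    ledger <- data.frame(d_i = character(), d_j = character(),
                         cc_ij = numeric(), cc_ji = numeric(),
                         freq_i = numeric(), freq_j = numeric(),
                         i_dominates_j = logical(), j_dominates_i = logical(),
                         stringsAsFactors = FALSE)
  }
  if (m == 1L) {
    split <- 1L
  } else {
    score <- vapply(seq_len(m), function(s) {
      if (s == m) return(0)
      pre <- seq_len(s); suf <- seq(s + 1L, m)
      sum(dom[pre, suf]) - sum(dom[suf, pre])
    }, numeric(1))
    # never split after the last entry unless it is uniquely best is moot:
    # score(m) = 0, so a strictly positive earlier split wins; ties take
    # the smallest prefix
    split <- which.max(score)
  }
  primaries <- nodes[seq_len(split)]
  complications <- if (split < m) nodes[seq(split + 1L, m)] else character()
  new("UDResult", cluster = as.integer(cluster), lcop = lcop[, c("node", "order")],
      members = lcop$members, primaries = primaries,
      complications = complications, rho = rho, dominance = ledger,
      splitIndex = as.integer(split))
}

#' Primary diseases and complications of a UD split
#'
#' @param x a [UDResult-class] object.
#' @return character vector of LCoP node tokens.
#' @export
udPrimaries <- function(x) {
  stopifnot(is(x, "UDResult"))
  x@primaries
}

#' @rdname udPrimaries
#' @export
udComplications <- function(x) {
  stopifnot(is(x, "UDResult"))
  x@complications
}

setMethod("show", "UDResult", function(object) {
  cat("UDResult: unifying diagnosis =",
      paste(object@primaries, collapse = ", "), "\n")
  if (length(object@complications))
    cat("  complications =", paste(object@complications, collapse = ", "),
        "\n")
  cat("  dominance ratio rho =", object@rho, "| split after position",
      object@splitIndex, "\n")
})

setMethod("show", "CCoM", function(object) {
  cat("CCoM over", length(object@nodes), "LCoP entries (",
      object@direction, "counting,", object@coreSize, "core patients)\n")
  print(round(object@values, 3))
})

setMethod("show", "CoreZone", function(object) {
  cat("CoreZone of cluster", object@cluster, "-", length(object@members),
      "patients (", object@mode, "=", object@param, "), exemplar",
      object@exemplar, "\n")
})
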
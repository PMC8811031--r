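# Shared fixtures and independent oracles for the test suite.

# independent LCA oracle: climb the parent map of the materialised tree
# (the implementation derives chains syntactically, this walks the stored
# parent pointers instead)
oracleLCA <- function(ontology, a, b) {
  nd <- ontologyNodes(ontology)
  chain <- function(code) {
    path <- code
    while (!is.na(nd$parent[match(code, nd$canonical)])) {
      code <- nd$parent[match(code, nd$canonical)]
      path <- c(path, code)
    }
    rev(path)  # root first
  }
  ca <- chain(a); cb <- chain(b)
  common <- intersect(ca, cb)
  common[length(common)]
}

# exhaustive exemplar-subset search maximizing net similarity
# sum_i max_{e in E} S[i, e] restricted to members assigned to their best
# exemplar, plus p per exemplar; feasible for N <= 8
oracleBestNetSimilarity <- function(values, p) {
  n <- nrow(values)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    assign_sim <- vapply(seq_len(n), function(i) {
      if (i %in% ex) return(0)  # exemplar similarity counted via p below
      max(values[i, ex])
    }, numeric(1))
    net <- sum(assign_sim) + length(ex) * p
    if (net > best) best <- net
  }
  best
}

netSimilarityOf <- function(values, labels, exemplarIdx, p) {
  n <- nrow(values)
  s <- 0
  for (i in seq_len(n)) {
    e <- exemplarIdx[labels[i]]
    if (i != e) s <- s + values[i, e]
  }
  s + length(exemplarIdx) * p
}

# direct entropy arithmetic on a contingency table (feature x class)
oracleIG <- function(tab) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  n <- sum(tab)
  hy <- H(colSums(tab) / n)
  hyx <- sum(vapply(seq_len(nrow(tab)), function(i) {
    ni <- sum(tab[i, ])
    if (ni == 0) return(0)
    (ni / n) * H(tab[i, ] / ni)
  }, numeric(1)))
  hy - hyx
}

# small hand-built cohort: two tight groups in different chapters
blockCohort <- function() {
  rows <- list(
    A1 = c("428.0", "427.31"), A2 = c("428.0", "427.31"),
    A3 = c("428.0", "401.9"),
    B1 = c("584.9", "599.0"), B2 = c("584.9", "599.0"),
    B3 = c("584.9", "585.9"))
  df <- do.call(rbind, lapply(names(rows), function(id)
    data.frame(patient_id = id, order = seq_along(rows[[id]]),
               code = rows[[id]], stringsAsFactors = FALSE)))
  DiagnosisRecords(df)
}

# the 12 typical codes of the larger printed cluster pattern with their
# occurrence frequencies and average orders
table2Entries <- function() {
  data.frame(
    code = c("518.81", "038.9", "785.52", "584.9", "427.31", "995.92",
             "428.0", "486", "599.0", "401.9", "276.2", "250.0"),
    probability = c(0.526, 0.608, 0.729, 0.554, 0.593, 0.941,
                    0.729, 0.334, 0.389, 0.343, 0.360, 0.383),
    avg_order = c(7.665, 7.545, 7.813, 7.377, 8.038, 8.031,
                  7.703, 7.805, 7.701, 7.807, 7.875, 8.062),
    stringsAsFactors = FALSE)
}

table2TDCCoP <- function() {
  e <- table2Entries()
  e$rank <- rankByAvgOrder(e$avg_order, e$probability, e$code)
  e <- e[order(e$rank), ]
  rownames(e) <- NULL
  new("TDCCoP", cluster = 2L, entries = e, delta1 = 0.3)
}

enDash <- function(a, b) paste0(a, "–", b)
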
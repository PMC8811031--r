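# Exemplar-based patient clustering by affinity propagation
# (responsibility/availability message passing) with the median-based
# preference rule, cluster support and the sum-of-similarities score.

#' Exemplar preference from the similarity matrix
#'
#' The shared preference placed on the similarity diagonal before message
#' passing: the median off-diagonal similarity minus a coefficient times
#' the number of patients.  Larger coefficients yield fewer clusters.
#'
#' @param S a [PatientSimilarity-class] object.
#' @param pCoe non-negative preference coefficient (default 0.025).
#' @return numeric preference p.
#' @export
apPreference <- function(S, pCoe = 0.025) {
  stopifnot(is(S, "PatientSimilarity"), pCoe >= 0)
  v <- simValues(S)
  n <- nrow(v)
  stopifnot(n >= 2L)
  stats::median(v[upper.tri(v)]) - pCoe * n
}

#' Affinity propagation clustering of a patient similarity matrix
#'
#' Standard responsibility/availability message passing with damping.  The
#' diagonal of the similarity matrix is replaced by the preference `p`;
#' after convergence, points whose availability plus responsibility is
#' positive become exemplars, and every patient is assigned to the
#' exemplar it is most similar to (ties to the lowest exemplar index).  A
#' tiny seeded jitter (relative magnitude <= 1e-12) breaks exact
#' symmetric ties that would otherwise oscillate.
#'
#' @param S a [PatientSimilarity-class] object.
#' @param p numeric preference; supply directly (e.g. for sweeps) or
#'   compute via [apPreference()].
#' @param damping message damping factor in [0.5, 1).
#' @param maxIter maximum message-passing iterations.
#' @param convergence iterations of unchanged exemplar set required to
#'   declare convergence.
#' @param seed integer seed for the tie-breaking jitter.
#' @return an [APClustering-class] object.  If the exemplar set has not
#'   stabilised within `maxIter`, the result is returned with
#'   `converged = FALSE` and a warning.
#' @examples
#' df <- data.frame(patient_id = rep(1:4, each = 2), order = rep(1:2, 4),
#'                  code = rep(c("428.0", "427.31", "486", "518.81"),
#'                             each = 2)[c(1, 2, 1, 2, 3, 4, 3, 4)])
#' rec <- DiagnosisRecords(df)
#' ont <- buildOntology(unique(df$code))
#' S <- similarityMatrix(rec, ont)
#' apCluster(S, p = -1)
#' @export
apCluster <- function(S, p, damping = 0.9, maxIter = 1000L,
                      convergence = 50L, seed = 1L) {
  stopifnot(is(S, "PatientSimilarity"), is.numeric(p), length(p) == 1L,
            damping >= 0.5, damping < 1)
  ids <- patientIDs(S)
  n <- length(ids)
  s <- simValues(S)
  diag(s) <- p
  # seeded symmetric-degeneracy jitter, as in reference implementations
  set.seed(as.integer(seed))
  scale <- max(abs(s))
  if (scale == 0) scale <- 1
  s <- s + matrix(stats::rnorm(n * n), n, n) * 1e-12 * scale
  R <- A <- matrix(0, n, n)
  stable <- 0L
  lastEx <- integer()
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # responsibilities
    AS <- A + s
    m1 <- apply(AS, 1L, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    m2 <- apply(AS2, 1L, max)
    Rmax <- matrix(m1, n, n)
    Rmax[cbind(seq_len(n), w1)] <- m2
    R <- damping * R + (1 - damping) * (s - Rmax)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, lastEx) && length(ex)) stable <- stable + 1L
    else stable <- 0L
    lastEx <- ex
    if (stable >= convergence) break
  }
  converged <- stable >= convergence
  if (!converged)
    warning("affinity propagation did not converge within ", maxIter,
            " iterations", call. = FALSE)
  ex <- lastEx
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  # assign members to their most similar exemplar; ties to lowest index
  sim2ex <- simValues(S)[, ex, drop = FALSE]
  labels <- max.col(sim2ex, ties.method = "first")
  labels[ex] <- seq_along(ex)
  # drop exemplars that attracted nobody (can happen on degenerate input)
  used <- sort(unique(labels))
  ex <- ex[used]
  labels <- match(labels, used)
  names(labels) <- ids
  K <- length(ex)
  supports <- as.numeric(table(factor(labels, levels = seq_len(K))) / n)
  res <- new("APClustering", labels = stats::setNames(as.integer(labels), ids),
             exemplars = ids[ex], K = as.integer(K), supports = supports,
             SS = 0, preference = p, iterations = it, converged = converged)
  res@SS <- sumOfSimilarities(S, res)
  res
}

#' @rdname patientIDs
#' @export
setMethod("patientIDs", "APClustering", function(x) names(x@labels))

#' Cluster labels, exemplars, and cluster count
#'
#' @param x an [APClustering-class] object.
#' @return `clusterLabels`: named integer vector; `exemplars`: character
#'   vector of exemplar ids; `numClusters`: integer K.
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "APClustering"))
  x@labels
}

#' @rdname clusterLabels
#' @export
exemplars <- function(x) {
  stopifnot(is(x, "APClustering"))
  x@exemplars
}

#' @rdname clusterLabels
#' @export
numClusters <- function(x) {
  stopifnot(is(x, "APClustering"))
  x@K
}

#' Cluster support (popularity)
#'
#' Fraction of the cohort assigned to cluster `k`.
#'
#' @param result an [APClustering-class] object.
#' @param k cluster index in 1..K; if missing, all supports are returned.
#' @return numeric fraction(s).
#' @export
clusterSupport <- function(result, k) {
  stopifnot(is(result, "APClustering"))
  if (missing(k)) return(result@supports)
  if (!(length(k) == 1L && k %in% seq_len(result@K)))
    stop("invalid cluster index", call. = FALSE)
  result@supports[k]
}

#' Sum of member-to-exemplar similarities
#'
#' Clustering quality score: the sum over clusters of each member's
#' similarity to its cluster exemplar (the exemplar itself contributes the
#' unit diagonal).
#'
#' @param S the [PatientSimilarity-class] the clustering was run on.
#' @param result an [APClustering-class] object.
#' @return numeric SS value.
#' @export
sumOfSimilarities <- function(S, result) {
  stopifnot(is(S, "PatientSimilarity"), is(result, "APClustering"))
  v <- simValues(S)
  ids <- patientIDs(S)
  lab <- result@labels[ids]
  exIdx <- match(result@exemplars, ids)
  sum(v[cbind(seq_along(ids), exIdx[lab])])
}

#' Sweep the preference coefficient
#'
#' Runs [apCluster()] over a grid of preference coefficients and reports
#' the resulting cluster counts and scores, mirroring the usual procedure
#' for choosing the granularity.
#'
#' @param S a [PatientSimilarity-class] object.
#' @param pCoe numeric vector of preference coefficients.
#' @param ... passed to [apCluster()].
#' @return data.frame with columns `p_coe`, `p`, `K`, `SS`, `converged`.
#' @export
sweepPreference <- function(S, pCoe = seq(0.01, 0.04, by = 0.005), ...) {
  rows <- lapply(pCoe, function(pc) {
    p <- apPreference(S, pc)
    r <- apCluster(S, p, ...)
    data.frame(p_coe = pc, p = p, K = r@K, SS = r@SS, converged = r@converged)
  })
  do.call(rbind, rows)
}

setMethod("show", "APClustering", function(object) {
  cat("APClustering:", length(object@labels), "patients in", object@K,
      "cluster(s)\n")
  cat(sprintf("  preference %.4f, SS %.3f, %d iterations, converged: %s\n",
              object@preference, object@SS, object@iterations,
              object@converged))
  cat("  supports:", paste(sprintf("%.3f", object@supports), collapse = ", "),
      "\n")
})
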
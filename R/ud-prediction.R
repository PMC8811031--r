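# Admission-feature assembly, information-gain feature selection, and
# multi-class unifying-diagnosis prediction under stratified Z-fold
# cross-validation.

#' Multi-class prediction report
#'
#' @slot metrics data.frame, one row per classifier: accuracy, weighted
#'   precision/recall/F1, weighted one-vs-rest AUC, mean CV error.
#' @slot foldErrors numeric matrix of per-fold misclassification rates
#'   (classifier x fold).
#' @slot confusion list of pooled confusion matrices per classifier.
#' @slot selected list of per-fold selected feature name vectors.
#' @slot importance data.frame of random-forest feature importances (or
#'   zero rows when the forest was not among the classifiers).
#' @slot Z integer number of folds.
#' @export
setClass("PredictionReport",
  representation(metrics = "data.frame", foldErrors = "matrix",
                 confusion = "list", selected = "list",
                 importance = "data.frame", Z = "integer"))

setValidity("PredictionReport", function(object) {
  m <- object@metrics
  cols <- c("accuracy", "precision", "recall", "f1", "auc", "cv_error")
  if (!all(cols %in% names(m))) return("metrics columns missing")
  vals <- unlist(m[cols])
  if (any(vals < -1e-9 | vals > 1 + 1e-9, na.rm = TRUE))
    return("metrics must lie in [0, 1]")
  TRUE
})

#' Five-tuple summary of a laboratory time series
#'
#' Summarises the repeated measurements of one laboratory indicator
#' during a stay as (min, max, median, mean, variance).  Timestamps
#' beyond the ordering are irrelevant to these statistics.  Variance is
#' the population variance (divide by n), as a descriptive summary of the
#' observed series; a single observation has variance 0.
#'
#' @param values numeric vector of observations; an empty series returns
#'   all-`NA` (to be handled by the imputation policy downstream).
#' @return named numeric vector `min`, `max`, `median`, `mean`, `var`.
#' @examples
#' labFiveTuple(c(1, 2, 3))  # variance 2/3
#' @export
labFiveTuple <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    return(c(min = NA_real_, max = NA_real_, median = NA_real_,
             mean = NA_real_, var = NA_real_))
  c(min = min(values), max = max(values), median = stats::median(values),
    mean = mean(values),
    var = mean((values - mean(values))^2))
}

#' Default symptom dictionary
#'
#' Term and abbreviation lists for the sixteen admission-note symptom
#' flags (fever, abdominal pain, shortness of breath, ...).  Multi-word
#' terms are matched as token sequences.
#'
#' @return named list: symptom -> character vector of terms.
#' @export
symptomDictionary <- function() {
  list(
    fever = c("fever", "febrile", "pyrexia"),
    abdominal_pain = c("abdominal pain", "abd pain", "stomach ache",
                       "epigastric pain"),
    shortness_of_breath = c("shortness of breath", "sob", "dyspnea",
                            "short of breath"),
    nausea_vomiting = c("nausea", "vomiting", "emesis", "n v"),
    weakness = c("weakness", "weak"),
    diarrhea = c("diarrhea", "diarrhoea", "loose stools"),
    dizziness = c("dizziness", "dizzy", "lightheaded", "vertigo"),
    palpitation = c("palpitation", "palpitations"),
    cough = c("cough", "coughing"),
    fatigue = c("fatigue", "tired", "malaise", "lethargy"),
    discomfort = c("discomfort"),
    dysuria = c("dysuria", "painful urination"),
    shock = c("shock", "hypotensive"),
    weight_change = c("weight loss", "weight gain", "weight change"),
    loss_of_appetite = c("loss of appetite", "anorexia", "poor appetite",
                         "decreased appetite"),
    night_sweating = c("night sweats", "night sweating", "nocturnal sweating")
  )
}

.NEGATIONS <- c("no", "not", "denies", "denied", "deny", "without", "non",
                "negative", "neg", "afebrile")

#' Extract symptom flags from a clinical text snippet
#'
#' Simplified dictionary matcher over chief-complaint /
#' history-of-present-illness text: a flag is set when any dictionary
#' term (case-insensitive, after tokenization) matches and no negation
#' token occurs within a fixed window before the match.  This is a
#' deliberately lightweight surrogate for a full clinical NLP pipeline.
#'
#' @param text character vector of snippets (empty strings give all-zero
#'   flags).
#' @param dictionary named list of term vectors; defaults to
#'   [symptomDictionary()].
#' @param negations character vector of negation tokens.
#' @param window number of preceding tokens scanned for a negation.
#' @return integer 0/1 matrix, one row per snippet, one column per
#'   symptom.
#' @examples
#' extractSymptoms("denies fever, reports cough")
#' @export
extractSymptoms <- function(text, dictionary = symptomDictionary(),
                            negations = .NEGATIONS, window = 3L) {
  stopifnot(is.character(text), is.list(dictionary))
  flags <- matrix(0L, nrow = length(text), ncol = length(dictionary),
                  dimnames = list(NULL, names(dictionary)))
  termTokens <- lapply(dictionary, function(terms)
    lapply(terms, function(tm) strsplit(tolower(tm), "[^a-z0-9]+")[[1L]]))
  for (r in seq_along(text)) {
    # negation scope ends at punctuation or an adversative conjunction
    clauses <- strsplit(tolower(text[r]),
                        "[,;.!?]|\\b(but|however|except)\\b")[[1L]]
    for (clause in clauses) {
      tok <- strsplit(clause, "[^a-z0-9]+")[[1L]]
      tok <- tok[nzchar(tok)]
      if (!length(tok)) next
      for (sy in seq_along(termTokens)) {
        if (flags[r, sy] == 1L) next
        hit <- FALSE
        for (tt in termTokens[[sy]]) {
          L <- length(tt)
          if (L > length(tok)) next
          starts <- which(tok == tt[1L])
          for (st in starts) {
            if (st + L - 1L > length(tok)) next
            if (!all(tok[st:(st + L - 1L)] == tt)) next
            pre <- if (st == 1L) character() else
              tok[max(1L, st - window):(st - 1L)]
            if (!any(pre %in% negations)) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) flags[r, sy] <- 1L
      }
    }
  }
  flags
}

# one-hot encode factors/characters with > 2 levels, binary -> single 0/1,
# numerics pass through; prefix all names
.encodeBlock <- function(block, prefix) {
  stopifnot(is.data.frame(block))
  cols <- lapply(names(block), function(nm) {
    x <- block[[nm]]
    if (is.numeric(x)) {
      out <- data.frame(x)
      names(out) <- nm
      return(out)
    }
    x <- factor(x)
    if (nlevels(x) <= 2L) {
      out <- data.frame(as.integer(x == levels(x)[nlevels(x)]))
      names(out) <- nm
      return(out)
    }
    out <- as.data.frame(lapply(levels(x), function(lv) as.integer(x == lv)))
    names(out) <- paste0(nm, "_", gsub("[^A-Za-z0-9]+", "_", levels(x)))
    out
  })
  out <- do.call(cbind, cols)
  names(out) <- paste0(prefix, names(out))
  rownames(out) <- rownames(block)
  out
}

#' Fuse admission feature blocks into one table
#'
#' Column-binds the demographic, symptom, laboratory five-tuple and
#' severity blocks after encoding: categorical columns with more than two
#' levels are one-hot encoded, binary columns become single 0/1 columns,
#' and numeric columns are min-max normalised to [0, 1].  Blocks are
#' matched by rownames (patient ids); an id mismatch is rejected with the
#' orphan ids listed.
#'
#' @param de,sy,le,sev data.frames with patient ids as rownames.
#' @param normalize logical; min-max normalise numeric columns.
#' @return data.frame with `de_`/`sy_`/`le_`/`sev_` prefixed columns and
#'   patient ids as rownames.
#' @export
fuseFeatures <- function(de, sy, le, sev, normalize = TRUE) {
  blocks <- list(de = de, sy = as.data.frame(sy), le = le, sev = sev)
  ids <- rownames(blocks$de)
  for (nm in names(blocks)) {
    other <- rownames(blocks[[nm]])
    orphans <- c(setdiff(ids, other), setdiff(other, ids))
    if (length(orphans))
      stop("patient id mismatch between feature blocks: ",
           paste(utils::head(orphans, 10L), collapse = ", "), call. = FALSE)
    blocks[[nm]] <- blocks[[nm]][ids, , drop = FALSE]
  }
  enc <- mapply(.encodeBlock, blocks, paste0(names(blocks), "_"),
                SIMPLIFY = FALSE)
  out <- do.call(cbind, unname(enc))
  if (normalize) {
    for (nm in names(out)) {
      x <- out[[nm]]
      rng <- range(x, na.rm = TRUE)
      if (is.finite(rng[1L]) && rng[2L] > rng[1L])
        out[[nm]] <- (x - rng[1L]) / (rng[2L] - rng[1L])
      else out[[nm]] <- ifelse(is.na(x), NA_real_, 0)
    }
  }
  rownames(out) <- ids
  out
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.discretize <- function(x, bins) {
  if (!is.numeric(x)) return(factor(x))
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               na.rm = TRUE, type = 7))
  if (length(br) < 2L) return(factor(x))
  cut(x, breaks = br, include.lowest = TRUE, right = TRUE)
}

#' Information gain of a feature for class labels
#'
#' Entropy reduction of the label distribution given the feature, in
#' bits.  Numeric features are discretised to equal-frequency bins first.
#' Missing feature values form their own category.
#'
#' @param x feature vector (numeric or categorical).
#' @param y class labels (>= 2 distinct classes; constant labels give 0
#'   by convention).
#' @param bins number of equal-frequency bins for numeric features.
#' @return non-negative numeric IG value.
#' @examples
#' informationGain(c(0, 0, 1, 1), c("a", "a", "b", "b"))  # 1 bit
#' @export
informationGain <- function(x, y, bins = 10L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) return(0)
  xb <- .discretize(x, bins)
  xb <- addNA(xb, ifany = TRUE)
  hy <- .entropy(as.numeric(table(y)) / length(y))
  tab <- table(xb, y)
  px <- rowSums(tab) / sum(tab)
  hcond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (px[i] == 0) return(0)
    px[i] * .entropy(tab[i, ] / sum(tab[i, ]))
  }, numeric(1)))
  max(hy - hcond, 0)
}

#' Information-gain feature selection
#'
#' Keeps the features whose information gain for the labels strictly
#' exceeds `delta2` (default 0.005).  Inside cross-validation this is
#' recomputed on each training fold only.
#'
#' @param x data.frame of features.
#' @param y class labels.
#' @param delta2 non-negative IG threshold.
#' @param bins discretisation bins for numeric features.
#' @return list with `data` (the reduced feature data.frame) and `ig`
#'   (named IG values for all input features).
#' @export
selectFeatures <- function(x, y, delta2 = 0.005, bins = 10L) {
  stopifnot(is.data.frame(x), delta2 >= 0)
  ig <- vapply(x, informationGain, numeric(1), y = y, bins = bins)
  keep <- names(ig)[ig > delta2]
  if (!length(keep))
    stop("no feature exceeds the information-gain threshold delta2 = ",
         delta2, "; lower delta2", call. = FALSE)
  list(data = x[, keep, drop = FALSE], ig = ig)
}

# seeded random oversampling of minority classes to the majority count
.oversample <- function(idx, y) {
  counts <- table(y[idx])
  target <- max(counts)
  unlist(lapply(names(counts), function(cl) {
    rows <- idx[y[idx] == cl]
    if (length(rows) == target) rows
    else c(rows, sample(rows, target - length(rows), replace = TRUE))
  }), use.names = FALSE)
}

.fitPredict <- function(classifier, xtr, ytr, xte, seed) {
  lev <- levels(ytr)
  set.seed(seed)
  prob <- switch(classifier,
    logistic = {
      fit <- nnet::multinom(y ~ ., data = cbind(xtr, y = ytr), trace = FALSE,
                            MaxNWts = 100000)
      p <- stats::predict(fit, newdata = xte, type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p, deparse.level = 0)
      if (ncol(p) == length(lev)) colnames(p) <- if (is.null(colnames(p)))
        lev else colnames(p)
      p
    },
    tree = {
      fit <- rpart::rpart(y ~ ., data = cbind(xtr, y = ytr),
                          method = "class")
      stats::predict(fit, newdata = xte, type = "prob")
    },
    forest = {
      fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = 200)
      stats::predict(fit, newdata = xte, type = "prob")
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(xtr), y = ytr, probability = TRUE)
      pr <- stats::predict(fit, as.matrix(xte), probability = TRUE)
      attr(pr, "probabilities")[, , drop = FALSE]
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(xtr),
                                  label = as.integer(ytr) - 1L)
      fit <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                              num_class = length(lev),
                                              max_depth = 4,
                                              eta = 0.3,
                                              nthread = 1),
                                data = dtr, nrounds = 40, verbose = 0)
      p <- stats::predict(fit, as.matrix(xte))
      if (is.null(dim(p)))
        p <- matrix(p, ncol = length(lev), byrow = TRUE)
      dimnames(p) <- list(NULL, lev)
      p
    },
    stop("unknown classifier: ", classifier))
  prob <- prob[, lev, drop = FALSE]
  prob / pmax(rowSums(prob), .Machine$double.eps)
}

# weighted one-vs-rest AUC; weights are class supports in y
.weightedAUC <- function(y, prob) {
  lev <- levels(y)
  w <- as.numeric(table(y)[lev]) / length(y)
  aucs <- vapply(lev, function(cl) {
    resp <- as.integer(y == cl)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  sum(w * aucs, na.rm = TRUE) / sum(w[!is.na(aucs)])
}

.weightedPRF <- function(conf) {
  lev <- rownames(conf)
  support <- rowSums(conf)
  w <- support / sum(support)
  pre <- vapply(lev, function(cl) {
    denom <- sum(conf[, cl])
    if (denom == 0) 0 else conf[cl, cl] / denom
  }, numeric(1))
  rec <- vapply(lev, function(cl) {
    denom <- sum(conf[cl, ])
    if (denom == 0) 0 else conf[cl, cl] / denom
  }, numeric(1))
  f1 <- ifelse(pre + rec == 0, 0, 2 * pre * rec / (pre + rec))
  c(precision = sum(w * pre), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Train and evaluate unifying-diagnosis classifiers
#'
#' Stratified Z-fold cross-validation of multi-class classifiers over an
#' admission feature table.  Within every training fold only: missing
#' numeric values are imputed by the training-fold median (with a
#' missingness indicator column added), features are selected by
#' information gain, and minority classes are randomly oversampled to the
#' majority count.  The held-out fold never influences selection or
#' oversampling.
#'
#' Reported metrics: accuracy, support-weighted precision/recall/F1
#' (weighted recall equals accuracy by construction), support-weighted
#' one-vs-rest AUC, and the mean CV error (per-fold 0/1 mismatch rate,
#' since unifying-diagnosis labels are nominal).
#'
#' @param x data.frame of fused features (see [fuseFeatures()]).
#' @param y class labels (cluster / unifying-diagnosis index per
#'   patient); every class must have at least `Z` members.
#' @param classifiers subset of `"logistic"`, `"tree"`, `"forest"`,
#'   `"svm"`, `"xgboost"`.
#' @param Z number of folds (5 or 10; default 10).
#' @param seed integer seed controlling folds, oversampling and model
#'   fits.
#' @param delta2 information-gain threshold for in-fold selection; set to
#'   a negative value to disable selection.
#' @param oversample logical; oversample minority classes in training
#'   folds.
#' @return a [PredictionReport-class] object.
#' @export
trainAndEvaluate <- function(x, y,
                             classifiers = c("logistic", "tree", "forest",
                                             "svm", "xgboost"),
                             Z = 10L, seed = 1L, delta2 = 0.005,
                             oversample = TRUE) {
  stopifnot(is.data.frame(x))
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  y <- droplevels(factor(y))
  Z <- as.integer(Z)
  if (!Z %in% c(5L, 10L)) stop("Z must be 5 or 10", call. = FALSE)
  if (any(table(y) < Z))
    stop("every class needs at least Z = ", Z,
         " members; use a smaller Z", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    rows <- sample(which(y == cl))
    folds[rows] <- rep_len(seq_len(Z), length(rows))
  }
  lev <- levels(y)
  prob <- lapply(classifiers, function(cf)
    matrix(NA_real_, length(y), length(lev), dimnames = list(NULL, lev)))
  names(prob) <- classifiers
  foldErr <- matrix(NA_real_, length(classifiers), Z,
                    dimnames = list(classifiers, NULL))
  selected <- vector("list", Z)
  for (z in seq_len(Z)) {
    te <- which(folds == z); tr <- which(folds != z)
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    # training-fold median imputation + missingness indicators
    for (nm in names(x)) {
      if (anyNA(x[[nm]])) {
        med <- stats::median(xtr[[nm]], na.rm = TRUE)
        if (is.na(med)) med <- 0
        ind <- paste0(nm, "_missing")
        xtr[[ind]] <- as.integer(is.na(xtr[[nm]]))
        xte[[ind]] <- as.integer(is.na(xte[[nm]]))
        xtr[[nm]][is.na(xtr[[nm]])] <- med
        xte[[nm]][is.na(xte[[nm]])] <- med
      }
    }
    if (delta2 >= 0) {
      sel <- selectFeatures(xtr, y[tr], delta2)
      keep <- names(sel$data)
    } else keep <- names(xtr)
    selected[[z]] <- keep
    xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
    rows <- if (oversample) .oversample(seq_len(nrow(xtr)), y[tr]) else
      seq_len(nrow(xtr))
    for (cf in classifiers) {
      p <- .fitPredict(cf, xtr[rows, , drop = FALSE], y[tr][rows], xte,
                       seed + z)
      prob[[cf]][te, ] <- p
      pred <- lev[max.col(p, ties.method = "first")]
      foldErr[cf, z] <- mean(pred != as.character(y[te]))
    }
  }
  confusion <- list()
  metrics <- do.call(rbind, lapply(classifiers, function(cf) {
    pred <- factor(lev[max.col(prob[[cf]], ties.method = "first")],
                   levels = lev)
    conf <- table(truth = y, predicted = pred)
    confusion[[cf]] <<- conf
    prf <- .weightedPRF(conf)
    data.frame(classifier = cf,
               accuracy = mean(pred == y),
               precision = prf["precision"], recall = prf["recall"],
               f1 = prf["f1"],
               auc = .weightedAUC(y, prob[[cf]]),
               cv_error = mean(foldErr[cf, ]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  importance <- data.frame(feature = character(), importance = numeric(),
                           stringsAsFactors = FALSE)
  if ("forest" %in% classifiers) {
    ximp <- x
    for (nm in names(ximp)) if (anyNA(ximp[[nm]])) {
      med <- stats::median(ximp[[nm]], na.rm = TRUE)
      ximp[[nm]][is.na(ximp[[nm]])] <- if (is.na(med)) 0 else med
    }
    importance <- featureImportance(ximp, y, seed = seed)
  }
  new("PredictionReport", metrics = metrics, foldErrors = foldErr,
      confusion = confusion, selected = selected, importance = importance,
      Z = Z)
}

#' Random-forest feature importance ranking
#'
#' Impurity-based (mean decrease in Gini) importances from a random
#' forest fit, normalised to sum to 1 and sorted descending.
#'
#' @param x data.frame of features (no missing values).
#' @param y class labels.
#' @param seed integer seed for the forest.
#' @param ntree number of trees.
#' @return data.frame with columns `feature`, `importance`.
#' @export
featureImportance <- function(x, y, seed = 1L, ntree = 500L) {
  stopifnot(is.data.frame(x))
  y <- droplevels(factor(y))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prediction report metrics
#'
#' @param x a [PredictionReport-class] object.
#' @return data.frame of per-classifier metrics.
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "PredictionReport"))
  x@metrics
}

#' @rdname reportMetrics
#' @export
reportConfusion <- function(x) {
  stopifnot(is(x, "PredictionReport"))
  x@confusion
}

#' @rdname reportMetrics
#' @export
reportImportance <- function(x) {
  stopifnot(is(x, "PredictionReport"))
  x@importance
}

setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport (", object@Z, "-fold stratified CV)\n", sep = "")
  print(object@metrics, row.names = FALSE, digits = 3)
})
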
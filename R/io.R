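# Readers and writers for the pipeline's CSV/JSON dialects, and the
# end-to-end run orchestration.

#' Read a diagnoses CSV
#'
#' Long-format reader for (patient id, diagnosis order, ICD-9 code) rows
#' in the usual critical-care export dialect (dotless codes accepted).
#' Unparseable codes are reported with their line numbers; patients left
#' with zero valid codes are dropped with a warning.
#'
#' @param path CSV file path.
#' @param id,order,code column names.
#' @return a [DiagnosisRecords-class] object.
#' @export
readDiagnoses <- function(path, id = "patient_id", order = "order",
                          code = "code") {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  miss <- setdiff(c(id, order, code), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- vapply(df[[code]], function(cd)
    !inherits(try(.canonOne(cd), silent = TRUE), "try-error"), logical(1))
  if (any(!ok)) {
    bad <- which(!ok)
    warning("dropping ", length(bad), " row(s) with unparseable codes (lines ",
            paste(utils::head(bad + 1L, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "", ")", call. = FALSE)
    dropped <- setdiff(unique(df[[id]]), unique(df[[id]][ok]))
    if (length(dropped))
      warning("patient(s) with zero valid codes dropped: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  df[[order]] <- as.integer(df[[order]])
  DiagnosisRecords(df, id = id, order = order, code = code)
}

#' Write diagnoses to CSV
#'
#' Emits the same long-format dialect [readDiagnoses()] consumes.
#'
#' @param records a [DiagnosisRecords-class] object.
#' @param path output CSV path.
#' @export
writeDiagnoses <- function(records, path) {
  stopifnot(is(records, "DiagnosisRecords"))
  utils::write.csv(records@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a patient similarity matrix CSV
#'
#' Square CSV with patient ids as header row and first column; values at
#' full precision.
#'
#' @param S a [PatientSimilarity-class] object.
#' @param path CSV path.
#' @export
writeSimilarity <- function(S, path) {
  stopifnot(is(S, "PatientSimilarity"))
  df <- data.frame(patient_id = patientIDs(S),
                   format(simValues(S), digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSimilarity
#' @export
readSimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  v <- matrix(as.numeric(v), nrow(v), ncol(v), dimnames = list(ids, ids))
  v <- (v + t(v)) / 2  # absorb decimal round-trip asymmetry
  new("PatientSimilarity", ids = ids, values = v)
}

#' Write cluster assignments
#'
#' CSV of (patient id, cluster index, is_exemplar), plus a metadata JSON
#' next to it with the preference, K, SS, supports and convergence flag.
#'
#' @param result an [APClustering-class] object.
#' @param path output CSV path; metadata goes to `<path>.meta.json`.
#' @param params optional named list of resolved parameters embedded in
#'   the metadata.
#' @export
writeClusters <- function(result, path, params = list()) {
  stopifnot(is(result, "APClustering"))
  df <- data.frame(patient_id = names(result@labels),
                   cluster = as.integer(result@labels),
                   is_exemplar = names(result@labels) %in% result@exemplars)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(p = result@preference, K = result@K, SS = result@SS,
                 supports = result@supports, converged = result@converged,
                 iterations = result@iterations), params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write TDCCoP and UD reports as JSON
#'
#' @param tdccops list of [TDCCoP-class] objects.
#' @param path output JSON path.
#' @param dictionary optional data.frame (code, short_title) used to
#'   label codes.
#' @param params optional resolved parameter list embedded in the report.
#' @export
writeTDCCoP <- function(tdccops, path, dictionary = NULL, params = list()) {
  payload <- lapply(tdccops, function(t) {
    e <- tdccopEntries(t)
    if (!is.null(dictionary))
      e$short_title <- dictionary$short_title[match(e$code, dictionary$code)]
    list(cluster = t@cluster, delta1 = t@delta1, entries = e)
  })
  jsonlite::write_json(list(params = params, tdccop = payload), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeTDCCoP
#' @param uds list of [UDResult-class] objects.
#' @param ccoms list of matching [CCoM-class] objects.
#' @export
writeUD <- function(uds, ccoms, path, params = list()) {
  payload <- lapply(seq_along(uds), function(i) {
    u <- uds[[i]]
    list(cluster = u@cluster,
         lcop = lapply(seq_len(nrow(u@lcop)), function(r)
           list(node = u@lcop$node[r], order = u@lcop$order[r],
                members = u@members[[r]])),
         ccom = ccomValues(ccoms[[i]]),
         direction = ccoms[[i]]@direction,
         primaries = u@primaries, complications = u@complications,
         rho = u@rho, dominance = u@dominance)
  })
  jsonlite::write_json(list(params = params, ud = payload), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

#' Write admission features (with labels) to CSV
#'
#' Block-tagged dialect: columns are prefixed `de_`, `sy_`, `le_`,
#' `sev_`; the label column holds the cluster / unifying-diagnosis index.
#'
#' @param blocks list with `de`, `sy`, `le`, `sev` data.frames (patient
#'   ids as rownames), e.g. from [generateAdmissionFeatures()].
#' @param path output CSV path.
#' @param labels optional labels named by patient id.
#' @param label name of the label column.
#' @export
writeFeatures <- function(blocks, path, labels = NULL, label = "label") {
  pref <- mapply(function(b, p) {
    names(b) <- paste0(p, "_", names(b)); b
  }, blocks, names(blocks), SIMPLIFY = FALSE)
  out <- do.call(cbind, unname(pref))
  out <- cbind(patient_id = rownames(out), out)
  if (!is.null(labels)) out[[label]] <- unname(labels[rownames(out)])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @return `readFeatures`: list with `blocks` (de/sy/le/sev data.frames),
#'   `labels` (or NULL), `ids`.
#' @export
readFeatures <- function(path, label = "label") {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = TRUE)
  ids <- as.character(df$patient_id)
  labels <- if (label %in% names(df))
    stats::setNames(df[[label]], ids) else NULL
  blocks <- lapply(c(de = "de", sy = "sy", le = "le", sev = "sev"),
                   function(p) {
    cols <- grep(paste0("^", p, "_"), names(df), value = TRUE)
    b <- df[, cols, drop = FALSE]
    names(b) <- sub(paste0("^", p, "_"), "", cols)
    rownames(b) <- ids
    b
  })
  list(blocks = blocks, labels = labels, ids = ids)
}

#' Resolved pipeline configuration
#'
#' Collects every tunable parameter of an end-to-end run with the
#' standard defaults (preference coefficient 0.025, top-800 core zone,
#' delta1 = 0.3, delta2 = 0.005, rho = 1.5, Z = 10).
#'
#' @param diagnoses path to a diagnoses CSV (or NULL when records are
#'   passed to [runPipeline()] directly).
#' @param features optional path to a feature CSV; prediction is skipped
#'   without it.
#' @param outDir output directory for run artifacts.
#' @param pCoe,coreMode,coreN,tau,delta1,delta2,rho,Z,damping,seed,
#'   direction,cosineVariant,method pipeline parameters; see the
#'   stage functions.
#' @return named list of resolved parameters.
#' @export
pipelineConfig <- function(diagnoses = NULL, features = NULL,
                           outDir = tempfile("unidiag_run_"),
                           pCoe = 0.025, coreMode = "top-n", coreN = 800L,
                           tau = NULL, delta1 = 0.3, delta2 = 0.005,
                           rho = 1.5, Z = 10L, damping = 0.9, seed = 1L,
                           direction = "symmetric", cosineVariant = "sqrt",
                           method = "ontology") {
  list(diagnoses = diagnoses, features = features, outDir = outDir,
       pCoe = pCoe, coreMode = coreMode, coreN = coreN, tau = tau,
       delta1 = delta1, delta2 = delta2, rho = rho, Z = Z,
       damping = damping, seed = seed, direction = direction,
       cosineVariant = cosineVariant, method = method)
}

.logLine <- function(con, stage, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  writeLines(line, con)
  message(line)
}

#' Run the full identification and prediction pipeline
#'
#' Executes similarity -> clustering -> TDCCoP extraction -> UD
#' identification -> prediction, writing the similarity matrix CSV,
#' cluster CSV (+ metadata JSON), TDCCoP JSON, UD JSON and metrics JSON
#' into the configured output directory together with the resolved
#' configuration and a structured run log.  Prediction is skipped with a
#' notice when no feature table is given.
#'
#' @param config a [pipelineConfig()] list.
#' @param records optional [DiagnosisRecords-class], overriding
#'   `config$diagnoses`.
#' @param featureBlocks optional list of de/sy/le/sev blocks, overriding
#'   `config$features`.
#' @return invisibly, a list with the fitted stage objects and artifact
#'   paths.
#' @export
runPipeline <- function(config, records = NULL, featureBlocks = NULL) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run_log.txt")
  con <- file(logPath, open = "wt")
  on.exit(close(con), add = TRUE)
  params <- config[setdiff(names(config), c("diagnoses", "features",
                                            "outDir"))]
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- "read"
  out <- tryCatch({
    if (is.null(records)) records <- readDiagnoses(config$diagnoses)
    .logLine(con, stage, length(patientIDs(records)), " patients read")

    stage <- "similarity"
    ont <- buildOntology(unique(records@records$code))
    t0 <- proc.time()[3L]
    S <- similarityMatrix(records, ont, method = config$method,
                          cosineVariant = config$cosineVariant)
    simPath <- file.path(config$outDir, "similarity.csv")
    writeSimilarity(S, simPath)
    .logLine(con, stage, "matrix ", nrow(simValues(S)), "x",
             ncol(simValues(S)), " in ",
             round(proc.time()[3L] - t0, 2), "s")

    stage <- "cluster"
    p <- apPreference(S, config$pCoe)
    clus <- apCluster(S, p, damping = config$damping, seed = config$seed)
    cluPath <- file.path(config$outDir, "clusters.csv")
    writeClusters(clus, cluPath, params = params)
    .logLine(con, stage, "K=", numClusters(clus), " converged=",
             clus@converged)

    stage <- "tdccop"
    cores <- lapply(seq_len(numClusters(clus)), function(k)
      suppressWarnings(
        if (config$coreMode == "top-n")
          coreZone(clus, S, k, mode = "top-n", n = config$coreN)
        else coreZone(clus, S, k, mode = "threshold", tau = config$tau)))
    tdccops <- lapply(cores, buildTDCCoP, records = records,
                      delta1 = config$delta1)
    tdcPath <- file.path(config$outDir, "tdccop.json")
    writeTDCCoP(tdccops, tdcPath, params = params)
    .logLine(con, stage, "typical codes per cluster: ",
             paste(vapply(tdccops, function(t) nrow(tdccopEntries(t)),
                          integer(1)), collapse = "/"))

    stage <- "identify"
    keep <- vapply(tdccops, function(t) nrow(tdccopEntries(t)) > 0L,
                   logical(1))
    uds <- list(); ccoms <- list()
    for (k in which(keep)) {
      lc <- groupLCoP(tdccops[[k]], ont)
      lc <- lcopOrder(lc, tdccops[[k]])
      cc <- conditionalCoOccurrence(lc, cores[[k]], records, ont,
                                    direction = config$direction)
      uds[[length(uds) + 1L]] <- identifyUD(lc, cc, rho = config$rho,
                                            cluster = k)
      ccoms[[length(ccoms) + 1L]] <- cc
    }
    udPath <- file.path(config$outDir, "ud.json")
    writeUD(uds, ccoms, udPath, params = params)
    .logLine(con, stage, length(uds), " cluster UD report(s)")

    stage <- "predict"
    report <- NULL
    if (is.null(featureBlocks) && !is.null(config$features))
      featureBlocks <- readFeatures(config$features)$blocks
    if (is.null(featureBlocks)) {
      .logLine(con, stage, "no feature table supplied; prediction skipped")
    } else {
      x <- fuseFeatures(featureBlocks$de, featureBlocks$sy,
                        featureBlocks$le, featureBlocks$sev)
      y <- clusterLabels(clus)[rownames(x)]
      report <- trainAndEvaluate(x, y, Z = config$Z, seed = config$seed,
                                 delta2 = config$delta2)
      jsonlite::write_json(list(params = params,
                                metrics = reportMetrics(report)),
                           file.path(config$outDir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      .logLine(con, stage, "metrics written for ",
               nrow(reportMetrics(report)), " classifier(s)")
    }
    list(records = records, ontology = ont, similarity = S,
         clustering = clus, cores = cores, tdccops = tdccops, uds = uds,
         ccoms = ccoms, report = report, outDir = config$outDir)
  }, error = function(e) {
    .logLine(con, stage, "FAILED: ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}
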
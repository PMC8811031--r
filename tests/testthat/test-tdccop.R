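# small deterministic cluster for core-zone tests: exemplar-like patient
# plus progressively less similar members
coreFixture <- function() {
  rows <- list(
    E  = c("428.0", "427.31", "401.9"),
    M1 = c("428.0", "427.31", "401.9"),
    M2 = c("428.0", "427.31"),
    M3 = c("428.0", "584.9"),
    M4 = c("038.9", "584.9"))
  df <- do.call(rbind, lapply(names(rows), function(id)
    data.frame(patient_id = id, order = seq_along(rows[[id]]),
               code = rows[[id]], stringsAsFactors = FALSE)))
  rec <- DiagnosisRecords(df)
  ont <- buildOntology(unique(unlist(codeSets(rec))))
  S <- similarityMatrix(rec, ont)
  res <- apCluster(S, p = -10, seed = 1)  # one cluster
  list(rec = rec, ont = ont, S = S, res = res)
}

test_that("threshold mode spans whole cluster at 0 and exemplar at 1", {
  f <- coreFixture()
  expect_identical(numClusters(f$res), 1L)
  all_core <- coreZone(f$res, f$S, 1, mode = "threshold", tau = 0)
  expect_setequal(coreMembers(all_core), patientIDs(f$rec))
  tight <- coreZone(f$res, f$S, 1, mode = "threshold", tau = 1)
  ex <- exemplars(f$res)[1]
  # only patients identical to the exemplar survive tau = 1
  sets <- codeSets(f$rec)
  expect_true(all(vapply(coreMembers(tight), function(m)
    setequal(sets[[m]], sets[[ex]]), logical(1))))
  expect_true(ex %in% coreMembers(tight))
})

test_that("top-n mode clamps to the cluster size with a warning", {
  f <- coreFixture()
  expect_warning(core <- coreZone(f$res, f$S, 1, mode = "top-n", n = 800),
                 "clamping")
  expect_length(coreMembers(core), 5L)
  core2 <- coreZone(f$res, f$S, 1, mode = "top-n", n = 3)
  expect_length(coreMembers(core2), 3L)
  expect_identical(coreMembers(core2)[1], exemplars(f$res)[1])
})

test_that("occurrence probability counts patients, not repeats", {
  f <- coreFixture()
  core <- coreZone(f$res, f$S, 1, mode = "threshold", tau = 0)
  expect_equal(unname(codeProbability(core, f$rec, "428.0")), 4 / 5)
  expect_equal(unname(codeProbability(core, f$rec, "584.9")), 2 / 5)
  expect_equal(unname(codeProbability(core, f$rec, "999.9")), 0)
})

test_that("typical code threshold is strictly greater-than", {
  # 10 patients; codeX in 3 (prob .30, dropped), codeY in 4 (prob .40, kept)
  df <- do.call(rbind, lapply(1:10, function(i) {
    codes <- c("038.9",
               if (i <= 3) "584.9" else NULL,
               if (i <= 4) "428.0" else NULL)
    data.frame(patient_id = paste0("p", i), order = seq_along(codes),
               code = codes, stringsAsFactors = FALSE)
  }))
  rec <- DiagnosisRecords(df)
  ont <- buildOntology(unique(unlist(codeSets(rec))))
  S <- similarityMatrix(rec, ont)
  res <- apCluster(S, p = -50, seed = 1)
  core <- coreZone(res, S, 1, mode = "threshold", tau = 0)
  td <- typicalCodes(core, rec, delta1 = 0.3)
  expect_true("428.0" %in% td$code)
  expect_false("584.9" %in% td$code)
  td0 <- typicalCodes(core, rec, delta1 = 0)
  expect_setequal(td0$code, c("038.9", "584.9", "428.0"))
})

test_that("average order averages over containing patients only", {
  df <- data.frame(patient_id = c("a", "a", "b", "b", "c"),
                   order = c(1, 3, 2, 5, 1),
                   code = c("038.9", "428.0", "584.9", "428.0", "038.9"))
  rec <- DiagnosisRecords(df)
  ont <- buildOntology(unique(unlist(codeSets(rec))))
  S <- similarityMatrix(rec, ont)
  res <- apCluster(S, p = -50, seed = 1)
  core <- coreZone(res, S, 1, mode = "threshold", tau = 0)
  expect_equal(unname(averageOrder(core, rec, "428.0")), 4)   # (3+5)/2
  expect_equal(unname(averageOrder(core, rec, "584.9")), 2)   # b only
  expect_error(averageOrder(core, rec, "999.9"), "no core patient")
})

test_that("the sorting function reproduces the three-code worked example", {
  expect_identical(rankByAvgOrder(c(5.3, 7.8, 3.8)), c(2L, 3L, 1L))
  expect_identical(rankByAvgOrder(42), 1L)
  # ties resolved by higher probability, then code
  expect_identical(rankByAvgOrder(c(2, 2), probability = c(0.2, 0.9),
                                  code = c("b", "a")), c(2L, 1L))
  expect_identical(rankByAvgOrder(c(2, 2), probability = c(0.5, 0.5),
                                  code = c("b", "a")), c(2L, 1L))
})

test_that("printed cluster-pattern ranks are reproduced from average orders", {
  e <- table2Entries()
  ranks <- rankByAvgOrder(e$avg_order, e$probability, e$code)
  want <- c("518.81" = 3L, "038.9" = 2L, "785.52" = 8L, "584.9" = 1L,
            "427.31" = 11L, "995.92" = 10L, "428.0" = 5L, "486" = 6L,
            "599.0" = 4L, "401.9" = 7L, "276.2" = 9L, "250.0" = 12L)
  expect_identical(ranks, unname(want[e$code]))
})

test_that("TDCCoP construction agrees with a stable-sort oracle", {
  f <- coreFixture()
  core <- coreZone(f$res, f$S, 1, mode = "threshold", tau = 0)
  td <- buildTDCCoP(core, f$rec, delta1 = 0.3)
  e <- tdccopEntries(td)
  expect_identical(e$rank, seq_len(nrow(e)))
  oracle <- order(e$avg_order, -e$probability, e$code)
  expect_identical(e$code, e$code[oracle])  # already rank-sorted
  expect_true(all(e$probability > 0.3))
  # empty pattern with a warning when the bar is unattainable
  expect_warning(td0 <- buildTDCCoP(core, f$rec, delta1 = 0.99), "no typical")
  expect_identical(nrow(tdccopEntries(td0)), 0L)
})

test_that("probabilities and orders ignore core member ordering", {
  f <- coreFixture()
  core <- coreZone(f$res, f$S, 1, mode = "threshold", tau = 0)
  shuffled <- new("CoreZone", cluster = 1L, exemplar = core@exemplar,
                  members = rev(coreMembers(core)), mode = "threshold",
                  param = 0)
  expect_equal(codeProbability(core, f$rec, "428.0"),
               codeProbability(shuffled, f$rec, "428.0"))
  expect_equal(averageOrder(core, f$rec, "428.0"),
               averageOrder(shuffled, f$rec, "428.0"))
})

test_that("planted signatures give stable typical codes across core sizes", {
  cfg <- cohortConfig(nPatients = 90, seed = 21)
  gen <- generateDiagnoses(cfg)
  ont <- buildOntology(unique(unlist(codeSets(gen$records))))
  S <- similarityMatrix(gen$records, ont)
  res <- apCluster(S, p = apPreference(S, 0.025), seed = 1)
  expect_identical(numClusters(res), 3L)
  k <- clusterLabels(res)[[exemplars(res)[1]]]
  stab <- tdcStability(res, S, gen$records, k, coreSizes = c(15, 20, 25),
                       delta1 = 0.3)
  expect_true(all(stab$agreement))
  truth <- groundTruth(cfg)
  hit <- vapply(truth, function(g) setequal(g$tdcs, stab$sets[[1]]),
                logical(1))
  expect_identical(sum(hit), 1L)
})
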
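table2Ontology <- function() buildOntology(table2Entries()$code)

test_that("LCA grouping of the printed pattern yields the seven entries", {
  td <- table2TDCCoP()
  ont <- table2Ontology()
  lc <- groupLCoP(td, ont)
  expect_length(lc$node, 7L)
  expect_setequal(lc$node,
                  c(enDash("580", "629"), "038.9", enDash("460", "519"),
                    enDash("390", "459"), "785.52", enDash("240", "279"),
                    "995.92"))
  # partition: every typical code covered exactly once
  expect_setequal(unlist(lc$members), tdccopEntries(td)$code)
  expect_identical(anyDuplicated(unlist(lc$members)), 0L)
})

test_that("entry orders are the minimum member re-ranks", {
  td <- table2TDCCoP()
  lc <- lcopOrder(groupLCoP(td, table2Ontology()), td)
  want <- c("580–629" = 1L, "038.9" = 2L, "460–519" = 3L, "390–459" = 5L,
            "785.52" = 8L, "240–279" = 9L, "995.92" = 10L)
  expect_identical(setNames(lc$order, lc$node), want)
  expect_identical(lc$order, sort(lc$order))
})

test_that("grouping respects ontology structure in the small cases", {
  # all codes under one subcategory collapse to it
  e <- data.frame(code = c("550.12", "550.13"), probability = c(0.5, 0.6),
                  avg_order = c(1, 2), rank = 1:2)
  td <- new("TDCCoP", cluster = 1L, entries = e, delta1 = 0.3)
  lc <- groupLCoP(td, buildOntology(e$code))
  expect_identical(lc$node, "550.1")
  # pairwise different chapters stay themselves
  e2 <- data.frame(code = c("038.9", "428.0", "584.9"),
                   probability = 0.5, avg_order = 1:3, rank = 1:3)
  td2 <- new("TDCCoP", cluster = 1L, entries = e2, delta1 = 0.3)
  lc2 <- groupLCoP(td2, buildOntology(e2$code))
  expect_setequal(lc2$node, e2$code)
  expect_true(all(lengths(lc2$members) == 1L))
})

test_that("no LCoP node is the root and multi-member nodes are ancestors", {
  td <- table2TDCCoP()
  ont <- table2Ontology()
  lc <- groupLCoP(td, ont)
  expect_false("ROOT" %in% lc$node)
  for (i in seq_along(lc$node)) {
    if (length(lc$members[[i]]) > 1L) {
      for (m in lc$members[[i]])
        expect_true(lc$node[i] %in% icd9Ancestors(ont, m))
      expect_lt(codeLevel(ont, lc$node[i]),
                min(codeLevel(ont, lc$members[[i]])))
    } else {
      expect_identical(lc$node[i], lc$members[[i]])
    }
  }
})

# six hand-enumerated core patients over three LCoP entries:
# X = 584.9 (genitourinary), Y = 486 (respiratory), Z = 038.9
ccomFixture <- function() {
  rows <- list(
    p1 = c("584.9", "486"),          # X, Y
    p2 = c("584.9", "486", "038.9"), # X, Y, Z
    p3 = c("584.9"),                 # X
    p4 = c("486"),                   # Y
    p5 = c("038.9", "584.9"),        # Z, X
    p6 = c("584.9", "038.9"))        # X, Z
  df <- do.call(rbind, lapply(names(rows), function(id)
    data.frame(patient_id = id, order = seq_along(rows[[id]]),
               code = rows[[id]], stringsAsFactors = FALSE)))
  rec <- DiagnosisRecords(df)
  ont <- buildOntology(unique(unlist(codeSets(rec))))
  core <- new("CoreZone", cluster = 1L, exemplar = "p1",
              members = names(rows), mode = "threshold", param = 0)
  lc <- data.frame(node = c("584.9", "486", "038.9"), order = 1:3,
                   stringsAsFactors = FALSE)
  lc$members <- list("584.9", "486", "038.9")
  list(rec = rec, ont = ont, core = core, lc = lc)
}

test_that("CCoM matches hand-enumerated contingency counts", {
  f <- ccomFixture()
  cc <- conditionalCoOccurrence(f$lc, f$core, f$rec, f$ont)
  v <- ccomValues(cc)
  # marginals: X in 5/6, Y in 3/6, Z in 3/6
  expect_equal(unname(diag(v)), c(5 / 6, 3 / 6, 3 / 6))
  # co-occurrences: XY=2, XZ=3, YZ=1
  expect_equal(v["584.9", "486"], 2 / 5)
  expect_equal(v["486", "584.9"], 2 / 3)
  expect_equal(v["584.9", "038.9"], 3 / 5)
  expect_equal(v["038.9", "584.9"], 3 / 3)
  expect_equal(v["486", "038.9"], 1 / 3)
  expect_equal(v["038.9", "486"], 1 / 3)
})

test_that("order-directed counting respects diagnosis precedence", {
  f <- ccomFixture()
  cc <- conditionalCoOccurrence(f$lc, f$core, f$rec, f$ont,
                                direction = "order-directed")
  v <- ccomValues(cc)
  # among the 3 patients having X and Z, X precedes Z in p2 and p6
  expect_equal(v["584.9", "038.9"], 2 / 5)
  expect_equal(v["038.9", "584.9"], 1 / 3)
  expect_equal(unname(diag(v)), c(5 / 6, 3 / 6, 3 / 6))
})

test_that("range entries match patients through descendant codes", {
  f <- ccomFixture()
  lc <- data.frame(node = c(enDash("580", "629"), enDash("460", "519")),
                   order = 1:2, stringsAsFactors = FALSE)
  lc$members <- list("584.9", "486")
  cc <- conditionalCoOccurrence(lc, f$core, f$rec, f$ont)
  v <- ccomValues(cc)
  expect_equal(unname(diag(v)), c(5 / 6, 3 / 6))
  expect_equal(v[1, 2], 2 / 5)
})

test_that("empty entries produce a zero row with a warning", {
  f <- ccomFixture()
  lc <- data.frame(node = c("584.9", "599.1"), order = 1:2,
                   stringsAsFactors = FALSE)
  lc$members <- list("584.9", "599.1")
  ont <- buildOntology(c(unique(unlist(codeSets(f$rec))), "599.1"))
  expect_warning(cc <- conditionalCoOccurrence(lc, f$core, f$rec, ont),
                 "no core patient")
  expect_equal(unname(ccomValues(cc)[2, ]), c(0, 0))
})

test_that("dominated suffix entries become complications", {
  nodes <- c("a1", "a2", "a3", "b1", "b2")
  v <- matrix(0.5, 5, 5, dimnames = list(nodes, nodes))
  diag(v) <- c(0.9, 0.85, 0.8, 0.3, 0.25)  # prefix far more frequent
  v[1:3, 4:5] <- 0.9; v[4:5, 1:3] <- 0.2   # and conditionally dominant
  lc <- data.frame(node = nodes, order = 1:5, stringsAsFactors = FALSE)
  lc$members <- as.list(nodes)
  cc <- new("CCoM", nodes = nodes, members = lc$members, values = v,
            coreSize = 10L, direction = "symmetric")
  ud <- identifyUD(lc, cc, rho = 1.5)
  expect_identical(udPrimaries(ud), c("a1", "a2", "a3"))
  expect_identical(udComplications(ud), c("b1", "b2"))
  expect_identical(ud@splitIndex, 3L)
  expect_true(all(c("i_dominates_j", "j_dominates_i") %in%
                    names(ud@dominance)))
})

test_that("degenerate splits follow the tie rules", {
  # uniform CCoM: no dominance anywhere, smallest prefix wins
  nodes <- c("x", "y", "z")
  v <- matrix(0.4, 3, 3, dimnames = list(nodes, nodes))
  diag(v) <- 0.5
  lc <- data.frame(node = nodes, order = 1:3, stringsAsFactors = FALSE)
  lc$members <- as.list(nodes)
  cc <- new("CCoM", nodes = nodes, members = lc$members, values = v,
            coreSize = 10L, direction = "symmetric")
  ud <- identifyUD(lc, cc, rho = 1.5)
  expect_identical(udPrimaries(ud), "x")
  expect_identical(udComplications(ud), c("y", "z"))
  # single entry is its own unifying diagnosis
  lc1 <- data.frame(node = "x", order = 1L, stringsAsFactors = FALSE)
  lc1$members <- list("x")
  cc1 <- new("CCoM", nodes = "x", members = list("x"),
             values = matrix(0.8, 1, 1, dimnames = list("x", "x")),
             coreSize = 10L, direction = "symmetric")
  ud1 <- identifyUD(lc1, cc1)
  expect_identical(udPrimaries(ud1), "x")
  expect_length(udComplications(ud1), 0L)
})

test_that("raising rho never creates new dominance", {
  set.seed(8)
  nodes <- paste0("n", 1:4)
  v <- matrix(runif(16, 0.1, 0.9), 4, 4, dimnames = list(nodes, nodes))
  lc <- data.frame(node = nodes, order = 1:4, stringsAsFactors = FALSE)
  lc$members <- as.list(nodes)
  cc <- new("CCoM", nodes = nodes, members = lc$members,
            values = pmin(v, 1), coreSize = 10L, direction = "symmetric")
  d_low <- identifyUD(lc, cc, rho = 1.2)@dominance
  d_high <- identifyUD(lc, cc, rho = 2.5)@dominance
  expect_true(all(d_low$i_dominates_j | !d_high$i_dominates_j))
  expect_true(all(d_low$j_dominates_i | !d_high$j_dominates_i))
})
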
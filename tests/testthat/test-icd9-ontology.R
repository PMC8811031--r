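test_that("canonicalization bridges dotless and dotted dialects", {
  got <- icd9Canonicalize(c("0389", "38.9", "550.12", "541", "V5861",
                            "E9500", "V58.61"))
  expect_equal(got$canonical,
               c("038.9", "038.9", "550.12", "541", "V58.61", "E950.0",
                 "V58.61"))
  expect_equal(got$level, c(4L, 4L, 5L, 3L, 5L, 4L, 5L))
  expect_equal(got$kind[3], "extension")
  expect_equal(got$kind[4], "category")
})

test_that("malformed codes are rejected with the offending string", {
  expect_error(icd9Canonicalize("X123"), "X123")
  expect_error(icd9Canonicalize("550.123"), "550.123")
  expect_error(icd9Canonicalize("1234.5"), "1234.5")
  expect_error(icd9Canonicalize("E950.12"), "E950.12")
  expect_error(icd9Canonicalize(""), "empty")
})

test_that("range tokens resolve against the packaged tables", {
  got <- icd9Canonicalize(c("520-579", "030-041", "520–579"))
  expect_equal(got$kind, c("chapter", "section", "chapter"))
  expect_equal(got$level, c(1L, 2L, 1L))
  expect_error(icd9Canonicalize("123-456"), "range")
})

test_that("level depth runs 0 at root through 5 at extensions", {
  ont <- buildOntology(c("550.12", "038.9"))
  expect_identical(codeLevel(ont, "ROOT"), 0L)
  expect_identical(codeLevel(ont, "520-579"), 1L)
  expect_identical(codeLevel(ont, "544-553"), 2L)
  expect_identical(codeLevel(ont, "550"), 3L)
  expect_identical(codeLevel(ont, "550.1"), 4L)
  expect_identical(codeLevel(ont, "550.12"), 5L)
  expect_error(codeLevel(ont, "999.9"), "not in ontology")
})

test_that("information content equals level depth", {
  ont <- buildOntology(c("550.12", "541"))
  expect_identical(informationContent(ont, c("550.12", "541", "ROOT")),
                   c(5L, 3L, 0L))
})

test_that("LCA matches the printed worked examples", {
  ont <- buildOntology(c("550.12", "550.13", "541", "038.9", "428.0"))
  expect_identical(icd9LCA(ont, "550.12", "550.13"), "550.1")
  expect_identical(icd9LCA(ont, "541", "550.13"), enDash("520", "579"))
  expect_identical(icd9LCA(ont, "038.9", "428.0"), "ROOT")
})

test_that("LCA is symmetric and idempotent", {
  universe <- c("550.12", "550.13", "550.11", "541", "038.9", "038.0",
                "428.0", "427.31", "584.9", "V58.61", "E950.0")
  ont <- buildOntology(universe)
  for (a in universe[c(1, 4, 7, 10)]) for (b in universe[c(2, 5, 9, 11)]) {
    expect_identical(icd9LCA(ont, a, b), icd9LCA(ont, b, a))
  }
  expect_identical(icd9LCA(ont, universe, universe),
                   icd9Canonicalize(universe)$canonical)
})

test_that("LCA agrees with the parent-map brute-force oracle", {
  universe <- c("550.12", "550.13", "550.11", "550.9", "541", "543.9",
                "038.9", "038.0", "041.11", "428.0", "427.31", "401.9",
                "584.9", "599.0", "V58.61", "V10.3", "E950.0", "E878.8")
  ont <- buildOntology(universe)
  can <- icd9Canonicalize(universe)$canonical
  set.seed(11)
  idx <- cbind(sample(length(can), 400, replace = TRUE),
               sample(length(can), 400, replace = TRUE))
  got <- icd9LCA(ont, can[idx[, 1]], can[idx[, 2]])
  want <- vapply(seq_len(nrow(idx)), function(r)
    oracleLCA(ont, can[idx[r, 1]], can[idx[r, 2]]), character(1))
  expect_identical(got, want)
})

test_that("IC decreases by exactly one along any root path", {
  ont <- buildOntology(c("550.12", "V58.61", "E950.0", "038.9"))
  nd <- ontologyNodes(ont)
  for (leaf in c("550.12", "V58.61", "E950.0", "038.9")) {
    chain <- icd9Ancestors(ont, leaf)
    ics <- informationContent(ont, chain)
    expect_equal(diff(ics), rep(1L, length(chain) - 1L))
  }
})

test_that("ontology construction materialises the ancestor closure", {
  ont <- buildOntology(c("550.12", "550.13", "541"))
  nd <- ontologyNodes(ont)
  expect_setequal(nd$canonical,
                  c("ROOT", enDash("520", "579"), enDash("544", "553"),
                    enDash("540", "543"), "550", "550.1", "550.12",
                    "550.13", "541"))
  # every non-root parent chain terminates at root within 5 steps
  for (n in setdiff(nd$canonical, "ROOT")) {
    expect_lte(length(icd9Ancestors(ont, n)) - 1L, 5L)
  }
  expect_identical(ontologyNodes(buildOntology(character()))$canonical,
                   "ROOT")
  expect_identical(icd9Ancestors(buildOntology("0389"), "038.9"),
                   c("ROOT", enDash("001", "139"), enDash("030", "041"),
                     "038", "038.9"))
})

test_that("codes outside every chapter range are rejected", {
  expect_error(buildOntology("V92.0"), "V92")
})
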
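test_that("lab five-tuples follow the population-variance convention", {
  expect_equal(labFiveTuple(c(5, 5, 5)),
               c(min = 5, max = 5, median = 5, mean = 5, var = 0))
  expect_equal(labFiveTuple(c(1, 2, 3)),
               c(min = 1, max = 3, median = 2, mean = 2, var = 2 / 3))
  expect_equal(labFiveTuple(7.5),
               c(min = 7.5, max = 7.5, median = 7.5, mean = 7.5, var = 0))
  expect_true(all(is.na(labFiveTuple(numeric()))))
  tup <- labFiveTuple(rnorm(20))
  expect_lte(tup["min"], tup["median"]); expect_lte(tup["median"], tup["max"])
  expect_lte(tup["min"], tup["mean"]);  expect_lte(tup["mean"], tup["max"])
  expect_gte(tup["var"], 0)
})

test_that("symptom extraction honours negation windows and abbreviations", {
  f <- extractSymptoms("denies fever, reports cough")
  expect_identical(unname(f[1, "fever"]), 0L)
  expect_identical(unname(f[1, "cough"]), 1L)
  f2 <- extractSymptoms("SOB on exertion")
  expect_identical(unname(f2[1, "shortness_of_breath"]), 1L)
  f3 <- extractSymptoms("")
  expect_true(all(f3 == 0L))
  f4 <- extractSymptoms(c("no nausea but night sweats",
                          "abd pain and weight loss"))
  expect_identical(unname(f4[1, "nausea_vomiting"]), 0L)
  expect_identical(unname(f4[1, "night_sweating"]), 1L)
  expect_identical(unname(f4[2, "abdominal_pain"]), 1L)
  expect_identical(unname(f4[2, "weight_change"]), 1L)
})

test_that("feature fusion keeps schema parity and normalises to [0, 1]", {
  ids <- paste0("p", 1:8)
  de <- data.frame(age = c(20, 30, 40, 50, 60, 70, 80, 89),
                   gender = c(0, 1, 0, 1, 0, 1, 0, 1),
                   adm = c(1, 2, 3, 1, 2, 3, 1, 2), row.names = ids)
  sy <- as.data.frame(matrix(rbinom(8 * 16, 1, 0.3), 8, 16,
                             dimnames = list(ids, paste0("s", 1:16))))
  le <- as.data.frame(matrix(rnorm(8 * 95), 8, 95,
                             dimnames = list(ids, paste0("l", 1:95))))
  sev <- as.data.frame(matrix(rpois(8 * 6, 5), 8, 6,
                              dimnames = list(ids, paste0("v", 1:6))))
  x <- fuseFeatures(de, sy, le, sev)
  expect_identical(ncol(x), 120L)  # 3 + 16 + 95 + 6, all numeric blocks
  expect_true(all(vapply(x, min, numeric(1)) >= 0))
  expect_true(all(vapply(x, max, numeric(1)) <= 1))
  expect_true(all(grepl("^(de|sy|le|sev)_", names(x))))
})

test_that("multi-level factors are one-hot encoded", {
  ids <- paste0("p", 1:6)
  de <- data.frame(adm = factor(c("emergency", "elective", "urgent",
                                  "emergency", "urgent", "elective")),
                   row.names = ids)
  blank <- data.frame(z = rep(0, 6), row.names = ids)
  x <- fuseFeatures(de, blank, blank, blank)
  admCols <- grep("^de_adm_", names(x), value = TRUE)
  expect_length(admCols, 3L)
  expect_true(all(rowSums(x[admCols]) == 1))
})

test_that("feature blocks with mismatched ids are rejected", {
  a <- data.frame(v = 1:3, row.names = c("p1", "p2", "p3"))
  b <- data.frame(v = 1:3, row.names = c("p1", "p2", "p9"))
  expect_error(fuseFeatures(a, b, a, a), "p9")
})

test_that("information gain matches direct entropy arithmetic", {
  # perfectly predictive binary feature on balanced binary labels
  expect_equal(informationGain(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1.0)
  # independent feature
  expect_equal(informationGain(c(0, 1, 0, 1), c("a", "a", "b", "b")), 0.0)
  # constant labels give zero by convention
  expect_equal(informationGain(c(1, 2, 3), c("a", "a", "a")), 0.0)
  # 3-class toy contingency, checked against the entropy oracle
  x <- rep(c("lo", "mid", "hi"), times = c(6, 6, 6))
  y <- c(rep("A", 4), rep("B", 2), rep("A", 1), rep("B", 4), rep("C", 1),
         rep("C", 5), rep("A", 1))
  expect_equal(informationGain(x, y), oracleIG(table(x, y)))
  # numeric feature: equal-frequency binning keeps IG non-negative
  set.seed(2)
  xn <- rnorm(100); yn <- sample(c("a", "b"), 100, TRUE)
  expect_gte(informationGain(xn, yn), 0)
  expect_lt(informationGain(xn, yn), 0.35)
})

test_that("selection keeps strictly-above-threshold features only", {
  set.seed(3)
  n <- 60
  y <- rep(c("a", "b", "c"), each = n / 3)
  x <- data.frame(strong = as.integer(factor(y)) + rnorm(n, sd = 0.1),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- selectFeatures(x, y, delta2 = 0.5)
  expect_identical(names(sel$data), "strong")
  expect_gt(sel$ig[["strong"]], sel$ig[["noise1"]])
  expect_error(selectFeatures(x, y, delta2 = 10), "lower delta2")
})

test_that("separable classes are predicted nearly perfectly", {
  set.seed(4)
  n <- 90
  y <- rep(c("a", "b", "c"), each = n / 3)
  mu <- c(a = -3, b = 0, c = 3)
  x <- data.frame(f1 = rnorm(n, mu[y], 0.3), f2 = rnorm(n, -mu[y], 0.3),
                  f3 = rnorm(n))
  rep_ <- trainAndEvaluate(x, y, classifiers = c("logistic", "forest",
                                                 "xgboost"),
                           Z = 5, seed = 1, delta2 = 0.005)
  m <- reportMetrics(rep_)
  expect_true(all(m$accuracy > 0.9))
  expect_true(all(m$cv_error < 0.1))
  expect_true(all(m$auc > 0.95))
})

test_that("weighted recall equals accuracy for every classifier", {
  set.seed(5)
  n <- 80
  y <- rep(c("a", "b"), times = c(50, 30))
  x <- data.frame(f1 = rnorm(n, as.integer(factor(y)), 1.2),
                  f2 = rnorm(n))
  rep_ <- trainAndEvaluate(x, y, classifiers = c("logistic", "tree", "svm"),
                           Z = 5, seed = 2)
  m <- reportMetrics(rep_)
  expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
})

test_that("metrics recompute from the exported confusion matrices", {
  set.seed(6)
  n <- 60
  y <- rep(c("a", "b", "c"), each = n / 3)
  x <- data.frame(f1 = rnorm(n, as.integer(factor(y)) * 2, 0.8),
                  f2 = rnorm(n))
  rep_ <- trainAndEvaluate(x, y, classifiers = "forest", Z = 5, seed = 3)
  conf <- reportConfusion(rep_)$forest
  expect_equal(sum(diag(conf)) / sum(conf),
               reportMetrics(rep_)$accuracy)
})

test_that("label-copy canary under permuted labels stays at chance", {
  set.seed(7)
  n <- 90
  y0 <- rep(c("a", "b", "c"), each = n / 3)
  y <- sample(y0)  # permuted target: no feature should predict it
  x <- data.frame(canary = as.integer(factor(y0)),  # original labels
                  n1 = rnorm(n), n2 = rnorm(n))
  rep_ <- trainAndEvaluate(x, y, classifiers = c("logistic", "forest"),
                           Z = 5, seed = 8, delta2 = -1)
  acc <- reportMetrics(rep_)$accuracy
  # chance for 3 balanced classes is 1/3; binomial band on n = 90
  expect_true(all(abs(acc - 1 / 3) < 0.2))
})

test_that("class sizes below Z are rejected", {
  y <- c(rep("a", 20), rep("b", 3))
  x <- data.frame(f = rnorm(23))
  expect_error(trainAndEvaluate(x, y, classifiers = "tree", Z = 5),
               "smaller Z")
  expect_error(trainAndEvaluate(x, y, classifiers = "tree", Z = 7),
               "5 or 10")
})

test_that("forest importance finds a planted feature and sums to one", {
  set.seed(9)
  n <- 80
  y <- rep(c("a", "b"), each = n / 2)
  x <- data.frame(planted = as.integer(factor(y)) + rnorm(n, sd = 0.1),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  imp <- featureImportance(x, y, seed = 1, ntree = 300)
  expect_identical(imp$feature[1], "planted")
  expect_equal(sum(imp$importance), 1.0)
})
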
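test_that("binarisation maps scores by the >= cutoff convention", {
  sc <- matrix(c(25, 15, 0.5, 0.3, -0.3, 0.2), nrow = 2,
               dimnames = list(c("K303N", "N373S"),
                               c("CADD", "REVEL", "Eigen")))
  pm <- binarizeCalls(PredictionMatrix(scores = sc))
  expect_equal(unname(calls(pm)["K303N", ]), c("P", "P", "N"))
  expect_equal(unname(calls(pm)["N373S", ]), c("N", "N", "P"))
  expect_true(all(toolType(pm) == "binary"))
  # strict override flips the boundary case only
  pm2 <- binarizeCalls(PredictionMatrix(scores = sc), strict = "REVEL")
  expect_equal(calls(pm2)["K303N", "REVEL"], "N")
  expect_equal(calls(pm2)["K303N", "CADD"], "P")
})

test_that("binarisation is idempotent, monotone, and keeps missing cells", {
  set.seed(42)
  for (rep in 1:5) {
    sc <- matrix(rnorm(30), nrow = 6,
                 dimnames = list(sprintf("A%dC", 1:6),
                                 c("Eigen", "REVEL", "CADD", "MVP",
                                   "SuSPect")))
    sc[sample(length(sc), 4)] <- NA
    pm <- PredictionMatrix(scores = sc)
    b1 <- binarizeCalls(pm)
    expect_identical(calls(binarizeCalls(b1)), calls(b1))
    expect_identical(is.na(calls(b1)), is.na(sc))
    # raising any score never flips P -> N
    sc2 <- sc + abs(rnorm(length(sc)))
    b2 <- binarizeCalls(PredictionMatrix(scores = sc2))
    flipped <- !is.na(sc) & calls(b1) == "P" & calls(b2) == "N"
    expect_false(any(flipped))
  }
})

test_that("a scored tool without a cutoff is a configuration error", {
  sc <- matrix(1, 1, 1, dimnames = list("A1C", "mystery_tool"))
  expect_error(binarizeCalls(PredictionMatrix(scores = sc)), "mystery_tool")
})

test_that("confusion counts partition the benchmark and report missing", {
  labels <- benchLabels27_3()
  # all 27 pathogenic called P, 1 of 3 benign called P
  pred <- callsFromCounts(list(TP = 27, FN = 0, TN = 2, FP = 1), labels)
  cc <- confusionCounts(pred, labels)
  expect_equal(cc[c("TP", "FN", "FP", "TN")],
               list(TP = 27, FN = 0, FP = 1, TN = 2))
  # perfect and all-Neutral classifiers
  perfect <- confusionCounts(
    callsFromCounts(list(TP = 27, FN = 0, TN = 3, FP = 0), labels), labels)
  expect_equal(perfect[c("TP", "TN", "FP", "FN")],
               list(TP = 27, TN = 3, FP = 0, FN = 0))
  allN <- confusionCounts(stats::setNames(rep("N", 30), names(labels)),
                          labels)
  expect_equal(allN[c("TP", "FN", "TN", "FP")],
               list(TP = 0, FN = 27, TN = 3, FP = 0))
  # missing predictions excluded, named; unlabeled variant errors
  pred2 <- pred; pred2[3] <- NA
  cc2 <- confusionCounts(pred2, labels)
  expect_equal(cc2$n_missing, 1)
  expect_equal(sum(unlist(cc2[c("TP", "TN", "FP", "FN")])), 29)
  expect_error(confusionCounts(c(Z9A = "P"), labels), "Z9A")
})

test_that("metrics follow their formulas and flag zero denominators", {
  m <- toolMetrics(list(TP = 27, FN = 0, FP = 1, TN = 2))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 27 / 28)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 29 / 30)
  m2 <- toolMetrics(list(TP = 24, FN = 3, FP = 1, TN = 2))
  expect_equal(roundHalfUp(c(m2$recall, m2$precision, m2$specificity,
                             m2$accuracy)), c(0.89, 0.96, 0.67, 0.87))
  # no positive calls at all -> precision undefined, not zero
  m3 <- toolMetrics(list(TP = 0, FN = 27, FP = 0, TN = 3))
  expect_true(is.na(m3$precision))
  expect_equal(m3$undefined, "precision")
  expect_error(toolMetrics(list(TP = -1, FN = 0, FP = 0, TN = 0)),
               "negative")
})

test_that("accuracy interpolates the class accuracies; FP=0 gives precision 1", {
  set.seed(11)
  for (i in 1:20) {
    cc <- list(TP = sample(0:27, 1), FN = 0, FP = sample(0:3, 1), TN = 0)
    cc$FN <- 27 - cc$TP; cc$TN <- 3 - cc$FP
    m <- toolMetrics(cc)
    expect_gte(m$accuracy, min(m$recall, m$specificity) - 1e-12)
    expect_lte(m$accuracy, max(m$recall, m$specificity) + 1e-12)
    if (cc$FP == 0 && cc$TP > 0) expect_equal(m$precision, 1)
  }
})

test_that("tool selection applies both thresholds inclusively", {
  perf <- data.frame(tool = c("a", "b", "c"),
                     recall = c(0.78, 0.77, 1.00),
                     specificity = c(0.67, 1.00, 0.66))
  expect_equal(selectTools(perf), "a")
  expect_equal(selectTools(perf, 0, 0), c("a", "b", "c"))
  perf$recall[1] <- NA
  expect_error(selectTools(perf), "a")
})

test_that("ConPath votes equal a brute-force per-column count", {
  set.seed(7)
  for (i in 1:10) {
    nv <- sample(3:12, 1); nt <- sample(3:21, 1)
    cl <- matrix(sample(c("P", "N"), nv * nt, replace = TRUE), nv, nt,
                 dimnames = list(sprintf("A%dV", seq_len(nv)),
                                 sprintf("t%d", seq_len(nt))))
    pm <- PredictionMatrix(calls = cl)
    cp <- conPath(pm)
    brute <- apply(cl, 1, function(x) sum(x == "P"))
    expect_equal(cp$votes, unname(brute))
    thr <- floor(nt / 2) + 1
    expect_equal(cp$call == "Pathogenic", unname(brute >= thr))
  }
})

test_that("ConPath default threshold scales with the panel and reports size", {
  cl <- matrix("P", 2, 5, dimnames = list(c("A1V", "A2V"), letters[1:5]))
  cp <- conPath(PredictionMatrix(calls = cl))
  expect_equal(cp$panel_size, c(5, 5))
  expect_equal(unique(cp$call), "Pathogenic")  # 5 >= floor(5/2)+1 = 3
  cp2 <- conPath(PredictionMatrix(calls = cl), pathogenicMin = 6)
  expect_equal(unique(cp2$call), "Neutral")
})

test_that("missing panel predictions error under the strict policy, warn under neutral", {
  cl <- matrix(c("P", NA, "P", "N"), 2, 2,
               dimnames = list(c("A1V", "A2V"), c("t1", "t2")))
  pm <- PredictionMatrix(calls = cl)
  expect_error(conPath(pm), "A2V/t1")
  expect_warning(cp <- conPath(pm, missingPolicy = "neutral"), "A2V/t1")
  expect_equal(cp$votes, c(2L, 0L))
})

test_that("tool name canonicalisation unifies published spellings", {
  expect_equal(canonicalToolName(c("Mut. Assesor", "Mut. Assessor",
                                   "MutationAssessor")),
               rep("MutationAssessor", 3))
  expect_equal(canonicalToolName("SusPect"), "SuSPect")
  expect_equal(canonicalToolName("never-heard-of-it"), "never-heard-of-it")
  expect_equal(canonicalToolName("x", extra = c(x = "y")), "y")
})

test_that("variant ids parse and invalid ones are rejected", {
  pv <- parseVariant(c("K303N", "T306I"))
  expect_equal(pv$pos, c(303L, 306L))
  expect_equal(pv$mut, c("N", "I"))
  expect_error(parseVariant("K303K"), "identical")
  expect_error(parseVariant("303KN"), "malformed")
})
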
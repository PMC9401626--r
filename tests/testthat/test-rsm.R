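test_that("buildTerms produces the canonical second-order basis", {
  t6 <- buildTerms(6)
  expect_length(t6, 28L)  # 1 + 6 + 6 + 15
  t2 <- buildTerms(c("A", "B"))
  expect_setequal(vapply(t2, termLabel, character(1)),
                  c("Intercept", "A", "B", "A^2", "B^2", "A*B"))
  expect_length(buildTerms(6, thirdOrder = list("X1^2*X2")), 29L)
  # duplicates collapse; degree > 3 rejected
  expect_length(buildTerms(c("A", "B"), thirdOrder = list("A*B")), 6L)
  expect_error(parseTermLabel("A^4", c("A", "B")), "degree 4")
})

test_that("term labels round-trip through the parser", {
  fn <- c("IL7", "IL3", "TNFa")
  for (lab in c("Intercept", "IL7", "IL7^2", "IL7*TNFa", "IL7^2*IL3")) {
    expect_equal(termLabel(parseTermLabel(lab, fn)), lab)
  }
  expect_error(parseTermLabel("IL7*GMCSF", fn), "unknown factor 'GMCSF'")
  expect_error(parseTermLabel("IL7^x", fn), "cannot parse term token")
})

test_that("noiseless synthetic data is interpolated exactly", {
  d <- integerDesign(3)
  tr <- responseSurfaceTruth(
    "proT", c(Intercept = 500, F1 = 20, F2 = -10, "F1^2" = -5,
              "F1*F2" = 3), transform = "identity", noiseSd = 0)
  tab <- genDoseResponse(list(tr), d, seed = 1)
  m <- fitResponse(d, tab, "proT", transform = "identity")
  est <- coef(m)
  expect_lt(abs(est[["Intercept"]] - 500), 1e-8)
  expect_lt(abs(est[["F1"]] - 20), 1e-8)
  expect_lt(abs(est[["F1^2"]] - (-5)), 1e-8)
  expect_lt(abs(est[["F1*F2"]] - 3), 1e-8)
  expect_lt(max(abs(est[setdiff(names(est),
                                c("Intercept", "F1", "F2", "F1^2", "F1*F2"))])),
            1e-8)
  expect_equal(fitStats(m)$r.squared, 1)
})

test_that("an all-zero response yields zero coefficients and undefined R2", {
  d <- twoFactorDesign()
  tab <- data.frame(run_id = rownames(codedMatrix(d)), response = "y",
                    count = 0L)
  m <- fitResponse(d, tab, "y", transform = "log1p")
  expect_equal(max(abs(coef(m))), 0)
  expect_true(is.na(fitStats(m)$r.squared))
})

test_that("OLS residuals are orthogonal to the model columns", {
  d <- sixFactorDesign()
  tr <- responseSurfaceTruth("y", c(Intercept = 6, F1 = 0.5, "F2^2" = -0.3),
                             transform = "log1p", noiseSd = 0.3)
  tab <- genDoseResponse(list(tr), d, seed = 7)
  m <- fitResponse(d, tab, "y", transform = "log1p")
  X <- designModelMatrix(d, modelTerms(m))
  y <- log1p(tab$count[match(rownames(codedMatrix(d)), tab$run_id)])
  res <- y - as.numeric(X %*% m@coefficients)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
})

test_that("coefficient estimates are unbiased under transformed-scale noise", {
  d <- twoFactorDesign(alpha = 2, nCenter = 4L)
  truth <- c(Intercept = 1000, F1 = 40, F2 = -25, "F1^2" = -15)
  noiseSd <- 10
  ests <- t(vapply(1:200, function(s) {
    tr <- responseSurfaceTruth("y", truth, "identity", noiseSd)
    tab <- genDoseResponse(list(tr), d, seed = s)
    coef(fitResponse(d, tab, "y", "identity"))[names(truth)]
  }, numeric(4)))
  X <- designModelMatrix(d)
  se <- noiseSd * sqrt(diag(solve(crossprod(X))))[names(truth)] / sqrt(200)
  expect_true(all(abs(colMeans(ests) - truth) < 3 * se + 0.05))
})

test_that("rank deficiency and missing runs are reported with names", {
  d <- twoFactorDesign()
  tr <- responseSurfaceTruth("y", c(Intercept = 100), "identity", 0)
  tab <- genDoseResponse(list(tr), d, seed = 1)
  dup <- buildTerms(c("F1", "F2"))
  dup <- c(dup, dup[2])  # duplicate the F1 column
  expect_error(fitResponse(d, tab, "y", "identity", terms = dup),
               "aliased terms: F1")
  expect_error(fitResponse(d, tab[-1, ], "y", "identity"),
               "missing counts.*run01")
})

test_that("prediction evaluates the polynomial and back-transforms", {
  m <- exactModel(c("F1", "F2"), c(Intercept = 2), transform = "log1p")
  p <- predictResponse(m, c(0.7, -1.2))
  expect_equal(p$transformed, 2)
  expect_equal(p$count, exp(2) - 1)
  m2 <- exactModel(c("F1", "F2"),
                   c(Intercept = 1.5, F1 = 2, "F2^2" = -0.4), "identity")
  expect_equal(predictResponse(m2, c(0, 0))$transformed, 1.5)
  # negative predictions clip to zero on the count scale
  expect_equal(predictResponse(m2, c(-2, 0))$count, 0)
  expect_gte(min(predictResponse(m2, codedMatrix(twoFactorDesign()))$count), 0)
})

test_that("coefficient tables round-trip losslessly through CSV", {
  d <- sixFactorDesign()
  tr <- responseSurfaceTruth("proT", c(Intercept = 5.3, F1 = 0.41,
                                       "F3*F5" = 0.07), "log1p", 0.2)
  tab <- genDoseResponse(list(tr), d, seed = 3)
  m <- fitResponse(d, tab, "proT")
  path <- withr::local_tempfile(fileext = ".csv")
  writeCoefCsv(list(m), path)
  m2 <- readCoefCsv(path, factorNames(d))[["proT"]]
  pts <- codedMatrix(d)
  expect_lt(max(abs(predictResponse(m2, pts)$transformed -
                    predictResponse(m, pts)$transformed)), 1e-10)
})

test_that("greedy third-order selection finds a true cubic and stops", {
  d <- integerDesign(3)
  base <- buildTerms(c("F1", "F2", "F3"))
  # pure cubics only: on this small design a mixed cubic like F1^2*F2 is
  # exactly aliased with {F2, F2^3} and would tie with the true term
  cand <- list("F1^3", "F2^3", "F3^3")
  # no cubic in truth: base terms unchanged
  tr0 <- responseSurfaceTruth("y", c(Intercept = 500, F1 = 10, "F2^2" = -4),
                              "identity", 0)
  tab0 <- genDoseResponse(list(tr0), d, seed = 1)
  sel0 <- selectThirdOrder(d, tab0, "y", "identity", base, cand)
  expect_equal(vapply(sel0, termLabel, character(1)),
               vapply(base, termLabel, character(1)))
  # exactly one strong cubic: that term (and only it) is selected
  tr1 <- responseSurfaceTruth("y", c(Intercept = 500, F1 = 10, "F2^3" = 8),
                              "identity", 0)
  tab1 <- genDoseResponse(list(tr1), d, seed = 1)
  sel1 <- selectThirdOrder(d, tab1, "y", "identity", base, cand)
  extra <- setdiff(vapply(sel1, termLabel, character(1)),
                   vapply(base, termLabel, character(1)))
  expect_equal(extra, "F2^3")
  # duplicated candidates collapse to one term; selection is deterministic
  sel2 <- selectThirdOrder(d, tab1, "y", "identity", base,
                           list("F2^3", "F2^3"))
  expect_equal(vapply(sel2, termLabel, character(1)),
               vapply(sel1, termLabel, character(1)))
})
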
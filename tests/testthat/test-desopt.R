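test_that("individual desirability ramps from L to U", {
  expect_equal(desirability(0, L = 0, U = 10), 0)
  expect_equal(desirability(10, L = 0, U = 10), 1)
  expect_equal(desirability(5, L = 0, U = 10), 0.5)
  expect_equal(desirability(-3, L = 0, U = 10), 0)   # below L
  expect_equal(desirability(40, L = 0, U = 10), 1)   # above U
  expect_equal(desirability(5, L = 0, U = 10, w = 2), 0.25)
  v <- sort(stats::runif(50, -5, 15))
  expect_true(all(diff(desirability(v, 0, 10, w = 1.7)) >= 0))
})

test_that("overall desirability is a geometric mean with zero annihilation", {
  expect_equal(overallDesirability(c(0.25, 1)), 0.5)
  expect_equal(overallDesirability(c(0.9, 0, 0.8)), 0)
  expect_equal(overallDesirability(c(0.7, 0.7, 0.7)), 0.7)  # idempotence
  expect_error(overallDesirability(numeric(0)), "at least one")
})

test_that("the search recovers an interior analytic optimum to 1e-3", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"),
                  c(Intercept = 10, F1 = 1, "F1^2" = -1, "F2^2" = -1))
  # unique maximizer of 10 + x1 - x1^2 - x2^2 at (0.5, 0), ||x*|| < radius
  opt <- optimizeDesirability(list(m), desirabilitySpec("y", L = 0, U = 11),
                              d, optimizationConfig(seed = 3L))
  expect_lt(max(abs(optimumCoded(opt) - c(0.5, 0))), 1e-3)
  expect_false(opt@degenerate)
  # concentration mapping of the averaged optimum
  expect_equal(optimumConc(opt)[["F1"]],
               codedToConc(factorSpec("F1", 1, 10), optimumCoded(opt)[["F1"]]))
})

test_that("a monotone response pushes the optimum to the sphere boundary", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"), c(Intercept = 10, F1 = 1))
  opt <- optimizeDesirability(list(m), desirabilitySpec("y", L = 0, U = 13),
                              d, optimizationConfig(seed = 4L))
  x <- optimumCoded(opt)
  expect_equal(sqrt(sum(x^2)), 2.366, tolerance = 1e-4)
  expect_equal(x[["F1"]], 2.366, tolerance = 1e-3)
})

test_that("every reported solution respects the hypersphere constraint", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"), c(Intercept = 5, F1 = 2, F2 = 1))
  opt <- optimizeDesirability(list(m), desirabilitySpec("y", L = 0, U = 20),
                              d, optimizationConfig(seed = 9L))
  X <- as.matrix(solutions(opt)[, c("F1", "F2")])
  expect_true(all(sqrt(rowSums(X^2)) <= 2.366 + 1e-6))
  expect_false(is.unsorted(rev(solutions(opt)$D)))
})

test_that("the result is invariant to spec order and duplicated responses", {
  d <- twoFactorDesign()
  m1 <- exactModel(c("F1", "F2"),
                   c(Intercept = 10, F1 = 1, "F1^2" = -1, "F2^2" = -1),
                   response = "y1")
  m2 <- exactModel(c("F1", "F2"),
                   c(Intercept = 8, F2 = 0.5, "F1^2" = -0.5),
                   response = "y2")
  s1 <- desirabilitySpec("y1", L = 0, U = 11)
  s2 <- desirabilitySpec("y2", L = 0, U = 9)
  a <- optimizeDesirability(list(m1, m2), rbind(s1, s2), d,
                            optimizationConfig(seed = 6L))
  b <- optimizeDesirability(list(m2, m1), rbind(s2, s1), d,
                            optimizationConfig(seed = 6L))
  expect_equal(optimumCoded(a), optimumCoded(b))
  expect_equal(solutions(a), solutions(b))
  # geometric-mean idempotence: duplicating a response changes nothing
  m1b <- exactModel(c("F1", "F2"),
                    c(Intercept = 10, F1 = 1, "F1^2" = -1, "F2^2" = -1),
                    response = "y1b")
  s1b <- desirabilitySpec("y1b", L = 0, U = 11)
  one <- optimizeDesirability(list(m1), s1, d, optimizationConfig(seed = 2L))
  two <- optimizeDesirability(list(m1, m1b), rbind(s1, s1b), d,
                              optimizationConfig(seed = 2L))
  expect_equal(optimumCoded(one), optimumCoded(two))
})

test_that("fixed seeds reproduce the search exactly", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"), c(Intercept = 10, F1 = 1, "F2^2" = -2))
  s <- desirabilitySpec("y", L = 0, U = 14)
  a <- optimizeDesirability(list(m), s, d, optimizationConfig(seed = 12L))
  b <- optimizeDesirability(list(m), s, d, optimizationConfig(seed = 12L))
  expect_identical(solutions(a), solutions(b))
  expect_identical(optimumConc(a), optimumConc(b))
})

test_that("an objective flat at zero is flagged as degenerate", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"), c(Intercept = 1))
  # anchors far above anything the model can reach: every d_i = 0
  opt <- optimizeDesirability(list(m),
                              desirabilitySpec("y", L = 100, U = 200), d,
                              optimizationConfig(seed = 1L))
  expect_true(opt@degenerate)
  expect_equal(solutions(opt)$D, rep(0, 25))
})

test_that("misaligned models and specs are rejected", {
  d <- twoFactorDesign()
  m <- exactModel(c("F1", "F2"), c(Intercept = 1), response = "y1")
  expect_error(
    optimizeDesirability(list(m), desirabilitySpec("other", 0, 1), d),
    "align by response name")
})
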
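test_that("formula parsing handles counts, implicit ones, and bad input", {
  expect_equal(parseFormula("C"), c(C = 1L))
  expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parseFormula("C11H26NO3Si2"),
               c(C = 11L, H = 26L, N = 1L, O = 3L, Si = 2L))
  expect_error(parseFormula("C6Px2"), "unsupported element|malformed")
  expect_error(parseFormula("c6h12"), "malformed")
})

test_that("element patterns match the abundance table and enumeration", {
  expect_equal(abundance(elementPattern("C", 0, 3)), c(1, 0, 0, 0))
  expect_equal(abundance(elementPattern("C", 1, 1)), c(0.9893, 0.0107))
  ## two silicon atoms: M+1 from one 29Si, computed by explicit enumeration
  si2 <- abundance(elementPattern("Si", 2, 2))
  expect_equal(si2[2], 2 * 0.04685 * 0.92223, tolerance = 1e-12)
  expect_equal(si2, bruteForcePattern(c(Si = 2L), 2), tolerance = 1e-12)
  expect_error(elementPattern("Xx", 1, 2), "unknown element")
})

test_that("convolution is commutative, associative, and has an identity", {
  a <- elementPattern("C", 3, 6)
  b <- elementPattern("Si", 2, 6)
  cc <- elementPattern("O", 4, 6)
  id <- new("IsotopePattern", abundance = c(1, rep(0, 6)), truncated = FALSE)
  expect_equal(abundance(convolvePatterns(a, id)), abundance(a))
  expect_equal(abundance(convolvePatterns(a, b)),
               abundance(convolvePatterns(b, a)), tolerance = 1e-14)
  lhs <- convolvePatterns(convolvePatterns(a, b), cc)
  rhs <- convolvePatterns(a, convolvePatterns(b, cc))
  expect_equal(abundance(lhs), abundance(rhs), tolerance = 1e-12)
  ## binomial square
  half <- new("IsotopePattern", abundance = c(0.5, 0.5, 0), truncated = TRUE)
  expect_equal(abundance(convolvePatterns(half, half)), c(0.25, 0.5, 0.25))
  ## C3 * C3 = C6
  expect_equal(abundance(convolvePatterns(a, a)),
               abundance(elementPattern("C", 6, 6)), tolerance = 1e-14)
  expect_error(convolvePatterns(a, new("IsotopePattern", abundance = c(1, 0),
                                       truncated = TRUE)), "different K")
})

test_that("natural patterns match closed forms and exhaustive enumeration", {
  ## binomial closed form for pure carbon
  c6 <- abundance(naturalPattern("C6", 6))
  expect_equal(c6[2], 6 * 0.0107 * 0.9893^5, tolerance = 1e-12)
  expect_equal(abundance(naturalPattern(integer(0), 3)), c(1, 0, 0, 0))
  ## enumeration oracle on mixed formulas up to 12 atoms
  for (f in c("CSi", "C3H6O3", "C2H5NO2", "C6H5O")) {
    K <- 4
    expect_equal(abundance(naturalPattern(f, K)), bruteForcePattern(f, K),
                 tolerance = 1e-10, label = f)
  }
})

test_that("correction matrix columns equal shifted reduced-formula patterns", {
  cm <- buildCorrectionMatrix("C6Si", 3, K = 5)
  m <- correctionMatrix(cm)
  expect_equal(dim(m), c(6L, 4L))
  for (j in 0:3) {
    oracle <- bruteForcePattern(c(C = 6L - j, Si = 1L), 5 - j)
    expect_equal(unname(m[(j + 1):6, j + 1]), oracle, tolerance = 1e-10)
    if (j > 0) expect_equal(unname(m[1:j, j + 1]), rep(0, j))
  }
  ## degenerate cases
  cm0 <- buildCorrectionMatrix("C6H12O6", 0, K = 2)
  expect_equal(unname(correctionMatrix(cm0)[, 1]),
               abundance(naturalPattern("C6H12O6", 2)))
  cm3 <- buildCorrectionMatrix("C3", 3)
  expect_equal(unname(correctionMatrix(cm3)[4, 4]), 1)
  expect_error(buildCorrectionMatrix("C2", 3), "exceeds fragment carbon")
})

test_that("correction inverts the forward convolution exactly (round trip)", {
  lib <- readFragmentLibrary()
  set.seed(42)
  for (i in seq_len(nrow(lib))) {
    cm <- buildCorrectionMatrix(lib$formula[i], lib$n_backbone[i],
                                fragmentId = lib$fragment_id[i])
    x <- randomSimplex(lib$n_backbone[i] + 1L)
    measured <- as.numeric(correctionMatrix(cm) %*% x)
    out <- correctMid(measured, cm, metabolite = lib$metabolite[i])
    expect_equal(fractions(out), x, tolerance = 1e-8, label = lib$metabolite[i])
  }
})

test_that("an unlabeled sample corrects to M+0 with near-zero enrichment", {
  lib <- readFragmentLibrary()
  for (i in seq_len(nrow(lib))) {
    cm <- buildCorrectionMatrix(lib$formula[i], lib$n_backbone[i])
    measured <- abundance(naturalPattern(lib$formula[i],
                                         nrow(correctionMatrix(cm)) - 1L))
    out <- correctMid(measured, cm)
    expect_equal(fractions(out)[1], 1, tolerance = 1e-7)
    expect_lt(fractionalEnrichment(out), 0.005)
  }
})

test_that("correction is robust to measurement noise (Monte-Carlo)", {
  cm <- buildCorrectionMatrix("C11H26NO2Si2", 3, fragmentId = "alanine")
  A <- correctionMatrix(cm)
  set.seed(7)
  hits <- 0L; total <- 0L
  for (trial in 1:500) {
    x <- randomSimplex(4)
    noisy <- pmax(as.numeric(A %*% x) * (1 + stats::rnorm(nrow(A), 0, 0.01)), 0)
    est <- fractions(correctMid(noisy, cm))
    hits <- hits + sum(abs(est - x) <= 0.02)
    total <- total + 4L
  }
  expect_gt(hits / total, 0.95)
})

test_that("correctMid rejects degenerate input", {
  cm <- buildCorrectionMatrix("C3", 3)
  expect_error(correctMid(rep(0, 7), cm), "all-zero")
  expect_error(correctMid(c(1, 2), cm), "length")
  expect_error(correctMid(c(-1, rep(1, 6)), cm), ">= 0")
})

test_that("fractional enrichment follows both conventions", {
  expect_equal(fractionalEnrichment(c(1, 0, 0, 0)), 0)
  expect_equal(fractionalEnrichment(c(0, 0, 0, 1)), 1)
  expect_equal(fractionalEnrichment(c(0.5, 0, 0, 0.5)), 0.5)
  expect_equal(fractionalEnrichment(c(0.5, 0.5, 0, 0), "labeled-fraction"), 0.5)
  expect_equal(fractionalEnrichment(c(0.5, 0.5, 0, 0)), 0.5 / 3)
  expect_error(fractionalEnrichment(1), "no backbone carbons")
})

test_that("corrected MIDs stay on the simplex under random noisy input", {
  cm <- buildCorrectionMatrix("C19H43N2O3Si3", 5, fragmentId = "glutamine")
  A <- correctionMatrix(cm)
  set.seed(11)
  for (trial in 1:50) {
    x <- randomSimplex(6)
    noisy <- pmax(as.numeric(A %*% x) * exp(stats::rnorm(nrow(A), 0, 0.05)), 0)
    f <- fractions(correctMid(noisy, cm))
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})
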
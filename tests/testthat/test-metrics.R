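test_that("gamma of identical volumes is zero with full pass rate", {
  g <- regularGrid(c(12, 12), 1e-3)
  v <- randomSmoothVolume(c(12, 12), seed = 1)
  d <- doseVolume(v, g)
  gm <- gammaMap(d, d)
  expect_true(all(gm$gamma[!is.na(gm$gamma)] == 0))
  expect_equal(gm$pass_rate, 1)
})

test_that("uniform volumes differing by exactly the dose criterion sit on the boundary", {
  g <- regularGrid(c(10, 10), 1e-3)
  ref <- doseVolume(array(1, c(10, 10)), g)
  tst <- doseVolume(array(1 - 0.03, c(10, 10)), g)
  gm <- gammaMap(ref, tst, gammaCriteria(delta_d = 3, delta_dose = 0.03))
  expect_equal(max(abs(gm$gamma - 1)), 0, tolerance = 1e-12)
  expect_equal(gm$pass_rate, 1)  # gamma = 1 passes
})

test_that("a hot voxel displaced by exactly the DTA criterion scores gamma 1", {
  g <- regularGrid(c(15, 15), 1e-3)
  ref <- array(0, c(15, 15)); ref[8, 8] <- 1
  tst <- array(0, c(15, 15)); tst[11, 8] <- 1   # 3 voxels = 3 mm = delta_d
  gm <- gammaMap(doseVolume(ref, g), doseVolume(tst, g),
                 gammaCriteria(delta_d = 3, delta_dose = 0.03,
                               low_dose_threshold = 0.5))
  expect_equal(gm$n_scored, 1L)
  expect_equal(gm$gamma[8, 8], 1, tolerance = 1e-12)
})

test_that("the pruned gamma search equals the exhaustive brute-force oracle", {
  for (dims in list(c(8, 8, 8), c(12, 12), c(16, 16, 16))) {
    ref <- randomSmoothVolume(dims, seed = 5 + length(dims))
    tst <- randomSmoothVolume(dims, seed = 50 + length(dims))
    crit <- gammaCriteria(delta_d = 2, delta_dose = 0.05)
    g <- regularGrid(dims, 1e-3)
    fast <- gammaMap(doseVolume(ref, g), doseVolume(tst, g), crit)
    brute <- gammaBruteForce(ref, tst, crit, rep(1, length(dims)))
    expect_equal(fast$gamma, brute$gamma, tolerance = 1e-12)
    expect_equal(fast$pass_rate, brute$pass_rate)
  }
})

test_that("loosening gamma criteria never lowers the pass rate", {
  dims <- c(16, 16)
  g <- regularGrid(dims, 1e-3)
  ref <- doseVolume(randomSmoothVolume(dims, 7), g)
  tst <- doseVolume(randomSmoothVolume(dims, 70), g)
  base <- gammaMap(ref, tst, gammaCriteria(2, 0.02))$pass_rate
  expect_gte(gammaMap(ref, tst, gammaCriteria(4, 0.02))$pass_rate, base)
  expect_gte(gammaMap(ref, tst, gammaCriteria(2, 0.05))$pass_rate, base)
  rate <- gammaMap(ref, tst)$pass_rate
  expect_gte(rate, 0); expect_lte(rate, 1)
})

test_that("gamma is asymmetric in reference and test", {
  g <- regularGrid(c(9, 9), 1e-3)
  ref <- array(0, c(9, 9)); ref[5, 5] <- 1
  tst <- array(1, c(9, 9))
  a <- gammaMap(doseVolume(ref, g), doseVolume(tst, g))$pass_rate
  b <- gammaMap(doseVolume(tst, g), doseVolume(ref, g))$pass_rate
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("zero reference dose is rejected", {
  g <- regularGrid(c(4, 4), 1e-3)
  z <- doseVolume(array(0, c(4, 4)), g)
  expect_error(gammaMap(z, z), "no positive")
})

test_that("global SSIM matches hand evaluation and its identities", {
  expect_equal(ssimIndex(array(c(0, 1), 2), array(c(0, 1), 2),
                         dynamic_range = 1), 1)
  ## ref = [0,1], test = [1,0], L = 1: mu = 0.5, sigma2 = 0.25, cov = -0.25
  ## => (0.5001 * -0.4991) / (0.5001 * 0.5009) = -0.49910 / 0.50090
  hand <- -0.4991 / 0.5009
  expect_equal(ssimIndex(array(c(0, 1), 2), array(c(1, 0), 2),
                         dynamic_range = 1), hand, tolerance = 1e-6)
  set.seed(8)
  a <- array(runif(64), c(8, 8)); b <- array(runif(64), c(8, 8))
  expect_equal(ssimIndex(a, b, dynamic_range = 1),
               ssimIndex(b, a, dynamic_range = 1))
  expect_lte(ssimIndex(a, b, dynamic_range = 1), 1)
  expect_error(ssimIndex(a, array(0, c(4, 4))), "shape")
})

test_that("PSNR matches hand evaluation and documents its conventions", {
  a <- array(c(1, 0), 2)
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, array(c(0.5, 0), 2)), 20 * log10(sqrt(2) / 0.5),
               tolerance = 1e-12)
  ## literal mode uses the full voxel-count prefactor
  expect_equal(psnr(a, array(c(0.5, 0), 2), mode = "literal"),
               20 * log10(2 / 0.5), tolerance = 1e-12)
  ## adding the same offset changes max|ref| but not the L2 term
  b <- array(c(0.5, 0), 2)
  expect_false(isTRUE(all.equal(psnr(a, b), psnr(a + 1, b + 1))))
  expect_error(psnr(array(0, 2), a), "zero")
})

test_that("evaluateMethods aggregates per-method metrics", {
  g <- regularGrid(c(12, 12), 1e-3)
  v <- randomSmoothVolume(c(12, 12), 3)
  p0 <- pressureVolume(v, g, "p0")
  same <- pressureVolume(v, g, "p_pred")
  off <- pressureVolume(pmax(v - 0.2, 0), g, "p_pred")
  rep1 <- evaluateMethods(list(list(p0 = p0, exact = same, biased = off)))
  s <- rep1$summary
  expect_equal(s$ssim_mean[s$method == "exact"], 1)
  expect_equal(s$gamma_pass_mean[s$method == "exact"], 1)
  expect_equal(s$ssim_sd, c(0, 0))  # n = 1 => sd 0
  expect_error(evaluateMethods(list()), "empty")
})
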
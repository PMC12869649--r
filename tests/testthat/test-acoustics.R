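test_that("dose to pressure follows the Grueneisen relation", {
  g <- regularGrid(c(8, 8), 1e-3)
  med <- waterMedium(g)  # Gamma 0.11, eta 1, rho 1000
  z <- doseToPressure(doseVolume(array(0, c(8, 8)), g), med)
  expect_true(all(volumeValues(z) == 0))
  d <- doseVolume(array(0.0172, c(8, 8)), g)
  p <- doseToPressure(d, med)
  expect_equal(max(volumeValues(p)), 1.892, tolerance = 1e-12)
  d2 <- doseVolume(array(2 * 0.0172, c(8, 8)), g)
  expect_equal(volumeValues(doseToPressure(d2, med)), 2 * volumeValues(p))
  g2 <- regularGrid(c(8, 9), 1e-3)
  expect_error(doseToPressure(d, waterMedium(g2)), "grid")
})

test_that("CFL violations and out-of-grid sensors are rejected", {
  g <- regularGrid(c(24, 24), 1e-3)
  med <- waterMedium(g)
  p0 <- spherePressure(g, c(11e-3, 11e-3), 3e-3)
  expect_error(propagate(p0, med, matrix(c(11e-3, 11e-3), 1), 5e-6,
                         dt = 1e-6),
               "maximum stable dt")
  expect_error(propagate(p0, med, matrix(c(50e-3, 11e-3), 1), 5e-6),
               "outside the grid")
})

test_that("signals are causal: nothing arrives before r/c", {
  ## a compact smooth source: a hard-edged source is not representable on a
  ## band-limited grid and its spectral interpolant rings over the whole
  ## domain, so causality is asserted for a source the grid can carry, with
  ## a guard band covering the source's smooth skirt
  g <- regularGrid(c(48, 48), 1e-3)
  med <- waterMedium(g)
  p0 <- spherePressure(g, c(23e-3, 23e-3), 2e-3, 1, edge_width = 0.75e-3)
  ts <- propagate(p0, med, matrix(c(23e-3 + 15e-3, 23e-3), 1), 20e-6)[[1]]
  t_arr <- (15e-3 - 2e-3 - 5e-3) / 1500
  early <- ts@samples[timeAxis(ts) < t_arr]
  expect_lt(max(abs(early)), 0.01 * max(abs(ts@samples)))
})

test_that("solver matches the closed-form spherical-source signal", {
  ## smooth-edged ball (edge = 1 voxel): exact closed form
  ## p(r,t) = (r - ct) f(|r - ct|) / (2r); radii spanning 2-4 voxels here,
  ## the 6-voxel case runs in the acceptance suite on a larger grid
  for (rad_vox in c(2, 4)) {
    g <- regularGrid(rep(48, 3), 1e-3)
    med <- waterMedium(g)
    ctr <- rep(23e-3, 3)
    p0 <- spherePressure(g, ctr, rad_vox * 1e-3, 1, edge_width = 1e-3)
    dt <- maxStableDt(med)
    dur <- 1.3 * (12 + rad_vox) * 1e-3 / 1500
    rec <- propagate(p0, med, matrix(ctr + c(12e-3, 0, 0), 1), dur, dt,
                     pml_layers = 8L)[[1]]
    ana <- analyticSphereSignal(1, rad_vox * 1e-3, 12e-3, 1500, dt, dur,
                                edge_width = 1e-3)
    nn <- min(length(rec@samples), length(ana@samples))
    expect_lt(relL2(rec@samples[1:nn], ana@samples[1:nn]), 0.02)
  }
})

test_that("the hard-sphere N-wave has the textbook amplitude and support", {
  ts <- analyticSphereSignal(1, 2e-3, 10e-3, 1500, 1e-8)
  expect_equal(max(ts@samples), 1 * 2e-3 / (2 * 10e-3), tolerance = 0.01)
  t_lead <- (10e-3 - 2e-3) / 1500
  expect_true(all(ts@samples[timeAxis(ts) < t_lead - 1e-8] == 0))
  ts2 <- analyticSphereSignal(1, 2e-3, 20e-3, 1500, 1e-8)
  expect_equal(max(ts2@samples), max(ts@samples) / 2, tolerance = 0.01)
  expect_error(analyticSphereSignal(1, 5e-3, 4e-3, 1500, 1e-8), "outside")
})

test_that("propagation is linear in the initial pressure", {
  g <- regularGrid(c(40, 40), 1e-3)
  med <- waterMedium(g)
  pa <- spherePressure(g, c(15e-3, 19e-3), 3e-3, 1, edge_width = 1e-3)
  pb <- spherePressure(g, c(24e-3, 19e-3), 2e-3, 1, edge_width = 1e-3)
  sens <- matrix(c(19e-3, 28e-3), 1)
  ya <- propagate(pa, med, sens, 25e-6)[[1]]@samples
  yb <- propagate(pb, med, sens, 25e-6)[[1]]@samples
  comb <- pressureVolume(2 * volumeValues(pa) + 0.5 * volumeValues(pb),
                         g, "p0")
  yc <- propagate(comb, med, sens, 25e-6)[[1]]@samples
  expect_equal(yc, 2 * ya + 0.5 * yb, tolerance = 1e-10)
})

test_that("the absorbing boundary leaves under 1% residual after the last arrival", {
  g <- regularGrid(rep(48, 3), 1e-3)
  med <- waterMedium(g)
  ctr <- rep(23e-3, 3)
  p0 <- spherePressure(g, ctr, 2e-3, 1, edge_width = 1e-3)
  dt <- maxStableDt(med)
  s <- propagate(p0, med, matrix(ctr + c(10e-3, 0, 0), 1), 70e-6, dt,
                 pml_layers = 10L)[[1]]@samples
  ta <- (seq_along(s) - 1) * dt
  ## last geometric arrival at ~ (10 + 3) mm / c ~ 9 us; allow settling
  expect_lt(max(abs(s[ta >= 30e-6])), 0.01 * max(abs(s)))
})

test_that("halving the spacing reduces the oracle error", {
  err <- sapply(c(2e-3, 1e-3), function(dx) {
    n <- round(48e-3 / dx)
    g <- regularGrid(rep(n, 3), dx)
    med <- waterMedium(g)
    ctr <- rep((round(23e-3 / dx)) * dx, 3)
    p0 <- spherePressure(g, ctr, 4e-3, 1, edge_width = 2e-3)
    dt <- maxStableDt(med)
    dur <- 1.3 * 16e-3 / 1500
    rec <- propagate(p0, med, matrix(ctr + c(12e-3, 0, 0), 1), dur, dt,
                     pml_layers = 6L)[[1]]
    ana <- analyticSphereSignal(1, 4e-3, 12e-3, 1500, dt, dur,
                                edge_width = 2e-3)
    nn <- min(length(rec@samples), length(ana@samples))
    relL2(rec@samples[1:nn], ana@samples[1:nn])
  })
  expect_lt(err[2], err[1])
})
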
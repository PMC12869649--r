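test_that("Bragg peak lands on the range-energy power law across energies", {
  g <- regularGrid(c(96, 24), 1e-3)
  for (E in c(50, 60, 70, 80)) {
    spec <- protonBeamSpec(E, entry = c(0, 0.011))
    d <- protonPencilBeam(spec, g)
    R <- 0.0022 * E^1.77 * 1e-2
    depth_profile <- volumeValues(d)[, 12]
    z_peak <- gridCoords(g, 1)[which.max(depth_profile)]
    expect_lt(abs(z_peak - R), 1e-3 + 1e-9)
  }
})

test_that("proton dose scales linearly with fluence and vanishes at zero", {
  g <- regularGrid(c(64, 24), 1e-3)
  s1 <- protonBeamSpec(55, entry = c(0, 0.011), fluence_scale = 1)
  s2 <- protonBeamSpec(55, entry = c(0, 0.011), fluence_scale = 2)
  s0 <- protonBeamSpec(55, entry = c(0, 0.011), fluence_scale = 0)
  d1 <- protonPencilBeam(s1, g)
  expect_equal(max(volumeValues(d1)), 1)
  expect_equal(volumeValues(protonPencilBeam(s2, g)), 2 * volumeValues(d1))
  expect_true(all(volumeValues(protonPencilBeam(s0, g)) == 0))
  expect_true(all(volumeValues(d1) >= 0))
})

test_that("a Bragg peak beyond the grid is rejected with the required extent", {
  g <- regularGrid(c(32, 24), 1e-3)  # 32 mm deep; 80 MeV needs ~52 mm
  expect_error(protonPencilBeam(protonBeamSpec(80, entry = c(0, 0.011)), g),
               "outside the grid")
})

test_that("electron field has the documented maximum, r50 and degenerate errors", {
  g <- regularGrid(c(64, 48), 1e-3)
  spec <- electronBeamSpec(field_size = 20e-3, r50 = 40e-3,
                           entry = c(0, 0.0235), direction = c(1, 0))
  d <- electronFlashBeam(spec, g)
  expect_equal(max(volumeValues(d)), 1)           # dose_per_pulse default 1 Gy
  ## central-axis depth profile crosses 50% of max at r50 within 1%
  prof <- volumeValues(d)[, which.max(volumeValues(d)[45, ])]
  at_r50 <- stats::approx(gridCoords(g, 1), prof, xout = 40e-3)$y
  expect_lt(abs(at_r50 - 0.5), 0.01)
  expect_error(electronBeamSpec(field_size = 0, r50 = 40e-3), "field_size")
  deep <- electronBeamSpec(field_size = 20e-3, r50 = 80e-3,
                           entry = c(0, 0.0235), direction = c(1, 0))
  expect_error(electronFlashBeam(deep, g), "deeper than the grid")
})

test_that("instantaneous dose rate is dose over pulse duration", {
  expect_equal(instantaneousDoseRate(1, 1e-6), 1e6)
  expect_equal(instantaneousDoseRate(0, 5e-6), 0)
  expect_equal(instantaneousDoseRate(2, 4e-6), 5e5)
  expect_error(instantaneousDoseRate(1, 0), "pulse_duration")
})

test_that("frame rate under pulse averaging divides the repetition rate", {
  expect_equal(imagingFrameRate(750, 10), 75)
  expect_error(imagingFrameRate(750, 0))
})

test_that("pulse profiles are unit-area and the box has the right amplitude", {
  delta <- makePulse("delta", dt = 1e-7)
  expect_identical(delta@samples, 1)
  box <- makePulse("box", duration = 1e-6, dt = 1e-7)
  expect_length(box@samples, 10)
  expect_equal(box@samples, rep(1e6, 10))
  for (kind in c("box", "gaussian", "double-gaussian")) {
    p <- makePulse(kind, duration = 2e-6, dt = 1e-7)
    expect_equal(sum(p@samples) * p@dt, 1, tolerance = 1e-9)
  }
  expect_error(makePulse("sawtooth", 1e-6, 1e-7))
})

test_that("the tank catalog enumerates, excludes and splits consistently", {
  cat35 <- watertankCatalog(7, 5, 0, split = c(20, 5, 8), seed = 3)
  expect_equal(catalogCounts(cat35)$total, 35)
  expect_equal(catalogCounts(cat35)$usable, 35)

  cat33 <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 3)
  cnt <- catalogCounts(cat33)
  expect_equal(cnt$total, 35)
  expect_equal(cnt$excluded, 2)
  expect_equal(cnt$usable, 33)
  expect_equal(c(cnt$train, cnt$val, cnt$test), c(20, 5, 8))
  expect_equal(cnt$total, cnt$usable + cnt$excluded)
  e <- catalogEntries(cat33)
  expect_equal(sum(e$split != ""), 33)
  ## 5-position protocol: centre plus 1 cm shifts in four directions
  shifts <- unique(e[, c("shift_x_mm", "shift_y_mm")])
  expect_setequal(paste(shifts$shift_x_mm, shifts$shift_y_mm),
                  c("0 0", "-10 0", "10 0", "0 10", "0 -10"))
})

test_that("catalogs are reproducible from their seed", {
  a <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 9)
  b <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 9)
  expect_identical(catalogEntries(a), catalogEntries(b))
  c2 <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 10)
  expect_false(identical(catalogEntries(a), catalogEntries(c2)))
})

test_that("oversubscribed splits are rejected", {
  expect_error(watertankCatalog(2, 2, 1, split = c(3, 1, 1), seed = 1),
               "exceed")
})
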
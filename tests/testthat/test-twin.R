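test_that("pulse convolution: identity, area preservation, commutativity", {
  dt <- 1e-7
  set.seed(1)
  sig <- timeSeries(rnorm(200), dt)
  delta <- makePulse("delta", dt = dt)
  expect_equal(applyPulse(sig, delta)@samples, sig@samples)

  box <- makePulse("box", duration = 1e-6, dt = dt)
  ## integral is preserved for a signal that has fully decayed inside the
  ## window (pad with zeros so the truncation loses nothing)
  sig2 <- timeSeries(c(rnorm(100), rep(0, 50)), dt)
  out <- applyPulse(sig2, box)
  expect_equal(sum(out@samples) * dt, sum(sig2@samples) * dt,
               tolerance = 1e-9)
  expect_equal(out@t0, sig2@t0)

  g2 <- makePulse("gaussian", duration = 2e-6, dt = dt)
  ab <- applyPulse(applyPulse(sig2, box), g2)
  ba <- applyPulse(applyPulse(sig2, g2), box)
  expect_equal(ab@samples, ba@samples, tolerance = 1e-12)
})

test_that("a 3x3 mm element at 1 mm sub-pitch integrates nine sub-elements", {
  arr <- transducerArray(matrix(c(0, 0, 0), 1), element_size = 3e-3,
                         sub_pitch = 1e-3, normal = c(1, 0, 0))
  offs3d <- subElementOffsets(arr, 3L)
  expect_equal(nrow(offs3d), 9)
  expect_setequal(unique(offs3d[, 2]), c(-1e-3, 0, 1e-3))
  expect_true(all(offs3d[, 1] == 0))  # displacements lie in the element plane
  expect_equal(nrow(subElementOffsets(arr, 2L)), 3)

  dt <- 1e-7
  subs <- lapply(1:9, function(i) timeSeries(rep(i, 50), dt))
  summed <- finiteElementSignal(subs)
  expect_equal(summed@samples, rep(sum(1:9), 50))
  one <- timeSeries(rnorm(30), dt)
  expect_equal(finiteElementSignal(list(one))@samples, one@samples)
  nine <- finiteElementSignal(rep(list(one), 9))
  expect_equal(nine@samples, 9 * one@samples)
  bad <- timeSeries(rnorm(30), 2 * dt)
  expect_error(finiteElementSignal(list(one, bad)), "share")
})

test_that("impulse response filtering is multiplication in the frequency domain", {
  dt <- 1e-7
  ir <- impulseResponse("damped-sinusoid", f0 = 1e6, q = 2, dt = dt)
  expect_equal(applyImpulseResponse(timeSeries(c(1, rep(0, 99)), dt),
                                    impulseResponse("delta", dt = dt))@samples,
               c(1, rep(0, 99)))
  ## chirp through the filter: spectrum of the (full, untruncated)
  ## convolution equals the product of spectra
  n <- 256
  t <- (0:(n - 1)) * dt
  chirp <- sin(2 * pi * (2e5 + 3e10 * t) * t) * exp(-((t - 8e-6) / 5e-6)^2)
  out <- radiacoustics:::convFull(chirp, ir@samples)
  m <- length(out)
  pad <- function(x) c(x, rep(0, m - length(x)))
  expect_equal(fft(out), fft(pad(chirp)) * fft(pad(ir@samples)),
               tolerance = 1e-8)
  ## band-pass behaviour: on-resonance tone passes with more gain than 3 f0
  tone <- function(f) sin(2 * pi * f * t)
  gain <- function(f) {
    y <- applyImpulseResponse(timeSeries(tone(f), dt), ir)@samples
    sqrt(mean(y[100:n]^2) / mean(tone(f)[100:n]^2))
  }
  expect_gt(gain(1e6), gain(3e6))
  expect_error(impulseResponse("samples", samples = rep(0, 5), dt = dt),
               "zero")
})

test_that("the forward operator composes the full chain and is linear", {
  tw <- smallTwin()
  g <- tw$grid
  p0 <- spherePressure(g, c(10e-3, 11e-3), 2e-3, 1, edge_width = 1e-3)
  s1 <- forwardOperator(p0, tw$twin)
  expect_s4_class(s1, "Sinogram")
  expect_equal(nChannels(s1), 5)
  expect_equal(s1@units_flag, "relative")
  ## linearity: F(2 a + b) = 2 F(a) + F(b)
  pb <- spherePressure(g, c(16e-3, 13e-3), 1.5e-3, 1, edge_width = 1e-3)
  comb <- pressureVolume(2 * volumeValues(p0) + volumeValues(pb), g, "p0")
  expect_equal(sinogramData(forwardOperator(comb, tw$twin)),
               2 * sinogramData(s1) +
                 sinogramData(forwardOperator(pb, tw$twin)),
               tolerance = 1e-10)
})

test_that("with identity pulse, IR and aperture, F reduces to raw propagation", {
  tw <- smallTwin(pulse_kind = "delta", ir_kind = "delta",
                  sub_pitch = 3e-3)  # one sub-element per element
  p0 <- spherePressure(tw$grid, c(10e-3, 11e-3), 2e-3, 1, edge_width = 1e-3)
  s <- forwardOperator(p0, tw$twin)
  pts <- radiacoustics:::arraySensorPoints(tw$array, 2L)$points
  raw <- propagate(p0, tw$medium, pts, tw$twin@duration, tw$twin@dt,
                   scheme = "adjoint-core")
  for (i in 1:5)
    expect_equal(s@data[i, ], raw[[i]]@samples, tolerance = 1e-12)
})

test_that("swapping pulse and impulse-response order leaves F unchanged", {
  dt <- 1e-7
  sig <- timeSeries(c(rnorm(80), rep(0, 60)), dt)
  pulse <- makePulse("box", 1e-6, dt)
  ir <- impulseResponse("damped-sinusoid", f0 = 1e6, q = 2, dt = dt)
  a <- applyImpulseResponse(applyPulse(sig, pulse), ir)
  b <- applyPulse(applyImpulseResponse(sig, ir), pulse)
  expect_equal(a@samples, b@samples, tolerance = 1e-10)
})

test_that("a 16 x 16 matrix array produces a 256-channel sinogram", {
  arr <- planarArray(16, 16, pitch = 3e-3,
                     center = c(18e-3, 25.5e-3, 25.5e-3),
                     normal = c(-1, 0, 0))
  expect_equal(nElements(arr), 256)
  expect_equal(arr@layout, c(16L, 16L))
  g <- regularGrid(c(20, 52, 52), 1e-3)
  med <- waterMedium(g)
  dt <- maxStableDt(med)
  twin <- twinConfig(makePulse("delta", dt = dt),
                     arr, impulseResponse("delta", dt = dt), med,
                     duration = 8e-6)
  p0v <- array(0, c(20, 52, 52)); p0v[6, 26, 26] <- 1
  s <- forwardOperator(pressureVolume(p0v, g, "p0"), twin)
  expect_equal(nChannels(s), 256)
  expect_equal(s@channel_map, 1:256)
})

test_that("the adjoint operator is the exact transpose of F", {
  tw <- smallTwin()
  tp <- radiacoustics:::twinPlan(tw$twin)
  set.seed(4)
  x <- array(runif(prod(gridShape(tw$grid))), gridShape(tw$grid))
  y <- matrix(rnorm(5 * tp$n_t), 5, tp$n_t)
  lhs <- sum(radiacoustics:::twinForwardRaw(x, tp) * y)
  rhs <- sum(x * radiacoustics:::twinAdjointRaw(y, tp))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("sub-element refinement is converged at the default 3-sub split", {
  ## distant source: signals from a 3 vs 5 sub-element aperture agree < 5%
  g <- regularGrid(c(48, 32), 1e-3)
  med <- waterMedium(g)
  dt <- maxStableDt(med)
  p0 <- spherePressure(g, c(10e-3, 15e-3), 2e-3, 1, edge_width = 1e-3)
  mk <- function(sub_pitch) {
    arr <- transducerArray(cbind(42e-3, 15e-3), element_size = 3e-3,
                           sub_pitch = sub_pitch, normal = c(-1, 0, 0))
    twin <- twinConfig(makePulse("delta", dt = dt), arr,
                       impulseResponse("delta", dt = dt), med, 40e-6)
    sinogramData(forwardOperator(p0, twin))[1, ] /
      (3e-3 / sub_pitch)  # per-sub normalisation for comparison
  }
  s3 <- mk(1e-3)
  s5 <- mk(0.6e-3)
  expect_lt(relL2(s5, s3), 0.05)
})
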
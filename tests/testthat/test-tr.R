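test_that("time reversal of a sinogram is an index flip and an involution", {
  set.seed(2)
  s <- sinogram(matrix(rnorm(3 * 20), 3, 20), dt = 1e-7)
  r <- reverseSinogram(s)
  expect_equal(r@data[, 1], s@data[, 20])
  expect_equal(r@data[2, 3], s@data[2, 18])
  expect_equal(dim(r@data), dim(s@data))
  expect_equal(r@channel_map, s@channel_map)
  expect_equal(r@dt, s@dt)
  expect_identical(reverseSinogram(r)@data, s@data)
})

test_that("a zero sinogram reconstructs to a zero volume", {
  tw <- smallTwin()
  s0 <- sinogram(matrix(0, 5, 100), dt = tw$dt)
  p <- trReconstruct(s0, trConfig(tw$medium, tw$array))
  expect_true(all(volumeValues(p) == 0))
  expect_equal(pressureRole(p), "p_rec")
})

test_that("channel/array mismatch is rejected", {
  tw <- smallTwin()
  bad <- sinogram(matrix(0, 4, 100), dt = tw$dt)
  bad@data[1, 1] <- 1
  expect_error(trReconstruct(bad, trConfig(tw$medium, tw$array)),
               "4 channels")
})

test_that("full-ring forward followed by TR refocuses the disc phantom", {
  fx <- fullRingTR()
  prec <- trReconstruct(fx$sino, trConfig(fx$med, fx$arr))
  r <- cor(as.vector(volumeValues(prec)), as.vector(volumeValues(fx$p0)))
  expect_gte(r, 0.95)
})

test_that("TR is linear in the sinogram", {
  fx <- fullRingTR()
  cfg <- trConfig(fx$med, fx$arr)
  p1 <- trReconstruct(fx$sino, cfg)
  s2 <- sinogram(2.5 * fx$sino@data, dt = fx$sino@dt)
  p2 <- trReconstruct(s2, cfg)
  expect_equal(volumeValues(p2), 2.5 * volumeValues(p1), tolerance = 1e-10)
})

test_that("reconstruction fidelity grows with angular coverage", {
  fx <- fullRingTR()
  cors <- sapply(c(90, 180, 360), function(deg) {
    keep <- fx$th <= deg / 180 * pi
    sub <- sinogram(fx$sino@data[keep, , drop = FALSE], dt = fx$sino@dt)
    arr <- transducerArray(fx$arr@element_centers[keep, , drop = FALSE],
                           element_size = 1e-3, sub_pitch = 1e-3,
                           normal = c(1, 0, 0))
    prec <- trReconstruct(sub, trConfig(fx$med, arr))
    cor(as.vector(volumeValues(prec)), as.vector(volumeValues(fx$p0)))
  })
  expect_true(all(diff(cors) > 0))
})

test_that("limited-view planar TR localises a Bragg-peak source within 2 voxels", {
  ## raw acoustic recording (no pulse/IR colouring) on a planar line array
  g <- regularGrid(c(64, 48), 1e-3)
  med <- waterMedium(g)
  spec <- protonBeamSpec(58, entry = c(10e-3, 23e-3), direction = c(1, 0),
                         fluence_scale = 0.0172)
  p0 <- doseToPressure(protonPencilBeam(spec, g), med)
  dt <- maxStableDt(med)
  arr <- transducerArray(cbind(54e-3, (seq_len(10) + 5.5) * 3e-3 - 12e-3),
                         element_size = 3e-3, sub_pitch = 1e-3,
                         normal = c(-1, 0, 0))
  pts <- radiacoustics:::arraySensorPoints(arr, 2L)
  rec <- propagate(p0, med, pts$points, 55e-6, dt)
  elem <- rowsum(do.call(rbind, lapply(rec, function(t) t@samples)),
                 pts$group)
  sino <- sinogram(elem, dt = dt)
  prec <- trReconstruct(sino, trConfig(med, arr))
  ia <- arrayInd(which.max(volumeValues(p0)), gridShape(g))[1, ]
  ib <- arrayInd(which.max(volumeValues(prec)), gridShape(g))[1, ]
  expect_lte(sqrt(sum((ia - ib)^2)), 2)
  ## limited view distorts morphology: negative artifacts are expected
  expect_lt(min(volumeValues(prec)), 0)
})

test_that("dirichlet injection mode also refocuses the source", {
  fx <- fullRingTR()
  prec <- trReconstruct(fx$sino, trConfig(fx$med, fx$arr,
                                          injection_mode = "dirichlet"))
  r <- cor(as.vector(volumeValues(prec)), as.vector(volumeValues(fx$p0)))
  expect_gt(r, 0.8)
})
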
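test_that("the pressure loss is the mean squared voxel difference", {
  g <- regularGrid(c(2, 1), 1e-3)
  a <- pressureVolume(array(c(0, 0), c(2, 1)), g, "p_pred")
  b <- pressureVolume(array(c(3, 4), c(2, 1)), g, "p0")
  expect_equal(pressureLoss(a, a), 0)
  expect_equal(pressureLoss(b, pressureVolume(array(c(4, 5), c(2, 1)), g,
                                              "p0")), 1)
  expect_equal(pressureLoss(a, b), (9 + 16) / 2)
  expect_error(pressureLoss(a, pressureVolume(array(0, c(3, 1)),
                                              regularGrid(c(3, 1), 1e-3))),
               "shape")
})

test_that("the sinogram loss is zero on self-consistent data and mean square otherwise", {
  tw <- smallTwin()
  p0 <- spherePressure(tw$grid, c(10e-3, 11e-3), 2e-3, 1, edge_width = 1e-3)
  s_m <- forwardOperator(p0, tw$twin)
  expect_equal(sinogramLoss(p0, s_m, tw$twin), 0, tolerance = 1e-20)
  zero <- pressureVolume(array(0, gridShape(tw$grid)), tw$grid, "p_pred")
  expect_equal(sinogramLoss(zero, s_m, tw$twin), mean(s_m@data^2))
})

test_that("the total loss combines the two terms linearly", {
  expect_equal(totalLoss(2, 3, 1, 2), 8)
  expect_equal(totalLoss(5, 7, 1, 0), 5)   # supervised reduction
  expect_equal(totalLoss(5, 7, 0, 1), 7)   # pure physics self-supervision
  expect_error(totalLoss(1, 1, -1, 1), ">= 0")
})

test_that("the physics-loss gradient matches finite differences", {
  ## small twin, one voxel perturbed: the analytic gradient comes from the
  ## exact adjoint of F and must agree with a centred difference
  g <- regularGrid(c(8, 8, 8), 2e-3)
  med <- waterMedium(g)
  dt <- maxStableDt(med)
  arr <- transducerArray(cbind(13e-3, c(5, 9) * 1e-3, 7e-3),
                         element_size = 2e-3, sub_pitch = 1e-3,
                         normal = c(-1, 0, 0))
  twin <- twinConfig(makePulse("gaussian", 2e-6, dt), arr,
                     impulseResponse("damped-sinusoid", f0 = 5e5, q = 2,
                                     dt = dt),
                     med, duration = 15e-6)
  tp <- radiacoustics:::twinPlan(twin)
  set.seed(3)
  pred <- array(runif(512), c(8, 8, 8))
  s_m <- forwardOperator(spherePressure(g, rep(7e-3, 3), 3e-3, 1,
                                        edge_width = 2e-3), twin)
  r <- radiacoustics:::twinForwardRaw(pred, tp) - s_m@data
  gan <- radiacoustics:::twinAdjointRaw(2 * r / length(r), tp)
  lossAt <- function(p) mean((radiacoustics:::twinForwardRaw(p, tp) -
                              s_m@data)^2)
  h <- 1e-5
  for (i in c(100, 256, 400)) {
    pp <- pred; pp[i] <- pp[i] + h
    pm <- pred; pm[i] <- pm[i] - h
    fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
    expect_equal(gan[i], fd, tolerance = 1e-4)
  }
})

test_that("network backpropagation matches finite differences", {
  set.seed(5)
  shape <- c(8L, 8L)
  ncfg <- networkConfig(shape, depth = 2, base_channels = 3)
  net <- radiacoustics:::initNetwork(ncfg, seed = 2)
  x <- array(rnorm(64), shape)
  tgt <- array(rnorm(64), shape)
  fw <- radiacoustics:::netForward(net, x)
  gr <- radiacoustics:::netBackward(net, 2 * (fw$y - tgt) / 64, fw$cache)
  lossf <- function(params) {
    net2 <- net; net2$params <- params
    mean((radiacoustics:::netForward(net2, x)$y - tgt)^2)
  }
  h <- 1e-6
  for (nm in c("enc1a", "enc2b", "up1", "dec1", "head", "inskip")) {
    p2 <- net$params; p2[[nm]]$W[[1]][1, 1] <- p2[[nm]]$W[[1]][1, 1] + h
    p3 <- net$params; p3[[nm]]$W[[1]][1, 1] <- p3[[nm]]$W[[1]][1, 1] - h
    fd <- (lossf(p2) - lossf(p3)) / (2 * h)
    expect_equal(gr[[nm]]$dW[[1]][1, 1], fd, tolerance = 1e-5)
  }
})

## tiny but real training setup shared by the behavioural tests
tinyStudy <- function() memoFixture("tinystudy", function() {
  setup <- watertankSetup(grid_shape = c(64, 48), n_elements = 8L,
                          array_x = 52e-3)
  catalog <- watertankCatalog(3, 2, 0, split = c(5, 0, 1), seed = 5,
                              energies = c(50, 56, 62))
  records <- simulateWatertankStudy(catalog, setup)
  list(setup = setup, records = records)
})

test_that("training is deterministic given the seed and logs a consistent history", {
  ts <- tinyStudy()
  train_set <- lapply(studySplit(ts$records, "train"), function(r) r$sample)
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  run <- function() trainEnhancer(train_set, ncfg,
                                  trainConfig(epochs = 3, seed = 21),
                                  ts$setup$twin)
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  ## loss decomposition identity at every epoch
  expect_equal(a$history$total,
               a$model$lambda1 * a$history$loss_p +
                 a$model$lambda2 * a$history$loss_s,
               tolerance = 1e-12)
})

test_that("auto lambda2 balances the two loss terms at the start", {
  ts <- tinyStudy()
  train_set <- lapply(studySplit(ts$records, "train"), function(r) r$sample)
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  out <- trainEnhancer(train_set, ncfg, trainConfig(epochs = 1, seed = 2),
                       ts$setup$twin)
  h1 <- out$history[1, ]
  ratio <- (out$model$lambda2 * h1$loss_s) / (out$model$lambda1 * h1$loss_p)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("physics-only training on unlabeled samples reduces the sinogram loss", {
  ts <- tinyStudy()
  unl <- lapply(studySplit(ts$records, "train")[1:3], function(r)
    trainingSample(r$p_rec, r$s_m, p0 = NULL))
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  out <- trainEnhancer(unl, ncfg,
                       trainConfig(epochs = 8, lambda1 = 0, lambda2 = 1,
                                   seed = 3),
                       ts$setup$twin)
  expect_lt(tail(out$history$loss_s, 1), out$history$loss_s[1])
  expect_true(all(out$history$loss_p == 0))
})

test_that("enhance preserves shape, respects non-negativity and input scale", {
  ts <- tinyStudy()
  train_set <- lapply(studySplit(ts$records, "train"), function(r) r$sample)
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  out <- trainEnhancer(train_set, ncfg, trainConfig(epochs = 5, seed = 7),
                       ts$setup$twin)
  te <- studySplit(ts$records, "test")[[1]]
  pp <- enhance(te$p_rec, out$model)
  expect_equal(dim(volumeValues(pp)), dim(volumeValues(te$p_rec)))
  expect_gte(min(volumeValues(pp)), 0)
  expect_equal(pressureRole(pp), "p_pred")
  ## scale equivariance: the per-sample normalisation divides out
  scaled <- pressureVolume(10 * volumeValues(te$p_rec), te$p_rec@grid,
                           "p_rec")
  expect_equal(volumeValues(enhance(scaled, out$model)),
               10 * volumeValues(pp), tolerance = 1e-9)
  wrong <- pressureVolume(array(0, c(16, 16)), regularGrid(c(16, 16), 1e-3),
                          "p_rec")
  expect_error(enhance(wrong, out$model), "shape")
})

test_that("checkpoints round-trip and fine-tuning resumes from saved weights", {
  ts <- tinyStudy()
  train_set <- lapply(studySplit(ts$records, "train"), function(r) r$sample)
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  out <- trainEnhancer(train_set, ncfg, trainConfig(epochs = 8, seed = 7),
                       ts$setup$twin)
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(out$model, path)
  model2 <- loadCheckpoint(path)
  expect_identical(model2$params, out$model$params)
  ## warm start: with a vanishing learning rate the first fine-tune epoch
  ## sits at the checkpoint's converged loss, well below a cold start
  ft <- fineTune(model2, train_set,
                 trainConfig(epochs = 1, seed = 8, lr = 1e-10),
                 ts$setup$twin)
  cold <- trainEnhancer(train_set, ncfg,
                        trainConfig(epochs = 1, seed = 8, lr = 1e-10),
                        ts$setup$twin)
  expect_lt(ft$history$loss_p[1], cold$history$loss_p[1])
})

test_that("training rejects empty or inconsistent datasets", {
  ts <- tinyStudy()
  ncfg <- networkConfig(gridShape(ts$setup$grid), depth = 2,
                        base_channels = 4)
  expect_error(trainEnhancer(list(), ncfg, trainConfig(epochs = 1)),
               "empty")
  bad_grid <- regularGrid(c(16, 16), 1e-3)
  bad <- trainingSample(pressureVolume(array(1, c(16, 16)), bad_grid,
                                       "p_rec"),
                        sinogram(matrix(0, 2, 4), 1e-7))
  expect_error(trainEnhancer(list(bad), ncfg, trainConfig(epochs = 1),
                             ts$setup$twin),
               "shape")
})
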
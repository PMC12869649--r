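## Shared fixtures.  Everything is generated in code; the heavyweight
## synthetic study + trained models are built once per session and memoised.

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

## small 2D twin used by operator-level tests (fast: ~150 time steps)
smallTwin <- function(pulse_kind = "gaussian", ir_kind = "damped-sinusoid",
                      n_elem = 5L, sub_pitch = 1e-3, element_size = 3e-3) {
  g <- regularGrid(c(32, 24), 1e-3)
  med <- waterMedium(g)
  dt <- maxStableDt(med)
  arr <- transducerArray(cbind(26e-3, (seq_len(n_elem) + 3) * 3e-3 - 6e-3),
                         element_size = element_size, sub_pitch = sub_pitch,
                         normal = c(-1, 0, 0))
  pulse <- if (pulse_kind == "delta") makePulse("delta", dt = dt)
           else makePulse(pulse_kind, 2e-6, dt)
  ir <- if (ir_kind == "delta") impulseResponse("delta", dt = dt)
        else impulseResponse("damped-sinusoid", f0 = 1e6, q = 2, dt = dt)
  list(grid = g, medium = med, dt = dt, array = arr,
       twin = twinConfig(pulse, arr, ir, med, duration = 30e-6))
}

## memoised session cache
.fixture_env <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## the full synthetic tank benchmark: catalog, study records, trained PINN
## and supervised baseline (shared by the reconstruction-quality tests)
tankBenchmark <- function() memoFixture("tank", function() {
  setup <- watertankSetup()
  catalog <- watertankCatalog(7, 5, 2, split = c(20, 5, 8), seed = 1)
  records <- simulateWatertankStudy(catalog, setup)
  net_cfg <- networkConfig(gridShape(setup$grid), depth = 2,
                           base_channels = 8)
  pinn <- trainEnhancer(studyTrainingSet(records), net_cfg,
                        trainConfig(epochs = 30, seed = 11), setup$twin)
  unet <- trainEnhancer(studyTrainingSet(records, labeled_only = TRUE),
                        net_cfg,
                        trainConfig(epochs = 30, lambda2 = 0, seed = 11))
  list(setup = setup, catalog = catalog, records = records,
       net_cfg = net_cfg, pinn = pinn, unet = unet)
})

## shared full-ring fixture: forward + TR on a disc phantom
fullRingTR <- function() memoFixture("fullring", function() {
  g <- regularGrid(c(64, 64), 1e-3)
  med <- waterMedium(g)
  ctr <- c(31.5e-3, 31.5e-3)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  ring <- cbind(ctr[1] + 20e-3 * cos(th), ctr[2] + 20e-3 * sin(th))
  p0 <- spherePressure(g, ctr + c(4e-3, -2e-3), 5e-3, 1, edge_width = 1e-3)
  dt <- maxStableDt(med)
  rec <- propagate(p0, med, ring, 45e-6, dt)
  sino <- sinogram(do.call(rbind, lapply(rec, function(t) t@samples)), dt)
  arr <- transducerArray(cbind(ring, 0), element_size = 1e-3,
                         sub_pitch = 1e-3, normal = c(1, 0, 0))
  list(g = g, med = med, p0 = p0, sino = sino, arr = arr, th = th)
})

## brute-force gamma oracle: exhaustive search over every voxel pair
gammaBruteForce <- function(ref, tst, crit, spacing_mm) {
  dims <- dim(ref)
  d <- length(dims)
  coords <- arrayInd(seq_along(ref), dims)
  sp <- matrix(rep(spacing_mm, each = nrow(coords)), ncol = d)
  phys <- (coords - 1) * sp
  dD <- crit@delta_dose * max(ref)
  scored <- ref >= crit@low_dose_threshold * max(ref)
  g <- array(NA_real_, dims)
  tv <- as.vector(tst)
  for (i in which(scored)) {
    dist2 <- rowSums((phys - matrix(phys[i, ], nrow(phys), d, byrow = TRUE))^2)
    g2 <- dist2 / crit@delta_d^2 + ((ref[i] - tv) / dD)^2
    g[i] <- sqrt(min(g2))
  }
  list(gamma = g, pass_rate = mean(g[scored] <= 1 + 1e-9))
}

## smooth random non-negative volume (for gamma equality tests)
randomSmoothVolume <- function(dims, seed) {
  set.seed(seed)
  v <- array(runif(prod(dims)), dims)
  for (a in seq_along(dims)) {
    k <- dims[a]
    sm <- outer(seq_len(k), seq_len(k), function(i, j) exp(-(i - j)^2 / 4))
    sm <- sm / rowSums(sm)
    m <- matrix(aperm(v, c(a, setdiff(seq_along(dims), a))), nrow = k)
    m <- sm %*% m
    v <- aperm(array(m, dims[c(a, setdiff(seq_along(dims), a))]),
               order(c(a, setdiff(seq_along(dims), a))))
  }
  v / max(v)
}
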
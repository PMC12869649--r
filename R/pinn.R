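## Physics-informed enhancement network.
##
## A compact additive-skip convolutional encoder-decoder (U-Net family, 2D
## or 3D) maps the time-reversal reconstruction p_rec to a prediction of the
## initial pressure p0.  Training minimises the dual objective
##   L = lambda1 * mean|N(p_rec) - p0|^2  +  lambda2 * mean|F(N(p_rec)) - S_m|^2
## where F is the digital-twin forward operator.  No deep-learning framework
## is used: forward and backward passes are written directly on top of BLAS
## matrix products, and the physics term back-propagates through the exact
## discrete adjoint of F, so gradients are exact to machine precision.

#' Network architecture configuration
#'
#' @param shape spatial input shape (2D or 3D), divisible by 2^(depth-1).
#' @param depth number of resolution levels (default 2).
#' @param base_channels feature maps at the first level (default 8).
#' @param final_activation `"nonneg"` (output rectified to >= 0 at
#'   inference) or `"linear"` (raw network output, for ablation).
#' @return a [NetworkConfig].
#' @export
networkConfig <- function(shape, depth = 2L, base_channels = 8L,
                          final_activation = "nonneg") {
  new("NetworkConfig", depth = as.integer(depth),
      base_channels = as.integer(base_channels), shape = as.integer(shape),
      final_activation = final_activation)
}

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param lambda1 image-domain loss weight (default 1).
#' @param lambda2 sinogram-domain physics loss weight; `NA` (default)
#'   auto-balances it once at epoch 0 so both terms start at the same
#'   magnitude.
#' @param lr learning rate of the Adam optimiser (default 1e-3).
#' @param batch_size minibatch size (default 4).
#' @param seed integer seed controlling init and batching.
#' @param normalization per-sample scale policy: `"max"` or `"none"`.
#' @return a [TrainConfig].
#' @export
trainConfig <- function(epochs = 30L, lambda1 = 1, lambda2 = NA_real_,
                        lr = 1e-3, batch_size = 4L, seed = 1L,
                        normalization = "max") {
  new("TrainConfig", lambda1 = lambda1, lambda2 = lambda2, lr = lr,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      seed = as.integer(seed), normalization = normalization)
}

#' Bundle a training sample
#'
#' @param p_rec time-reversal reconstruction (network input).
#' @param s_m measured sinogram (physics-loss target).
#' @param p0 ground-truth initial pressure, or NULL for self-supervised
#'   samples (usable when lambda1 = 0 or mixed into a dataset).
#' @param normalization scale policy; `"max"` stores max|p_rec| as the scale.
#' @return a [TrainingSample].
#' @export
trainingSample <- function(p_rec, s_m, p0 = NULL, normalization = "max") {
  scale <- if (normalization == "max") max(abs(p_rec@values)) else 1
  if (!is.finite(scale) || scale <= 0) scale <- 1
  new("TrainingSample", p_rec = p_rec, p0 = p0, s_m = s_m, scale = scale)
}

## ---- array plumbing -------------------------------------------------------

## shift the spatial axes of a (spatial..., C) array, zero padding
shiftFeat <- function(x, off) {
  dims <- dim(x)
  d <- length(dims) - 1L
  out <- array(0, dims)
  src <- vector("list", d); dst <- vector("list", d)
  for (a in seq_len(d)) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(dims[a] - o); dst[[a]] <- src[[a]] + o }
    else { src[[a]] <- seq.int(1 - o, dims[a]); dst[[a]] <- seq_len(dims[a] + o) }
    if (length(src[[a]]) == 0) return(out)
  }
  if (d == 2L) out[dst[[1]], dst[[2]], ] <- x[src[[1]], src[[2]], , drop = FALSE]
  else out[dst[[1]], dst[[2]], dst[[3]], ] <-
    x[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  out
}

## precomputed geometry per resolution level
netGeometry <- function(shape, depth) {
  d <- length(shape)
  levels <- vector("list", depth)
  sp <- shape
  for (l in seq_len(depth)) {
    npix <- prod(sp)
    lev <- list(sp = sp, npix = npix)
    if (l < depth) {
      coarse <- sp %/% 2L
      Fidx <- array(seq_len(npix), sp)
      corners <- as.matrix(expand.grid(rep(list(0:1), d)))
      kids <- matrix(0L, prod(coarse), nrow(corners))
      ci <- lapply(coarse, seq_len)
      for (j in seq_len(nrow(corners))) {
        coords <- lapply(seq_len(d), function(a) 2L * ci[[a]] - 1L + corners[j, a])
        kids[, j] <- as.vector(do.call(`[`, c(list(Fidx), coords)))
      }
      Cidx <- array(seq_len(prod(coarse)), coarse)
      up_coords <- lapply(seq_len(d), function(a) ceiling(seq_len(sp[a]) / 2))
      upmap <- as.vector(do.call(`[`, c(list(Cidx), up_coords)))
      lev$kids <- kids
      lev$upmap <- upmap
      sp <- coarse
    }
    levels[[l]] <- lev
  }
  offsets <- as.matrix(expand.grid(rep(list(-1:1), d)))
  list(levels = levels, offsets = offsets, d = d)
}

## ---- conv primitives ------------------------------------------------------

convInit <- function(c_in, c_out, n_off) {
  fan_in <- c_in * n_off
  list(W = lapply(seq_len(n_off), function(o)
    matrix(rnorm(c_in * c_out, sd = sqrt(2 / fan_in)), c_in, c_out)),
    b = numeric(c_out))
}

conv1Init <- function(c_in, c_out) {
  list(W = list(matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)),
       b = numeric(c_out))
}

## x: (spatial..., C_in) array; returns (spatial..., C_out)
convFwd <- function(x, layer, geom) {
  dims <- dim(x)
  sp <- dims[-length(dims)]
  npix <- prod(sp)
  c_out <- length(layer$b)
  n_off <- length(layer$W)
  out <- matrix(rep(layer$b, each = npix), npix, c_out)
  if (n_off == 1L) {
    out <- out + matrix(x, npix) %*% layer$W[[1]]
  } else {
    for (o in seq_len(n_off)) {
      xs <- shiftFeat(x, geom$offsets[o, ])
      out <- out + matrix(xs, npix) %*% layer$W[[o]]
    }
  }
  array(out, c(sp, c_out))
}

## backward: returns list(dx, dW, db)
convBwd <- function(x, dout, layer, geom) {
  dims <- dim(x)
  sp <- dims[-length(dims)]
  npix <- prod(sp)
  c_in <- dims[length(dims)]
  n_off <- length(layer$W)
  dom <- matrix(dout, npix)
  db <- colSums(dom)
  dW <- vector("list", n_off)
  dx <- array(0, dims)
  if (n_off == 1L) {
    dW[[1]] <- crossprod(matrix(x, npix), dom)
    dx <- array(dom %*% t(layer$W[[1]]), dims)
  } else {
    for (o in seq_len(n_off)) {
      off <- geom$offsets[o, ]
      xs <- shiftFeat(x, off)
      dW[[o]] <- crossprod(matrix(xs, npix), dom)
      contrib <- array(dom %*% t(layer$W[[o]]), c(sp, c_in))
      dx <- dx + shiftFeat(contrib, -off)
    }
  }
  list(dx = dx, dW = dW, db = db)
}

poolFwd <- function(x, lev) {
  dims <- dim(x)
  npix_c <- nrow(lev$kids)
  C <- dims[length(dims)]
  xm <- matrix(x, prod(dims[-length(dims)]))
  acc <- matrix(0, npix_c, C)
  for (j in seq_len(ncol(lev$kids))) acc <- acc + xm[lev$kids[, j], , drop = FALSE]
  array(acc / ncol(lev$kids), c(dims[-length(dims)] %/% 2L, C))
}

poolBwd <- function(dcoarse, lev, sp_fine) {
  C <- dim(dcoarse)[length(dim(dcoarse))]
  dm <- matrix(dcoarse, nrow(lev$kids)) / ncol(lev$kids)
  out <- matrix(0, prod(sp_fine), C)
  for (j in seq_len(ncol(lev$kids))) out[lev$kids[, j], ] <- out[lev$kids[, j], ] + dm
  array(out, c(sp_fine, C))
}

upFwd <- function(x, lev) {
  C <- dim(x)[length(dim(x))]
  xm <- matrix(x, nrow = prod(dim(x)[-length(dim(x))]))
  array(xm[lev$upmap, , drop = FALSE], c(lev$sp, C))
}

upBwd <- function(dfine, lev) {
  C <- dim(dfine)[length(dim(dfine))]
  dm <- matrix(dfine, nrow = prod(lev$sp))
  acc <- rowsum(dm, lev$upmap, reorder = TRUE)
  array(acc, c(lev$sp %/% 2L, C))
}

## leaky rectifier: keeps a small negative-slope gradient so units cannot die
relu <- function(x) ifelse(x > 0, x, 0.1 * x)
reluGrad <- function(pre) ifelse(pre > 0, 1, 0.1)

## ---- network construction / forward / backward ---------------------------

initNetwork <- function(net_cfg, seed) {
  set.seed(seed)
  geom <- netGeometry(net_cfg@shape, net_cfg@depth)
  n_off <- nrow(geom$offsets)
  base <- net_cfg@base_channels
  ch <- base * 2L^(seq_len(net_cfg@depth) - 1L)
  params <- list()
  for (l in seq_len(net_cfg@depth)) {
    c_in <- if (l == 1L) 1L else ch[l - 1L]
    params[[paste0("enc", l, "a")]] <- convInit(c_in, ch[l], n_off)
    params[[paste0("enc", l, "b")]] <- convInit(ch[l], ch[l], n_off)
  }
  if (net_cfg@depth > 1L) {
    for (l in seq.int(net_cfg@depth - 1L, 1L)) {
      params[[paste0("up", l)]] <- convInit(ch[l + 1L], ch[l], n_off)
      params[[paste0("dec", l)]] <- convInit(ch[l], ch[l], n_off)
    }
  }
  params[["head"]] <- conv1Init(ch[1], 1L)
  ## direct input passthrough initialised at 1: the network starts near the
  ## identity map and learns a correction, which keeps gradients alive
  params[["inskip"]] <- list(W = list(matrix(1, 1, 1)), b = numeric(0))
  list(params = params, geom = geom, cfg = net_cfg)
}

## forward pass; returns prediction array (spatial) and cache for backprop
netForward <- function(net, x_spatial) {
  cfg <- net$cfg
  geom <- net$geom
  depth <- cfg@depth
  P <- net$params
  cache <- list(enc_in = list(), enc_mid = list(), enc_out = list(),
                pre_a = list(), pre_b = list())
  x <- array(x_spatial, c(dim(x_spatial), 1L))
  for (l in seq_len(depth)) {
    cache$enc_in[[l]] <- x
    za <- convFwd(x, P[[paste0("enc", l, "a")]], geom)
    cache$pre_a[[l]] <- za
    ha <- relu(za)
    cache$enc_mid[[l]] <- ha
    zb <- convFwd(ha, P[[paste0("enc", l, "b")]], geom)
    cache$pre_b[[l]] <- zb
    hb <- relu(zb)
    cache$enc_out[[l]] <- hb
    if (l < depth) x <- poolFwd(hb, geom$levels[[l]])
  }
  h <- cache$enc_out[[depth]]
  cache$up_in <- list(); cache$pre_up <- list(); cache$sum_in <- list()
  cache$pre_dec <- list()
  if (depth > 1L) {
    for (l in seq.int(depth - 1L, 1L)) {
      cache$up_in[[l]] <- h
      u <- upFwd(h, geom$levels[[l]])
      zu <- convFwd(u, P[[paste0("up", l)]], geom)
      cache$pre_up[[l]] <- zu
      hu <- relu(zu) + cache$enc_out[[l]]   # additive skip connection
      cache$sum_in[[l]] <- hu
      zd <- convFwd(hu, P[[paste0("dec", l)]], geom)
      cache$pre_dec[[l]] <- zd
      h <- relu(zd)
    }
  }
  cache$head_in <- h
  cache$x_in <- x_spatial
  zh <- convFwd(h, P[["head"]], geom) +
    P[["inskip"]]$W[[1]][1, 1] * array(x_spatial, dim = c(dim(x_spatial), 1L))
  cache$pre_head <- zh
  ## the head is linear during training (a saturating non-negativity
  ## activation starves the gradient when the mostly-zero background pushes
  ## the output down); the "nonneg" contract is enforced at inference
  dims <- dim(zh)
  list(y = array(zh, dims[-length(dims)]), cache = cache)
}

## backward pass; dy is gradient w.r.t. the (spatial) prediction
netBackward <- function(net, dy_spatial, cache) {
  cfg <- net$cfg
  geom <- net$geom
  depth <- cfg@depth
  P <- net$params
  grads <- list()
  dy <- array(dy_spatial, c(dim(dy_spatial), 1L))
  bw <- convBwd(cache$head_in, dy, P[["head"]], geom)
  grads[["head"]] <- list(dW = bw$dW, db = bw$db)
  grads[["inskip"]] <- list(dW = list(matrix(sum(as.vector(dy) *
                                               as.vector(cache$x_in)), 1, 1)),
                            db = numeric(0))
  dh <- bw$dx
  if (depth > 1L) {
    for (l in seq_len(depth - 1L)) {
      dzd <- dh * reluGrad(cache$pre_dec[[l]])
      bw <- convBwd(cache$sum_in[[l]], dzd, P[[paste0("dec", l)]], geom)
      grads[[paste0("dec", l)]] <- list(dW = bw$dW, db = bw$db)
      dhu <- bw$dx
      ## additive skip: gradient flows to both the up path and enc_out[l]
      dzu <- dhu * reluGrad(cache$pre_up[[l]])
      bw <- convBwd(upFwd(cache$up_in[[l]], geom$levels[[l]]), dzu,
                    P[[paste0("up", l)]], geom)
      grads[[paste0("up", l)]] <- list(dW = bw$dW, db = bw$db)
      dup <- upBwd(bw$dx, geom$levels[[l]])
      ## stash the skip gradient to merge during the encoder sweep
      grads[[paste0(".skip", l)]] <- dhu
      dh <- dup
    }
  }
  ## encoder sweep from the bottom level back to the input
  dhb <- dh  # gradient w.r.t. enc_out[depth]
  for (l in seq.int(depth, 1L)) {
    if (l < depth) {
      dhb <- poolBwd(dhb, geom$levels[[l]], dim(cache$enc_out[[l]])[
        -length(dim(cache$enc_out[[l]]))])
      dhb <- dhb + grads[[paste0(".skip", l)]]
      grads[[paste0(".skip", l)]] <- NULL
    }
    dzb <- dhb * reluGrad(cache$pre_b[[l]])
    bw <- convBwd(cache$enc_mid[[l]], dzb, P[[paste0("enc", l, "b")]], geom)
    grads[[paste0("enc", l, "b")]] <- list(dW = bw$dW, db = bw$db)
    dza <- bw$dx * reluGrad(cache$pre_a[[l]])
    bw <- convBwd(cache$enc_in[[l]], dza, P[[paste0("enc", l, "a")]], geom)
    grads[[paste0("enc", l, "a")]] <- list(dW = bw$dW, db = bw$db)
    dhb <- bw$dx
  }
  grads
}

## ---- losses ---------------------------------------------------------------

#' Image-domain (pressure) loss
#'
#' Mean squared voxel difference between prediction and target.
#'
#' @param pred,target [PressureVolume]s or arrays of the same shape.
#' @return scalar.
#' @export
pressureLoss <- function(pred, target) {
  p <- volValues(pred); t <- volValues(target)
  if (!identical(dim(p), dim(t))) stop("shape mismatch")
  mean((p - t)^2)
}

#' Sinogram-domain physics loss
#'
#' Pushes the prediction through the digital-twin forward operator and
#' returns the mean squared difference to the measured sinogram.
#'
#' @param pred a [PressureVolume] on the twin grid.
#' @param s_m measured [Sinogram].
#' @param twin a [TwinConfig] consistent with `s_m`.
#' @return scalar.
#' @export
sinogramLoss <- function(pred, s_m, twin) {
  S <- forwardOperator(pred, twin)
  if (!identical(dim(S@data), dim(s_m@data)))
    stop("sinogram geometry mismatch between twin and s_m")
  mean((S@data - s_m@data)^2)
}

#' Combined training loss
#'
#' @param loss_p image-domain loss value.
#' @param loss_s sinogram-domain loss value.
#' @param lambda1,lambda2 non-negative weights.
#' @return lambda1 * loss_p + lambda2 * loss_s.
#' @export
totalLoss <- function(loss_p, loss_s, lambda1, lambda2) {
  if (lambda1 < 0 || lambda2 < 0) stop("weights must be >= 0")
  lambda1 * loss_p + lambda2 * loss_s
}

## ---- optimiser ------------------------------------------------------------

adamInit <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adamStep <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    for (k in seq_along(params[[nm]]$W)) {
      state$m[[nm]]$W[[k]] <- beta1 * state$m[[nm]]$W[[k]] + (1 - beta1) * g$dW[[k]]
      state$v[[nm]]$W[[k]] <- beta2 * state$v[[nm]]$W[[k]] + (1 - beta2) * g$dW[[k]]^2
      mhat <- state$m[[nm]]$W[[k]] / (1 - beta1^t)
      vhat <- state$v[[nm]]$W[[k]] / (1 - beta2^t)
      params[[nm]]$W[[k]] <- params[[nm]]$W[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state$m[[nm]]$b <- beta1 * state$m[[nm]]$b + (1 - beta1) * g$db
    state$v[[nm]]$b <- beta2 * state$v[[nm]]$b + (1 - beta2) * g$db^2
    mhat <- state$m[[nm]]$b / (1 - beta1^t)
    vhat <- state$v[[nm]]$b / (1 - beta2^t)
    params[[nm]]$b <- params[[nm]]$b - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## per-sample loss and parameter gradients
sampleLossGrad <- function(net, smp, tp, lambda1, lambda2, want_grad = TRUE) {
  x <- smp$x
  fw <- netForward(net, x)
  yhat <- fw$y
  n_vox <- length(yhat)
  has_p0 <- !is.null(smp$t)
  lp <- if (has_p0) mean((yhat - smp$t)^2) else 0
  dy <- array(0, dim(yhat))
  if (has_p0 && lambda1 > 0) dy <- dy + lambda1 * 2 * (yhat - smp$t) / n_vox
  ls <- 0
  if (!is.null(tp) && (lambda2 > 0 || !want_grad)) {
    S <- twinForwardRaw(yhat, tp)
    r <- S - smp$s
    ls <- mean(r^2)
    if (want_grad && lambda2 > 0) {
      dS <- 2 * r / length(r)
      dy <- dy + lambda2 * array(twinAdjointRaw(dS, tp), dim(yhat))
    }
  }
  grads <- if (want_grad) netBackward(net, dy, fw$cache) else NULL
  list(lp = lp, ls = ls, grads = grads)
}

accumulateGrads <- function(acc, g, w = 1) {
  if (is.null(acc)) {
    for (nm in names(g)) {
      g[[nm]]$dW <- lapply(g[[nm]]$dW, function(x) x * w)
      g[[nm]]$db <- g[[nm]]$db * w
    }
    return(g)
  }
  for (nm in names(g)) {
    for (k in seq_along(g[[nm]]$dW))
      acc[[nm]]$dW[[k]] <- acc[[nm]]$dW[[k]] + w * g[[nm]]$dW[[k]]
    acc[[nm]]$db <- acc[[nm]]$db + w * g[[nm]]$db
  }
  acc
}

## ---- training / inference -------------------------------------------------

#' Train the physics-informed enhancement network
#'
#' Seeded, deterministic-given-seed training of the enhancement network
#' under the dual image/sinogram loss.  Each sample is normalised by its
#' stored scale (inputs, targets and sinograms alike -- every stage of the
#' forward chain is linear, so one scalar serves all three).  With
#' `lambda2 = NA` the physics weight is set once, before the first update,
#' to `lambda1 * loss_p / loss_s` evaluated at initialisation, so both terms
#' start at the same magnitude; with a supplied `lambda2` (e.g. 0, the plain
#' supervised baseline) it is used as given.
#'
#' @param dataset list of [TrainingSample]s.
#' @param net_cfg a [NetworkConfig].
#' @param train_cfg a [TrainConfig].
#' @param twin a [TwinConfig], required when the physics term is active.
#' @param init_params optional parameter list to warm-start from (used by
#'   [fineTune()]); default random init from the seed.
#' @return list with `model` (weights + configs + normalisation policy) and
#'   `history` (data.frame: epoch, loss_p, loss_s, total).
#' @export
trainEnhancer <- function(dataset, net_cfg, train_cfg, twin = NULL,
                          init_params = NULL) {
  if (length(dataset) == 0) stop("empty dataset")
  shp <- net_cfg@shape
  for (smp in dataset) {
    if (!identical(as.integer(dim(smp@p_rec@values)), shp))
      stop("sample shape inconsistent with network configuration")
  }
  lambda1 <- train_cfg@lambda1
  lambda2 <- train_cfg@lambda2
  auto_l2 <- is.na(lambda2)
  if (auto_l2 && is.null(twin)) stop("auto lambda2 requires a twin")
  if (!auto_l2 && lambda2 > 0 && is.null(twin))
    stop("lambda2 > 0 requires a twin")
  tp <- if (!is.null(twin)) twinPlan(twin) else NULL
  ## pre-normalised plain-array views of the samples
  samples <- lapply(dataset, function(smp) {
    list(x = smp@p_rec@values / smp@scale,
         t = if (!is.null(smp@p0)) smp@p0@values / smp@scale else NULL,
         s = smp@s_m@data / smp@scale)
  })
  net <- initNetwork(net_cfg, train_cfg@seed)
  if (!is.null(init_params)) net$params <- init_params
  if (auto_l2) {
    lp0 <- 0; ls0 <- 0; n_p <- 0
    for (smp in samples) {
      r <- sampleLossGrad(net, smp, tp, 1, 1, want_grad = FALSE)
      if (!is.null(smp$t)) { lp0 <- lp0 + r$lp; n_p <- n_p + 1 }
      ls0 <- ls0 + r$ls
    }
    lp0 <- if (n_p > 0) lp0 / n_p else 0
    ls0 <- ls0 / length(samples)
    lambda2 <- if (ls0 > 0 && lp0 > 0) lambda1 * lp0 / ls0 else 1
  }
  state <- list(m = adamInit(net$params), v = adamInit(net$params))
  history <- data.frame()
  tstep <- 0
  n <- length(samples)
  for (epoch in seq_len(train_cfg@epochs)) {
    ord <- sample.int(n)
    ep_lp <- 0; ep_ls <- 0; n_p <- 0
    for (start in seq(1, n, by = train_cfg@batch_size)) {
      idx <- ord[start:min(n, start + train_cfg@batch_size - 1L)]
      acc <- NULL
      for (i in idx) {
        r <- sampleLossGrad(net, samples[[i]], tp, lambda1, lambda2)
        if (!is.finite(r$lp) || !is.finite(r$ls))
          stop(sprintf("non-finite loss at epoch %d (sample %d): loss_p=%g loss_s=%g",
                       epoch, i, r$lp, r$ls))
        if (!is.null(samples[[i]]$t)) { ep_lp <- ep_lp + r$lp; n_p <- n_p + 1 }
        ep_ls <- ep_ls + r$ls
        acc <- accumulateGrads(acc, r$grads, 1 / length(idx))
      }
      tstep <- tstep + 1
      upd <- adamStep(net$params, acc, state, train_cfg@lr, tstep)
      net$params <- upd$params
      state <- upd$state
    }
    lp <- if (n_p > 0) ep_lp / n_p else 0
    ls <- ep_ls / n
    history <- rbind(history, data.frame(
      epoch = epoch, loss_p = lp, loss_s = ls,
      total = totalLoss(lp, ls, lambda1, lambda2)))
  }
  model <- list(params = net$params, net_cfg = net_cfg,
                train_cfg = train_cfg, lambda1 = lambda1, lambda2 = lambda2,
                normalization = train_cfg@normalization,
                package_version = as.character(utils::packageVersion(
                  "radiacoustics")))
  list(model = model, history = history)
}

#' Apply the trained enhancement network
#'
#' Normalises the input by its own scale (per the model's stored policy),
#' runs the network and re-applies the scale, so the output lives on the
#' input's physical scale.  With the `"nonneg"` final activation the output
#' is non-negative everywhere.
#'
#' @param p_rec a [PressureVolume] matching the model's input shape.
#' @param model trained model from [trainEnhancer()].
#' @return a [PressureVolume] with role `"p_pred"`.
#' @export
enhance <- function(p_rec, model) {
  if (!identical(as.integer(dim(p_rec@values)), model$net_cfg@shape))
    stop("input shape does not match the trained network")
  scale <- if (model$normalization == "max") max(abs(p_rec@values)) else 1
  if (!is.finite(scale) || scale <= 0) scale <- 1
  net <- list(params = model$params, geom = netGeometry(model$net_cfg@shape,
                                                        model$net_cfg@depth),
              cfg = model$net_cfg)
  y <- netForward(net, p_rec@values / scale)$y
  if (model$net_cfg@final_activation == "nonneg") y <- pmax(y, 0)
  pressureVolume(y * scale, p_rec@grid, role = "p_pred")
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, architecture and training configuration
#' and the normalisation policy, so training can resume (fine-tuning on a
#' new catalog) or inference can run elsewhere.
#'
#' @param model trained model (from [trainEnhancer()]).
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Continue training from a checkpoint
#'
#' Fine-tuning entry point: reloads the architecture, re-seeds from the new
#' training configuration and continues optimisation on a new dataset
#' starting from the checkpointed weights.
#'
#' @param model checkpointed model.
#' @param dataset new list of [TrainingSample]s.
#' @param train_cfg new [TrainConfig].
#' @param twin a [TwinConfig] for the physics term.
#' @return as [trainEnhancer()].
#' @export
fineTune <- function(model, dataset, train_cfg, twin = NULL) {
  trainEnhancer(dataset, model$net_cfg, train_cfg, twin,
                init_params = model$params)
}
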
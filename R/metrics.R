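## Dosimetric and image-quality evaluation: gamma index (distance-to-
## agreement + dose difference), global SSIM, and PSNR.

#' Gamma-index acceptance criteria
#'
#' Defaults are the clinical 3 mm / 3% criteria with a 10% low-dose
#' threshold and global (max reference dose) normalisation.
#'
#' @param delta_d distance-to-agreement (mm).
#' @param delta_dose dose criterion as a fraction of max reference dose.
#' @param low_dose_threshold exclude reference voxels below this fraction of
#'   the max reference dose.
#' @return a [GammaCriteria].
#' @export
gammaCriteria <- function(delta_d = 3, delta_dose = 0.03,
                          low_dose_threshold = 0.1) {
  new("GammaCriteria", delta_d = delta_d, delta_dose = delta_dose,
      low_dose_threshold = low_dose_threshold)
}

## index a d-dimensional array with a list of per-axis index vectors
subArray <- function(x, ix) do.call(`[`, c(list(x), ix))

volValues <- function(x) if (is(x, "DoseVolume") || is(x, "PressureVolume"))
  x@values else as.array(x)

volSpacingMM <- function(x, default = 1) {
  if (is(x, "DoseVolume") || is(x, "PressureVolume")) x@grid@spacing * 1e3
  else rep(default, length(dim(as.array(x))))
}

## enumerate integer voxel offsets sorted by physical distance
offsetTable <- function(maxoff, spacing_mm) {
  d <- length(maxoff)
  offs <- as.matrix(expand.grid(lapply(seq_len(d), function(a)
    seq.int(-maxoff[a], maxoff[a]))))
  dist2 <- drop(offs^2 %*% spacing_mm^2)
  ord <- order(dist2)
  list(offs = offs[ord, , drop = FALSE], dist2 = dist2[ord])
}

## shift an array by an integer offset, padding with NA
shiftPad <- function(x, off) {
  dims <- dim(x)
  d <- length(dims)
  out <- array(NA_real_, dims)
  src <- vector("list", d); dst <- vector("list", d)
  for (a in seq_len(d)) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(dims[a] - o); dst[[a]] <- src[[a]] + o }
    else { src[[a]] <- seq.int(1 - o, dims[a]); dst[[a]] <- seq_len(dims[a] + o) }
    if (length(src[[a]]) == 0) return(out)
  }
  if (d == 1L) out[dst[[1]]] <- x[src[[1]]]
  else if (d == 2L) out[dst[[1]], dst[[2]]] <- x[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Gamma-index map and pass rate
#'
#' For every reference voxel above the low-dose threshold, gamma is the
#' minimum over evaluated positions of
#' sqrt(dist^2 / delta_d^2 + dose_diff^2 / delta_D^2), with the dose
#' criterion delta_D taken globally as `delta_dose * max(reference)`.  The
#' search is an exact pruned exhaustive search on the native voxel grid:
#' offsets are visited in order of increasing distance and enumeration stops
#' once the distance term alone exceeds every remaining voxel's current
#' minimum, so the result equals a brute-force search over all voxels.
#' A voxel passes when gamma <= 1.
#'
#' @param d_gt reference dose ([DoseVolume] or array).
#' @param d_pred evaluated dose on the same grid.
#' @param crit a [GammaCriteria].
#' @return list with `gamma` (array, NA below threshold), `pass_rate`
#'   (fraction of scored voxels with gamma <= 1) and `n_scored`.
#' @export
gammaMap <- function(d_gt, d_pred, crit = gammaCriteria()) {
  ref <- volValues(d_gt)
  tst <- volValues(d_pred)
  if (!identical(dim(ref), dim(tst))) stop("volumes must share a grid")
  if (max(ref) <= 0) stop("reference dose has no positive values")
  spacing <- volSpacingMM(d_gt)
  dims <- dim(ref)
  d <- length(dims)
  dD <- crit@delta_dose * max(ref)
  scored <- ref >= crit@low_dose_threshold * max(ref)
  ## start with the zero-offset gamma^2, then search outward
  g2 <- ((ref - tst) / dD)^2
  maxoff <- pmin(dims - 1L, ceiling(crit@delta_d * sqrt(max(g2[scored])) /
                                    spacing))
  tab <- offsetTable(maxoff, spacing)
  worst <- max(g2[scored])
  for (i in seq_len(nrow(tab$offs))) {
    if (all(tab$offs[i, ] == 0)) next
    dterm <- tab$dist2[i] / crit@delta_d^2
    if (dterm >= worst) break
    shifted <- shiftPad(tst, tab$offs[i, ])
    cand <- dterm + ((ref - shifted) / dD)^2
    upd <- !is.na(cand) & cand < g2
    g2[upd] <- cand[upd]
    worst <- max(g2[scored])
  }
  gamma <- sqrt(g2)
  gamma[!scored] <- NA_real_
  ## boundary cases (gamma exactly 1) pass; tolerate float rounding
  list(gamma = gamma, pass_rate = mean(gamma[scored] <= 1 + 1e-9),
       n_scored = sum(scored))
}

#' Global structural similarity index
#'
#' Single-window SSIM computed from the global means, variances and
#' covariance of the two images (population moments), with stabilisers
#' c1 = (k1 L)^2, c2 = (k2 L)^2.  `dynamic_range` L defaults to the maximum
#' of the reference image.  A sliding-window mean variant is available via
#' `windowed` (cubic window of edge `window` voxels).
#'
#' @param ref reference volume (array or volume object).
#' @param test test volume, same shape.
#' @param k1,k2 stabiliser constants (defaults 0.01 and 0.03).
#' @param dynamic_range L; default `max(ref)`.
#' @param windowed if TRUE, mean of local SSIM over a sliding window.
#' @param window window edge length in voxels (windowed variant).
#' @return SSIM scalar in [-1, 1].
#' @export
ssimIndex <- function(ref, test, k1 = 0.01, k2 = 0.03, dynamic_range = NULL,
                      windowed = FALSE, window = 7L) {
  r <- volValues(ref); i <- volValues(test)
  if (!identical(dim(r), dim(i))) stop("volumes must share a shape")
  if (is.null(dynamic_range)) dynamic_range <- max(r)
  if (dynamic_range <= 0) stop("dynamic_range must be > 0")
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  comp <- function(rv, iv) {
    mr <- mean(rv); mi <- mean(iv)
    vr <- mean((rv - mr)^2); vi <- mean((iv - mi)^2)
    cv <- mean((rv - mr) * (iv - mi))
    ((2 * mr * mi + c1) * (2 * cv + c2)) /
      ((mr^2 + mi^2 + c1) * (vr + vi + c2))
  }
  if (!windowed) return(comp(as.vector(r), as.vector(i)))
  dims <- dim(r)
  d <- length(dims)
  starts <- lapply(seq_len(d), function(a)
    seq(1L, max(1L, dims[a] - window + 1L), by = max(1L, window %/% 2)))
  gridpts <- as.matrix(expand.grid(starts))
  vals <- apply(gridpts, 1, function(s0) {
    ix <- lapply(seq_len(d), function(a)
      s0[a]:min(dims[a], s0[a] + window - 1L))
    rv <- subArray(r, ix)
    iv <- subArray(i, ix)
    comp(as.vector(rv), as.vector(iv))
  })
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `mode = "rmse"` (default) reads the prefactor as sqrt(voxel count), i.e.
#' the standard PSNR = 20 log10(max|ref| / RMSE).  `mode = "literal"`
#' multiplies by the full voxel count instead (the formula as sometimes
#' printed with an M x N prefactor); both are provided for comparison.
#' Identical images return `Inf`.
#'
#' @param ref reference volume; must have a nonzero maximum.
#' @param test test volume, same shape.
#' @param mode `"rmse"` or `"literal"`.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, mode = c("rmse", "literal")) {
  mode <- match.arg(mode)
  r <- volValues(ref); i <- volValues(test)
  if (!identical(dim(r), dim(i))) stop("volumes must share a shape")
  if (max(abs(r)) == 0) stop("reference volume is identically zero")
  l2 <- sqrt(sum((i - r)^2))
  if (l2 == 0) return(Inf)
  pref <- if (mode == "rmse") sqrt(length(r)) else length(r)
  20 * log10(pref * max(abs(r)) / l2)
}

#' Evaluate reconstruction methods against ground truth
#'
#' Computes SSIM, PSNR and gamma pass rate for each method on each sample
#' and aggregates mean and standard deviation per method.
#'
#' @param samples list; each element is a named list with `p0` (ground
#'   truth) plus one entry per method (volumes on the same grid).
#' @param crit a [GammaCriteria].
#' @return list with `per_sample` (data.frame) and `summary` (data.frame of
#'   mean and sd per method and metric).
#' @export
evaluateMethods <- function(samples, crit = gammaCriteria()) {
  if (length(samples) == 0) stop("empty sample list")
  methods <- setdiff(names(samples[[1]]), "p0")
  rows <- list()
  for (si in seq_along(samples)) {
    smp <- samples[[si]]
    for (m in methods) {
      gm <- gammaMap(smp$p0, smp[[m]], crit)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = si, method = m,
        ssim = ssimIndex(smp$p0, smp[[m]]),
        psnr = psnr(smp$p0, smp[[m]]),
        gamma_pass = gm$pass_rate)
    }
  }
  per_sample <- do.call(rbind, rows)
  agg <- lapply(split(per_sample, per_sample$method), function(df) {
    data.frame(method = df$method[1],
               ssim_mean = mean(df$ssim), ssim_sd = sd0(df$ssim),
               psnr_mean = mean(df$psnr), psnr_sd = sd0(df$psnr),
               gamma_pass_mean = mean(df$gamma_pass),
               gamma_pass_sd = sd0(df$gamma_pass))
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(per_sample = per_sample, summary = summary)
}

sd0 <- function(x) if (length(x) <= 1L) 0 else sd(x)

#' Write a metric report to CSV and JSON
#'
#' @param report result of [evaluateMethods()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeMetricReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "metrics_per_sample.csv")
  utils::write.csv(report$per_sample, csv, row.names = FALSE)
  csv2 <- file.path(dir, "metrics_summary.csv")
  utils::write.csv(report$summary, csv2, row.names = FALSE)
  js <- file.path(dir, "metrics.json")
  jsonlite::write_json(list(per_sample = report$per_sample,
                            summary = report$summary), js, digits = NA)
  invisible(c(csv, csv2, js))
}
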
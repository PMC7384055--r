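#' Rigid motion correction of an ASL series
#'
#' Integer-voxel translation correction: each volume is aligned to the
#' voxelwise median volume of the series by exhaustive search over shifts,
#' maximising the correlation between the shifted volume and the median.
#' Candidate shifts are visited in order of increasing magnitude, so a
#' volume that is already aligned keeps the identity transform; volumes with
#' zero variance also keep the identity transform. This simple correction is
#' adequate for the integer-voxel rigid motion of the phantom; it does not
#' attempt nonlinear or sub-voxel registration.
#'
#' @param series An `asl_series` object (>= 2 volumes).
#' @param max_shift Maximum translation searched per axis, in voxels; scalar
#'   or length 3.
#' @param n_passes Number of align-and-refine passes. The median of a
#'   motion-affected series is blurred along the motion axes, which can pull
#'   a correlation peak one voxel off; a second pass against the median of
#'   the realigned series removes this.
#' @return The series with aligned volumes; the estimated per-volume shifts
#'   (the corrections applied) are stored in `$shifts_estimated`.
#' @export
rigid_motion_correct <- function(series, max_shift = 3, n_passes = 2) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$data)
  if (d[4] < 2) stop("need at least two volumes", call. = FALSE)
  max_shift <- rep_len(as.integer(max_shift), 3)
  cand <- expand.grid(sx = -max_shift[1]:max_shift[1],
                      sy = -max_shift[2]:max_shift[2],
                      sz = -max_shift[3]:max_shift[3])
  cand <- cand[order(abs(cand$sx) + abs(cand$sy) + abs(cand$sz)), ]
  est <- matrix(0L, d[4], 3)
  for (pass in seq_len(n_passes)) {
    current <- series$data
    for (v in seq_len(d[4])) {
      current[, , , v] <- .shift_volume(series$data[, , , v], est[v, ])
    }
    ref_vec <- as.vector(apply(current, 1:3, stats::median))
    for (v in seq_len(d[4])) {
      vol <- series$data[, , , v]
      if (stats::sd(vol) == 0) next
      best <- est[v, ]
      best_cor <- -Inf
      for (i in seq_len(nrow(cand))) {
        s <- c(cand$sx[i], cand$sy[i], cand$sz[i])
        shifted <- .shift_volume(vol, s)
        cc <- suppressWarnings(stats::cor(as.vector(shifted), ref_vec))
        if (is.finite(cc) && cc > best_cor + 1e-12) {
          best_cor <- cc
          best <- s
        }
      }
      est[v, ] <- best
    }
  }
  # the absolute frame is unidentifiable from the data (any constant offset
  # of all shifts is self-consistent); anchor it so the net correction is
  # zero per axis
  est <- sweep(est, 2, round(apply(est, 2, stats::median)))
  out <- series$data
  for (v in seq_len(d[4])) {
    out[, , , v] <- .shift_volume(series$data[, , , v], est[v, ])
  }
  series$data <- out
  series$shifts_estimated <- est
  series
}

#' Pairwise label-control subtraction
#'
#' Subtracts each label volume from its immediately preceding control volume
#' (perfusion-positive sign convention), dropping the trailing pseudo-M0
#' volume.
#'
#' @param series An `asl_series` object with alternating control/label
#'   volumes followed by one pseudo-M0 volume.
#' @return An object of class `subtraction_stack`: a list with the 4-D
#'   difference array `dm` (one volume per pair) and `n_pairs`.
#' @export
pairwise_subtract <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  cond <- series$conditions
  nvol <- length(cond)
  n_pairs <- (nvol - 1) %/% 2
  expected <- c(rep(c("control", "label"), n_pairs), "m0")
  if (nvol < 3 || nvol %% 2 == 0 || !identical(cond, expected)) {
    stop("malformed series: expected alternating control/label pairs ",
         "followed by one pseudo-M0 volume", call. = FALSE)
  }
  d <- dim(series$data)
  dm <- array(0, c(d[1:3], n_pairs))
  for (r in seq_len(n_pairs)) {
    dm[, , , r] <- series$data[, , , 2L * r - 1L] - series$data[, , , 2L * r]
  }
  structure(list(dm = dm, n_pairs = n_pairs), class = "subtraction_stack")
}

#' Outlier rejection of subtraction images
#'
#' A pair is rejected when strictly more than `frac` of the voxels inside
#' the uterus mask deviate from the voxelwise temporal mean by strictly more
#' than `sd_thresh` temporal SDs. The voxelwise mean and sample SD are
#' computed once over all repetitions (single pass -- the criterion is not
#' re-evaluated after removals). With `sd_mode = "pooled"` a single SD
#' pooled over all uterus voxels replaces the voxelwise SD.
#'
#' @param stack A [pairwise_subtract()] result (>= 2 pairs).
#' @param uterus_mask Logical mask of the uterus region.
#' @param frac Maximum tolerated fraction of deviant voxels (default 0.2).
#' @param sd_thresh Deviation threshold in temporal SDs (default 1.5).
#' @param sd_mode `"voxelwise"` (default) or `"pooled"`.
#' @return Integer vector of kept pair indices, in order. The per-pair
#'   deviant-voxel fractions are attached as attribute `"deviant_frac"`.
#' @export
reject_outliers <- function(stack, uterus_mask, frac = 0.2, sd_thresh = 1.5,
                            sd_mode = c("voxelwise", "pooled")) {
  stopifnot(inherits(stack, "subtraction_stack"))
  sd_mode <- match.arg(sd_mode)
  R <- stack$n_pairs
  if (R < 2) stop("need at least two pairs for outlier rejection",
                  call. = FALSE)
  if (!any(uterus_mask)) stop("empty uterus mask", call. = FALSE)
  mat <- matrix(stack$dm, ncol = R)[as.vector(uterus_mask), , drop = FALSE]
  mu <- rowMeans(mat)
  dev <- abs(mat - mu)
  if (sd_mode == "voxelwise") {
    sdv <- sqrt(rowSums((mat - mu)^2) / (R - 1))
    thr <- sd_thresh * sdv
  } else {
    thr <- sd_thresh * sqrt(sum((mat - mu)^2) / (nrow(mat) * (R - 1)))
  }
  deviant_frac <- colMeans(dev > thr)
  kept <- which(deviant_frac <= frac)
  if (length(kept) == 0) {
    stop("all pairs rejected; review the rejection thresholds", call. = FALSE)
  }
  structure(kept, deviant_frac = deviant_frac)
}

#' Single M0 value from the pseudo-M0 image
#'
#' The pseudo-M0 images can show marked spatial heterogeneity (septa between
#' lobules), so a single high-percentile value over the whole-placenta ROI
#' is used as an estimate of the inflowing-blood signal: by default the 80th
#' percentile, with R's linear-interpolation convention (type 7).
#'
#' @param m0_volume The pseudo-M0 volume (3-D array).
#' @param roi_placenta Logical mask of the whole-placenta ROI (non-empty).
#' @param percentile Percentile in (0, 1); default 0.8.
#' @return The M0 scalar (> 0).
#' @export
estimate_m0 <- function(m0_volume, roi_placenta, percentile = 0.8) {
  vals <- m0_volume[roi_placenta]
  if (length(vals) == 0) stop("empty placenta ROI", call. = FALSE)
  m0 <- stats::quantile(vals, percentile, type = 7, names = FALSE)
  if (!is.finite(m0) || m0 <= 0) {
    stop("non-positive M0 estimate; check the pseudo-M0 image", call. = FALSE)
  }
  m0
}

#' Perfusion-weighted signal map
#'
#' Averages the kept subtraction images and normalises by the M0 scalar:
#' PWS = (mean difference / M0) x 100, in percent.
#'
#' @param stack A [pairwise_subtract()] result.
#' @param kept Indices of kept pairs (from [reject_outliers()]).
#' @param m0 M0 scalar (> 0).
#' @return List with `pws` (percent, 3-D) and `dm_mean` (3-D) volumes.
#' @export
compute_pws <- function(stack, kept, m0) {
  stopifnot(inherits(stack, "subtraction_stack"), length(kept) >= 1, m0 > 0)
  d <- dim(stack$dm)
  dm_mean <- array(rowMeans(matrix(stack$dm, ncol = d[4])[, kept, drop = FALSE]),
                   d[1:3])
  list(pws = 100 * dm_mean / m0, dm_mean = dm_mean)
}

#' Temporal SNR map of the subtraction images
#'
#' Voxelwise temporal mean divided by temporal SD over the kept subtraction
#' images, with the sample (n - 1) SD convention. Voxels with zero temporal
#' SD are flagged undefined (NaN).
#'
#' @inheritParams compute_pws
#' @return 3-D tSNR volume (NaN where undefined).
#' @export
compute_tsnr <- function(stack, kept) {
  stopifnot(inherits(stack, "subtraction_stack"))
  if (length(kept) < 2) {
    stop("need at least two kept pairs for tSNR", call. = FALSE)
  }
  d <- dim(stack$dm)
  mat <- matrix(stack$dm, ncol = d[4])[, kept, drop = FALSE]
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (length(kept) - 1))
  tsnr <- mu / sdv
  tsnr[sdv == 0] <- NaN
  array(tsnr, d[1:3])
}

#' Normalized temporal SD of source volumes
#'
#' Voxelwise 100 x SD / mean over a set of source volumes (the acquired
#' label/control images of one scan), used as a motion/stability quality
#' metric; normalising by the voxel mean compensates for global intensity
#' differences. Undefined (NaN) where the temporal mean is not positive.
#'
#' @param source 4-D array of source volumes (>= 2).
#' @return 3-D normalized tSD volume in percent (NaN where undefined).
#' @export
normalized_tsd <- function(source) {
  d <- dim(source)
  stopifnot(length(d) == 4, d[4] >= 2)
  mat <- matrix(source, ncol = d[4])
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (d[4] - 1))
  out <- 100 * sdv / mu
  out[mu <= 0] <- NaN
  array(out, d[1:3])
}

#' ROI statistics of perfusion metric maps
#'
#' Mean, sample SD and voxel counts of each metric within each ROI:
#' the whole placenta, each focal region, and the average over the focal
#' regions (mean and SD of the per-region means). Undefined (non-finite)
#' voxels are excluded from the averages; the number excluded is reported.
#'
#' @param maps Named list of 3-D metric volumes (e.g. `pws`, `tsnr`,
#'   `ntsd`).
#' @param rois List with `placenta` (logical mask) and optionally `focal`
#'   (list of logical masks), as returned by [phantom_rois()].
#' @return A data.frame with columns `roi`, `metric`, `mean`, `sd`,
#'   `n_voxels`, `n_excluded`.
#' @export
roi_summary <- function(maps, rois) {
  stopifnot(is.list(maps), length(maps) > 0, !is.null(names(maps)))
  roi_list <- list(placenta = rois$placenta)
  for (j in seq_along(rois$focal)) {
    roi_list[[paste0("focal_", j)]] <- rois$focal[[j]]
  }
  for (m in roi_list) {
    if (!any(m)) stop("empty ROI", call. = FALSE)
  }
  rows <- list()
  for (metric in names(maps)) {
    vol <- maps[[metric]]
    region_means <- numeric(0)
    for (rn in names(roi_list)) {
      vals <- vol[roi_list[[rn]]]
      ok <- is.finite(vals)
      rows[[length(rows) + 1]] <- data.frame(
        roi = rn, metric = metric,
        mean = if (any(ok)) mean(vals[ok]) else NA_real_,
        sd = if (sum(ok) > 1) stats::sd(vals[ok]) else NA_real_,
        n_voxels = sum(ok), n_excluded = sum(!ok))
      if (startsWith(rn, "focal_")) {
        region_means <- c(region_means, mean(vals[ok]))
      }
    }
    if (length(region_means) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        roi = "focal_avg", metric = metric,
        mean = mean(region_means),
        sd = if (length(region_means) > 1) stats::sd(region_means) else NA_real_,
        n_voxels = length(region_means), n_excluded = 0L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full VS-ASL processing chain
#'
#' Runs the standard processing of one scan: optional rigid motion
#' correction, normalized temporal SD of the source volumes, pairwise
#' subtraction, single-pass outlier rejection within the uterus mask,
#' averaging of the kept pairs, M0 estimation as a percentile of the
#' pseudo-M0 within the placenta ROI, and the PWS and tSNR maps, followed by
#' ROI statistics.
#'
#' @param series An `asl_series` object.
#' @param rois ROI set: list with `placenta`, `uterus` (logical masks) and
#'   optionally `focal` (list of masks); see [phantom_rois()].
#' @param moco Logical; run [rigid_motion_correct()] first.
#' @param m0_percentile Percentile for [estimate_m0()] (default 0.8).
#' @param reject_frac,reject_sd,sd_mode Outlier-rejection settings (see
#'   [reject_outliers()]).
#' @param max_shift Search range for motion correction, voxels.
#' @return An object of class `perfusion_maps`: `pws`, `tsnr`, `ntsd`,
#'   `dm_mean` volumes, the `m0` scalar, `kept_pairs`, `roi_stats`
#'   (data.frame) and a `provenance` list recording the settings used.
#' @export
analyze_series <- function(series, rois, moco = FALSE, m0_percentile = 0.8,
                           reject_frac = 0.2, reject_sd = 1.5,
                           sd_mode = "voxelwise", max_shift = 3) {
  stopifnot(inherits(series, "asl_series"))
  if (is.null(rois$placenta) || is.null(rois$uterus)) {
    stop("rois must provide placenta and uterus masks", call. = FALSE)
  }
  if (moco) {
    series <- rigid_motion_correct(series, max_shift = max_shift)
  }
  nvol <- dim(series$data)[4]
  ntsd <- normalized_tsd(series$data[, , , seq_len(nvol - 1L), drop = FALSE])
  stack <- pairwise_subtract(series)
  kept <- reject_outliers(stack, rois$uterus, frac = reject_frac,
                          sd_thresh = reject_sd, sd_mode = sd_mode)
  m0 <- estimate_m0(series$data[, , , nvol], rois$placenta,
                    percentile = m0_percentile)
  pw <- compute_pws(stack, kept, m0)
  tsnr <- compute_tsnr(stack, kept)
  maps <- list(pws = pw$pws, tsnr = tsnr, ntsd = ntsd)
  stats_df <- roi_summary(maps, rois)
  structure(list(
    pws = pw$pws, tsnr = tsnr, ntsd = ntsd, dm_mean = pw$dm_mean,
    m0 = m0, kept_pairs = as.integer(kept),
    roi_stats = stats_df,
    provenance = list(
      kept_pairs = as.integer(kept),
      n_rejected = stack$n_pairs - length(kept),
      deviant_frac = as.numeric(attr(kept, "deviant_frac")),
      m0 = m0, m0_percentile = m0_percentile,
      reject_frac = reject_frac, reject_sd = reject_sd, sd_mode = sd_mode,
      moco = moco
    )
  ), class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("Perfusion maps: M0 = %.3f, kept %d pairs (rejected %d)\n",
              x$m0, length(x$kept_pairs), x$provenance$n_rejected))
  pl <- x$roi_stats[x$roi_stats$roi == "placenta" & x$roi_stats$metric == "pws", ]
  if (nrow(pl) == 1) {
    cat(sprintf("  whole-placenta PWS: %.3f +/- %.3f %%\n", pl$mean, pl$sd))
  }
  invisible(x)
}
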
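#' Specification of the synthetic placenta phantom
#'
#' Parametric description of a 4-D digital placenta used to emulate VS-ASL
#' acquisitions with known ground truth. The geometry is deliberately
#' parametric rather than anatomical -- an ellipsoidal placenta inside a
#' larger uterine ellipsoid on the acquisition grid -- because only the
#' statistical structure of the data matters for exercising the processing
#' chain. Focal hyperintense regions (intervillous-space blood pools) are
#' small spheres placed preferentially towards the basal-plate slices. Three
#' tissue classes carry the perfusion kinetics: focal pools, maternal-side
#' parenchyma and fetal-side parenchyma, each with its own blood volume
#' fraction, labeling-time and readout-time mean velocity vectors and
#' arrival time; arrival times additionally increase from the basal towards
#' the chorionic plate.
#'
#' @param dim Grid dimensions (x = RL, y = SI, z = AP/slice axis).
#' @param voxel_mm In-plane and through-plane voxel size in mm.
#' @param slice_gap_mm Gap between slices in mm (the slice pitch is
#'   `voxel_mm[3] + slice_gap_mm`).
#' @param placenta_center,placenta_semiaxes Ellipsoid centre and semi-axes in
#'   voxel units; defaults scale with the grid.
#' @param uterus_margin Margin (voxels, in-plane) of the uterine ellipsoid
#'   around the placenta; through-plane margin is one slice.
#' @param n_focal Number of focal hyperintense regions.
#' @param focal_radius Radius of the focal spheres in voxel units.
#' @param compartments Named list of per-class parameters (see
#'   [default_compartments()]).
#' @param arrival_gradient_ms Additional arrival time from the most basal to
#'   the most chorionic placental slice, in ms.
#' @param velocity_sdlog Log-normal spread of per-voxel velocity magnitudes
#'   around the class means (0 disables heterogeneity). The default (0.9,
#'   a geometric SD of about 2.5) reflects the wide span of blood velocities
#'   across the placental feeding tree, from sub-cm/s pooling in the
#'   intervillous space to tens of cm/s in umbilical vessels.
#' @param target_pws_placenta Requested whole-placenta mean of the true
#'   perfusion-weighted signal in percent (generator rescales amplitudes to
#'   hit it exactly); `NULL` disables rescaling. Default 2.4, a typical
#'   whole-placenta group mean.
#' @param target_pws_focal Requested mean over the focal-region means, in
#'   percent; default 4.3, a typical focal group mean.
#' @param m0_base Baseline pseudo-M0 intensity (arbitrary units).
#' @param m0_septa_depth Fractional attenuation of the septa pattern in the
#'   pseudo-M0 image (lobule boundaries appear dark).
#' @param m0_septa_frac Fraction of placental voxels in the septa pattern.
#' @param m0_smooth_amp Amplitude of the smooth pseudo-M0 heterogeneity.
#' @param t1_tissue_ms Longitudinal relaxation time of placental tissue used
#'   for the background-suppression dynamics, in ms.
#' @param t1_signal_ms Decay constant applied to the label, in ms; `NULL`
#'   uses the T1 of maternal blood. Setting a shorter value emulates decay
#'   faster than blood T1 (for example an early large-vessel component).
#' @param arrival_ramp_ms Width of the smooth label arrival ramp; 0 = hard
#'   step.
#' @param noise_sd Temporal noise SD as a fraction of the mean placental
#'   control-image intensity. The default 0.067 matches a typical group-mean
#'   normalized temporal SD of source images.
#' @param corrupted_pairs Indices of label-control pairs whose label image
#'   receives a global additive offset (emulating spurious labeling).
#' @param corruption_amp Offset amplitude in multiples of the noise SD.
#' @param motion_amp Maximum rigid translation per repetition, in voxels;
#'   scalar or length-3 (per axis). 0 disables motion.
#' @param seed Integer seed; fully determines the phantom.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(88, 84, 13),
                         voxel_mm = c(4, 4, 4),
                         slice_gap_mm = 0.4,
                         placenta_center = NULL,
                         placenta_semiaxes = NULL,
                         uterus_margin = 3,
                         n_focal = 4,
                         focal_radius = 2.2,
                         compartments = default_compartments(),
                         arrival_gradient_ms = 200,
                         velocity_sdlog = 0.9,
                         target_pws_placenta = 2.4,
                         target_pws_focal = 4.3,
                         m0_base = 100,
                         m0_septa_depth = 0.25,
                         m0_septa_frac = 0.2,
                         m0_smooth_amp = 0.10,
                         t1_tissue_ms = 1820,
                         t1_signal_ms = NULL,
                         arrival_ramp_ms = 0,
                         noise_sd = 0.067,
                         corrupted_pairs = integer(0),
                         corruption_amp = 10,
                         motion_amp = 0,
                         seed = 1) {
  stopifnot(length(dim) == 3, all(dim >= 4))
  if (is.null(placenta_center)) placenta_center <- (dim + 1) / 2
  if (is.null(placenta_semiaxes)) {
    placenta_semiaxes <- pmax(c(0.34, 0.33, 0.35) * dim, c(2, 2, 1.2))
  }
  stopifnot(length(placenta_center) == 3, length(placenta_semiaxes) == 3,
            all(placenta_semiaxes > 0))
  cls <- c("focal", "maternal", "fetal")
  if (!all(cls %in% names(compartments))) {
    stop("compartments must name classes: ", paste(cls, collapse = ", "),
         call. = FALSE)
  }
  for (cmp in compartments) {
    if (cmp$bvf < 0 || cmp$bvf > 1) {
      stop("blood volume fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(n_focal >= 0, focal_radius > 0, noise_sd >= 0,
            corruption_amp >= 0, all(motion_amp >= 0), t1_tissue_ms > 0)
  motion_amp <- as.integer(rep_len(motion_amp, 3))
  structure(list(
    dim = as.integer(dim), voxel_mm = voxel_mm, slice_gap_mm = slice_gap_mm,
    placenta_center = placenta_center, placenta_semiaxes = placenta_semiaxes,
    uterus_margin = uterus_margin,
    n_focal = as.integer(n_focal), focal_radius = focal_radius,
    compartments = compartments,
    arrival_gradient_ms = arrival_gradient_ms,
    velocity_sdlog = velocity_sdlog,
    target_pws_placenta = target_pws_placenta,
    target_pws_focal = target_pws_focal,
    m0_base = m0_base, m0_septa_depth = m0_septa_depth,
    m0_septa_frac = m0_septa_frac, m0_smooth_amp = m0_smooth_amp,
    t1_tissue_ms = t1_tissue_ms, t1_signal_ms = t1_signal_ms,
    arrival_ramp_ms = arrival_ramp_ms,
    noise_sd = noise_sd,
    corrupted_pairs = as.integer(corrupted_pairs),
    corruption_amp = corruption_amp,
    motion_amp = motion_amp,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default tissue-class parameters of the placenta phantom
#'
#' Velocities are mean 3-vectors in cm/s in the (RL, SI, AP) frame; the
#' dominant component is along AP, the expected net maternal inflow
#' direction for an anterior placenta. Focal pools are fed quickly (short
#' arrival time) but hold slow, pooling blood at readout, so a second VS
#' module before readout barely affects them. Fetal-side parenchyma has
#' delayed arrival and readout velocities above the reference cutoff, so it
#' is suppressed by a dual protocol.
#'
#' @return Named list with classes `focal`, `maternal`, `fetal`; each holds
#'   `bvf`, `v_label`, `v_readout` (cm/s 3-vectors) and `tau_a_ms`.
#' @export
default_compartments <- function() {
  list(
    focal = list(bvf = 0.85, v_label = c(0.4, 0.4, 2.5),
                 v_readout = c(0.05, 0.05, 0.15), tau_a_ms = 200),
    maternal = list(bvf = 0.60, v_label = c(0.3, 0.3, 2.0),
                    v_readout = c(0.2, 0.2, 1.0), tau_a_ms = 350),
    fetal = list(bvf = 0.60, v_label = c(0.5, 0.5, 2.2),
                 v_readout = c(0.6, 0.6, 3.0), tau_a_ms = 1000)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Placenta phantom spec: %dx%dx%d grid, %d focal regions, seed %d\n",
              x$dim[1], x$dim[2], x$dim[3], x$n_focal, x$seed))
  cat(sprintf("  targets: placenta PWS %s%%, focal PWS %s%%; noise SD %g\n",
              format(x$target_pws_placenta), format(x$target_pws_focal),
              x$noise_sd))
  invisible(x)
}

# coordinate index arrays for a grid
.grid_coords <- function(dims) {
  a <- array(0, dims)
  list(x = slice.index(a, 1), y = slice.index(a, 2), z = slice.index(a, 3))
}

.ellipsoid_mask <- function(coords, center, semiaxes) {
  ((coords$x - center[1]) / semiaxes[1])^2 +
    ((coords$y - center[2]) / semiaxes[2])^2 +
    ((coords$z - center[3]) / semiaxes[3])^2 <= 1
}

# low-frequency random field in [-1, 1], consumes RNG
.smooth_field <- function(coords, dims, n_comp = 4, max_freq = 3) {
  f <- array(0, dims)
  for (j in seq_len(n_comp)) {
    fr <- sample.int(max_freq, 3, replace = TRUE)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    f <- f + amp * cos(2 * pi * (fr[1] * coords$x / dims[1] +
                                 fr[2] * coords$y / dims[2] +
                                 fr[3] * coords$z / dims[3]) + ph)
  }
  f / max(abs(f))
}

# place n disjoint spheres inside the placenta, biased towards basal slices;
# returns list of logical masks
.place_focal <- function(spec, coords, placenta) {
  dims <- spec$dim
  r <- spec$focal_radius
  zscale <- (spec$voxel_mm[3] + spec$slice_gap_mm) / spec$voxel_mm[1]
  inner <- ((coords$x - spec$placenta_center[1]) / spec$placenta_semiaxes[1])^2 +
    ((coords$y - spec$placenta_center[2]) / spec$placenta_semiaxes[2])^2 +
    ((coords$z - spec$placenta_center[3]) / spec$placenta_semiaxes[3])^2 <= 0.6
  cand <- which(placenta & inner)
  if (length(cand) == 0 && spec$n_focal > 0) {
    stop("placenta too small to place focal regions", call. = FALSE)
  }
  zc <- coords$z[cand]
  # bias towards low slice index (basal plate side)
  w <- (max(zc) - zc + 1)^2
  masks <- list()
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (length(masks) < spec$n_focal) {
    tries <- tries + 1
    if (tries > 500) {
      stop("could not place the requested focal regions inside the placenta",
           call. = FALSE)
    }
    i <- cand[sample.int(length(cand), 1, prob = w)]
    ctr <- c(coords$x[i], coords$y[i], coords$z[i])
    if (nrow(centers) > 0) {
      d <- sqrt(colSums((t(centers) - ctr)^2))
      if (any(d < 2 * r + 1)) next
    }
    m <- ((coords$x - ctr[1])^2 + (coords$y - ctr[2])^2 +
            ((coords$z - ctr[3]) * zscale)^2) <= r^2
    if (!all(placenta[m])) next
    masks[[length(masks) + 1]] <- m
    centers <- rbind(centers, ctr)
  }
  masks
}

# ground-truth difference signal for one protocol, before amplitude rescaling
.raw_dm <- function(geom, protocol, spec, constants) {
  dm <- array(0, spec$dim)
  idx <- which(geom$placenta)
  if (length(idx) == 0) return(dm)
  g1 <- protocol$vs$direction
  vl <- abs(geom$vl[, 1] * g1[1] + geom$vl[, 2] * g1[2] + geom$vl[, 3] * g1[3])
  vr <- 0
  if (isTRUE(protocol$dual)) {
    g2 <- protocol$second_vs$direction
    vr <- abs(geom$vr[, 1] * g2[1] + geom$vr[, 2] * g2[2] + geom$vr[, 3] * g2[3])
  }
  pld_eff <- effective_pld(protocol, geom$slice0)
  rel <- label_signal(vl, pld_eff, geom$tau, protocol,
                      v_readout_cm_s = vr,
                      t1_ms = spec$t1_signal_ms,
                      ramp_ms = spec$arrival_ramp_ms,
                      constants = constants)
  dm[idx] <- geom$bvf * geom$m0v * rel
  dm
}

#' Build a ground-truth placenta phantom
#'
#' Deterministically (given the spec's seed) generates the phantom geometry,
#' tissue-class maps, heterogeneous pseudo-M0 field and the voxelwise
#' label-control difference field for one protocol, using the closed-form
#' signal model with each slice's effective inflow time. The true
#' perfusion-weighted signal (PWS) field is the difference field divided by
#' the 80th percentile of the noise-free pseudo-M0 within the placenta,
#' times 100. When PWS targets are set, focal and non-focal amplitudes are
#' rescaled so the whole-placenta mean and the mean over focal-region means
#' hit the targets exactly.
#'
#' For parameter sweeps, pass the sweep's reference protocol as
#' `reference_protocol`: the amplitude scaling is then computed at the
#' reference settings and carried over unchanged, so that across-level
#' signal changes follow the physics rather than being renormalised away.
#'
#' @param spec A [phantom_spec()] object.
#' @param protocol An [protocol_params()] object.
#' @param constants A [physical_constants()] object.
#' @param reference_protocol Optional protocol at which to anchor the
#'   amplitude rescaling (defaults to `protocol` itself).
#'
#' @return An object of class `gt_phantom`: masks (`placenta`, `uterus`,
#'   list of `focal`), compartment label array, pseudo-M0 field, true
#'   difference field `dm`, true PWS field `pws_true`, the M0 scalar used,
#'   and the per-voxel kinetic maps.
#' @export
build_phantom <- function(spec, protocol = reference_protocol(),
                          constants = physical_constants(),
                          reference_protocol = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(protocol, "asl_protocol"))
  if (protocol$n_slices != spec$dim[3]) {
    stop("protocol slice count must match the phantom grid", call. = FALSE)
  }
  set.seed(spec$seed)
  dims <- spec$dim
  coords <- .grid_coords(dims)
  placenta <- .ellipsoid_mask(coords, spec$placenta_center,
                              spec$placenta_semiaxes)
  uterus <- .ellipsoid_mask(coords, spec$placenta_center,
                            spec$placenta_semiaxes +
                              c(spec$uterus_margin, spec$uterus_margin, 1))
  uterus <- uterus | placenta
  focal <- .place_focal(spec, coords, placenta)
  focal_all <- Reduce(`|`, focal, array(FALSE, dims))

  # compartment labels: 0 none, 1 maternal, 2 fetal, 3.. focal regions
  compartment <- array(0L, dims)
  compartment[placenta & coords$z <= spec$placenta_center[3]] <- 1L
  compartment[placenta & coords$z > spec$placenta_center[3]] <- 2L
  for (j in seq_along(focal)) compartment[focal[[j]]] <- 2L + j

  # per-voxel kinetic maps over the placenta
  idx <- which(placenta)
  n <- length(idx)
  zvox <- coords$z[idx]
  zr <- range(zvox)
  zfrac <- if (zr[2] > zr[1]) (zvox - zr[1]) / (zr[2] - zr[1]) else 0
  cls <- ifelse(compartment[idx] >= 3L, "focal",
                ifelse(compartment[idx] == 1L, "maternal", "fetal"))
  bvf <- numeric(n)
  tau <- numeric(n)
  vl <- matrix(0, n, 3)
  vr <- matrix(0, n, 3)
  jit <- function(k) {
    if (spec$velocity_sdlog > 0) {
      exp(stats::rnorm(k, -spec$velocity_sdlog^2 / 2, spec$velocity_sdlog))
    } else {
      rep(1, k)
    }
  }
  for (cn in c("focal", "maternal", "fetal")) {
    sel <- cls == cn
    k <- sum(sel)
    if (k == 0) next
    cmp <- spec$compartments[[cn]]
    bvf[sel] <- cmp$bvf
    tau[sel] <- cmp$tau_a_ms
    vl[sel, ] <- outer(jit(k), cmp$v_label)
    vr[sel, ] <- outer(jit(k), cmp$v_readout)
  }
  tau <- tau + spec$arrival_gradient_ms * zfrac

  # pseudo-M0: smooth heterogeneity plus dark septa bands in the placenta
  s1 <- .smooth_field(coords, dims)
  s2 <- .smooth_field(coords, dims)
  m0 <- array(0, dims)
  m0[uterus] <- spec$m0_base * 0.75 * (1 + 0.5 * spec$m0_smooth_amp * s1[uterus])
  m0[placenta] <- spec$m0_base * (1 + spec$m0_smooth_amp * s1[placenta])
  if (spec$m0_septa_frac > 0 && spec$m0_septa_depth > 0) {
    thr <- stats::quantile(s2[placenta], 1 - spec$m0_septa_frac, names = FALSE)
    septa <- placenta & s2 > thr
    m0[septa] <- m0[septa] * (1 - spec$m0_septa_depth)
  }

  geom <- list(placenta = placenta, bvf = bvf, tau = tau, vl = vl, vr = vr,
               slice0 = zvox - 1L, m0v = m0[idx])
  m0_scale <- stats::quantile(m0[placenta], 0.8, type = 7, names = FALSE)

  # amplitude rescaling, anchored at the reference protocol if given
  anchor <- if (is.null(reference_protocol)) protocol else reference_protocol
  dm_anchor <- .raw_dm(geom, anchor, spec, constants)
  scale_focal <- 1
  scale_par <- 1
  if (!is.null(spec$target_pws_placenta)) {
    pws_anchor <- 100 * dm_anchor / m0_scale
    sum_focal <- sum(pws_anchor[focal_all])
    if (!is.null(spec$target_pws_focal) && length(focal) > 0) {
      fmeans <- vapply(focal, function(m) mean(pws_anchor[m]), numeric(1))
      if (mean(fmeans) <= 0) {
        stop("cannot rescale: focal regions carry no signal at the anchor protocol",
             call. = FALSE)
      }
      scale_focal <- spec$target_pws_focal / mean(fmeans)
    }
    nonfocal <- placenta & !focal_all
    sum_nonfocal <- sum(pws_anchor[nonfocal])
    if (sum_nonfocal <= 0) {
      stop("cannot rescale: placenta carries no signal at the anchor protocol",
           call. = FALSE)
    }
    scale_par <- (spec$target_pws_placenta * sum(placenta) -
                    scale_focal * sum_focal) / sum_nonfocal
    if (scale_par < 0) {
      stop("PWS targets inconsistent: focal target leaves no parenchymal signal",
           call. = FALSE)
    }
  }
  scale_field <- array(1, dims)
  scale_field[placenta] <- scale_par
  scale_field[focal_all] <- scale_focal

  dm <- if (is.null(reference_protocol)) dm_anchor else {
    .raw_dm(geom, protocol, spec, constants)
  }
  dm <- dm * scale_field
  pws_true <- 100 * dm / m0_scale

  structure(list(
    spec = spec, protocol = protocol, constants = constants,
    placenta = placenta, uterus = uterus, focal = focal,
    compartment = compartment, m0 = m0,
    bvf = bvf, tau = tau, v_label = vl, v_readout = vr,
    dm = dm, pws_true = pws_true,
    m0_scale = m0_scale,
    scale_focal = scale_focal, scale_parenchyma = scale_par
  ), class = "gt_phantom")
}

#' @export
print.gt_phantom <- function(x, ...) {
  cat(sprintf("Ground-truth phantom: %dx%dx%d, %d placenta voxels, %d focal regions\n",
              dim(x$m0)[1], dim(x$m0)[2], dim(x$m0)[3],
              sum(x$placenta), length(x$focal)))
  cat(sprintf("  whole-placenta mean true PWS: %.4f%%; M0 scalar %.3f\n",
              mean(x$pws_true[x$placenta]), x$m0_scale))
  invisible(x)
}

#' Region-of-interest set of a phantom
#'
#' @param gt A [build_phantom()] result.
#' @return A list with `placenta` (logical mask), `focal` (list of logical
#'   masks) and `uterus` (logical mask), the format expected by
#'   [analyze_series()].
#' @export
phantom_rois <- function(gt) {
  stopifnot(inherits(gt, "gt_phantom"))
  list(placenta = gt$placenta, focal = gt$focal, uterus = gt$uterus)
}

# integer-voxel rigid translation with zero fill
.shift_volume <- function(vol, s, fill = 0) {
  if (all(s == 0)) return(vol)
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (abs(s[a]) >= d[a]) return(out)
    if (s[a] >= 0) {
      dst[[a]] <- (1 + s[a]):d[a]
      src[[a]] <- 1:(d[a] - s[a])
    } else {
      dst[[a]] <- 1:(d[a] + s[a])
      src[[a]] <- (1 - s[a]):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Simulate a VS-ASL acquisition of a phantom
#'
#' Renders the interleaved control/label repetitions plus the final pseudo-M0
#' volume. Control volumes are the background-suppressed static tissue (via
#' the inversion-recovery model at each slice's acquisition time) plus the
#' fully relaxed blood pool; label volumes are control minus the ground-truth
#' difference field. The pseudo-M0 volume is rendered without background
#' suppression and without labeling. Independent Gaussian noise is added to
#' every voxel of every volume with SD equal to `noise_sd` times the mean
#' noise-free placental control intensity. Corrupted pairs receive a global
#' additive offset on their label image; if motion is enabled, each
#' repetition (and the pseudo-M0 volume) is rigidly translated by an integer
#' number of voxels.
#'
#' @param gt A [build_phantom()] result.
#' @param seed Seed for noise, motion and corruption randomness (geometry is
#'   fixed by the phantom).
#' @return An object of class `asl_series`: the 4-D data array, per-volume
#'   conditions (`"control"`, `"label"`, `"m0"`), the protocol, the applied
#'   shifts and the noise SD used.
#' @export
simulate_series <- function(gt, seed = gt$spec$seed + 1L) {
  stopifnot(inherits(gt, "gt_phantom"))
  spec <- gt$spec
  protocol <- gt$protocol
  dims <- spec$dim
  n_pairs <- protocol$n_pairs
  nvol <- 2L * n_pairs + 1L

  t_slices <- effective_pld(protocol, seq_len(dims[3]) - 1L)
  mz_bgs <- bgs_longitudinal_mz(spec$t1_tissue_ms, protocol$bgs_ms, t_slices)
  bvf_vol <- array(0, dims)
  bvf_vol[gt$placenta] <- gt$bvf
  ctrl0 <- array(0, dims)
  for (k in seq_len(dims[3])) {
    ctrl0[, , k] <- gt$m0[, , k] * ((1 - bvf_vol[, , k]) * mz_bgs[k] +
                                      bvf_vol[, , k])
  }
  label0 <- ctrl0 - gt$dm
  sigma <- spec$noise_sd * mean(ctrl0[gt$placenta])

  set.seed(seed)
  shifts <- matrix(0L, nvol, 3)
  if (any(spec$motion_amp > 0)) {
    for (r in seq_len(n_pairs)) {
      s <- vapply(1:3, function(a) {
        if (spec$motion_amp[a] == 0) 0L else {
          sample.int(2L * spec$motion_amp[a] + 1L, 1L) - spec$motion_amp[a] - 1L
        }
      }, integer(1))
      shifts[2L * r - 1L, ] <- s
      shifts[2L * r, ] <- s
    }
    shifts[nvol, ] <- vapply(1:3, function(a) {
      if (spec$motion_amp[a] == 0) 0L else {
        sample.int(2L * spec$motion_amp[a] + 1L, 1L) - spec$motion_amp[a] - 1L
      }
    }, integer(1))
  }

  data <- array(0, c(dims, nvol))
  conditions <- c(rep(c("control", "label"), n_pairs), "m0")
  for (r in seq_len(n_pairs)) {
    lab <- label0
    if (r %in% spec$corrupted_pairs) {
      lab <- lab + spec$corruption_amp * sigma
    }
    data[, , , 2L * r - 1L] <- .shift_volume(ctrl0, shifts[2L * r - 1L, ])
    data[, , , 2L * r] <- .shift_volume(lab, shifts[2L * r, ])
  }
  data[, , , nvol] <- .shift_volume(gt$m0, shifts[nvol, ])
  if (sigma > 0) {
    data <- data + stats::rnorm(length(data), sd = sigma)
  }

  structure(list(
    data = data,
    conditions = conditions,
    protocol = protocol,
    voxel_mm = c(spec$voxel_mm[1:2], spec$voxel_mm[3] + spec$slice_gap_mm),
    shifts_true = shifts,
    sigma = sigma,
    seed = as.integer(seed)
  ), class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VS-ASL series: %dx%dx%d, %d volumes (%d pairs + pseudo-M0)\n",
              d[1], d[2], d[3], d[4], (d[4] - 1) %/% 2))
  invisible(x)
}
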
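#' First gradient moment of a VS module
#'
#' Effective first moment m1 of the motion-sensitising gradient waveform,
#' using the idealised rectangular-lobe convention in which the effective
#' lobe separation spans the whole module: m1 = G * delta * T_module (SI
#' units). This convention reproduces the nominal reference cutoff velocity
#' of the modelled protocol family to within rounding.
#'
#' @param vs A [vs_module_params()] object.
#' @return First moment in T s^2 m^-1.
#' @examples
#' first_gradient_moment(vs_module_params())  # 7.8e-7
#' @export
first_gradient_moment <- function(vs) {
  stopifnot(inherits(vs, "vs_module"))
  (vs$gradient_mT_m * 1e-3) * (vs$duration_ms * 1e-3) * (vs$module_ms * 1e-3)
}

#' Cutoff velocity of a VS module
#'
#' The mean laminar velocity of complete laminar-averaged saturation,
#' Vc = pi / (gamma * m1) (the laminar-flow convention of Wu and Wong):
#' the laminar-averaged response sin(2 pi v / Vc) / (2 pi v / Vc) reaches
#' zero at v = Vc (its first null is at Vc / 2). Spins with mean velocity
#' around and above Vc are, on laminar average, saturated by the module.
#'
#' @param vs A [vs_module_params()] object.
#' @param constants A [physical_constants()] object.
#' @return Cutoff velocity in cm/s. `Inf` when the gradient strength is zero
#'   (no velocity selection).
#' @examples
#' cutoff_velocity(vs_module_params())  # about 1.5 cm/s
#' @export
cutoff_velocity <- function(vs, constants = physical_constants()) {
  m1 <- first_gradient_moment(vs)
  if (m1 == 0) {
    return(Inf)
  }
  100 * pi / (constants$gamma * m1)
}

#' Longitudinal response of plug flow to a VS module
#'
#' Residual longitudinal magnetization fraction of spins moving at constant
#' velocity `v` along the encoding direction. In the label condition the
#' module imprints mz = cos(gamma * m1 * v) = cos(pi * v / Vc); in the
#' control condition no gradients are played and mz = 1 -- unless the module
#' has `enabled_in_control = TRUE` (the second module of dual VS-ASL), in
#' which case the cosine applies in both conditions.
#'
#' @param v_cm_s Velocity along the encoding direction in cm/s (sign =
#'   direction); vectorised.
#' @param vs A [vs_module_params()] object.
#' @param condition `"label"` or `"control"`.
#' @param constants A [physical_constants()] object.
#' @return Longitudinal magnetization fraction(s) in \[-1, 1\].
#' @examples
#' vs <- vs_module_params()
#' vc <- cutoff_velocity(vs)
#' plug_flow_response(c(0, vc / 2, vc), vs)  # 1, 0, -1
#' @export
plug_flow_response <- function(v_cm_s, vs, condition = c("label", "control"),
                               constants = physical_constants()) {
  condition <- match.arg(condition)
  if (condition == "control" && !isTRUE(vs$enabled_in_control)) {
    return(rep(1, length(v_cm_s)))
  }
  m1 <- first_gradient_moment(vs)
  cos(constants$gamma * m1 * v_cm_s / 100)
}

#' Laminar-averaged longitudinal response of a VS module
#'
#' Average of [plug_flow_response()] over the laminar velocity distribution
#' of a voxel with mean velocity `v_mean`: a parabolic flow profile implies a
#' uniform velocity density on \[0, 2 v_mean\], giving
#' mz = sin(2 pi v_mean / Vc) / (2 pi v_mean / Vc), with limit 1 as
#' v_mean -> 0. The module's saturation efficiency is
#' E_sat(v_mean) = 1 - mz.
#'
#' @param v_mean_cm_s Voxel mean velocity magnitude along the encoding
#'   direction, in cm/s (>= 0); vectorised.
#' @inheritParams plug_flow_response
#' @return Longitudinal magnetization fraction(s); in \[-0.2173, 1\].
#' @examples
#' vs <- vs_module_params()
#' vc <- cutoff_velocity(vs)
#' laminar_mean_response(c(0, vc / 4, vc), vs)  # 1, 2/pi, 0
#' @export
laminar_mean_response <- function(v_mean_cm_s, vs,
                                  constants = physical_constants()) {
  vc <- cutoff_velocity(vs, constants)
  x <- 2 * pi * v_mean_cm_s / vc   # zero when vc is infinite
  small <- abs(x) < 1e-6
  out <- numeric(length(x))
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Saturation efficiency of a VS module under laminar flow
#'
#' Convenience wrapper: `1 - laminar_mean_response(...)`.
#'
#' @inheritParams laminar_mean_response
#' @return Label saturation efficiency in \[0, 1.2173\].
#' @export
saturation_efficiency <- function(v_mean_cm_s, vs,
                                  constants = physical_constants()) {
  1 - laminar_mean_response(v_mean_cm_s, vs, constants)
}

#' Diffusion weighting (b-value) of a VS module
#'
#' b-value of the motion-sensitising waveform under the idealised
#' bipolar-pair convention: two refocused lobe pairs with lobe separation
#' Delta = T_module / 2, giving b = 2 (gamma G delta)^2 (Delta - delta / 3).
#' The convention is declared because exact waveform timings vary between
#' implementations.
#'
#' @inheritParams cutoff_velocity
#' @return b-value in s/mm^2.
#' @export
b_value <- function(vs, constants = physical_constants()) {
  stopifnot(inherits(vs, "vs_module"))
  g <- vs$gradient_mT_m * 1e-3
  delta <- vs$duration_ms * 1e-3
  Delta <- vs$module_ms * 1e-3 / 2
  2 * (constants$gamma * g * delta)^2 * (Delta - delta / 3) * 1e-6
}

#' Fractional subtraction error due to diffusion during the VS module
#'
#' The motion-sensitising gradients attenuate the label image by exp(-b D)
#' through diffusion; since the control image is unattenuated, the fraction
#' 1 - exp(-b D) leaks into the subtraction as spurious signal.
#'
#' @inheritParams cutoff_velocity
#' @param D Diffusivity in mm^2/s (>= 0); defaults to the free-water
#'   reference value.
#' @return Fractional subtraction error in \[0, 1\].
#' @examples
#' diffusion_subtraction_error(vs_module_params())
#' @export
diffusion_subtraction_error <- function(vs, D = NULL,
                                        constants = physical_constants()) {
  if (is.null(D)) D <- constants$D_free
  if (any(D < 0)) stop("diffusivity must be >= 0", call. = FALSE)
  1 - exp(-b_value(vs, constants) * D)
}

#' Longitudinal magnetization under background suppression
#'
#' Piecewise inversion-recovery of static tissue: between events the
#' magnetization relaxes as mz(t) = 1 - (1 - mz+) exp(-dt / T1); each
#' inversion pulse flips mz instantaneously with perfect efficiency.
#'
#' @param t1_ms Tissue longitudinal relaxation time in ms (> 0).
#' @param inversion_times_ms Sorted inversion times in ms (after the end of
#'   the labeling module); must all precede `t_ms`.
#' @param t_ms Evaluation time(s) in ms; vectorised.
#' @param mz0 Initial longitudinal magnetization fraction at t = 0.
#' @return Longitudinal magnetization fraction(s) at `t_ms`.
#' @examples
#' bgs_longitudinal_mz(1820, c(50, 1160), 1600)  # about 0.283
#' @export
bgs_longitudinal_mz <- function(t1_ms, inversion_times_ms, t_ms, mz0 = 1) {
  if (!is.numeric(t1_ms) || t1_ms <= 0) {
    stop("T1 must be > 0", call. = FALSE)
  }
  if (length(inversion_times_ms) > 0 && is.unsorted(inversion_times_ms)) {
    stop("inversion times must be sorted", call. = FALSE)
  }
  one <- function(t) {
    if (length(inversion_times_ms) > 0 && any(inversion_times_ms >= t)) {
      stop("all inversion times must precede the evaluation time",
           call. = FALSE)
    }
    mz <- mz0
    t_prev <- 0
    for (ti in inversion_times_ms) {
      mz <- 1 - (1 - mz) * exp(-(ti - t_prev) / t1_ms)
      mz <- -mz
      t_prev <- ti
    }
    1 - (1 - mz) * exp(-(t - t_prev) / t1_ms)
  }
  vapply(t_ms, one, numeric(1))
}

#' Effective post-labeling delay of a slice
#'
#' Slices are read out sequentially in ascending order (basal towards
#' chorionic plate), so slice `k` (0-based) sees an inflow time of
#' PLD + k * slice readout time.
#'
#' @param protocol An [protocol_params()] object.
#' @param slice_index 0-based slice index (vectorised).
#' @return Effective PLD(s) in ms.
#' @examples
#' effective_pld(reference_protocol(), 12)  # 1600 + 12*69
#' @export
effective_pld <- function(protocol, slice_index) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (any(slice_index < 0 | slice_index >= protocol$n_slices)) {
    stop("slice index out of range", call. = FALSE)
  }
  protocol$pld_ms + slice_index * protocol$slice_readout_ms
}

#' Perfusion-weighted signal of one voxel's blood pool
#'
#' Kinetic model of the label-control difference as a fraction of the local
#' blood magnetization: the label saturation efficiency of the VS module at
#' the voxel's labeling-time mean velocity, gated by the arrival of label
#' (a hard step at the arrival time by default, optionally a linear ramp)
#' and attenuated by T1 decay over the effective inflow time. Under a dual
#' protocol the second module's laminar response at the voxel's readout-time
#' mean velocity multiplies the difference in both conditions, suppressing
#' signal wherever blood is still faster than the cutoff at readout.
#'
#' @param v_label_cm_s Mean velocity magnitude along the encoding direction
#'   at labeling time, cm/s (vectorised).
#' @param pld_eff_ms Effective post-labeling delay in ms (vectorised).
#' @param tau_a_ms Arrival time of labeled blood in ms (vectorised).
#' @param protocol An [protocol_params()] object.
#' @param v_readout_cm_s Mean velocity magnitude along the second module's
#'   encoding direction at readout time, cm/s; only used for dual protocols.
#' @param t1_ms Decay constant applied to the label, in ms; defaults to the
#'   T1 of maternal blood.
#' @param ramp_ms Width of the smooth arrival ramp in ms; 0 gives a hard
#'   step (label present once `pld_eff_ms >= tau_a_ms`).
#' @param constants A [physical_constants()] object.
#' @return Difference signal as a fraction of local blood magnetization.
#' @examples
#' p <- reference_protocol()
#' vc <- cutoff_velocity(p$vs)
#' label_signal(vc, 1681, 0, p)  # exp(-1), full saturation
#' @export
label_signal <- function(v_label_cm_s, pld_eff_ms, tau_a_ms, protocol,
                         v_readout_cm_s = 0, t1_ms = NULL, ramp_ms = 0,
                         constants = physical_constants()) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (is.null(t1_ms)) t1_ms <- constants$T1_blood
  e_sat <- saturation_efficiency(abs(v_label_cm_s), protocol$vs, constants)
  if (ramp_ms > 0) {
    h <- pmin(1, pmax(0, (pld_eff_ms - tau_a_ms) / ramp_ms))
  } else {
    h <- as.numeric(pld_eff_ms >= tau_a_ms)
  }
  dm <- e_sat * h * exp(-pld_eff_ms / t1_ms)
  if (isTRUE(protocol$dual)) {
    dm <- dm * laminar_mean_response(abs(v_readout_cm_s), protocol$second_vs,
                                     constants)
  }
  dm
}

#' Total scan duration
#'
#' Duration of one ASL scan: 2 * n_pairs label/control acquisitions, one
#' pseudo-M0 acquisition, and `n_prep` dummy TR periods, each lasting one TR.
#' The default of three dummy periods was calibrated once against the
#' nominal duration of the reference scan (56 TR periods) and is applied
#' uniformly.
#'
#' @param protocol An [protocol_params()] object.
#' @return Duration in seconds.
#' @examples
#' scan_duration(reference_protocol())  # 196 s = 3 min 16 s
#' scan_duration(dual_protocol())       # 358.4 s
#' @export
scan_duration <- function(protocol) {
  stopifnot(inherits(protocol, "asl_protocol"))
  (2 * protocol$n_pairs + 1 + protocol$n_prep) * protocol$tr_ms / 1000
}

#' T1 decay reference curve for multi-PLD perfusion values
#'
#' Expected ROI-averaged perfusion-weighted signal at a given inflow time if
#' the signal measured at PLD 400 ms decayed purely with the T1 of maternal
#' blood: PWS(PLD) = PWS(400) * exp(-(PLD - 400) / T1_blood). Used as the
#' reference line against which measured multi-PLD decays are compared.
#'
#' @param pws_at_400 ROI-averaged PWS at PLD 400 ms (percent).
#' @param pld_ms Inflow time(s) >= 400 ms (vectorised).
#' @param constants A [physical_constants()] object.
#' @return Reference PWS value(s) in percent.
#' @export
t1_decay_reference <- function(pws_at_400, pld_ms,
                               constants = physical_constants()) {
  if (any(pld_ms < 400)) {
    stop("the reference curve starts at PLD 400 ms", call. = FALSE)
  }
  pws_at_400 * exp(-(pld_ms - 400) / constants$T1_blood)
}

#' Label and control responses of a voxel's blood at one velocity
#'
#' Convenience bundle of [plug_flow_response()] in both conditions: the
#' longitudinal magnetization fraction after the labeling module in the
#' label and control conditions, and their static difference
#' (control minus label, the signal available before arrival gating and
#' decay).
#'
#' @inheritParams plug_flow_response
#' @return A list with `mz_label`, `mz_control` and `dm_static`
#'   (= `mz_control - mz_label`, in \[0, 2\] for a standard module).
#' @export
label_response <- function(v_cm_s, vs, constants = physical_constants()) {
  mz_label <- plug_flow_response(v_cm_s, vs, "label", constants)
  mz_control <- plug_flow_response(v_cm_s, vs, "control", constants)
  list(mz_label = mz_label, mz_control = mz_control,
       dm_static = mz_control - mz_label)
}
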
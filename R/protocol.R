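#' Velocity-selective labeling module parameters
#'
#' Describes one velocity-selective (VS) labeling module: motion-sensitising
#' gradient strength and duration, total module duration, and the velocity
#' encoding direction. The defaults are the reference settings of the
#' protocol family this package models (13 mT/m, 1.2 ms, 50 ms, encoding
#' anterior-posterior), which correspond to a cutoff velocity of about
#' 1.6 cm/s.
#'
#' @param gradient_mT_m Gradient strength G in mT/m (>= 0; 0 disables
#'   velocity selection).
#' @param duration_ms Gradient lobe duration delta in ms (0 < delta < module
#'   duration).
#' @param module_ms Total labeling module duration in ms.
#' @param direction Velocity encoding direction: `"AP"`, `"SI"`, `"RL"` or a
#'   numeric 3-vector (see [encoding_direction()]).
#' @param enabled_in_control Logical; `TRUE` for a second VS module placed
#'   before the readout, whose gradients are enabled in both label and
#'   control conditions (dual VS-ASL). `FALSE` for the initial labeling
#'   module.
#'
#' @return An object of class `vs_module`.
#' @examples
#' vs_module_params()
#' vs_module_params(gradient_mT_m = 6)
#' @export
vs_module_params <- function(gradient_mT_m = 13,
                             duration_ms = 1.2,
                             module_ms = 50,
                             direction = "AP",
                             enabled_in_control = FALSE) {
  if (!is.numeric(gradient_mT_m) || gradient_mT_m < 0) {
    stop("gradient strength must be >= 0", call. = FALSE)
  }
  if (!is.numeric(duration_ms) || duration_ms <= 0 ||
      !is.numeric(module_ms) || module_ms <= 0 || duration_ms >= module_ms) {
    stop("need 0 < gradient duration < module duration", call. = FALSE)
  }
  structure(list(
    gradient_mT_m = gradient_mT_m,
    duration_ms = duration_ms,
    module_ms = module_ms,
    direction = encoding_direction(direction),
    direction_label = if (is.character(direction)) direction else "custom",
    enabled_in_control = isTRUE(enabled_in_control)
  ), class = "vs_module")
}

#' @export
print.vs_module <- function(x, ...) {
  cat(sprintf(
    "VS module: G = %g mT/m, delta = %g ms, duration = %g ms, encoding %s%s\n",
    x$gradient_mT_m, x$duration_ms, x$module_ms, x$direction_label,
    if (x$enabled_in_control) " (gradients on in control)" else ""))
  invisible(x)
}

#' Acquisition protocol for one VS-ASL scan
#'
#' Collects everything the signal model and phantom need to know about one
#' scan: the VS module(s), inflow time (post-labeling delay, PLD),
#' background-suppression (BGS) inversion times, repetition time, number of
#' label-control pairs, and the multi-slice readout timing. Slices are
#' acquired in ascending order from the basal towards the chorionic plate;
#' each slice adds `slice_readout_ms` to the effective PLD
#' (see [effective_pld()]).
#'
#' @param vs A [vs_module_params()] object (the labeling module).
#' @param pld_ms Post-labeling delay in ms (> 0).
#' @param bgs_ms Inversion times in ms after the end of the labeling module;
#'   strictly increasing and all smaller than `pld_ms`. Defaults to the
#'   stored timings for this PLD ([bgs_inversion_times()]).
#' @param tr_ms Repetition time in ms.
#' @param n_pairs Number of label-control pairs (>= 1).
#' @param n_prep Number of dummy (preparation) TR periods per scan.
#' @param n_slices Number of slices.
#' @param slice_readout_ms Readout time per slice in ms.
#' @param dual Logical; add a second VS module directly before the readout,
#'   with the same cutoff velocity, whose gradients are enabled in both
#'   conditions.
#' @param second_vs Optional [vs_module_params()] for the second module; by
#'   default a copy of `vs` with `enabled_in_control = TRUE`.
#' @param metadata Free-form list (FOV, EPI factor, ...); informational only.
#'
#' @return An object of class `asl_protocol`.
#' @examples
#' reference_protocol()
#' protocol_params(pld_ms = 1000)
#' @export
protocol_params <- function(vs = vs_module_params(),
                            pld_ms = 1600,
                            bgs_ms = bgs_inversion_times(pld_ms),
                            tr_ms = 3500,
                            n_pairs = 26,
                            n_prep = 3,
                            n_slices = 13,
                            slice_readout_ms = 69,
                            dual = FALSE,
                            second_vs = NULL,
                            metadata = list()) {
  stopifnot(inherits(vs, "vs_module"))
  if (!is.numeric(pld_ms) || pld_ms <= 0) {
    stop("PLD must be > 0", call. = FALSE)
  }
  if (length(bgs_ms) > 0) {
    if (any(diff(bgs_ms) <= 0)) {
      stop("BGS inversion times must be strictly increasing", call. = FALSE)
    }
    if (any(bgs_ms >= pld_ms)) {
      stop("BGS inversion times must precede the readout (be < PLD)",
           call. = FALSE)
    }
  }
  if (n_pairs < 1) stop("need at least one label-control pair", call. = FALSE)
  stopifnot(tr_ms > 0, n_prep >= 0, n_slices >= 1, slice_readout_ms >= 0)
  if (dual && is.null(second_vs)) {
    second_vs <- vs
    second_vs$enabled_in_control <- TRUE
  }
  if (!is.null(second_vs)) stopifnot(inherits(second_vs, "vs_module"))
  structure(list(
    vs = vs,
    dual = isTRUE(dual),
    second_vs = if (isTRUE(dual)) second_vs else NULL,
    pld_ms = pld_ms,
    bgs_ms = bgs_ms,
    tr_ms = tr_ms,
    n_pairs = as.integer(n_pairs),
    n_prep = as.integer(n_prep),
    n_slices = as.integer(n_slices),
    slice_readout_ms = slice_readout_ms,
    metadata = metadata
  ), class = "asl_protocol")
}

#' Reference VS-ASL protocol
#'
#' The reference scan of the protocol family this package models: single VS
#' module at 13 mT/m / 1.2 ms / 50 ms (cutoff about 1.6 cm/s), AP encoding,
#' PLD 1600 ms with BGS inversions at 50 and 1160 ms, TR 3500 ms, 26
#' label-control pairs plus one pseudo-M0 image, 13 slices at 69 ms each.
#'
#' @param ... Overrides passed on to [protocol_params()].
#' @return An `asl_protocol` object.
#' @export
reference_protocol <- function(...) {
  protocol_params(...)
}

#' Dual VS-ASL protocol
#'
#' Same as [reference_protocol()] but with a second VS module before the
#' readout (gradients enabled in both conditions) and the longer TR of
#' 6400 ms imposed by the additional RF pulses.
#'
#' @param ... Overrides passed on to [protocol_params()].
#' @return An `asl_protocol` object.
#' @export
dual_protocol <- function(...) {
  args <- utils::modifyList(list(dual = TRUE, tr_ms = 6400), list(...))
  do.call(protocol_params, args)
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat(sprintf("VS-ASL protocol: %s VS, PLD %g ms, TR %g ms, %d pairs + pseudo-M0\n",
              if (x$dual) "dual" else "single", x$pld_ms, x$tr_ms, x$n_pairs))
  cat(sprintf("  BGS inversions at %s ms; %d slices x %g ms readout\n",
              paste(x$bgs_ms, collapse = "/"), x$n_slices, x$slice_readout_ms))
  print(x$vs)
  invisible(x)
}
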
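# Serialisation: 4-D NIfTI series with JSON protocol sidecars, labeled ROI
# volumes, YAML phantom specs. Unit suffixes are kept in the JSON key names.

.protocol_to_list <- function(protocol) {
  vs_to_list <- function(vs) list(
    gradient_mT_m = vs$gradient_mT_m,
    duration_ms = vs$duration_ms,
    module_ms = vs$module_ms,
    direction = as.numeric(vs$direction),
    direction_label = vs$direction_label,
    enabled_in_control = vs$enabled_in_control
  )
  out <- list(
    vs = vs_to_list(protocol$vs),
    dual = protocol$dual,
    pld_ms = protocol$pld_ms,
    bgs_ms = protocol$bgs_ms,
    tr_ms = protocol$tr_ms,
    n_pairs = protocol$n_pairs,
    n_prep = protocol$n_prep,
    n_slices = protocol$n_slices,
    slice_readout_ms = protocol$slice_readout_ms,
    metadata = protocol$metadata
  )
  if (!is.null(protocol$second_vs)) {
    out$second_vs <- vs_to_list(protocol$second_vs)
  }
  out
}

.protocol_from_list <- function(x) {
  vs_from_list <- function(v) vs_module_params(
    gradient_mT_m = v$gradient_mT_m,
    duration_ms = v$duration_ms,
    module_ms = v$module_ms,
    direction = if (identical(v$direction_label, "custom"))
      as.numeric(v$direction) else v$direction_label,
    enabled_in_control = isTRUE(v$enabled_in_control)
  )
  protocol_params(
    vs = vs_from_list(x$vs),
    pld_ms = x$pld_ms,
    bgs_ms = as.numeric(unlist(x$bgs_ms)),
    tr_ms = x$tr_ms,
    n_pairs = x$n_pairs,
    n_prep = x$n_prep,
    n_slices = x$n_slices,
    slice_readout_ms = x$slice_readout_ms,
    dual = isTRUE(x$dual),
    second_vs = if (!is.null(x$second_vs)) vs_from_list(x$second_vs),
    metadata = if (is.null(x$metadata)) list() else x$metadata
  )
}

#' Write / read a protocol as a JSON sidecar
#'
#' @param protocol An [protocol_params()] object.
#' @param path Path of the JSON file.
#' @return `write_protocol_json` returns `path` invisibly;
#'   `read_protocol_json` returns an `asl_protocol`.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "asl_protocol"))
  jsonlite::write_json(.protocol_to_list(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  .protocol_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write an ASL series as NIfTI plus JSON sidecar
#'
#' Writes `<prefix>.nii.gz` (the 4-D data) and `<prefix>.json` (protocol,
#' per-volume conditions, applied shifts and noise SD).
#'
#' @param series An `asl_series` object.
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, the two paths written.
#' @export
write_asl_series <- function(series, prefix) {
  stopifnot(inherits(series, "asl_series"))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(series$data, pixdim = series$voxel_mm),
                     nii)
  sidecar <- list(
    protocol = .protocol_to_list(series$protocol),
    conditions = series$conditions,
    voxel_mm = series$voxel_mm,
    shifts_true = series$shifts_true,
    sigma = series$sigma,
    seed = series$seed
  )
  js <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(nii, js))
}

#' Read an ASL series written by [write_asl_series()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `asl_series` object.
#' @export
read_asl_series <- function(prefix) {
  data <- array(as.numeric(RNifti::readNifti(paste0(prefix, ".nii.gz"))),
                dim = dim(RNifti::readNifti(paste0(prefix, ".nii.gz"))))
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(
    data = data,
    conditions = as.character(sc$conditions),
    protocol = .protocol_from_list(sc$protocol),
    voxel_mm = as.numeric(sc$voxel_mm),
    shifts_true = matrix(as.integer(sc$shifts_true), ncol = 3),
    sigma = as.numeric(sc$sigma),
    seed = as.integer(sc$seed)
  ), class = "asl_series")
}

#' Write / read ROI masks as a labeled NIfTI volume
#'
#' Label convention: 0 outside the uterus, 1 uterus outside the placenta,
#' 2 placental parenchyma, 3 and above the focal regions. The placenta ROI
#' is every voxel with label >= 2; the uterus mask is every voxel with
#' label >= 1.
#'
#' @param rois ROI set (see [phantom_rois()]).
#' @param path Path of the NIfTI file.
#' @param voxel_mm Voxel dimensions in mm.
#' @return `write_roi_masks` returns `path` invisibly; `read_roi_masks`
#'   returns an ROI set.
#' @export
write_roi_masks <- function(rois, path, voxel_mm = c(4, 4, 4.4)) {
  lab <- array(0L, dim(rois$placenta))
  lab[rois$uterus] <- 1L
  lab[rois$placenta] <- 2L
  for (j in seq_along(rois$focal)) {
    lab[rois$focal[[j]]] <- 2L + j
  }
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = voxel_mm), path)
  invisible(path)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(path) {
  lab <- RNifti::readNifti(path)
  lab <- array(as.integer(lab), dim = dim(lab))
  n_focal <- max(0L, max(lab) - 2L)
  list(
    placenta = lab >= 2L,
    focal = lapply(seq_len(n_focal), function(j) lab == 2L + j),
    uterus = lab >= 1L
  )
}

#' Write / read a phantom spec as YAML
#'
#' @param spec A [phantom_spec()] object.
#' @param path Path of the YAML file.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$compartments <- lapply(x$compartments, function(cmp) {
    cmp$v_label <- as.numeric(unlist(cmp$v_label))
    cmp$v_readout <- as.numeric(unlist(cmp$v_readout))
    cmp
  })
  do.call(phantom_spec, x)
}

#' Write perfusion maps and ROI statistics to a directory
#'
#' Writes `pws.nii.gz`, `tsnr.nii.gz`, `ntsd.nii.gz`, `roi_stats.csv` and
#' `provenance.json` (kept pairs, M0 and the processing settings).
#'
#' @param maps An [analyze_series()] result.
#' @param out_dir Output directory (created if needed).
#' @param voxel_mm Voxel dimensions in mm.
#' @return Invisibly, the output directory.
#' @export
write_perfusion_maps <- function(maps, out_dir, voxel_mm = c(4, 4, 4.4)) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("pws", "tsnr", "ntsd")) {
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = voxel_mm),
                       file.path(out_dir, paste0(nm, ".nii.gz")))
  }
  utils::write.csv(maps$roi_stats, file.path(out_dir, "roi_stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(maps$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Assemble an ASL series from a data array and a protocol
#'
#' For data arriving as a plain 4-D NIfTI plus a protocol sidecar: volumes
#' are taken as interleaved control/label pairs followed by one pseudo-M0
#' volume unless explicit conditions are given.
#'
#' @param data 4-D numeric array (x, y, z, volume).
#' @param protocol An [protocol_params()] object.
#' @param voxel_mm Voxel dimensions in mm (including any slice gap in the
#'   third element).
#' @param conditions Optional per-volume condition labels (`"control"`,
#'   `"label"`, `"m0"`).
#' @return An `asl_series` object.
#' @export
asl_series <- function(data, protocol, voxel_mm = c(4, 4, 4.4),
                       conditions = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 4, inherits(protocol, "asl_protocol"))
  n_pairs <- (d[4] - 1L) %/% 2L
  if (d[4] != 2L * n_pairs + 1L || n_pairs < 1L) {
    stop("expected an odd number of volumes: control/label pairs plus one ",
         "pseudo-M0 volume", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- c(rep(c("control", "label"), n_pairs), "m0")
  }
  structure(list(
    data = data, conditions = conditions, protocol = protocol,
    voxel_mm = voxel_mm, shifts_true = matrix(0L, d[4], 3),
    sigma = NA_real_, seed = NA_integer_
  ), class = "asl_series")
}
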
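# Reduced phantom and protocol used by the unit tests: same structure as the
# full-size defaults but on a coarser grid with fewer pairs, so property
# loops over many seeds stay fast.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(dim = c(32, 30, 10), n_focal = 4, focal_radius = 1.6, seed = 1),
    list(...), keep.null = TRUE)
  do.call(phantom_spec, args)
}

small_protocol <- function(...) {
  args <- utils::modifyList(list(n_pairs = 8, n_slices = 10), list(...))
  do.call(protocol_params, args)
}

# spec with the placenta kept clear of the grid borders, for motion tests
motion_spec <- function(...) {
  args <- utils::modifyList(
    list(dim = c(32, 30, 10), placenta_semiaxes = c(8, 7, 2.5),
         uterus_margin = 2, n_focal = 2, focal_radius = 1.4,
         motion_amp = c(2, 2, 0), seed = 1),
    list(...), keep.null = TRUE)
  do.call(phantom_spec, args)
}

roi_value <- function(res, roi, metric) {
  st <- res$roi_stats
  st$mean[st$roi == roi & st$metric == metric]
}
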
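test_that("phantom generation is fully determined by the seed", {
  spec <- small_spec(seed = 5)
  p <- small_protocol()
  gt1 <- build_phantom(spec, p)
  gt2 <- build_phantom(spec, p)
  expect_identical(gt1$pws_true, gt2$pws_true)
  expect_identical(gt1$m0, gt2$m0)
  s1 <- simulate_series(gt1, seed = 9)
  s2 <- simulate_series(gt2, seed = 9)
  expect_identical(s1$data, s2$data)
  # a different seed changes the geometry
  gt3 <- build_phantom(small_spec(seed = 6), p)
  expect_false(identical(gt1$m0, gt3$m0))
})

test_that("masks are nested and focal regions sit towards the basal plate", {
  gt <- build_phantom(small_spec(seed = 2), small_protocol())
  focal_all <- Reduce(`|`, gt$focal)
  expect_true(all(gt$placenta[focal_all]))
  expect_true(all(gt$uterus[gt$placenta]))
  expect_length(gt$focal, 4)
  # disjoint focal regions
  expect_equal(sum(focal_all), sum(vapply(gt$focal, sum, 1L)))
  # centre of focal mass below the placenta mid-slice (basal side)
  z <- slice.index(array(0, dim(gt$m0)), 3)
  expect_lt(mean(z[focal_all]), mean(z[gt$placenta]))
})

test_that("zero blood volume gives an identically zero difference field", {
  cmp <- default_compartments()
  for (nm in names(cmp)) cmp[[nm]]$bvf <- 0
  spec <- small_spec(compartments = cmp, target_pws_placenta = NULL,
                     target_pws_focal = NULL)
  gt <- build_phantom(spec, small_protocol())
  expect_true(all(gt$dm == 0))
})

test_that("generator rescaling hits the requested PWS targets exactly", {
  gt <- build_phantom(small_spec(seed = 3), small_protocol())
  expect_equal(mean(gt$pws_true[gt$placenta]), 2.4, tolerance = 1e-6)
  fmeans <- vapply(gt$focal, function(m) mean(gt$pws_true[m]), 1)
  expect_equal(mean(fmeans), 4.3, tolerance = 1e-6)
  expect_true(all(gt$pws_true >= 0))
  gt2 <- build_phantom(small_spec(seed = 3, target_pws_placenta = 1.1,
                                  target_pws_focal = 2.0), small_protocol())
  expect_equal(mean(gt2$pws_true[gt2$placenta]), 1.1, tolerance = 1e-6)
})

test_that("noise-free simulation round-trips exactly through the pipeline", {
  spec <- small_spec(seed = 4, noise_sd = 0)
  gt <- build_phantom(spec, small_protocol())
  res <- analyze_series(simulate_series(gt), phantom_rois(gt))
  expect_lt(max(abs(res$pws - gt$pws_true)), 1e-6)
  expect_equal(length(res$kept_pairs), 8)
  expect_equal(res$m0, gt$m0_scale)
})

test_that("injected temporal noise is recovered by the normalized-tSD estimator", {
  # ROI-mean normalized tSD of the source images tracks the injected noise
  # fraction; label-control alternation and pseudo-M0 heterogeneity add a
  # small positive contribution
  vals <- vapply(1:4, function(s) {
    gt <- build_phantom(small_spec(seed = s, noise_sd = 0.067),
                        small_protocol(n_pairs = 26))
    res <- analyze_series(simulate_series(gt, seed = 100 + s),
                          phantom_rois(gt))
    roi_value(res, "placenta", "ntsd")
  }, 1)
  expect_lt(abs(mean(vals) - 6.7) / 6.7, 0.15)
})

test_that("corrupted pairs are exactly the ones flagged by outlier rejection", {
  spec <- small_spec(seed = 8, corrupted_pairs = c(2L, 5L),
                     corruption_amp = 10)
  gt <- build_phantom(spec, small_protocol())
  sim <- simulate_series(gt, seed = 21)
  stack <- pairwise_subtract(sim)
  kept <- reject_outliers(stack, gt$uterus)
  expect_equal(setdiff(1:8, kept), c(2L, 5L))
})

test_that("PWS decreases with increasing cutoff velocity (fixed phantom)", {
  spec <- small_spec(seed = 3, noise_sd = 0)
  ref <- small_protocol()
  tab <- vs_cutoff_settings()
  pws <- vapply(c(0.9, 1.6, 4.4, 10.2), function(vc) {
    g <- tab$gradient_mT_m[match(vc, tab$nominal_vc_cm_s)]
    p <- small_protocol(vs = vs_module_params(gradient_mT_m = g))
    gt <- build_phantom(spec, p, reference_protocol = ref)
    mean(gt$pws_true[gt$placenta])
  }, 1)
  expect_true(all(diff(pws) < 0))
})

test_that("PWS decreases with PLD once all label has arrived", {
  cmp <- default_compartments()
  for (nm in names(cmp)) cmp[[nm]]$tau_a_ms <- 150
  spec <- small_spec(seed = 3, noise_sd = 0, compartments = cmp,
                     arrival_gradient_ms = 0)
  ref <- small_protocol()
  pws <- vapply(c(400, 1000, 1600, 2200), function(pld) {
    p <- small_protocol(pld_ms = pld, bgs_ms = bgs_inversion_times(pld))
    gt <- build_phantom(spec, p, reference_protocol = ref)
    mean(gt$pws_true[gt$placenta])
  }, 1)
  expect_true(all(diff(pws) < 0))
})

test_that("dual VS never exceeds single VS voxelwise (noise-free)", {
  spec <- small_spec(seed = 6, noise_sd = 0)
  ref <- small_protocol()
  gt_s <- build_phantom(spec, ref, reference_protocol = ref)
  gt_d <- build_phantom(spec, small_protocol(dual = TRUE, tr_ms = 6400),
                        reference_protocol = ref)
  expect_true(all(gt_d$dm <= gt_s$dm + 1e-12))
  # slow focal pools barely affected, fast fetal parenchyma suppressed
  focal_all <- Reduce(`|`, gt_s$focal)
  fetal <- gt_s$compartment == 2L
  expect_gt(sum(gt_d$dm[focal_all]) / sum(gt_s$dm[focal_all]), 0.8)
  expect_lt(sum(gt_d$dm[fetal]) / sum(gt_s$dm[fetal]), 0.3)
})

test_that("whole-placenta PWS recovery is accurate over many noisy seeds", {
  # The averaged subtraction signal is an unbiased estimate; the full PWS
  # additionally carries the small upward bias of a percentile taken on a
  # single noisy pseudo-M0 volume (part of the modelled normalization
  # method), so the end-to-end bias is bounded rather than zero.
  errs <- errs_oracle_m0 <- numeric(50)
  for (s in 1:50) {
    gt <- build_phantom(small_spec(seed = s), small_protocol())
    sim <- simulate_series(gt, seed = 5000 + s)
    res <- analyze_series(sim, phantom_rois(gt))
    errs[s] <- (roi_value(res, "placenta", "pws") - 2.4) / 2.4
    pw <- compute_pws(pairwise_subtract(sim), res$kept_pairs, gt$m0_scale)
    errs_oracle_m0[s] <- (mean(pw$pws[gt$placenta]) - 2.4) / 2.4
  }
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(abs(mean(errs_oracle_m0)),
            2 * sd(errs_oracle_m0) / sqrt(length(errs_oracle_m0)))
})

test_that("phantom errors are informative", {
  expect_error(build_phantom(small_spec(), protocol_params(n_slices = 13)),
               "slice count")
  expect_error(phantom_spec(n_focal = 40, focal_radius = 8, dim = c(12, 12, 6)),
               NA)  # spec construction is fine ...
  expect_error(build_phantom(phantom_spec(n_focal = 40, focal_radius = 8,
                                          dim = c(12, 12, 6)),
                             protocol_params(n_slices = 6)),
               "focal")  # ... but placement must fail
})
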
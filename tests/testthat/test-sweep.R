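fast_spec <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0.01), list(...),
                            keep.null = TRUE)
  do.call(small_spec, args)
}

test_that("sweep results cover every level-seed combination", {
  res <- run_sweep("pld", levels = c(1000, 1600), spec = fast_spec(),
                   base_protocol = small_protocol(), n_seeds = 2)
  combos <- unique(res[, c("level", "seed")])
  expect_equal(nrow(combos), 4)
  expect_true(all(c("placenta", "focal_avg") %in% res$roi))
  expect_error(run_sweep("pld", levels = c(400, 1000), spec = fast_spec(),
                         base_protocol = small_protocol()),
               "reference level")
})

test_that("a reference-only PLD sweep has all ratios at 100", {
  res <- run_sweep("pld", levels = 1600, spec = fast_spec(),
                   base_protocol = small_protocol(), n_seeds = 2)
  expect_true(all(abs(res$ratio_pct[res$metric == "pws"] - 100) < 1e-9))
})

test_that("group-mean PWS decreases with cutoff velocity across seeds", {
  res <- run_sweep("cutoff_velocity", levels = c(0.9, 1.6, 4.4, 10.2),
                   spec = fast_spec(), base_protocol = small_protocol(),
                   n_seeds = 3)
  sm <- summarize_sweep(res)
  pl <- sm[sm$roi == "placenta" & sm$metric == "pws", ]
  pl <- pl[order(as.numeric(pl$level)), ]
  expect_true(all(diff(pl$mean) < 0))
})

test_that("PLD ratios follow pure T1 decay when all label arrives early", {
  cmp <- default_compartments()
  for (nm in names(cmp)) cmp[[nm]]$tau_a_ms <- 100
  spec <- fast_spec(compartments = cmp, arrival_gradient_ms = 0,
                    noise_sd = 0)
  res <- run_sweep("pld", levels = c(1600, 2200), spec = spec,
                   base_protocol = small_protocol(), n_seeds = 2)
  r <- res$ratio_pct[res$level == "2200" & res$roi == "placenta" &
                       res$metric == "pws"]
  expect_equal(r, rep(100 * exp(-600 / 1681), 2), tolerance = 1e-6)
})

test_that("direction sweep is flat for isotropic velocities, peaked for AP-dominant", {
  iso <- default_compartments()
  for (nm in names(iso)) {
    iso[[nm]]$v_label <- rep(mean(iso[[nm]]$v_label), 3)
    iso[[nm]]$v_readout <- rep(mean(iso[[nm]]$v_readout), 3)
  }
  spec_iso <- fast_spec(compartments = iso, noise_sd = 0)
  res <- run_sweep("encoding_direction", levels = c("AP", "SI", "RL"),
                   spec = spec_iso, base_protocol = small_protocol(),
                   n_seeds = 2)
  pl <- res[res$roi == "placenta" & res$metric == "pws", ]
  spread <- tapply(pl$value, pl$seed, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
  # default compartments are AP-dominant
  res2 <- run_sweep("encoding_direction", levels = c("AP", "SI", "RL"),
                    spec = fast_spec(noise_sd = 0),
                    base_protocol = small_protocol(), n_seeds = 2)
  pl2 <- res2[res2$roi == "placenta" & res2$metric == "pws", ]
  best <- tapply(seq_len(nrow(pl2)), pl2$seed,
                 function(i) pl2$level[i][which.max(pl2$value[i])])
  expect_true(all(best == "AP"))
})

test_that("dual VS lowers parenchymal PWS but spares slow focal pools", {
  res <- run_sweep("dual", levels = c("single", "dual"),
                   spec = fast_spec(noise_sd = 0),
                   base_protocol = small_protocol(), n_seeds = 2)
  pl <- res[res$roi == "placenta" & res$metric == "pws", ]
  for (s in unique(pl$seed)) {
    expect_lt(pl$value[pl$seed == s & pl$level == "dual"],
              pl$value[pl$seed == s & pl$level == "single"])
  }
  fa <- res[res$roi == "focal_avg" & res$metric == "pws", ]
  for (s in unique(fa$seed)) {
    rel <- fa$value[fa$seed == s & fa$level == "dual"] /
      fa$value[fa$seed == s & fa$level == "single"]
    expect_gt(rel, 0.8)
  }
})

test_that("the decay-constant fit inverts exact exponential ratios", {
  pld <- c(400, 1000, 1600, 2200)
  expect_equal(fit_pld_decay(pld, 100 * exp(-(pld - 1600) / 800)), 800,
               tolerance = 1e-9)
  teff <- fit_pld_decay(pld, c(329, 180, 100, 47))
  expect_lt(teff, 1681)   # measured decay is faster than blood T1
  expect_gt(teff, 400)
  expect_error(fit_pld_decay(pld, c(10, 50, 100, 200)), "decay")
})

test_that("exported report tables are consistent and deterministic", {
  res <- run_sweep("pld", levels = c(400, 1600), spec = fast_spec(),
                   base_protocol = small_protocol(), n_seeds = 2)
  out1 <- tempfile()
  paths <- export_report(res, out1)
  expect_true(all(file.exists(paths)))
  swp <- read.csv(file.path(out1, "sweep.csv"))
  smry <- read.csv(file.path(out1, "summary.csv"))
  # summary means equal hand-computed means of the sweep rows
  for (i in seq_len(nrow(smry))) {
    rows <- swp[swp$level == smry$level[i] & swp$roi == smry$roi[i] &
                  swp$metric == smry$metric[i], ]
    expect_equal(smry$mean[i], mean(rows$value), tolerance = 1e-12)
  }
  # decay table carries the T1 reference anchored at 400 ms
  decay <- read.csv(file.path(out1, "decay.csv"))
  pl <- decay[decay$roi == "placenta", ]
  expect_equal(pl$t1_reference[pl$pld_ms == 400], pl$mean[pl$pld_ms == 400])
  expect_equal(pl$t1_reference[pl$pld_ms == 1600],
               pl$mean[pl$pld_ms == 400] * exp(-1200 / 1681),
               tolerance = 1e-9)
  # byte-identical rewrite
  out2 <- tempfile()
  export_report(res, out2)
  for (f in c("sweep.csv", "summary.csv", "decay.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  unlink(c(out1, out2), recursive = TRUE)
  res$value <- NA_real_
  expect_error(export_report(res, tempfile()), "empty")
})
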
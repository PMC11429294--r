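test_that("presets freeze the reference parameter sets", {
  ec <- organism_preset("ecoli")
  expect_equal(ec$mu1, 0.25)
  expect_equal(ec$cell_footprint_mm2, 2.2e-6)
  expect_equal(ec$initial_dead_fraction, 0.43)
  pp <- organism_preset("pputida")
  expect_equal(pp$mu1, 0.15)
  cg <- organism_preset("cglutamicum")
  expect_equal(cg$mu1, 0.19)
  expect_equal(cg$resting_multiplier, 2)
  for (pr in list(ec, pp, cg)) {
    expect_equal(pr$k, -2.8)
    expect_equal(pr$f, 1e-4)
    expect_equal(pr$s, 0.02)
  }
  expect_error(organism_preset("bsubtilis"), "ecoli, pputida, cglutamicum")
})

test_that("noiseless colony series invert through the plate estimator", {
  for (name in c("ecoli", "pputida", "cglutamicum")) {
    pr <- organism_preset(name)
    tab <- generate_colony_series(name, n_timepoints = 5L, n_replicates = 2L)
    est <- estimate_growth_rates(tab, attr(tab, "cell_footprint"))
    expect_equal(est$mu, pr$mu1, tolerance = 1e-9)
  }
  # recovered generation-time ratio P. putida : E. coli = 5/3
  gt <- vapply(c("pputida", "ecoli"), function(n) {
    tab <- generate_colony_series(n)
    estimate_growth_rates(tab, attr(tab, "cell_footprint"))$generation_time
  }, numeric(1))
  expect_equal(unname(gt[1L] / gt[2L]), 5 / 3, tolerance = 1e-9)
})

test_that("noisy colony series give replicate scatter of the observed order", {
  tab <- generate_colony_series("ecoli", n_timepoints = 6L,
                                n_replicates = 7L, noise_sd = 0.05, seed = 2L)
  est <- estimate_growth_rates(tab, attr(tab, "cell_footprint"))
  expect_equal(est$mu, 0.25, tolerance = 0.05)
  expect_lt(est$sd_mu, 0.05)  # same order as the ~0.01 replicate SD on plates
  expect_gt(est$sd_mu, 0)
  # deterministic under the seed
  tab2 <- generate_colony_series("ecoli", n_timepoints = 6L,
                                 n_replicates = 7L, noise_sd = 0.05,
                                 seed = 2L)
  expect_identical(tab, tab2)
})

test_that("stage fractions start near the post-transformation composition", {
  gs <- generate_stage_fractions("ecoli")
  comp <- gs$composition
  expect_equal(comp$stage[1L], 0L)
  # ~43% dead right after heat shock; 0.01% of viable cells transformed
  expect_equal(comp$pct_dead_gfp_neg[1L], 43, tolerance = 1e-6)
  expect_equal(gs$observations$pct_transformed[1L], 0.01, tolerance = 1e-9)
  # compositions sum to 100% at every stage
  sums <- comp$pct_viable_gfp_pos + comp$pct_viable_gfp_neg +
    comp$pct_dead_gfp_pos + comp$pct_dead_gfp_neg
  expect_equal(sums, rep(100, nrow(comp)), tolerance = 1e-9)
  # final stage: almost pure transformed among viable cells
  n <- length(gs$observations$times)
  expect_lte(gs$observations$pct_nontransformed[n], 2)
})

test_that("zero-noise stage fractions close the loop through the fitter", {
  gs <- generate_stage_fractions("ecoli")
  fit <- fit_selection_model(
    data.frame(time_h = gs$observations$times,
               pct_transformed = gs$observations$pct_transformed,
               pct_nontransformed = gs$observations$pct_nontransformed),
    mu1 = 0.25)
  expect_lt(abs(fit$mu2_hat - (-0.7)), 1e-6)
  expect_lt(abs(fit$cx10_hat - 0.01), 1e-6)
})

test_that("noisy stage fractions are seeded and still sum to 100", {
  g1 <- generate_stage_fractions("ecoli", composition_noise_sd = 0.2,
                                 seed = 9L)
  g2 <- generate_stage_fractions("ecoli", composition_noise_sd = 0.2,
                                 seed = 9L)
  expect_identical(g1, g2)
  sums <- g1$composition$pct_viable_gfp_pos + g1$composition$pct_viable_gfp_neg +
    g1$composition$pct_dead_gfp_pos + g1$composition$pct_dead_gfp_neg
  expect_equal(sums, rep(100, nrow(g1$composition)), tolerance = 1e-9)
})

test_that("dilution series spans configs differing only in inoculum size", {
  cfgs <- generate_dilution_series("ecoli", c(7, 120))
  expect_named(cfgs, c("cfu_7", "cfu_120"))
  expect_equal(cfgs$cfu_7$params$initial_total * cfgs$cfu_7$params$f, 7)
  expect_equal(cfgs$cfu_120$params$initial_total * cfgs$cfu_120$params$f, 120)
  expect_equal(cfgs$cfu_7$params$mu1, cfgs$cfu_120$params$mu1)
  expect_equal(cfgs$cfu_7$carrying_capacity, cfgs$cfu_120$carrying_capacity)
  # empty inoculum: flat trace at the detection floor
  cfg0 <- generate_dilution_series("ecoli", 0)$cfu_0
  cfg0$backscatter_detection_limit <- 5
  sim0 <- simulate_selection(cfg0)
  expect_true(all(sim0$timeseries$backscatter == 5))
})

test_that("final biomass is log-linear in the initial cell count", {
  cfus <- round(exp(seq(log(7), log(120), length.out = 8)))
  cfgs <- generate_dilution_series("ecoli", cfus)
  final_bs <- vapply(cfgs, function(cfg) {
    ts <- simulate_selection(cfg)$timeseries
    ts$backscatter[nrow(ts)]
  }, numeric(1))
  fit <- stats::lm(final_bs ~ log(cfus))
  expect_gt(summary(fit)$r.squared, 0.8)
})
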
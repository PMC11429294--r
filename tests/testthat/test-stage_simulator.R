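test_that("noiseless simulation equals the closed forms at stage boundaries", {
  p <- ecoli_params()
  sched <- ecoli_schedule()
  sim <- simulate_selection(simulation_config(p, sched))
  ts <- sim$timeseries
  # total elapsed time with all transfers undone (dilution factor 0.5^k)
  final <- ts[nrow(ts), ]
  ref <- trajectory(p, t = total_time(sched))
  dil <- 0.5^3
  expect_equal(final$viable_transformed, ref$viable_transformed * dil,
               tolerance = 1e-10)
  expect_equal(final$viable_nontransformed, ref$viable_nontransformed * dil,
               tolerance = 1e-10)
  # intermediate boundary (end of stage 2, one transfer applied)
  b2 <- ts[ts$stage == 2L, ]
  b2 <- b2[nrow(b2), ]
  ref2 <- trajectory(p, t = b2$time_h)
  expect_equal(b2$viable_transformed, ref2$viable_transformed * 0.5,
               tolerance = 1e-10)
})

test_that("transfers preserve every composition percentage exactly", {
  p <- ecoli_params()
  sched <- ecoli_schedule()
  cfg <- simulation_config(p, sched, initial_dead_fraction = 0.43)
  sim <- simulate_selection(cfg)
  ts <- sim$timeseries
  for (s in 1:3) {
    pre <- ts[ts$stage == s, ]
    pre <- pre[nrow(pre), ]
    post <- ts[ts$stage == s + 1L, ][1L, ]
    tot_pre <- pre$viable_transformed + pre$viable_nontransformed + pre$dead
    tot_post <- post$viable_transformed + post$viable_nontransformed +
      post$dead
    expect_identical(post$viable_transformed / tot_post,
                     pre$viable_transformed / tot_pre)
    expect_identical(post$viable_nontransformed / tot_post,
                     pre$viable_nontransformed / tot_pre)
    expect_identical(post$dead / tot_post, pre$dead / tot_pre)
  }
})

test_that("the reference design enriches to at least 98% transformed", {
  sim <- simulate_selection(simulation_config(ecoli_params(),
                                              ecoli_schedule()))
  comp <- stage_compositions(sim)
  final <- comp[comp$stage == 4L, ]
  expect_gte(final$pct_viable_transformed_of_viable, 98)
  expect_lte(final$pct_viable_nontransformed_of_viable, 2)
})

test_that("identical config and seed reproduce the run bit for bit", {
  cfg <- simulation_config(ecoli_params(), ecoli_schedule(),
                           mu_heterogeneity_sd = 0.03, n_replicates = 4L,
                           noise_sd = 0.05, rng_seed = 7L)
  s1 <- simulate_selection(cfg)
  s2 <- simulate_selection(cfg)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$mu1_replicates, s2$mu1_replicates)
  # and a different seed gives a different draw
  cfg2 <- simulation_config(ecoli_params(), ecoli_schedule(),
                            mu_heterogeneity_sd = 0.03, n_replicates = 4L,
                            noise_sd = 0.05, rng_seed = 8L)
  expect_false(identical(simulate_selection(cfg2)$timeseries, s1$timeseries))
})

test_that("seeds are mandatory for stochastic configurations", {
  expect_error(simulation_config(ecoli_params(), ecoli_schedule(),
                                 noise_sd = 0.05), "rng_seed")
  expect_error(simulation_config(ecoli_params(), ecoli_schedule(),
                                 mu_heterogeneity_sd = 0.01), "rng_seed")
})

test_that("with no death the non-transformed pool rides along unchanged", {
  p <- suppressWarnings(
    selection_parameters(mu1 = 0.25, mu2 = 0, f = 1e-4, initial_total = 1e4))
  sched <- build_schedule(3, log(2) / 0.25)
  sim <- simulate_selection(simulation_config(p, sched))
  ts <- sim$timeseries
  dil <- c(1, 0.5, 0.25)[ts$stage]
  expect_equal(ts$viable_nontransformed, 9999 * dil, tolerance = 1e-10)
  expect_equal(ts$viable_transformed, exp(0.25 * ts$time_h) * dil,
               tolerance = 1e-10)
  expect_true(all(ts$dead == 0))
})

test_that("a carrying capacity caps total viable growth", {
  # growing population started below capacity saturates at K
  pg <- suppressWarnings(
    selection_parameters(mu1 = 0.3, mu2 = 0, f = 0.5, initial_total = 100))
  one_long_well <- build_schedule(1, generation_time = 40)
  simg <- simulate_selection(simulation_config(pg, one_long_well,
                                               carrying_capacity = 500))
  vg <- simg$timeseries$viable_transformed +
    simg$timeseries$viable_nontransformed
  expect_lte(max(vg), 500 * (1 + 1e-6))
  expect_gt(max(vg), 400)  # the brake engages, not just slow growth

  # an over-capacity inoculum stalls growth instead of shrinking transformants
  sim <- simulate_selection(simulation_config(ecoli_params(1e4),
                                              ecoli_schedule(),
                                              carrying_capacity = 5e3))
  first <- sim$timeseries[sim$timeseries$stage == 1L, ]
  expect_true(all(diff(first$viable_transformed) >= -1e-9))
  # deaths still proceed unbraked
  expect_true(all(diff(first$viable_nontransformed) < 0))
})

test_that("apparent growth rates recover mu1 once selection is complete", {
  p <- ecoli_params()
  # long run: the last stages hold essentially pure transformed culture
  sched <- build_schedule(8, log(2) / 0.25)
  sim <- simulate_selection(simulation_config(p, sched))
  ag <- apparent_growth_rates(sim)
  per <- attr(ag, "per_replicate")
  expect_equal(per$rate[per$stage == 7L], 0.25, tolerance = 1e-3)
  # single replicate: SD undefined
  expect_true(all(is.na(ag$sd_rate)))
})

test_that("replicate CV of the apparent rate shrinks as selection proceeds", {
  p <- ecoli_params()
  sched <- build_schedule(8, log(2) / 0.25)
  cvs <- t(vapply(1:20, function(s) {
    cfg <- simulation_config(p, sched, mu_heterogeneity_sd = 0.03,
                             n_replicates = 6L,
                             initial_dead_fraction = 0.43, rng_seed = s)
    apparent_growth_rates(simulate_selection(cfg))$sd_percent
  }, numeric(7L)))
  mean_cv <- colMeans(cvs, na.rm = TRUE)
  defined <- which(!is.nan(mean_cv) & colSums(!is.na(cvs)) > 10)
  expect_gte(length(defined), 2L)
  # non-increasing across growth-detectable stages
  expect_true(all(diff(mean_cv[defined]) <= 1e-8))
})

test_that("the backscatter proxy is linear above the detection floor", {
  expect_equal(backscatter_proxy(0, 2, 10), 10)
  expect_equal(backscatter_proxy(100, 2, 10), 200)
  expect_equal(backscatter_proxy(200, 2, 10), 400)  # doubling doubles
  expect_error(backscatter_proxy(1, 0), "positive")
})
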
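test_that("the rate ratio converts growth rates to death rates", {
  expect_equal(death_rate_from_k(0.25, -2.8), -0.7)
  expect_equal(death_rate_from_k(0.15, -2.8), -0.42)
  expect_equal(death_rate_from_k(0.19, 0), 0)
  expect_error(death_rate_from_k(-0.1, -2.8), "positive")
})

test_that("parameters enforce exclusivity of mu2 and k and derive the other", {
  p1 <- selection_parameters(mu1 = 0.25, k = -2.8, f = 1e-4)
  expect_equal(p1$mu2, -0.7)
  p2 <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4)
  expect_equal(p2$k, -2.8)
  expect_error(selection_parameters(0.25, mu2 = -0.7, k = -2.8, f = 1e-4),
               "exactly one")
  expect_error(selection_parameters(0.25, f = 1e-4), "exactly one")
  expect_error(selection_parameters(0.25, mu2 = -0.7, f = 0), "between 0 and 1")
  expect_error(selection_parameters(0.25, mu2 = -0.7, f = 1e-4, s = 1.2),
               "between 0 and 1")
  expect_error(selection_parameters(0.25, mu2 = 0.3, f = 1e-4), "mu1 > mu2")
  # growing contaminants permitted with a warning
  expect_warning(selection_parameters(0.25, mu2 = 0.1, f = 1e-4),
                 "dilution|rate difference")
})

test_that("the initial state splits viable cells by f and books the dead pool", {
  p <- ecoli_params()
  s <- initial_state(p)
  expect_equal(s$viable_transformed, 1)
  expect_equal(s$viable_nontransformed, 9999)
  expect_equal(s$dead, 0)

  p2 <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 0.5,
                             initial_total = 2)
  s2 <- initial_state(p2)
  expect_equal(c(s2$viable_transformed, s2$viable_nontransformed), c(1, 1))

  # dead fraction is of the total population: d/(1-d) * c_x0 on top of viable
  s3 <- initial_state(p, initial_dead_fraction = 0.43)
  expect_equal(s3$dead, 0.43 / 0.57 * 1e4)
  tot <- s3$viable_transformed + s3$viable_nontransformed + s3$dead
  expect_equal(s3$dead / tot, 0.43)
  expect_error(initial_state(p, initial_dead_fraction = 1), "\\[0, 1\\)")
})

test_that("the closed-form trajectory follows exponential growth and death", {
  p <- ecoli_params()
  s0 <- initial_state(p)
  expect_equal(trajectory(p, s0, 0), s0)
  st <- trajectory(p, s0, 13.813)
  expect_equal(st$viable_transformed, exp(0.25 * 13.813), tolerance = 1e-12)
  expect_equal(st$viable_transformed, 31.603, tolerance = 1e-4)
  expect_equal(st$viable_nontransformed, 9999 * exp(-0.7 * 13.813),
               tolerance = 1e-12)
  expect_equal(st$viable_nontransformed, 0.632, tolerance = 1e-3)
  frac <- st$viable_transformed /
    (st$viable_transformed + st$viable_nontransformed)
  expect_equal(100 * frac, 98.04, tolerance = 1e-3)
  expect_error(trajectory(p, s0, -1), "non-negative")
})

test_that("losses from the non-transformed pool are conserved as dead cells", {
  p <- ecoli_params()
  s0 <- initial_state(p, initial_dead_fraction = 0.2)
  for (t in c(0.5, 3, 10, 25)) {
    st <- trajectory(p, s0, t)
    expect_equal(st$viable_nontransformed + (st$dead - s0$dead),
                 s0$viable_nontransformed, tolerance = 1e-12)
  }
})

test_that("required time solves the selection criterion", {
  p <- ecoli_params()
  req <- required_time(p)
  expect_equal(req$t_required, oracle_required_time(0.25, -0.7, 1e-4, 0.02),
               tolerance = 1e-12)
  expect_equal(req$t_required, 13.8129, tolerance = 1e-4)
  expect_equal(req$n_generations_required, 4.98195, tolerance = 1e-5)
  expect_identical(req$n_generations_scheduled, 5L)
  expect_false(req$already_selected)

  pp <- selection_parameters(mu1 = 0.15, mu2 = -0.42, f = 1e-4, s = 0.02)
  expect_equal(required_time(pp)$t_required, 23.0215, tolerance = 1e-4)

  # boundary: criterion already met at the start
  p_done <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 50 / 51,
                                 s = 0.02)
  req_done <- required_time(p_done)
  expect_true(req_done$already_selected)
  expect_equal(req_done$t_required, 0)
})

test_that("trajectory at the required time meets the criterion exactly", {
  for (mu1 in c(0.15, 0.19, 0.25)) {
    for (f in c(1e-4, 1e-3, 0.05)) {
      p <- selection_parameters(mu1 = mu1, k = -2.8, f = f, s = 0.02)
      req <- required_time(p)
      st <- trajectory(p, initial_state(p), req$t_required)
      expect_equal(st$viable_nontransformed / st$viable_transformed, p$s,
                   tolerance = 1e-10)
    }
  }
})

test_that("the generation count in closed form is independent of mu1", {
  n_cf <- required_generations(k = -2.8, f = 1e-4, s = 0.02)
  expect_equal(n_cf, 4.98195, tolerance = 1e-5)
  set.seed(11)
  mus <- c(0.15, 0.19, 0.25, runif(100, 0.01, 2))
  for (mu1 in mus) {
    p <- selection_parameters(mu1 = mu1, k = -2.8, f = 1e-4, s = 0.02)
    n <- required_time(p)$n_generations_required
    expect_lt(abs(n - n_cf) / n_cf, 1e-10)
  }
  # no death: enrichment by growth-dilution alone
  expect_equal(required_generations(0, 1e-4, 0.02), 18.9314,
               tolerance = 1e-4)
  # boundary f where the starting ratio is already 50:1
  expect_equal(required_generations(-2.8, 50 / 51, 0.02), 0)
  expect_error(required_generations(1, 1e-4, 0.02), "k")
})

test_that("the viable transformed fraction increases monotonically in time", {
  p <- selection_parameters(mu1 = 0.2, mu2 = -0.3, f = 1e-3)
  ts <- trajectory_series(p, times = seq(0, 30, by = 0.5))
  frac <- ts$viable_transformed /
    (ts$viable_transformed + ts$viable_nontransformed)
  expect_true(all(diff(frac) > 0))
})

test_that("closed forms agree with RK4 numerical integration", {
  p <- ecoli_params()
  s0 <- initial_state(p)
  times <- seq(0, 30, by = 1e-3)
  rhs <- function(t, y, parms) list(c(p$mu1 * y[1L], p$mu2 * y[2L]))
  sol <- deSolve::rk4(c(s0$viable_transformed, s0$viable_nontransformed),
                      times, rhs, NULL)
  check_at <- c(2001L, 10001L, 30001L)  # t = 2, 10, 30 h
  for (i in check_at) {
    cf <- trajectory(p, s0, times[i])
    expect_lt(abs(sol[i, 2L] - cf$viable_transformed) /
                cf$viable_transformed, 1e-8)
    expect_lt(abs(sol[i, 3L] - cf$viable_nontransformed) /
                cf$viable_nontransformed, 1e-8)
  }
})
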
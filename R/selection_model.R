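#' Selection parameters for the two-subpopulation growth/death model
#'
#' Bundles the kinetic assumptions behind automated liquid clone selection
#' (ALCS): transformed cells grow exponentially at rate `mu1` while
#' non-transformed cells, lacking the plasmid-borne antibiotic resistance, die
#' exponentially at rate `mu2 < 0`.  Selection is declared successful once the
#' ratio of non-transformed to transformed viable cells has fallen to the
#' selection criterion `s` (0.02 corresponds to a 50:1 excess of
#' transformants).
#'
#' Exactly one of `mu2` and `k` must be supplied; the other is derived through
#' the proportionality `mu2 = k * mu1`, which is how the death-rate assumption
#' calibrated on one host is transferred to another (`k = -2.8` in the
#' reference calibration for *E. coli*).
#'
#' @param mu1 Growth rate of transformed cells, per hour. Must be positive.
#' @param mu2 Net rate of non-transformed cells, per hour; negative for death
#'   under antibiotic pressure. Mutually exclusive with `k`.
#' @param k Dimensionless ratio `mu2 / mu1`. Mutually exclusive with `mu2`.
#' @param f Fraction of transformed cells among all viable cells at the start
#'   of selection (`c_x10 / c_x0`), strictly between 0 and 1.
#' @param s Selection criterion: target ratio of non-transformed to
#'   transformed viable cells at the end of selection, strictly between 0
#'   and 1. Default 0.02.
#' @param initial_total Total viable cell count `c_x0` at the start of
#'   selection. Default 1 (fractions only).
#'
#' @return An object of class `selection_parameters` with elements `mu1`,
#'   `mu2`, `k`, `f`, `s`, `initial_total`.
#' @examples
#' selection_parameters(mu1 = 0.25, k = -2.8, f = 1e-4)
#' @export
selection_parameters <- function(mu1, mu2 = NULL, k = NULL, f, s = 0.02,
                                 initial_total = 1) {
  stopifnot(is.numeric(mu1), length(mu1) == 1L, is.finite(mu1))
  if (mu1 <= 0) {
    stop("`mu1` must be positive (growth of transformed cells).", call. = FALSE)
  }
  if (is.null(mu2) == is.null(k)) {
    stop("Supply exactly one of `mu2` and `k`; the other is derived.",
         call. = FALSE)
  }
  if (is.null(mu2)) {
    stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
    mu2 <- death_rate_from_k(mu1, k)
  } else {
    stopifnot(is.numeric(mu2), length(mu2) == 1L, is.finite(mu2))
    k <- mu2 / mu1
  }
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f >= 1) {
    stop("`f` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0 || s >= 1) {
    stop("`s` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!is.numeric(initial_total) || initial_total <= 0) {
    stop("`initial_total` must be positive.", call. = FALSE)
  }
  if (mu1 <= mu2) {
    stop("Selection requires `mu1 > mu2`.", call. = FALSE)
  }
  if (mu2 > 0) {
    warning("`mu2` > 0: non-transformed cells grow; enrichment is driven by ",
            "the rate difference only.", call. = FALSE)
  }
  structure(
    list(mu1 = mu1, mu2 = mu2, k = k, f = f, s = s,
         initial_total = initial_total),
    class = "selection_parameters"
  )
}

#' @export
print.selection_parameters <- function(x, ...) {
  cat("Selection parameters (two-subpopulation growth/death model)\n")
  cat(sprintf("  mu1 = %g /h (transformed), mu2 = %g /h (non-transformed), k = %g\n",
              x$mu1, x$mu2, x$k))
  cat(sprintf("  f = %g, s = %g, initial total = %g cells\n",
              x$f, x$s, x$initial_total))
  invisible(x)
}

#' Derive the non-transformed rate from the rate ratio
#'
#' Applies `mu2 = k * mu1`, the rule used to transfer a death-rate assumption
#' calibrated on one organism to another whose growth rate differs.
#'
#' @param mu1 Growth rate of transformed cells, per hour (positive).
#' @param k Dimensionless ratio `mu2/mu1` (negative for death).
#' @return The non-transformed net rate `k * mu1`, per hour.
#' @examples
#' death_rate_from_k(0.25, -2.8)  # -0.7 /h
#' @export
death_rate_from_k <- function(mu1, k) {
  stopifnot(is.numeric(mu1), is.numeric(k))
  if (any(mu1 <= 0)) stop("`mu1` must be positive.", call. = FALSE)
  k * mu1
}

#' Population state at a time point
#'
#' @param time Time in hours.
#' @param viable_transformed Viable transformed cell count (`c_x1`).
#' @param viable_nontransformed Viable non-transformed cell count (`c_x2`).
#' @param dead Dead cell count (accumulated; diluted at transfers like any
#'   other pool, never revived).
#' @return An object of class `population_state`.
#' @export
population_state <- function(time = 0, viable_transformed,
                             viable_nontransformed, dead = 0) {
  pools <- c(viable_transformed, viable_nontransformed, dead)
  stopifnot(is.numeric(time), length(time) == 1L)
  if (any(!is.finite(pools)) || any(pools < 0)) {
    stop("All population pools must be finite and non-negative.", call. = FALSE)
  }
  structure(
    list(time = time,
         viable_transformed = viable_transformed,
         viable_nontransformed = viable_nontransformed,
         dead = dead),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at t = %g h\n", x$time))
  cat(sprintf("  viable transformed:     %g\n", x$viable_transformed))
  cat(sprintf("  viable non-transformed: %g\n", x$viable_nontransformed))
  cat(sprintf("  dead:                   %g\n", x$dead))
  invisible(x)
}

#' Initial population state for a selection run
#'
#' Splits the initial viable population `c_x0` into transformed (`f * c_x0`)
#' and non-transformed (`(1 - f) * c_x0`) pools.  An initial dead pool -- e.g.
#' cells killed by the heat-shock transformation itself -- can be added via
#' `initial_dead_fraction`, interpreted as the dead share of the *total*
#' population, so `dead = d/(1 - d) * c_x0` on top of the viable `c_x0`.
#'
#' @param params A [selection_parameters()] object.
#' @param initial_dead_fraction Dead fraction of the total (dead + viable)
#'   population at time zero, in `[0, 1)`. Default 0.
#' @return A [population_state()] at time 0.
#' @examples
#' p <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4,
#'                           initial_total = 1e4)
#' initial_state(p)                              # (1, 9999, 0)
#' initial_state(p, initial_dead_fraction = 0.43)
#' @export
initial_state <- function(params, initial_dead_fraction = 0) {
  stopifnot(inherits(params, "selection_parameters"))
  d <- initial_dead_fraction
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d >= 1) {
    stop("`initial_dead_fraction` must lie in [0, 1).", call. = FALSE)
  }
  c0 <- params$initial_total
  population_state(
    time = 0,
    viable_transformed = params$f * c0,
    viable_nontransformed = (1 - params$f) * c0,
    dead = d / (1 - d) * c0
  )
}

#' Closed-form trajectory of the selection model
#'
#' Evolves a population state forward by pure exponential kinetics:
#' `c_x1(t) = c_x10 * exp(mu1 t)` for transformed cells and
#' `c_x2(t) = c_x20 * exp(mu2 t)` for non-transformed cells.  Cells lost from
#' the non-transformed pool (when `mu2 < 0`) are conserved into the dead pool,
#' so stage compositions including the dead percentage remain computable.
#'
#' @param params A [selection_parameters()] object.
#' @param state0 Starting [population_state()]; defaults to
#'   `initial_state(params)`.
#' @param t Elapsed time in hours (scalar, `>= 0`), measured from `state0`.
#' @return A [population_state()] at time `state0$time + t`.
#' @examples
#' p <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4,
#'                           initial_total = 1e4)
#' trajectory(p, t = required_time(p)$t_required)
#' @export
trajectory <- function(params, state0 = NULL, t) {
  stopifnot(inherits(params, "selection_parameters"))
  if (is.null(state0)) state0 <- initial_state(params)
  stopifnot(inherits(state0, "population_state"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("`t` must be a finite scalar.", call. = FALSE)
  }
  if (t < 0) stop("`t` must be non-negative.", call. = FALSE)
  cx1 <- state0$viable_transformed * exp(params$mu1 * t)
  cx2 <- state0$viable_nontransformed * exp(params$mu2 * t)
  died <- state0$viable_nontransformed - cx2
  # only actual losses accumulate as dead cells; growth (mu2 > 0) adds none
  dead <- state0$dead + max(died, 0)
  population_state(
    time = state0$time + t,
    viable_transformed = cx1,
    viable_nontransformed = cx2,
    dead = dead
  )
}

#' Trajectory evaluated on a time grid
#'
#' Vectorised companion of [trajectory()]: evaluates the closed forms at each
#' requested elapsed time and returns a tidy table.
#'
#' @inheritParams trajectory
#' @param times Numeric vector of elapsed hours (all `>= 0`).
#' @return A data.frame with columns `time_h`, `viable_transformed`,
#'   `viable_nontransformed`, `dead`.
#' @export
trajectory_series <- function(params, state0 = NULL, times) {
  if (is.null(state0)) state0 <- initial_state(params)
  states <- lapply(times, function(tt) trajectory(params, state0, tt))
  data.frame(
    time_h = vapply(states, `[[`, numeric(1), "time"),
    viable_transformed = vapply(states, `[[`, numeric(1), "viable_transformed"),
    viable_nontransformed = vapply(states, `[[`, numeric(1),
                                   "viable_nontransformed"),
    dead = vapply(states, `[[`, numeric(1), "dead")
  )
}

#' Required cultivation time and generation count for selection
#'
#' Solves the two-subpopulation model for the time at which the ratio of
#' non-transformed to transformed viable cells first reaches the selection
#' criterion `s`:
#' \deqn{t = \frac{\ln\!\big(s\,f/(1-f)\big)}{\mu_2 - \mu_1}}
#' The time is also expressed in generations of the transformed strain
#' (`t / (ln 2 / mu1)`), and rounded *up* to whole generations for scheduling,
#' since the schedule must meet or exceed the requirement.
#'
#' If the starting composition already satisfies the criterion
#' (`s * f / (1 - f) >= 1`), the requirement is zero and the result is flagged
#' with `already_selected = TRUE`.
#'
#' @param params A [selection_parameters()] object.
#' @return An object of class `selection_requirement`: a list with
#'   `t_required` (h), `n_generations_required` (real),
#'   `n_generations_scheduled` (integer ceiling), `already_selected` (flag),
#'   and the `params` used.
#' @examples
#' p <- selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4)
#' required_time(p)  # ~13.81 h, ~4.98 generations -> 5 scheduled
#' @export
required_time <- function(params) {
  stopifnot(inherits(params, "selection_parameters"))
  ratio0 <- params$s * params$f / (1 - params$f)
  if (ratio0 >= 1 - 1e-12) {  # tolerance absorbs float error at the boundary
    t_req <- 0
    already <- TRUE
  } else {
    t_req <- log(ratio0) / (params$mu2 - params$mu1)
    already <- FALSE
  }
  gen_time <- log(2) / params$mu1
  n_req <- t_req / gen_time
  structure(
    list(t_required = t_req,
         n_generations_required = n_req,
         n_generations_scheduled = as.integer(ceiling(n_req - 1e-9)),
         already_selected = already,
         params = params),
    class = "selection_requirement"
  )
}

#' @export
print.selection_requirement <- function(x, ...) {
  cat("Selection requirement\n")
  if (x$already_selected) {
    cat("  starting composition already satisfies the criterion (t = 0)\n")
  } else {
    cat(sprintf("  required time:        %.4f h\n", x$t_required))
    cat(sprintf("  required generations: %.4f (schedule %d)\n",
                x$n_generations_required, x$n_generations_scheduled))
  }
  invisible(x)
}

#' Required generations in closed form, independent of the absolute rate
#'
#' When the non-transformed rate is tied to the transformed rate through
#' `mu2 = k * mu1`, the required cultivation time expressed in generations of
#' the transformed strain no longer depends on `mu1`:
#' \deqn{n = \frac{\ln\!\big((1-f)/(s f)\big)}{(1-k)\,\ln 2}}
#' This is the quantity that makes a fixed stage count (e.g. five generations)
#' transferable across organisms with different absolute growth rates.
#'
#' @param k Rate ratio `mu2/mu1`, must satisfy `k < 1`.
#' @param f Initial transformed fraction, in (0, 1).
#' @param s Selection criterion, in (0, 1).
#' @return Required number of generations (real, `>= 0`).
#' @examples
#' required_generations(k = -2.8, f = 1e-4, s = 0.02)  # ~4.98
#' @export
required_generations <- function(k, f, s) {
  stopifnot(is.numeric(k), is.numeric(f), is.numeric(s))
  if (any(k >= 1)) {
    stop("`k` must be < 1: no selection is possible when non-transformed ",
         "cells match or outgrow transformed cells.", call. = FALSE)
  }
  if (any(f <= 0 | f >= 1) || any(s <= 0 | s >= 1)) {
    stop("`f` and `s` must lie strictly between 0 and 1.", call. = FALSE)
  }
  n <- log((1 - f) / (s * f)) / ((1 - k) * log(2))
  pmax(n, 0)
}
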
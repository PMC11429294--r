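#' Configuration of a stage-wise selection simulation
#'
#' Couples the kinetic parameters to a stage schedule and the observation
#' model of the microbioreactor: a backscatter proxy (signal proportional to
#' total cells, floored at a detection limit) and a GFP proxy (proportional to
#' viable transformed cells).  Optional features emulate real runs: a shared
#' carrying capacity (oxygen/nutrient limitation at high cell loads),
#' replicate-level heterogeneity of the transformed growth rate (one draw per
#' well lineage, truncated at zero), and measurement noise (multiplicative
#' lognormal on backscatter, additive Gaussian on composition logits).
#'
#' @param params A [selection_parameters()] object.
#' @param schedule A [build_schedule()] result.
#' @param carrying_capacity Shared viable-cell capacity `K`; `Inf` disables
#'   the logistic brake (default).
#' @param mu_heterogeneity_sd SD (per hour) of the per-replicate Gaussian draw
#'   of the transformed growth rate; 0 disables (default).
#' @param n_replicates Number of replicate well lineages (default 1).
#' @param initial_dead_fraction Dead fraction of the total population at
#'   inoculation (default 0).
#' @param backscatter_gain Signal per cell (default 1).
#' @param backscatter_detection_limit Signal floor (default 0).
#' @param gfp_gain GFP signal per viable transformed cell (default 1).
#' @param noise_sd Relative SD of multiplicative lognormal noise on the
#'   backscatter/GFP traces (default 0).
#' @param composition_noise_sd SD of additive Gaussian noise on composition
#'   logits (default 0).
#' @param rng_seed Integer seed; mandatory whenever any noise or
#'   heterogeneity is non-zero.
#' @param steps_per_stage Time-grid resolution within each stage (default 25).
#' @param sd_threshold Apparent growth rates at or below this value (per hour)
#'   are excluded from the replicate-SD summary (default 0.01).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params, schedule,
                              carrying_capacity = Inf,
                              mu_heterogeneity_sd = 0,
                              n_replicates = 1L,
                              initial_dead_fraction = 0,
                              backscatter_gain = 1,
                              backscatter_detection_limit = 0,
                              gfp_gain = 1,
                              noise_sd = 0,
                              composition_noise_sd = 0,
                              rng_seed = NULL,
                              steps_per_stage = 25L,
                              sd_threshold = 0.01) {
  stopifnot(inherits(params, "selection_parameters"),
            inherits(schedule, "stage_schedule"))
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1.", call. = FALSE)
  if (mu_heterogeneity_sd < 0 || noise_sd < 0 || composition_noise_sd < 0) {
    stop("Noise and heterogeneity SDs must be non-negative.", call. = FALSE)
  }
  if (!is.infinite(carrying_capacity) && carrying_capacity <= 0) {
    stop("`carrying_capacity` must be positive (or Inf to disable).",
         call. = FALSE)
  }
  stochastic <- mu_heterogeneity_sd > 0 || noise_sd > 0 ||
    composition_noise_sd > 0
  if (stochastic && is.null(rng_seed)) {
    stop("`rng_seed` is mandatory when any noise or heterogeneity is ",
         "non-zero.", call. = FALSE)
  }
  if (backscatter_gain <= 0) {
    stop("`backscatter_gain` must be positive.", call. = FALSE)
  }
  structure(
    list(params = params, schedule = schedule,
         carrying_capacity = carrying_capacity,
         mu_heterogeneity_sd = mu_heterogeneity_sd,
         n_replicates = as.integer(n_replicates),
         initial_dead_fraction = initial_dead_fraction,
         backscatter_gain = backscatter_gain,
         backscatter_detection_limit = backscatter_detection_limit,
         gfp_gain = gfp_gain,
         noise_sd = noise_sd,
         composition_noise_sd = composition_noise_sd,
         rng_seed = rng_seed,
         steps_per_stage = as.integer(steps_per_stage),
         sd_threshold = sd_threshold),
    class = "simulation_config"
  )
}

# one stage for one replicate: closed forms without capacity, otherwise the
# logistic-braked ODE (brake on growing pools only; the brake factor is
# floored at 0 so an over-capacity culture stalls instead of shrinking, and
# death is never braked)
run_stage_once <- function(mu1, mu2, state, duration, K, n_steps) {
  times <- seq(0, duration, length.out = n_steps)
  if (is.infinite(K)) {
    cx1 <- state$viable_transformed * exp(mu1 * times)
    cx2 <- state$viable_nontransformed * exp(mu2 * times)
    died <- pmax(state$viable_nontransformed - cx2, 0)
    data.frame(t = times, viable_transformed = cx1,
               viable_nontransformed = cx2, dead = state$dead + died)
  } else {
    rhs <- function(t, y, parms) {
      brake <- max(0, 1 - (y[1L] + y[2L]) / K)
      d1 <- if (mu1 > 0) mu1 * y[1L] * brake else mu1 * y[1L]
      d2 <- if (mu2 > 0) mu2 * y[2L] * brake else mu2 * y[2L]
      ddead <- max(0, -d2)
      list(c(d1, d2, ddead))
    }
    y0 <- c(state$viable_transformed, state$viable_nontransformed, state$dead)
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda")
    data.frame(t = times, viable_transformed = pmax(sol[, 2L], 0),
               viable_nontransformed = pmax(sol[, 3L], 0),
               dead = pmax(sol[, 4L], 0))
  }
}

#' Simulate a full selection run
#'
#' Evolves every replicate lineage through the scheduled stages.  Within a
#' stage, pools follow the two-subpopulation kinetics (closed forms, or the
#' logistic-braked variant when a carrying capacity is set).  At each
#' transfer, *every* pool -- including dead cells -- is multiplied by the
#' dilution factor, so all composition percentages are preserved across
#' transfers.  Observation proxies and noise are applied on top of the
#' deterministic pools; given the same config and seed the output is
#' bit-identical.
#'
#' @param config A [simulation_config()].
#' @return An object of class `alcs_simulation` with elements
#'   `timeseries` (tidy data.frame: `replicate`, `stage`, `time_h`,
#'   `viable_transformed`, `viable_nontransformed`, `dead`, `backscatter`,
#'   `gfp`), `mu1_replicates` (the per-replicate growth rates used), and
#'   `config`.
#' @export
simulate_selection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  sched <- config$schedule
  n_rep <- config$n_replicates

  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  mu1_rep <- rep(p$mu1, n_rep)
  if (config$mu_heterogeneity_sd > 0) {
    for (i in seq_len(n_rep)) {
      draw <- -1
      while (draw <= 0) {  # truncate at 0: growth rates are positive
        draw <- stats::rnorm(1L, p$mu1, config$mu_heterogeneity_sd)
      }
      mu1_rep[i] <- draw
    }
  }

  out <- vector("list", n_rep * nrow(sched$stages))
  idx <- 1L
  for (r in seq_len(n_rep)) {
    state <- initial_state(p, config$initial_dead_fraction)
    for (s in seq_len(nrow(sched$stages))) {
      stage <- sched$stages[s, ]
      grid <- run_stage_once(mu1_rep[r], p$mu2, state, stage$duration_h,
                             config$carrying_capacity, config$steps_per_stage)
      if (any(!is.finite(as.matrix(grid[-1L])))) {
        warning("Population counts overflowed; consider enabling a carrying ",
                "capacity.", call. = FALSE)
        grid[-1L] <- lapply(grid[-1L], function(x) {
          x[!is.finite(x)] <- .Machine$double.xmax
          x
        })
      }
      grid$time_h <- stage$start_time_h + grid$t
      grid$t <- NULL
      grid$replicate <- r
      grid$stage <- s
      out[[idx]] <- grid
      idx <- idx + 1L
      end <- grid[nrow(grid), ]
      state <- population_state(end$time_h, end$viable_transformed,
                                end$viable_nontransformed, end$dead)
      if (s < nrow(sched$stages)) {  # transfer: uniform dilution of all pools
        dil <- sched$dilution
        state <- population_state(state$time,
                                  state$viable_transformed * dil,
                                  state$viable_nontransformed * dil,
                                  state$dead * dil)
      }
    }
  }
  ts <- do.call(rbind, out)
  ts <- ts[, c("replicate", "stage", "time_h", "viable_transformed",
               "viable_nontransformed", "dead")]

  # the scattering trace tracks intact (viable) biomass; debris from lysed
  # dead cells is neglected in the observation model
  viable <- ts$viable_transformed + ts$viable_nontransformed
  ts$backscatter <- backscatter_proxy(viable, config$backscatter_gain,
                                      config$backscatter_detection_limit)
  ts$gfp <- config$gfp_gain * ts$viable_transformed
  if (config$noise_sd > 0) {
    n <- nrow(ts)
    sdlog <- sqrt(log(1 + config$noise_sd^2))
    ts$backscatter <- ts$backscatter *
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    ts$gfp <- ts$gfp * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  rownames(ts) <- NULL
  structure(
    list(timeseries = ts, mu1_replicates = mu1_rep, config = config),
    class = "alcs_simulation"
  )
}

#' @export
print.alcs_simulation <- function(x, ...) {
  comp <- stage_compositions(x)
  final <- comp[comp$stage == max(comp$stage), ]
  cat(sprintf("ALCS simulation: %d replicate(s), %d stage(s)\n",
              x$config$n_replicates, nrow(x$config$schedule$stages)))
  cat(sprintf("  final viable transformed: %.2f%% (mean of replicates)\n",
              mean(final$pct_viable_transformed_of_viable)))
  invisible(x)
}

#' Backscatter observation proxy
#'
#' Maps a cell count to the light-scattering signal of the microbioreactor:
#' linear in total cells above a detection limit, flat at the limit below it.
#'
#' @param total_cells Total cell count (viable + dead), vectorised.
#' @param gain Signal per cell (positive).
#' @param detection_limit Signal floor (default 0).
#' @return Signal values, `pmax(gain * total_cells, detection_limit)`.
#' @export
backscatter_proxy <- function(total_cells, gain = 1, detection_limit = 0) {
  if (!is.numeric(gain) || gain <= 0) {
    stop("`gain` must be positive.", call. = FALSE)
  }
  pmax(gain * total_cells, detection_limit)
}

#' Stage-end population compositions
#'
#' Extracts, for every replicate and stage, the composition at the stage end:
#' percentages of the total population (viable transformed, viable
#' non-transformed, dead) and of the viable population only (the quantity
#' flow-cytometry gating reports after excluding propidium-iodide-positive
#' events).  Optional logit noise configured on the simulation is applied
#' here, after which percentages are renormalised to sum to 100.
#'
#' @param sim An [simulate_selection()] result.
#' @return A data.frame with one row per replicate x stage.
#' @export
stage_compositions <- function(sim) {
  stopifnot(inherits(sim, "alcs_simulation"))
  ts <- sim$timeseries
  last <- stats::aggregate(time_h ~ replicate + stage, ts, max)
  comp <- merge(last, ts, by = c("replicate", "stage", "time_h"))
  comp <- comp[order(comp$replicate, comp$stage), ]
  tot <- comp$viable_transformed + comp$viable_nontransformed + comp$dead
  viable <- comp$viable_transformed + comp$viable_nontransformed
  pct <- cbind(
    viable_transformed = 100 * comp$viable_transformed / tot,
    viable_nontransformed = 100 * comp$viable_nontransformed / tot,
    dead = 100 * comp$dead / tot
  )
  nsd <- sim$config$composition_noise_sd
  if (nsd > 0) {
    # derived sub-seed: repeated calls on the same simulation give the same
    # noisy compositions
    set.seed(sim$config$rng_seed %% 2147483647L + 1L)
    pct <- t(apply(pct, 1L, function(p) {
      pr <- pmin(pmax(p / 100, 1e-12), 1 - 1e-12)
      lg <- log(pr / (1 - pr)) + stats::rnorm(length(pr), 0, nsd)
      q <- 1 / (1 + exp(-lg))
      100 * q / sum(q)
    }))
    colnames(pct) <- c("viable_transformed", "viable_nontransformed", "dead")
  }
  viable_pct <- pct[, "viable_transformed"] + pct[, "viable_nontransformed"]
  data.frame(
    replicate = comp$replicate,
    stage = comp$stage,
    time_h = comp$time_h,
    pct_viable_transformed = pct[, "viable_transformed"],
    pct_viable_nontransformed = pct[, "viable_nontransformed"],
    pct_dead = pct[, "dead"],
    pct_viable_transformed_of_viable =
      ifelse(viable_pct > 0, 100 * pct[, "viable_transformed"] / viable_pct,
             NA_real_),
    pct_viable_nontransformed_of_viable =
      ifelse(viable_pct > 0,
             100 * pct[, "viable_nontransformed"] / viable_pct, NA_real_),
    row.names = NULL
  )
}

#' Apparent growth rates per stage, with homogeneity summary
#'
#' Computes, for every replicate and stage, the log-slope of the total viable
#' count over the stage (the same estimator used for plate growth), then
#' summarises across replicates: the mean rate and the replicate SD expressed
#' as percent of the mean (coefficient of variation).  Replicates whose rate
#' does not exceed `threshold` are excluded from the SD, mirroring the
#' convention of discarding non-growing wells from the homogeneity readout;
#' when fewer than two replicates qualify the SD is reported as missing.
#'
#' @param sim An [simulate_selection()] result.
#' @param threshold Exclusion threshold in per hour; defaults to the value
#'   stored in the simulation config (0.01).
#' @param on Signal the rate is measured on: `"viable"` (the model's total
#'   viable count, default) or `"backscatter"` (the detection-limited, noisy
#'   observation proxy -- what an instrument actually sees, and the right
#'   choice when emulating measured stage rates).
#' @return A data.frame with columns `stage`, `mean_rate`, `sd_rate`,
#'   `sd_percent`, `n_included`, plus attribute `per_replicate` holding the
#'   replicate-level rates.
#' @export
apparent_growth_rates <- function(sim, threshold = NULL,
                                  on = c("viable", "backscatter")) {
  stopifnot(inherits(sim, "alcs_simulation"))
  on <- match.arg(on)
  if (is.null(threshold)) threshold <- sim$config$sd_threshold
  ts <- sim$timeseries
  per <- do.call(rbind, lapply(
    split(ts, list(ts$replicate, ts$stage), drop = TRUE),
    function(d) {
      viable <- if (on == "viable") {
        d$viable_transformed + d$viable_nontransformed
      } else {
        d$backscatter
      }
      keep <- viable > 0
      rate <- if (sum(keep) >= 2L) {
        unname(stats::coef(stats::lm(log(viable[keep]) ~ d$time_h[keep]))[2L])
      } else {
        NA_real_
      }
      data.frame(replicate = d$replicate[1L], stage = d$stage[1L],
                 rate = rate)
    }))
  per <- per[order(per$stage, per$replicate), ]
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$stage), function(d) {
    incl <- d$rate[!is.na(d$rate) & d$rate > threshold]
    sd_rate <- if (length(incl) >= 2L) stats::sd(incl) else NA_real_
    mean_incl <- if (length(incl) >= 1L) mean(incl) else NA_real_
    data.frame(
      stage = d$stage[1L],
      mean_rate = mean(d$rate, na.rm = TRUE),
      sd_rate = sd_rate,
      sd_percent = if (!is.na(sd_rate) && !is.na(mean_incl) &&
                       abs(mean_incl) > 0) 100 * sd_rate / abs(mean_incl)
                   else NA_real_,
      n_included = length(incl)
    )
  }))
  rownames(summ) <- NULL
  attr(summ, "per_replicate") <- per
  summ
}
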
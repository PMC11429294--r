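#' Organism presets for synthetic scenarios
#'
#' Frozen parameter sets for the three reference hosts, so that tests and
#' examples cite one source of truth.  Growth rates are the plate-derived
#' values (0.25 /h for *E. coli*, 0.15 /h for *P. putida*, 0.19 /h for
#' *C. glutamicum*); the non-transformed rate is tied to the growth rate via
#' `k = -2.8`; the initial transformed fraction is `f = 1e-4` and the
#' selection criterion `s = 0.02`.  The *E. coli* preset carries an initial
#' dead fraction of 0.43 (heat-shock casualties); the other hosts default to
#' 0, having no measured figure.  *C. glutamicum* carries a first-stage
#' resting multiplier of 2 (slow adaptation in liquid culture).
#'
#' @param name One of `"ecoli"`, `"pputida"`, `"cglutamicum"`.
#' @return A list of class `organism_preset` with elements `label`, `mu1`,
#'   `k`, `f`, `s`, `cell_footprint_mm2`, `initial_dead_fraction`,
#'   `resting_multiplier`, `initial_total`.
#' @examples
#' organism_preset("ecoli")
#' @export
organism_preset <- function(name = c("ecoli", "pputida", "cglutamicum")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("ecoli", "pputida", "cglutamicum")) {
    stop("Unknown preset '", paste(name, collapse = ","),
         "'. Valid presets: ecoli, pputida, cglutamicum.", call. = FALSE)
  }
  base <- list(k = -2.8, f = 1e-4, s = 0.02, initial_total = 1e4,
               resting_multiplier = 1, initial_dead_fraction = 0)
  preset <- switch(name,
    ecoli = utils::modifyList(base, list(
      label = "E. coli", mu1 = 0.25, cell_footprint_mm2 = 2.2e-6,
      initial_dead_fraction = 0.43)),
    pputida = utils::modifyList(base, list(
      label = "P. putida", mu1 = 0.15, cell_footprint_mm2 = 2e-6)),
    cglutamicum = utils::modifyList(base, list(
      label = "C. glutamicum", mu1 = 0.19, cell_footprint_mm2 = 2e-6,
      resting_multiplier = 2))
  )
  structure(preset, class = "organism_preset")
}

#' Selection parameters from a preset
#'
#' @param preset An [organism_preset()] or preset name.
#' @return A [selection_parameters()] object.
#' @export
preset_parameters <- function(preset) {
  if (is.character(preset)) preset <- organism_preset(preset)
  stopifnot(inherits(preset, "organism_preset"))
  selection_parameters(mu1 = preset$mu1, k = preset$k, f = preset$f,
                       s = preset$s, initial_total = preset$initial_total)
}

#' Default stage schedule for a preset
#'
#' Chains the requirement computation and the planner with the preset's
#' generation time and resting multiplier.
#'
#' @param preset An [organism_preset()] or preset name.
#' @return A `stage_schedule`.
#' @export
preset_schedule <- function(preset) {
  if (is.character(preset)) preset <- organism_preset(preset)
  params <- preset_parameters(preset)
  build_schedule(required_time(params),
                 generation_time = log(2) / params$mu1,
                 resting_multiplier = preset$resting_multiplier,
                 organism_label = preset$label)
}

#' Generate synthetic colony-area time series
#'
#' Emulates plate imaging: colony area grows as
#' `footprint * N0 * exp(mu1 * t)`, optionally perturbed by multiplicative
#' lognormal noise, sampled at evenly spaced times per replicate.
#'
#' @param preset An [organism_preset()] or preset name.
#' @param n_timepoints Images per replicate (>= 2, default 6).
#' @param n_replicates Plate replicates (default 3).
#' @param t_max Last imaging time in hours (default 25).
#' @param initial_cells Cells at time zero per replicate (default 1000).
#' @param noise_sd Relative SD of the lognormal area noise (default 0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return A data.frame with columns `replicate_id`, `time_h`,
#'   `cfu_area_mm2`, and attributes `cell_footprint` and `mu1`.
#' @examples
#' areas <- generate_colony_series("ecoli", noise_sd = 0)
#' estimate_growth_rates(areas, attr(areas, "cell_footprint"))
#' @export
generate_colony_series <- function(preset, n_timepoints = 6L,
                                   n_replicates = 3L, t_max = 25,
                                   initial_cells = 1000, noise_sd = 0,
                                   seed = NULL) {
  if (is.character(preset)) preset <- organism_preset(preset)
  stopifnot(inherits(preset, "organism_preset"), n_timepoints >= 2L,
            n_replicates >= 1L, t_max > 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is required when `noise_sd` > 0.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_max, length.out = n_timepoints)
  sdlog <- if (noise_sd > 0) sqrt(log(1 + noise_sd^2)) else 0
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    area <- preset$cell_footprint_mm2 * initial_cells *
      exp(preset$mu1 * times)
    if (sdlog > 0) {
      area <- area * stats::rlnorm(length(area), -sdlog^2 / 2, sdlog)
    }
    data.frame(replicate_id = sprintf("rep%02d", r), time_h = times,
               cfu_area_mm2 = area, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "cell_footprint") <- preset$cell_footprint_mm2
  attr(out, "mu1") <- preset$mu1
  out
}

#' Generate stage-wise population fractions
#'
#' Runs the stage simulator for a preset (ground truth) and returns the
#' composition table at every stage end -- including the inoculation
#' composition at time zero as "stage 0" -- in both the four-way gating
#' layout (viable/dead x GFP+/-; dead cells are GFP-negative in this model,
#' since only non-transformed cells die) and the viable-only percentages the
#' fitter consumes.
#'
#' @param preset An [organism_preset()] or preset name.
#' @param schedule Optional `stage_schedule`; defaults to
#'   [preset_schedule()].
#' @param composition_noise_sd Additive Gaussian SD on composition logits
#'   (default 0).
#' @param seed Integer seed; required when noise is non-zero.
#' @return A list with `composition` (data.frame: `stage`, `time_h`, four-way
#'   percentages summing to 100) and `observations` (a
#'   [fraction_observations()] of the viable-only percentages).
#' @export
generate_stage_fractions <- function(preset, schedule = NULL,
                                     composition_noise_sd = 0, seed = NULL) {
  if (is.character(preset)) preset <- organism_preset(preset)
  stopifnot(inherits(preset, "organism_preset"))
  if (is.null(schedule)) schedule <- preset_schedule(preset)
  params <- preset_parameters(preset)
  cfg <- simulation_config(
    params, schedule,
    initial_dead_fraction = preset$initial_dead_fraction,
    composition_noise_sd = composition_noise_sd,
    rng_seed = if (composition_noise_sd > 0) seed else NULL
  )
  sim <- simulate_selection(cfg)
  comp <- stage_compositions(sim)
  comp <- comp[comp$replicate == 1L, ]

  # prepend the inoculation composition as stage 0
  s0 <- initial_state(params, preset$initial_dead_fraction)
  tot0 <- s0$viable_transformed + s0$viable_nontransformed + s0$dead
  viab0 <- s0$viable_transformed + s0$viable_nontransformed
  stage0 <- data.frame(
    replicate = 1L, stage = 0L, time_h = 0,
    pct_viable_transformed = 100 * s0$viable_transformed / tot0,
    pct_viable_nontransformed = 100 * s0$viable_nontransformed / tot0,
    pct_dead = 100 * s0$dead / tot0,
    pct_viable_transformed_of_viable = 100 * s0$viable_transformed / viab0,
    pct_viable_nontransformed_of_viable =
      100 * s0$viable_nontransformed / viab0
  )
  comp <- rbind(stage0, comp)

  composition <- data.frame(
    stage = comp$stage,
    time_h = comp$time_h,
    pct_viable_gfp_pos = comp$pct_viable_transformed,
    pct_viable_gfp_neg = comp$pct_viable_nontransformed,
    pct_dead_gfp_pos = 0,  # transformed cells do not die in this model
    pct_dead_gfp_neg = comp$pct_dead
  )
  obs <- fraction_observations(
    times = comp$time_h,
    pct_transformed = comp$pct_viable_transformed_of_viable,
    pct_nontransformed = comp$pct_viable_nontransformed_of_viable
  )
  list(composition = composition, observations = obs)
}

#' Generate a dilution-series set of simulation configs
#'
#' Emulates inoculating the selection with differently diluted transformation
#' approaches: each config starts from `n0` transformed cells (with the
#' non-transformed and dead pools scaled by the same dilution, so `f` and the
#' dead fraction are unchanged), sharing every other setting.  A carrying
#' capacity is enabled by default so that large inocula saturate, reproducing
#' the flattening of end-point biomass against inoculum size seen when oxygen
#' becomes limiting.
#'
#' @param preset An [organism_preset()] or preset name.
#' @param initial_cfus Vector of initial transformed cell counts (>= 0;
#'   zero-count configs are returned with a token single transformed cell
#'   scaled to zero via `initial_total`, i.e. an empty well).
#' @param carrying_capacity Shared viable-cell capacity (default 2000, of the
#'   order of the largest end-point population so the upper inocula saturate).
#' @param schedule Optional `stage_schedule`; defaults to [preset_schedule()].
#' @param seed Integer seed recorded on each config.
#' @return A named list of [simulation_config()] objects (`cfu_<n>`).
#' @export
generate_dilution_series <- function(preset, initial_cfus,
                                     carrying_capacity = 2000,
                                     schedule = NULL, seed = 1L) {
  if (is.character(preset)) preset <- organism_preset(preset)
  stopifnot(inherits(preset, "organism_preset"), all(initial_cfus >= 0))
  if (is.null(schedule)) schedule <- preset_schedule(preset)
  configs <- lapply(initial_cfus, function(n0) {
    total <- if (n0 > 0) n0 / preset$f else .Machine$double.eps
    params <- selection_parameters(mu1 = preset$mu1, k = preset$k,
                                   f = preset$f, s = preset$s,
                                   initial_total = total)
    simulation_config(params, schedule,
                      carrying_capacity = carrying_capacity,
                      initial_dead_fraction = preset$initial_dead_fraction,
                      rng_seed = seed)
  })
  names(configs) <- paste0("cfu_", initial_cfus)
  configs
}
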
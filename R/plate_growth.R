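#' Colony-area time series from an agar plate
#'
#' Container for the raw input of plate-based growth estimation: the total
#' colony (CFU) area at successive imaging times, together with the average
#' footprint of a single cell of the organism, which converts area into an
#' absolute cell-number estimate.  Typical footprints are 2.2e-6 mm^2 for
#' *E. coli* and 2e-6 mm^2 for *P. putida* and *C. glutamicum*.
#'
#' @param timepoints Imaging times in hours; strictly increasing, at least 2.
#' @param cfu_area Total CFU area in mm^2 per timepoint; non-negative.
#' @param cell_footprint Average single-cell area in mm^2; positive.
#' @param organism_label Free-text organism tag.
#' @param replicate_id Identifier of the plate/well replicate.
#' @return An object of class `colony_area_series`.
#' @export
colony_area_series <- function(timepoints, cfu_area, cell_footprint,
                               organism_label = "", replicate_id = "r1") {
  stopifnot(is.numeric(timepoints), is.numeric(cfu_area))
  if (length(timepoints) < 2L) {
    stop("At least 2 timepoints are required.", call. = FALSE)
  }
  if (length(cfu_area) != length(timepoints)) {
    stop("`cfu_area` and `timepoints` must have equal length.", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing.", call. = FALSE)
  }
  if (any(cfu_area < 0)) {
    stop("`cfu_area` must be non-negative.", call. = FALSE)
  }
  if (!is.numeric(cell_footprint) || length(cell_footprint) != 1L ||
      cell_footprint <= 0) {
    stop("`cell_footprint` must be a positive scalar (mm^2 per cell).",
         call. = FALSE)
  }
  structure(
    list(timepoints = as.numeric(timepoints),
         cfu_area = as.numeric(cfu_area),
         cell_footprint = cell_footprint,
         organism_label = organism_label,
         replicate_id = replicate_id),
    class = "colony_area_series"
  )
}

#' Estimate cell number from colony area
#'
#' Divides the observed CFU area by the average footprint of a single cell,
#' assuming colonies keep a constant number of cell layers over the imaging
#' window (a 2D approximation that, if anything, underestimates growth and so
#' keeps the downstream selection design conservative).
#'
#' @param area CFU area in mm^2 (vectorised, non-negative).
#' @param cell_footprint Average single-cell area in mm^2 (positive scalar).
#' @return Estimated absolute cell number, `area / cell_footprint`.
#' @examples
#' estimate_cell_number(0.22, 2.2e-6)  # 1e5 cells
#' @export
estimate_cell_number <- function(area, cell_footprint) {
  stopifnot(is.numeric(area), is.numeric(cell_footprint))
  if (length(cell_footprint) != 1L || !is.finite(cell_footprint) ||
      cell_footprint <= 0) {
    stop("`cell_footprint` must be a positive scalar.", call. = FALSE)
  }
  if (any(area < 0)) stop("`area` must be non-negative.", call. = FALSE)
  area / cell_footprint
}

#' Estimate the exponential growth rate from a colony-area series
#'
#' Converts areas to cell numbers and fits the exponential growth law
#' `N(t) = N0 * exp(mu t)` on the log scale: a two-point difference quotient
#' `mu = (ln N(t2) - ln N(t1)) / (t2 - t1)` when exactly two positive counts
#' are available, and an ordinary least-squares fit of `ln N` versus `t`
#' otherwise.  Timepoints with zero area carry no log-scale information and
#' are dropped with a warning.
#'
#' @param series A [colony_area_series()].
#' @return An object of class `growth_estimate`: `mu` (per hour),
#'   `generation_time` (h, `ln 2 / mu`; `NA` when `mu <= 0`), `n_points`,
#'   `nonpositive_rate` flag, `replicate_id`, `organism_label`.
#' @examples
#' s <- colony_area_series(c(0, 27.631), c(1e3, 1e6) * 2.2e-6, 2.2e-6)
#' estimate_growth_rate(s)  # mu ~ 0.25 /h
#' @export
estimate_growth_rate <- function(series) {
  stopifnot(inherits(series, "colony_area_series"))
  counts <- estimate_cell_number(series$cfu_area, series$cell_footprint)
  keep <- counts > 0
  if (any(!keep)) {
    warning(sprintf("Dropping %d timepoint(s) with zero colony area from the log fit.",
                    sum(!keep)), call. = FALSE)
  }
  t <- series$timepoints[keep]
  n <- counts[keep]
  if (length(n) < 2L) {
    stop("Fewer than 2 timepoints with positive counts: cannot estimate a ",
         "growth rate.", call. = FALSE)
  }
  if (length(n) == 2L) {
    mu <- (log(n[2L]) - log(n[1L])) / (t[2L] - t[1L])
  } else {
    mu <- unname(stats::coef(stats::lm(log(n) ~ t))[2L])
  }
  nonpositive <- mu <= 0
  if (nonpositive) {
    warning("Estimated growth rate is non-positive; generation time undefined.",
            call. = FALSE)
  }
  structure(
    list(mu = mu,
         generation_time = if (nonpositive) NA_real_ else log(2) / mu,
         n_points = length(n),
         nonpositive_rate = nonpositive,
         replicate_id = series$replicate_id,
         organism_label = series$organism_label),
    class = "growth_estimate"
  )
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Growth estimate (%s, replicate %s): mu = %.4g /h",
              if (nzchar(x$organism_label)) x$organism_label else "unlabelled",
              x$replicate_id, x$mu))
  if (!is.na(x$generation_time)) {
    cat(sprintf(", generation time = %.4g h", x$generation_time))
  }
  cat(sprintf(" [%d points]\n", x$n_points))
  invisible(x)
}

#' Doubling time from a growth rate
#'
#' @param mu Growth rate per hour; must be positive.
#' @return Generation (doubling) time in hours, `ln 2 / mu`.
#' @examples
#' generation_time(0.25)  # 2.7726 h
#' @export
generation_time <- function(mu) {
  stopifnot(is.numeric(mu))
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("`mu` must be positive: no finite doubling time otherwise.",
         call. = FALSE)
  }
  log(2) / mu
}

#' Replicate-level growth estimation from a tidy colony-area table
#'
#' Runs [estimate_growth_rate()] per replicate and aggregates to the
#' mean +/- SD presentation customary for plate experiments.
#'
#' @param data A data.frame with columns `replicate_id`, `time_h`,
#'   `cfu_area_mm2` (the CSV dialect written by the synthetic generator).
#' @param cell_footprint Average single-cell area in mm^2.
#' @param organism_label Optional organism tag.
#' @return A list of class `growth_estimate_summary`: `mu` (mean across
#'   replicates), `sd_mu`, `generation_time` (`ln 2 /` mean mu),
#'   `n_replicates`, and `per_replicate` (data.frame).
#' @export
estimate_growth_rates <- function(data, cell_footprint, organism_label = "") {
  required <- c("replicate_id", "time_h", "cfu_area_mm2")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  per_rep <- lapply(split(data, data$replicate_id), function(d) {
    d <- d[order(d$time_h), ]
    est <- estimate_growth_rate(colony_area_series(
      d$time_h, d$cfu_area_mm2, cell_footprint,
      organism_label = organism_label,
      replicate_id = as.character(d$replicate_id[1L])
    ))
    data.frame(replicate_id = est$replicate_id, mu = est$mu,
               generation_time = est$generation_time,
               n_points = est$n_points)
  })
  per_rep <- do.call(rbind, per_rep)
  rownames(per_rep) <- NULL
  mu_mean <- mean(per_rep$mu)
  structure(
    list(mu = mu_mean,
         sd_mu = if (nrow(per_rep) > 1L) stats::sd(per_rep$mu) else NA_real_,
         generation_time = if (mu_mean > 0) log(2) / mu_mean else NA_real_,
         n_replicates = nrow(per_rep),
         organism_label = organism_label,
         per_replicate = per_rep),
    class = "growth_estimate_summary"
  )
}

#' @export
print.growth_estimate_summary <- function(x, ...) {
  cat(sprintf("Growth rate (%s): %.3g +/- %.3g /h (n = %d)\n",
              if (nzchar(x$organism_label)) x$organism_label else "unlabelled",
              x$mu, x$sd_mu, x$n_replicates))
  if (!is.na(x$generation_time)) {
    cat(sprintf("Generation time: %.3g h\n", x$generation_time))
  }
  invisible(x)
}
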
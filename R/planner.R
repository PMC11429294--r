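#' Build the stage/transfer schedule for a selection run
#'
#' Translates a generation-count requirement into the concrete serial-passage
#' layout used on the liquid-handling platform: the first well is cultivated
#' for `first_stage_generations` generation times (default 2, the extra
#' generation absorbing the post-transformation lag phase), every subsequent
#' well for exactly one generation time, with a 1:2 transfer (half the working
#' volume into an equal volume of fresh antibiotic medium) between wells.
#' Wells are appended until the scheduled generations cover the requirement.
#'
#' For slow-adapting hosts a `resting_multiplier` stretches the *duration* of
#' the first stage (e.g. 2 for *C. glutamicum*, doubling the first well's
#' residence time) without changing its generation bookkeeping, so the well
#' count matches the lag-free design.
#'
#' @param requirement A `selection_requirement` from [required_time()], or a
#'   plain positive integer number of generations to schedule.
#' @param generation_time Generation time of the transformed strain in hours.
#' @param first_stage_generations Generations booked to the first well
#'   (default 2: one growth + one lag equivalent).
#' @param resting_multiplier Duration multiplier applied to the first stage
#'   only (default 1).
#' @param dilution Transfer dilution as the carried-over fraction of the
#'   working volume, in (0, 1); default 0.5 (1:2).
#' @param inoculum_volume_ul Volume of transformation approach inoculated into
#'   the first well (default 50).
#' @param initial_medium_volume_ul Fresh medium preloaded in the first well
#'   (default 950).
#' @param working_volume_ul Working volume per well (default 1000).
#' @param organism_label Free-text organism tag.
#' @param wells Optional character vector of well IDs to use (defaults to
#'   `A1`, `A2`, ...).
#' @return An object of class `stage_schedule`: `stages` (data.frame
#'   `well_id`, `start_time_h`, `duration_h`, `duration_generations`),
#'   `transfers` (data.frame `time_h`, `source_well`, `dest_well`,
#'   `transfer_volume_ul`, `fresh_medium_volume_ul`), plus the scalar
#'   settings.
#' @examples
#' req <- required_time(selection_parameters(mu1 = 0.25, mu2 = -0.7, f = 1e-4))
#' build_schedule(req, generation_time = log(2) / 0.25)  # 4 wells, 3 transfers
#' @export
build_schedule <- function(requirement, generation_time,
                           first_stage_generations = 2,
                           resting_multiplier = 1,
                           dilution = 0.5,
                           inoculum_volume_ul = 50,
                           initial_medium_volume_ul = 950,
                           working_volume_ul = 1000,
                           organism_label = "",
                           wells = NULL) {
  n_gen <- if (inherits(requirement, "selection_requirement")) {
    requirement$n_generations_scheduled
  } else {
    requirement
  }
  if (!is.numeric(n_gen) || length(n_gen) != 1L || n_gen < 1) {
    stop("The requirement must schedule at least 1 generation.", call. = FALSE)
  }
  stopifnot(is.numeric(generation_time), generation_time > 0)
  if (first_stage_generations < 1) {
    stop("`first_stage_generations` must be >= 1.", call. = FALSE)
  }
  if (resting_multiplier < 1) {
    stop("`resting_multiplier` must be >= 1.", call. = FALSE)
  }
  if (!is.numeric(dilution) || dilution <= 0 || dilution >= 1) {
    stop("`dilution` must lie strictly between 0 and 1 (carried-over ",
         "fraction).", call. = FALSE)
  }

  # generation bookkeeping: first well books `first_stage_generations`
  # (resting padding adds time, not generations), each further well books 1
  n_subsequent <- max(0L, as.integer(ceiling(n_gen - first_stage_generations)))
  booked <- c(first_stage_generations, rep(1, n_subsequent))
  durations_gen <- booked
  durations_gen[1L] <- first_stage_generations * resting_multiplier
  durations_h <- durations_gen * generation_time
  n_stages <- length(durations_h)

  if (is.null(wells)) {
    wells <- paste0("A", seq_len(n_stages))
  } else if (length(wells) < n_stages) {
    stop(sprintf("Need %d wells but only %d supplied.", n_stages,
                 length(wells)), call. = FALSE)
  }
  wells <- wells[seq_len(n_stages)]

  starts <- cumsum(c(0, durations_h[-n_stages]))
  stages <- data.frame(
    well_id = wells,
    start_time_h = starts,
    duration_h = durations_h,
    duration_generations = durations_gen,
    stringsAsFactors = FALSE
  )
  transfer_vol <- dilution * working_volume_ul
  transfers <- if (n_stages > 1L) {
    data.frame(
      time_h = starts[-1L],
      source_well = wells[-n_stages],
      dest_well = wells[-1L],
      transfer_volume_ul = transfer_vol,
      fresh_medium_volume_ul = working_volume_ul - transfer_vol,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(time_h = numeric(0), source_well = character(0),
               dest_well = character(0), transfer_volume_ul = numeric(0),
               fresh_medium_volume_ul = numeric(0), stringsAsFactors = FALSE)
  }
  structure(
    list(stages = stages, transfers = transfers,
         generation_time = generation_time,
         dilution = dilution,
         inoculum_volume_ul = inoculum_volume_ul,
         initial_medium_volume_ul = initial_medium_volume_ul,
         working_volume_ul = working_volume_ul,
         first_stage_generations = first_stage_generations,
         resting_multiplier = resting_multiplier,
         organism_label = organism_label),
    class = "stage_schedule"
  )
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat(sprintf("Stage schedule%s: %d wells, %d transfers, %.4g h total\n",
              if (nzchar(x$organism_label)) paste0(" (", x$organism_label, ")")
              else "",
              nrow(x$stages), nrow(x$transfers), total_time(x)))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Total scheduled cultivation time
#'
#' @param schedule A [build_schedule()] result.
#' @return Total duration in hours across all stages.
#' @export
total_time <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  sum(schedule$stages$duration_h)
}

#' Assign parallel selections to microplate wells
#'
#' Lays out `n_selections` runs of `wells_per_selection` contiguous wells each
#' in row-major order on a standard plate.  A 48-well plate (6 rows x 8
#' columns) holds twelve 4-well selections; a 96-well plate holds 24.
#'
#' @param n_selections Number of parallel selection runs.
#' @param plate_format One of 48, 96, 384 wells.
#' @param wells_per_selection Wells per run (schedule length, default 4).
#' @return A named list mapping `selection_1`, ... to character vectors of
#'   well IDs.
#' @examples
#' plate_layout(12, 48)          # fills the plate
#' plate_layout(1, 48)$selection_1  # "A1" "A2" "A3" "A4"
#' @export
plate_layout <- function(n_selections, plate_format = 48,
                         wells_per_selection = 4) {
  dims <- switch(as.character(plate_format),
                 "48" = c(6L, 8L),
                 "96" = c(8L, 12L),
                 "384" = c(16L, 24L),
                 stop("`plate_format` must be one of 48, 96, 384.",
                      call. = FALSE))
  stopifnot(n_selections >= 1, wells_per_selection >= 1)
  capacity <- dims[1L] * floor(dims[2L] / wells_per_selection)
  if (n_selections > capacity) {
    stop(sprintf(paste0("Capacity exceeded: a %d-well plate holds at most %d ",
                        "selections of %d wells (row-major, no row ",
                        "wrapping)."),
                 plate_format, capacity, wells_per_selection), call. = FALSE)
  }
  rows <- LETTERS[seq_len(dims[1L])]
  per_row <- floor(dims[2L] / wells_per_selection)
  layout <- vector("list", n_selections)
  for (i in seq_len(n_selections)) {
    row <- rows[(i - 1L) %/% per_row + 1L]
    col0 <- ((i - 1L) %% per_row) * wells_per_selection
    layout[[i]] <- paste0(row, col0 + seq_len(wells_per_selection))
  }
  names(layout) <- paste0("selection_", seq_len(n_selections))
  layout
}

#' Export a schedule as a liquid-handling worklist
#'
#' Flattens a schedule into one row per pipetting event: the initial
#' inoculation, every transfer, and a terminal harvest marker (which carries
#' the end time so the schedule can be reconstructed from the worklist).
#' Rows are ordered by time, then destination well.
#'
#' @param schedule A [build_schedule()] result.
#' @return A data.frame with columns `time_h`, `event`, `source`, `dest`,
#'   `volume_ul`, `fresh_medium_ul`.
#' @export
export_worklist <- function(schedule) {
  stopifnot(inherits(schedule, "stage_schedule"))
  st <- schedule$stages
  tr <- schedule$transfers
  rows <- data.frame(
    time_h = 0,
    event = "inoculate",
    source = "inoculum",
    dest = st$well_id[1L],
    volume_ul = schedule$inoculum_volume_ul,
    fresh_medium_ul = schedule$initial_medium_volume_ul,
    stringsAsFactors = FALSE
  )
  if (nrow(tr) > 0L) {
    rows <- rbind(rows, data.frame(
      time_h = tr$time_h,
      event = "transfer",
      source = tr$source_well,
      dest = tr$dest_well,
      volume_ul = tr$transfer_volume_ul,
      fresh_medium_ul = tr$fresh_medium_volume_ul,
      stringsAsFactors = FALSE
    ))
  }
  last <- nrow(st)
  rows <- rbind(rows, data.frame(
    time_h = st$start_time_h[last] + st$duration_h[last],
    event = "harvest",
    source = st$well_id[last],
    dest = "",
    volume_ul = 0,
    fresh_medium_ul = 0,
    stringsAsFactors = FALSE
  ))
  rows <- rows[order(rows$time_h, rows$dest), ]
  rownames(rows) <- NULL
  rows
}

#' Reconstruct a schedule from an exported worklist
#'
#' Inverse of [export_worklist()] for round-trip checks and for re-importing
#' edited worklists.  Stage boundaries are taken from the transfer and harvest
#' times; the generation bookkeeping is recovered from the supplied
#' `generation_time`.
#'
#' @param worklist A data.frame as produced by [export_worklist()].
#' @param generation_time Generation time in hours used to express stage
#'   durations in generations.
#' @param first_stage_generations,resting_multiplier As in [build_schedule()];
#'   recorded on the rebuilt schedule.
#' @param organism_label Free-text organism tag.
#' @return A `stage_schedule`.
#' @export
schedule_from_worklist <- function(worklist, generation_time,
                                   first_stage_generations = 2,
                                   resting_multiplier = 1,
                                   organism_label = "") {
  needed <- c("time_h", "event", "source", "dest", "volume_ul",
              "fresh_medium_ul")
  missing_cols <- setdiff(needed, names(worklist))
  if (length(missing_cols) > 0L) {
    stop("Worklist is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  inoc <- worklist[worklist$event == "inoculate", , drop = FALSE]
  tr <- worklist[worklist$event == "transfer", , drop = FALSE]
  harv <- worklist[worklist$event == "harvest", , drop = FALSE]
  if (nrow(inoc) != 1L || nrow(harv) != 1L) {
    stop("Worklist must contain exactly one inoculation and one harvest row.",
         call. = FALSE)
  }
  tr <- tr[order(tr$time_h), , drop = FALSE]
  wells <- c(inoc$dest, tr$dest)
  boundaries <- c(0, tr$time_h, harv$time_h)
  durations_h <- diff(boundaries)
  working <- if (nrow(tr) > 0L) {
    tr$volume_ul[1L] + tr$fresh_medium_ul[1L]
  } else {
    inoc$volume_ul + inoc$fresh_medium_ul
  }
  dilution <- if (nrow(tr) > 0L) tr$volume_ul[1L] / working else 0.5
  stages <- data.frame(
    well_id = wells,
    start_time_h = boundaries[-length(boundaries)],
    duration_h = durations_h,
    duration_generations = durations_h / generation_time,
    stringsAsFactors = FALSE
  )
  transfers <- if (nrow(tr) > 0L) {
    data.frame(time_h = tr$time_h, source_well = tr$source,
               dest_well = tr$dest, transfer_volume_ul = tr$volume_ul,
               fresh_medium_volume_ul = tr$fresh_medium_ul,
               stringsAsFactors = FALSE)
  } else {
    data.frame(time_h = numeric(0), source_well = character(0),
               dest_well = character(0), transfer_volume_ul = numeric(0),
               fresh_medium_volume_ul = numeric(0), stringsAsFactors = FALSE)
  }
  structure(
    list(stages = stages, transfers = transfers,
         generation_time = generation_time,
         dilution = dilution,
         inoculum_volume_ul = inoc$volume_ul,
         initial_medium_volume_ul = inoc$fresh_medium_ul,
         working_volume_ul = working,
         first_stage_generations = first_stage_generations,
         resting_multiplier = resting_multiplier,
         organism_label = organism_label),
    class = "stage_schedule"
  )
}
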
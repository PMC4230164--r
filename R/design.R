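#' Acquisition geometry
#'
#' Describes the voxel grid and timing of one functional acquisition. Defaults
#' mirror a high-resolution slab acquisition: anisotropic 1.4 x 1.4 x 2.0 mm
#' voxels, TR 3 s, 112 volumes per run (336 s), 8 runs, on a desk-scale
#' 24 x 28 x 16 grid.
#'
#' @param grid_dims Integer triple, voxels per axis.
#' @param voxel_size_mm Positive real triple, voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes_per_run Volumes acquired per run.
#' @param n_runs Number of functional runs.
#' @return A list of class `acq_geometry`.
#' @export
acq_geometry <- function(grid_dims = c(24L, 28L, 16L),
                         voxel_size_mm = c(1.4, 1.4, 2.0),
                         tr_s = 3.0, n_volumes_per_run = 112L, n_runs = 8L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            tr_s > 0, n_volumes_per_run >= 1, n_runs >= 1)
  structure(list(grid_dims = grid_dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 tr_s = tr_s, n_volumes_per_run = as.integer(n_volumes_per_run),
                 n_runs = as.integer(n_runs)),
            class = "acq_geometry")
}

run_length_s <- function(geometry) geometry$n_volumes_per_run * geometry$tr_s

#' RAS+ affine for a geometry
#'
#' Maps 0-based voxel indices to world mm coordinates; the grid center sits at
#' the world origin.
#' @param geometry An [acq_geometry()].
#' @return 4 x 4 affine matrix.
#' @export
geometry_affine <- function(geometry) {
  vs <- geometry$voxel_size_mm
  orig <- -vs * (geometry$grid_dims - 1) / 2
  rbind(cbind(diag(vs), orig), c(0, 0, 0, 1))
}

#' Block-design experiment layout
#'
#' Builds the event table of a blocked stimulation experiment: per run, each
#' stimulus block (default 16 s) is preceded by a fixation block of the same
#' length, with a final fixation block closing the sequence; any remaining run
#' time is unmodeled rest. The within-run category order rotates Latin-square
#' style across runs (runs beyond one full rotation use the reversed category
#' list) so no two of the default 8 runs share an order.
#'
#' @param geometry An [acq_geometry()]; also sets the number of runs.
#' @param categories Stimulus category names.
#' @param block_duration_s Duration of every block, seconds.
#' @param blocks_per_category Stimulus blocks per category per run.
#' @param fixation_duration_s Duration of interleaved fixation blocks.
#' @return A list of class `experiment_design` with elements `geometry`,
#'   `events` (data.frame: `run`, `onset`, `duration`, `condition`; `run` is
#'   1-based, times in seconds) and `condition_names`.
#' @examples
#' d <- make_design()
#' sum(d$events$condition != "fixation")   # 32 stimulus blocks
#' @export
make_design <- function(geometry = acq_geometry(),
                        categories = c("face", "object", "body", "body_part"),
                        block_duration_s = 16,
                        blocks_per_category = 1L,
                        fixation_duration_s = block_duration_s) {
  stopifnot(length(categories) >= 2, block_duration_s > 0,
            blocks_per_category >= 1, fixation_duration_s >= 0)
  n_cat <- length(categories)
  n_stim <- n_cat * blocks_per_category
  total <- n_stim * block_duration_s + (n_stim + 1) * fixation_duration_s
  if (total > run_length_s(geometry)) {
    stop(sprintf("block schedule needs %.1f s but runs last only %.1f s",
                 total, run_length_s(geometry)))
  }
  events <- vector("list", geometry$n_runs)
  for (r in seq_len(geometry$n_runs)) {
    base <- if (((r - 1) %/% n_cat) %% 2 == 0) categories else rev(categories)
    rot <- (r - 1) %% n_cat
    ord <- if (rot == 0) base else c(base[-seq_len(rot)], base[seq_len(rot)])
    order_r <- rep(ord, blocks_per_category)
    onset <- 0
    rows <- list()
    for (b in seq_along(order_r)) {
      if (fixation_duration_s > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, onset = onset, duration = fixation_duration_s,
          condition = "fixation")
        onset <- onset + fixation_duration_s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, onset = onset, duration = block_duration_s,
        condition = order_r[b])
      onset <- onset + block_duration_s
    }
    if (fixation_duration_s > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, onset = onset, duration = fixation_duration_s,
        condition = "fixation")
    }
    events[[r]] <- do.call(rbind, rows)
  }
  design <- structure(list(geometry = geometry,
                           events = do.call(rbind, events),
                           condition_names = categories),
                      class = "experiment_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  ev <- design$events
  stopifnot(all(ev$onset >= 0), all(ev$duration > 0))
  if (any(ev$onset + ev$duration > run_length_s(design$geometry) + 1e-9)) {
    stop("events extend past the end of a run")
  }
  for (r in unique(ev$run)) {
    er <- ev[ev$run == r, ]
    er <- er[order(er$onset), ]
    if (any(er$onset[-1] < (er$onset + er$duration)[-nrow(er)] - 1e-9)) {
      stop(sprintf("overlapping blocks in run %d", r))
    }
    for (cond in design$condition_names) {
      if (!any(er$condition == cond)) {
        stop(sprintf("run %d lacks a '%s' block", r, cond))
      }
    }
  }
  invisible(design)
}
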
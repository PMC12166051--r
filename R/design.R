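# Canonical goal trajectories, stored as signed offsets goal - E[DAS points].
# The published design constrains: 20 goals per trajectory; the first two
# offsets within +/-5 so the DAS starts out near-optimal in every block;
# per-trajectory maxima of |offset| spanning 12..24; and 43.75% of all
# trials (140/320) inside the |offset| <= 5 window.  The concrete integer
# tables below honor all of these: maxima are {24, 20, 16, 12} and
# 4 + 8 + 9 + 14 = 35 of the 80 trajectory trials are in-window, giving
# 4 x 35 = 140 over the 16 blocks.  Trajectory 1 rises after the first
# half of the block and falls again; trajectory 4 stays mostly near zero.
.ynat_trajectories <- list(
  `1` = c(2L, 4L, 6L, 7L, 8L, 9L, 10L, 12L, 15L, 18L, 21L, 24L, 23L, 20L,
          17L, 14L, 11L, 8L, 5L, 3L),
  `2` = c(-1L, -4L, -6L, -9L, -12L, -15L, -18L, -20L, -19L, -17L, -14L,
          -11L, -8L, -6L, -4L, -2L, 0L, 2L, 4L, 5L),
  `3` = c(3L, 5L, 7L, 9L, 11L, 13L, 15L, 16L, 15L, 13L, 11L, 9L, 7L, 5L,
          3L, 1L, -1L, -3L, -4L, -5L),
  `4` = c(0L, -2L, 3L, 5L, -4L, 2L, 7L, 10L, 12L, 9L, 6L, 6L, -2L, 0L, 3L,
          -5L, 2L, 4L, -1L, 1L)
)

# Frozen pseudo-random order of trajectories over the 16 blocks: each
# segment of 4 blocks uses every trajectory once and no trajectory appears
# in two consecutive blocks (also across segment boundaries).
.ynat_block_trajectory <- c(1L, 2L, 3L, 4L, 2L, 4L, 1L, 3L, 4L, 2L, 3L, 1L,
                            3L, 1L, 4L, 2L)

# Frozen bonus blocks: 8 of 16, exactly two of the four presentations of
# each trajectory.
.ynat_bonus_blocks <- c(2L, 3L, 6L, 7L, 12L, 13L, 15L, 16L)

#' Canonical goal trajectory
#'
#' Returns one of the four shipped 20-trial goal trajectories as signed
#' offsets from the DAS's expected point sum, together with the absolute
#' goals for a given DAS sum.
#'
#' @param trajectory_id integer 1--4.
#' @param das_expected_sum expected DAS point sum (default 120).
#' @return list with `trajectory_id`, `offsets` (20 integers) and `goals`
#'   (`das_expected_sum + offsets`).
#' @export
build_goal_trajectory <- function(trajectory_id, das_expected_sum = 120L) {
  key <- as.character(trajectory_id)
  if (!key %in% names(.ynat_trajectories)) {
    stop("trajectory_id must be 1, 2, 3 or 4")
  }
  off <- .ynat_trajectories[[key]]
  list(trajectory_id = as.integer(trajectory_id), offsets = off,
       goals = as.integer(das_expected_sum) + off)
}

# Draw 4 DAS circle values (multiples of 10 in [10, 60]) summing to `target`.
.draw_das_values <- function(target) {
  vals <- seq(10L, 60L, by = 10L)
  repeat {
    v <- sample(vals, 4L, replace = TRUE)
    if (sum(v) == target) return(v)
  }
}

#' Build a grid layout for one block
#'
#' Places the given DAS circle values on the DAS path (in path order) and
#' fills every other non-start cell with a value drawn uniformly from the
#' allowed set (multiples of 10 in \[-60, 60\], zero excluded).  Uses the
#' current RNG state; wrap in a seed for reproducibility.
#'
#' @param space a `ynat_space`.
#' @param das_label the DAS sequence label.
#' @param das_cell_values 4 integers placed along the DAS path.
#' @return a `ynat_grid`.
#' @export
build_grid_layout <- function(space, das_label, das_cell_values) {
  das_cell_values <- as.integer(das_cell_values)
  if (!all(das_cell_values %in% .ynat_cell_values)) {
    stop("das_cell_values must be multiples of 10 in [-60, 60], zero excluded")
  }
  start <- space$start
  p <- path_cells(das_label, start)
  values <- matrix(sample(.ynat_cell_values, .ynat_grid_n^2,
                          replace = TRUE),
                   .ynat_grid_n, .ynat_grid_n)
  values[start[1L] + 1L, start[2L] + 1L] <- 0L
  values[cbind(p[-1L, 1L] + 1L, p[-1L, 2L] + 1L)] <- das_cell_values
  grid_layout(values, start)
}

#' Build the canonical 16-block experiment design
#'
#' Assembles the full session a participant (or simulated agent) faces:
#' 16 blocks of 20 trials, four canonical goal trajectories used once per
#' segment of four blocks with no consecutive repeats, 8 bonus blocks (two
#' per trajectory), constant-sum DAS circles whose placement changes
#' between blocks, and per-block grids of circle values.  The trajectory
#' order and bonus-block placement are frozen (every participant saw the
#' same session); the seed controls only the circle values.
#'
#' @param das_expected_sum constant DAS point sum (default 120).
#' @param das_label the DAS (default `"DDRR"`, two downs then two up-rights).
#' @param start_cell 0-based start cell (default grid center `c(2, 2)`).
#' @param seed integer seed for the grid values (default 2021).
#' @param noise_sd per-move point noise sd (default 1.3).
#' @return An object of class `ynat_design`: list with `space`, `blocks`
#'   (each with `grid`, `trajectory_id`, `offsets`, `goals`, `bonus_block`,
#'   `das_cell_values`), `das_label`, `das_index`, `das_expected_sum`,
#'   `segment_map`, `bonus_probability`, `bonus_amount`, `noise_sd`, and
#'   `true_sums` (16 x 36 matrix of noiseless per-sequence point sums).
#' @export
build_default_design <- function(das_expected_sum = 120L, das_label = "DDRR",
                                 start_cell = c(2L, 2L), seed = 2021L,
                                 noise_sd = 1.3) {
  das_expected_sum <- as.integer(das_expected_sum)
  space <- enumerate_sequences(start_cell)
  if (!das_label %in% space$labels) {
    stop("das_label '", das_label, "' is not a valid sequence from this start")
  }
  if (das_expected_sum < 40L || das_expected_sum > 240L ||
      das_expected_sum %% 10L != 0L) {
    stop("das_expected_sum must be reachable by four circle values in [10,60]")
  }
  n_seq <- length(space$labels)
  blocks <- vector("list", 16L)
  true_sums <- matrix(NA_integer_, 16L, n_seq)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (b in seq_len(16L)) {
    traj <- build_goal_trajectory(.ynat_block_trajectory[b], das_expected_sum)
    das_vals <- .draw_das_values(das_expected_sum)
    grid <- build_grid_layout(space, das_label, das_vals)
    v <- grid$values
    sums <- rowSums(matrix(v[space$cells[, -1L]], nrow = n_seq))
    true_sums[b, ] <- as.integer(sums)
    blocks[[b]] <- list(
      block_index = b,
      grid = grid,
      trajectory_id = traj$trajectory_id,
      offsets = traj$offsets,
      goals = traj$goals,
      bonus_block = b %in% .ynat_bonus_blocks,
      das_cell_values = das_vals
    )
  }
  structure(
    list(
      space = space,
      blocks = blocks,
      das_label = das_label,
      das_index = match(das_label, space$labels),
      das_expected_sum = das_expected_sum,
      segment_map = rep(1:4, each = 4L),
      bonus_probability = 0.25,
      bonus_amount = 20L,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      true_sums = true_sums
    ),
    class = "ynat_design"
  )
}

#' @export
print.ynat_design <- function(x, ...) {
  cat("Y-NAT experiment design: 16 blocks x 20 trials,",
      length(x$space$labels), "sequences\n")
  cat("  DAS:", x$das_label, "with expected sum", x$das_expected_sum, "\n")
  cat("  bonus blocks:", paste(which(vapply(x$blocks, `[[`, TRUE,
                                            "bonus_block")), collapse = " "),
      "\n")
  invisible(x)
}

# goal and bonus flag for (block, trial), both 1-based
.trial_goal <- function(design, block, trial) {
  design$blocks[[block]]$goals[trial]
}

# all 320 offsets in session order
.design_offsets <- function(design) {
  unlist(lapply(design$blocks, `[[`, "offsets"), use.names = FALSE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
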
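#' ynat: simulation and repetition-bias modelling for the Y-navigation task
#'
#' The Y-navigation task (Y-NAT) asks a player to move a token across a
#' 5-by-5 grid with exactly four moves (diagonal up-left, straight down,
#' diagonal up-right), collecting the point circle of every visited cell, in
#' order to match a trial-specific point goal as closely as possible.  A
#' highlighted constant-sum default action sequence (DAS) is available on
#' every trial.  This package provides the task simulator, a family of
#' categorical choice models with and without a count-based repetition bias,
#' Bayesian fitting, PSIS-LOO model comparison, behavioral summaries, and
#' parameter-/model-recovery pipelines.
#'
#' Coordinates are 0-based: rows 0--4 run top to bottom, columns 0--4 left to
#' right, so "down" is +1 row.  Sequence labels are 4-character strings over
#' the alphabet `L` (up-left), `D` (down), `R` (up-right); the canonical
#' ordering of the 36 valid sequences is plain ASCII sorting of labels.
#'
#' @keywords internal
"_PACKAGE"

# Move displacements under the row-0-at-top convention.
.ynat_moves <- list(
  L = c(-1L, -1L), # diagonal up-left
  D = c(1L, 0L),   # straight down
  R = c(-1L, 1L)   # diagonal up-right
)

.ynat_grid_n <- 5L

# Allowed circle values: multiples of 10 in [-60, 60], zero excluded.
.ynat_cell_values <- c(seq(-60L, -10L, by = 10L), seq(10L, 60L, by = 10L))

# column-major linear index of a 0-based (row, col) cell in a 5x5 matrix
.cell_id <- function(row, col) col * .ynat_grid_n + row + 1L

#' Enumerate all valid four-move action sequences from a start cell
#'
#' Generates every string over \{L, D, R\}^4 and keeps those whose path stays
#' inside the 5-by-5 grid and never revisits a cell (the start cell
#' included).  From the grid center `c(2, 2)` exactly 36 sequences survive,
#' the policy space of the task.
#'
#' @param start_cell integer vector `c(row, col)`, 0-based, inside the grid.
#' @return An object of class `ynat_space`: a list with `labels` (sorted
#'   4-character labels), `start`, `paths` (list of 5x2 coordinate matrices)
#'   and `cells` (n x 5 matrix of column-major cell indices, first column the
#'   start cell).
#' @examples
#' sp <- enumerate_sequences(c(2, 2))
#' length(sp$labels) # 36
#' @export
enumerate_sequences <- function(start_cell = c(2L, 2L)) {
  start_cell <- as.integer(start_cell)
  stopifnot(length(start_cell) == 2L)
  if (any(start_cell < 0L | start_cell >= .ynat_grid_n)) {
    stop("start_cell must lie inside the 5x5 grid (0-based coordinates)")
  }
  alph <- c("D", "L", "R")
  combos <- expand.grid(m1 = alph, m2 = alph, m3 = alph, m4 = alph,
                        stringsAsFactors = FALSE)
  labels <- apply(combos, 1L, paste0, collapse = "")
  keep <- vapply(labels, function(lab) {
    !inherits(try(path_cells(lab, start_cell), silent = TRUE), "try-error")
  }, logical(1))
  labels <- sort(labels[keep], method = "radix")
  paths <- lapply(labels, path_cells, start_cell = start_cell)
  cells <- t(vapply(paths, function(p) .cell_id(p[, 1L], p[, 2L]),
                    integer(5L)))
  structure(
    list(labels = labels, start = start_cell, paths = paths, cells = cells),
    class = "ynat_space"
  )
}

#' @export
print.ynat_space <- function(x, ...) {
  cat("Y-NAT sequence space:", length(x$labels),
      "valid 4-move sequences from start (",
      x$start[1L], ",", x$start[2L], ")\n", sep = " ")
  invisible(x)
}

#' Cells visited by an action sequence
#'
#' @param seq_label 4-character string over \{L, D, R\}.
#' @param start_cell 0-based `c(row, col)` start.
#' @return A 5x2 integer matrix of 0-based (row, col) coordinates; the first
#'   row is the start cell.  Errors name the offending move index if the
#'   path leaves the grid or revisits a cell.
#' @export
path_cells <- function(seq_label, start_cell = c(2L, 2L)) {
  moves <- strsplit(seq_label, "")[[1L]]
  if (length(moves) != 4L || !all(moves %in% names(.ynat_moves))) {
    stop("sequence label must be 4 characters over {L, D, R}: ", seq_label)
  }
  pos <- as.integer(start_cell)
  out <- matrix(NA_integer_, nrow = 5L, ncol = 2L)
  out[1L, ] <- pos
  for (i in seq_len(4L)) {
    pos <- pos + .ynat_moves[[moves[i]]]
    if (any(pos < 0L | pos >= .ynat_grid_n)) {
      stop(sprintf("sequence '%s' leaves the grid at move %d", seq_label, i))
    }
    if (any(out[seq_len(i), 1L] == pos[1L] & out[seq_len(i), 2L] == pos[2L],
            na.rm = TRUE)) {
      stop(sprintf("sequence '%s' revisits a cell at move %d", seq_label, i))
    }
    out[i + 1L, ] <- pos
  }
  out
}

#' Grid layout of circle points
#'
#' @param values 5x5 integer matrix indexed `[row + 1, col + 1]` (0-based
#'   task coordinates); every non-start entry must be a multiple of 10 in
#'   \[-60, 60\] excluding zero.  The start cell carries 0: it is never
#'   collected by any valid sequence.
#' @param start_cell 0-based `c(row, col)`.
#' @return An object of class `ynat_grid`.
#' @export
grid_layout <- function(values, start_cell = c(2L, 2L)) {
  values <- matrix(as.integer(values), nrow = .ynat_grid_n)
  start_cell <- as.integer(start_cell)
  v <- values
  v[start_cell[1L] + 1L, start_cell[2L] + 1L] <- NA_integer_
  bad <- !is.na(v) & !(v %in% .ynat_cell_values)
  if (any(bad)) {
    stop("grid values must be multiples of 10 in [-60, 60], zero excluded")
  }
  structure(list(values = values, start = start_cell), class = "ynat_grid")
}

#' Noiseless point total of a sequence
#'
#' Sum of the four circle values along the sequence's path, start cell
#' excluded.
#'
#' @param grid a `ynat_grid`.
#' @param seq_label 4-character sequence label.
#' @return integer total.
#' @export
sequence_points <- function(grid, seq_label) {
  p <- path_cells(seq_label, grid$start)
  sum(grid$values[cbind(p[-1L, 1L] + 1L, p[-1L, 2L] + 1L)])
}

# round half away from zero, the task's "nearest integer" for noisy points
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Realize noisy move points for a sequence
#'
#' Each collected circle's value receives additive Gaussian noise (mean 0,
#' sd `noise_sd`, task default 1.3), rounded to the nearest integer
#' (half away from zero).
#'
#' @param grid a `ynat_grid`.
#' @param seq_label sequence label.
#' @param noise_sd noise standard deviation; 0 disables noise.
#' @return list with `move_points` (4 integers) and `total`.
#' @export
realized_points <- function(grid, seq_label, noise_sd = 1.3) {
  p <- path_cells(seq_label, grid$start)
  base <- grid$values[cbind(p[-1L, 1L] + 1L, p[-1L, 2L] + 1L)]
  pts <- if (noise_sd > 0) {
    as.integer(base + .round_half_away(stats::rnorm(4L, 0, noise_sd)))
  } else {
    as.integer(base)
  }
  list(move_points = pts, total = sum(pts))
}

#' Trial reward from goal and collected points
#'
#' `max(0, 100 - 2 * |goal - points|)`: the reward falls by 2 per point of
#' absolute deviation from the goal and is floored at 0.  The probabilistic
#' DAS bonus is not part of this rule.
#'
#' @param goal trial goal in points.
#' @param points collected point total.
#' @return reward in \[0, 100\] (vectorized).
#' @export
trial_reward <- function(goal, points) {
  pmax(0, 100 - 2 * abs(goal - points))
}

#' Is the DAS one of the highest-expected-reward sequences?
#'
#' The DAS counts as optimal when the absolute difference between its
#' expected point sum and the trial goal is at most 5, since circle values
#' differ by at least 10 points.
#'
#' @param goal trial goal.
#' @param das_expected_sum the DAS's communicated expected point sum.
#' @return logical (vectorized).
#' @export
is_das_optimal <- function(goal, das_expected_sum) {
  abs(goal - das_expected_sum) <= 5
}

#' Classify a chosen sequence relative to the DAS
#'
#' `DAS` if identical; `PARTIAL_DAS` if it shares at least the first move
#' but differs somewhere; `INDEPENDENT` otherwise.
#'
#' @param seq_label chosen sequence label.
#' @param das_label the DAS label.
#' @return one of `"DAS"`, `"PARTIAL_DAS"`, `"INDEPENDENT"` (vectorized over
#'   `seq_label`).
#' @export
classify_sequence <- function(seq_label, das_label) {
  ifelse(seq_label == das_label, "DAS",
         ifelse(substr(seq_label, 1L, 1L) == substr(das_label, 1L, 1L),
                "PARTIAL_DAS", "INDEPENDENT"))
}
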
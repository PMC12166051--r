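# Tabular and JSON interfaces: participant trial tables as CSV, designs as
# JSON.  One dialect throughout: comma-separated, UTF-8, "." decimal.

.ynat_table_cols <- c("participant_id", "block", "trial", "trajectory_id",
                      "bonus_block", "goal", "sequence", "pts1", "pts2",
                      "pts3", "pts4", "points_total", "reward",
                      "bonus_received", "timeout", "rt_ms")

#' Write a participant trial table to CSV
#'
#' @param data trial table (as produced by [simulate_agent()] /
#'   [simulate_cohort()] or ingested from the deposit schema).
#' @param path output file.
#' @export
write_participant_table <- function(data, path) {
  missing <- setdiff(.ynat_table_cols, names(data))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(data[, .ynat_table_cols], path, row.names = FALSE,
                   na = "")
}

#' Read and validate a participant trial table
#'
#' Checks the documented schema: all columns present; each participant has
#' contiguous trials 1--20 within blocks 1--16; every non-timeout sequence
#' label belongs to the design's sequence space (timeout rows may leave the
#' sequence empty).  Rows are normalized to (participant, block, trial)
#' order.  Errors cite the offending row.
#'
#' @param path CSV file.
#' @param design a `ynat_design` used to validate sequence labels.
#' @return the validated trial table (data.frame).
#' @export
read_participant_table <- function(path, design) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(participant_id = "character",
                                         sequence = "character"))
  missing <- setdiff(.ynat_table_cols, names(data))
  if (length(missing)) {
    stop("file lacks column(s): ", paste(missing, collapse = ", "))
  }
  data$sequence[is.na(data$sequence)] <- ""
  data$bonus_block <- as.logical(data$bonus_block)
  data$bonus_received <- as.logical(data$bonus_received)
  data$timeout <- as.logical(data$timeout)
  ord <- order(data$participant_id, data$block, data$trial)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  bad_seq <- which(!data$timeout &
                     !(data$sequence %in% design$space$labels))
  if (length(bad_seq)) {
    stop("row ", bad_seq[1L], ": sequence '", data$sequence[bad_seq[1L]],
         "' is not in the sequence space")
  }
  for (pid in unique(data$participant_id)) {
    d <- data[data$participant_id == pid, ]
    expected <- data.frame(block = rep(1:16, each = 20L),
                           trial = rep(1:20, times = 16L))
    if (nrow(d) != 320L || any(d$block != expected$block) ||
        any(d$trial != expected$trial)) {
      first_bad <- which(data$participant_id == pid)[1L]
      stop("participant '", pid, "' (starting row ", first_bad,
           "): trials are not the contiguous 16 x 20 layout")
    }
  }
  data
}

#' Serialize an experiment design to JSON
#'
#' Grids are written as 5x5 integer arrays (row-major, row 0 first)
#' together with the start cell, DAS specification, trajectory assignment
#' and bonus flags — everything needed to reconstruct the design exactly.
#'
#' @param design a `ynat_design`.
#' @param path output JSON file.
#' @export
write_design_json <- function(design, path) {
  obj <- list(
    das_label = design$das_label,
    das_expected_sum = design$das_expected_sum,
    start_cell = design$space$start,
    bonus_probability = design$bonus_probability,
    bonus_amount = design$bonus_amount,
    noise_sd = design$noise_sd,
    seed = design$seed,
    blocks = lapply(design$blocks, function(b) {
      list(block_index = b$block_index,
           trajectory_id = b$trajectory_id,
           bonus_block = b$bonus_block,
           offsets = b$offsets,
           das_cell_values = b$das_cell_values,
           # row-major: one inner array per grid row (top row first)
           cell_values = unname(split(b$grid$values,
                                      row(b$grid$values))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read an experiment design from JSON
#'
#' @param path JSON file written by [write_design_json()].
#' @return a `ynat_design`.
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- enumerate_sequences(as.integer(obj$start_cell))
  n_seq <- length(space$labels)
  das_index <- match(obj$das_label, space$labels)
  blocks <- vector("list", length(obj$blocks$block_index))
  true_sums <- matrix(NA_integer_, length(blocks), n_seq)
  for (b in seq_along(blocks)) {
    cv <- obj$blocks$cell_values[[b]]
    vals <- if (is.matrix(cv)) cv else do.call(rbind, cv)
    grid <- grid_layout(vals, space$start)
    sums <- rowSums(matrix(grid$values[space$cells[, -1L]], nrow = n_seq))
    true_sums[b, ] <- as.integer(sums)
    off <- as.integer(obj$blocks$offsets[[b]])
    blocks[[b]] <- list(
      block_index = obj$blocks$block_index[b],
      grid = grid,
      trajectory_id = obj$blocks$trajectory_id[b],
      offsets = off,
      goals = as.integer(obj$das_expected_sum) + off,
      bonus_block = obj$blocks$bonus_block[b],
      das_cell_values = as.integer(obj$blocks$das_cell_values[[b]])
    )
  }
  structure(
    list(space = space, blocks = blocks, das_label = obj$das_label,
         das_index = das_index,
         das_expected_sum = as.integer(obj$das_expected_sum),
         segment_map = rep(seq_len(ceiling(length(blocks) / 4L)),
                           each = 4L)[seq_along(blocks)],
         bonus_probability = obj$bonus_probability,
         bonus_amount = as.integer(obj$bonus_amount),
         noise_sd = obj$noise_sd,
         seed = as.integer(obj$seed),
         true_sums = true_sums),
    class = "ynat_design"
  )
}
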
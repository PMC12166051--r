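#' Simulate one model-driven agent through a full session
#'
#' Plays all 16 x 20 trials: at each trial the agent's choice distribution
#' is computed from its current beliefs, a sequence is sampled, noisy move
#' points are realized, the reward is computed (plus a sampled +20 bonus at
#' probability 0.25 when the DAS is chosen in a bonus block), and beliefs
#' are updated.  Simulated agents never time out.
#'
#' @param params a `ynat_params`.
#' @param design a `ynat_design`.
#' @param seed integer seed; identical seeds give identical sessions.
#' @param participant_id id string written into the table.
#' @return data.frame with one row per trial and columns `participant_id`,
#'   `block`, `trial`, `trajectory_id`, `bonus_block`, `goal`, `sequence`,
#'   `pts1`..`pts4`, `points_total`, `reward`, `bonus_received`, `timeout`,
#'   `rt_ms`.
#' @export
simulate_agent <- function(params, design, seed,
                           participant_id = "agent_1") {
  stopifnot(inherits(params, "ynat_params"), inherits(design, "ynat_design"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  space <- design$space
  n_seq <- length(space$labels)
  beliefs <- init_beliefs(design)
  n_trials <- 16L * 20L
  block <- integer(n_trials); trial <- integer(n_trials)
  traj <- integer(n_trials); bonus_blk <- logical(n_trials)
  goal <- integer(n_trials); seq_lab <- character(n_trials)
  pts <- matrix(NA_integer_, n_trials, 4L)
  total <- integer(n_trials); reward <- integer(n_trials)
  bonus_rec <- logical(n_trials)
  i <- 0L
  for (b in seq_len(16L)) {
    blk <- design$blocks[[b]]
    if (b > 1L) beliefs <- new_block(beliefs)
    for (t in seq_len(20L)) {
      i <- i + 1L
      ctx <- list(goal = blk$goals[t], bonus = blk$bonus_block,
                  true_sums = design$true_sums[b, ])
      probs <- choice_probabilities(params, beliefs, ctx)
      k <- sample.int(n_seq, 1L, prob = probs)
      rp <- realized_points(blk$grid, space$labels[k], design$noise_sd)
      got_bonus <- blk$bonus_block && k == design$das_index &&
        stats::runif(1L) < design$bonus_probability
      block[i] <- b; trial[i] <- t
      traj[i] <- blk$trajectory_id; bonus_blk[i] <- blk$bonus_block
      goal[i] <- ctx$goal; seq_lab[i] <- space$labels[k]
      pts[i, ] <- rp$move_points; total[i] <- rp$total
      reward[i] <- as.integer(trial_reward(ctx$goal, rp$total)) +
        if (got_bonus) design$bonus_amount else 0L
      bonus_rec[i] <- got_bonus
      beliefs <- observe_trial(beliefs, k, rp$total)
    }
  }
  data.frame(
    participant_id = participant_id, block = block, trial = trial,
    trajectory_id = traj, bonus_block = bonus_blk, goal = goal,
    sequence = seq_lab, pts1 = pts[, 1L], pts2 = pts[, 2L],
    pts3 = pts[, 3L], pts4 = pts[, 4L], points_total = total,
    reward = reward, bonus_received = bonus_rec, timeout = FALSE,
    rt_ms = NA_real_, stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of agents
#'
#' @param spec list of entries `list(params = <ynat_params>, n = <agents>)`;
#'   a bare `ynat_params` is treated as one agent.
#' @param design a `ynat_design`.
#' @param seed master seed; per-agent seeds are derived deterministically.
#' @return concatenated trial table with unique `participant_id`s of the
#'   form `<model>_<k>`.
#' @export
simulate_cohort <- function(spec, design, seed) {
  if (inherits(spec, "ynat_params")) spec <- list(list(params = spec, n = 1L))
  out <- list(); idx <- 0L
  for (entry in spec) {
    if (inherits(entry, "ynat_params")) entry <- list(params = entry, n = 1L)
    n <- if (is.null(entry$n)) 1L else as.integer(entry$n)
    stopifnot(n >= 1L)
    for (k in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%03d", entry$params$model_id, idx)
      out[[idx]] <- simulate_agent(entry$params, design,
                                   seed = .derive_seed(seed, idx),
                                   participant_id = pid)
    }
  }
  do.call(rbind, out)
}

# deterministic stream of 32-bit-safe sub-seeds from a master seed
# (arithmetic in doubles: exact well below 2^53, result below 2^31)
.derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 +
                as.numeric(k) * 104729) %% 2147483629)
}
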
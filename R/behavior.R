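#' Summary behavioral measures for one participant
#'
#' Computes the task's standard summary statistics on the completed
#' (non-timeout) trials: the proportion of DAS choices overall, per half
#' (blocks 1--8 vs 9--16), per segment of four blocks, by bonus condition
#' and by DAS optimality (whether |goal - expected DAS points| <= 5); the
#' proportion of partial-DAS trials (first move matches the DAS; includes
#' full DAS trials); the number of distinct sequences used per half and
#' segment; mean reward per half; the timeout count; and the exclusion flag
#' for lack of behavioral variability (modal sequence above 90% of
#' completed trials).
#'
#' @param data one participant's trial table.
#' @param design a `ynat_design`.
#' @return object of class `ynat_summary` (a named list).
#' @export
summarize_participant <- function(data, design) {
  data <- data[order(data$block, data$trial), , drop = FALSE]
  if (nrow(data) != 320L) stop("expected 320 trial rows, got ", nrow(data))
  cc <- data[!data$timeout, , drop = FALSE]
  das <- design$das_label
  is_das <- cc$sequence == das
  is_partial <- substr(cc$sequence, 1L, 1L) == substr(das, 1L, 1L)
  half <- ifelse(cc$block <= 8L, 1L, 2L)
  segment <- design$segment_map[cc$block]
  offsets <- cc$goal - design$das_expected_sum
  optimal <- is_das_optimal(cc$goal, design$das_expected_sum)
  prop_by <- function(x, g) vapply(split(x, g), mean, 0)
  n_distinct_by <- function(g) {
    vapply(split(cc$sequence, g), function(s) length(unique(s)), 0L)
  }
  tab <- table(cc$sequence)
  structure(list(
    participant_id = data$participant_id[1L],
    p_das = mean(is_das),
    p_das_half = prop_by(is_das, half),
    p_das_segment = prop_by(is_das, segment),
    p_das_bonus = prop_by(is_das, ifelse(cc$bonus_block, "bonus",
                                         "no_bonus")),
    p_das_optimality = prop_by(is_das, ifelse(optimal, "das_optimal",
                                              "das_suboptimal")),
    p_partial_das = mean(is_partial),
    p_partial_das_half = prop_by(is_partial, half),
    p_partial_das_segment = prop_by(is_partial, segment),
    n_distinct = length(unique(cc$sequence)),
    n_distinct_half = n_distinct_by(half),
    n_distinct_segment = n_distinct_by(segment),
    mean_reward = mean(cc$reward),
    mean_reward_half = prop_by(cc$reward, half),
    n_timeouts = sum(data$timeout),
    excluded = max(tab) / nrow(cc) > 0.9
  ), class = "ynat_summary")
}

#' @export
print.ynat_summary <- function(x, ...) {
  cat("Participant", x$participant_id, "\n")
  cat(sprintf("  p(DAS) %.3f (halves %.3f / %.3f)  partial-DAS %.3f\n",
              x$p_das, x$p_das_half[1L], x$p_das_half[2L], x$p_partial_das))
  cat(sprintf("  distinct sequences %d  mean reward %.1f  timeouts %d%s\n",
              x$n_distinct, x$mean_reward, x$n_timeouts,
              if (x$excluded) "  [excluded: >90% one sequence]" else ""))
  invisible(x)
}

#' Tidy cohort summary table
#'
#' One row per participant x measure x window, ready for external
#' statistical software.
#'
#' @param cohort a multi-participant trial table.
#' @param design a `ynat_design`.
#' @return data.frame with columns `participant_id`, `measure`, `window`,
#'   `value`.
#' @export
summarize_cohort <- function(cohort, design) {
  rows <- lapply(split(cohort, cohort$participant_id), function(d) {
    s <- summarize_participant(d, design)
    measures <- list(
      c("p_das", "all", s$p_das),
      cbind("p_das", paste0("half", 1:2), s$p_das_half),
      cbind("p_das", paste0("segment", 1:4), s$p_das_segment),
      cbind("p_das", names(s$p_das_bonus), s$p_das_bonus),
      cbind("p_das", names(s$p_das_optimality), s$p_das_optimality),
      c("p_partial_das", "all", s$p_partial_das),
      cbind("p_partial_das", paste0("half", 1:2), s$p_partial_das_half),
      cbind("p_partial_das", paste0("segment", 1:4),
            s$p_partial_das_segment),
      c("n_distinct", "all", s$n_distinct),
      cbind("n_distinct", paste0("half", 1:2), s$n_distinct_half),
      cbind("n_distinct", paste0("segment", 1:4), s$n_distinct_segment),
      c("mean_reward", "all", s$mean_reward),
      cbind("mean_reward", paste0("half", 1:2), s$mean_reward_half),
      c("n_timeouts", "all", s$n_timeouts),
      c("excluded", "all", as.numeric(s$excluded))
    )
    m <- do.call(rbind, measures)
    data.frame(participant_id = s$participant_id, measure = m[, 1L],
               window = m[, 2L], value = as.numeric(m[, 3L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior predictive check: proportion of matched choices
#'
#' Simulates `n_agents` full sessions with parameters drawn from a fitted
#' posterior and scores, per trial, whether the simulated choice matches
#' the participant's observed choice.  Reports the overall match
#' proportion, the match proportions on observed-DAS and observed-non-DAS
#' trials, and the 1/36 chance level.
#'
#' @param posterior a `ynat_posterior` (from [fit_laplace()] or
#'   [fit_mcmc()]).
#' @param data the participant's observed trial table.
#' @param design a `ynat_design`.
#' @param n_agents number of simulated agents (default 1000; tests use
#'   fewer).
#' @param seed seed for both parameter draws and simulations.
#' @return list with `match`, `match_das`, `match_non_das`, `chance`,
#'   `n_agents`, `per_trial` (mean match per observed trial).
#' @export
ppc_match <- function(posterior, data, design, n_agents = 1000L, seed = 1L) {
  stopifnot(inherits(posterior, "ynat_posterior"), n_agents >= 1L)
  data <- data[order(data$block, data$trial), , drop = FALSE]
  obs <- data[!data$timeout, , drop = FALSE]
  key <- paste(obs$block, obs$trial)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 551L))
  n_draws <- nrow(posterior$pointwise_loglik)
  rows <- sample.int(n_draws, n_agents, replace = TRUE)
  match_mat <- matrix(NA, n_agents, nrow(obs))
  for (a in seq_len(n_agents)) {
    params <- if (ncol(posterior$draws) == 0L) {
      model_params("UNIFORM")
    } else {
      do.call(model_params,
              c(list(model_id = posterior$model_id),
                as.list(posterior$draws[rows[a], ])))
    }
    sim <- simulate_agent(params, design, seed = .derive_seed(seed, a))
    sim_key <- paste(sim$block, sim$trial)
    match_mat[a, ] <- sim$sequence[match(key, sim_key)] == obs$sequence
  }
  per_trial <- colMeans(match_mat)
  obs_das <- obs$sequence == design$das_label
  list(match = mean(match_mat),
       match_das = if (any(obs_das)) mean(match_mat[, obs_das]) else NA_real_,
       match_non_das = if (any(!obs_das)) mean(match_mat[, !obs_das])
                       else NA_real_,
       chance = 1 / length(design$space$labels),
       n_agents = n_agents, per_trial = per_trial)
}
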
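#' Parameter recovery study
#'
#' Simulates one agent per grid cell per seed from the repetition-bias
#' model, fits it back, and tabulates true versus estimated parameters
#' with Spearman rank correlations and mean signed errors.
#'
#' @param design a `ynat_design`.
#' @param param_grid data.frame with columns `h`, `beta`, `r0` (one row per
#'   cell).
#' @param n_seeds simulations per cell (default 2).
#' @param estimator `"map"` (default) or `"mcmc"` (posterior-mean
#'   estimates; slow).
#' @param seed master seed.
#' @param n_starts optimizer starts per fit.
#' @return object of class `ynat_recovery`: list with `rows` (data.frame of
#'   true/estimated values) and `summary` (per-parameter Spearman rho and
#'   mean signed error).
#' @export
run_parameter_recovery <- function(design, param_grid, n_seeds = 2L,
                                   estimator = c("map", "mcmc"), seed = 1L,
                                   n_starts = 8L) {
  estimator <- match.arg(estimator)
  stopifnot(nrow(param_grid) >= 1L)
  rows <- list(); i <- 0L
  for (s in seq_len(n_seeds)) {
    for (g in seq_len(nrow(param_grid))) {
      i <- i + 1L
      true <- param_grid[g, ]
      params <- model_params("EVPRM", beta = true$beta, r0 = true$r0,
                             h = true$h)
      agent_seed <- .derive_seed(seed, i)
      sim <- simulate_agent(params, design, seed = agent_seed,
                            participant_id = sprintf("rec_%03d", i))
      est <- tryCatch({
        if (estimator == "map") {
          fit <- fit_map("EVPRM", sim, design, n_starts = n_starts,
                         seed = agent_seed)
          unlist(fit$params[c("beta", "r0", "h")])
        } else {
          post <- fit_mcmc("EVPRM", sim, design, chains = 2L, draws = 300L,
                           warmup = 300L, seed = agent_seed)
          colMeans(post$draws)[c("beta", "r0", "h")]
        }
      }, error = function(e) {
        c(beta = NA_real_, r0 = NA_real_, h = NA_real_)
      })
      rows[[i]] <- data.frame(
        model_id = "EVPRM", seed = agent_seed, estimator = estimator,
        h_true = true$h, beta_true = true$beta, r0_true = true$r0,
        h_est = est[["h"]], beta_est = est[["beta"]], r0_est = est[["r0"]]
      )
    }
  }
  rows <- do.call(rbind, rows)
  ok <- stats::complete.cases(rows)
  # rank correlation is undefined for a degenerate (constant) grid axis
  safe_spearman <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  summ <- data.frame(
    parameter = c("h", "beta", "r0"),
    spearman_rho = c(
      safe_spearman(rows$h_true[ok], rows$h_est[ok]),
      safe_spearman(rows$beta_true[ok], rows$beta_est[ok]),
      safe_spearman(rows$r0_true[ok], rows$r0_est[ok])
    ),
    mean_signed_error = c(
      mean(rows$h_est[ok] - rows$h_true[ok]),
      mean(rows$beta_est[ok] - rows$beta_true[ok]),
      mean(rows$r0_est[ok] - rows$r0_true[ok])
    )
  )
  structure(list(rows = rows, summary = summ, n_failed = sum(!ok)),
            class = "ynat_recovery")
}

#' @export
print.ynat_recovery <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$rows), "simulated agents\n")
  print(x$summary, row.names = FALSE)
  if (x$n_failed > 0L) cat("  (", x$n_failed, "fits failed )\n")
  invisible(x)
}

#' Model recovery study
#'
#' Simulates `n_agents` per generating model, fits every candidate model
#' (EVPRM, EVPBM, EVPM, EVM, UNIFORM) to each agent, assigns the best
#' model per agent by lowest LOOIC, and returns the generating x selected
#' confusion table plus the group-level comparison per generating cohort.
#' The default estimator is the Laplace approximation at the posterior
#' mode with PSIS-LOO on its draws; `"mcmc"` substitutes the sampler.
#'
#' @param design a `ynat_design`.
#' @param per_model_params named list generating-model -> `ynat_params`.
#' @param n_agents agents per generating model.
#' @param seed master seed.
#' @param estimator `"laplace"` (default) or `"mcmc"`.
#' @param n_draws posterior draws per fit (default 400).
#' @param n_starts optimizer starts per fit (default 4).
#' @return object of class `ynat_model_recovery`: list with `confusion`
#'   (generating x selected counts), `comparisons` (named list of
#'   `ynat_comparison` per generating model) and `fitted_models`.
#' @export
run_model_recovery <- function(design, per_model_params, n_agents = 10L,
                               seed = 1L, estimator = c("laplace", "mcmc"),
                               n_draws = 400L, n_starts = 4L) {
  estimator <- match.arg(estimator)
  fitted_models <- c("EVPRM", "EVPBM", "EVPM", "EVM", "UNIFORM")
  gens <- names(per_model_params)
  confusion <- matrix(0L, length(gens), length(fitted_models),
                      dimnames = list(generating = gens,
                                      selected = fitted_models))
  comparisons <- list()
  agent_no <- 0L
  for (g in gens) {
    loos <- list()
    for (a in seq_len(n_agents)) {
      agent_no <- agent_no + 1L
      agent_seed <- .derive_seed(seed, 1000L + agent_no)
      sim <- simulate_agent(per_model_params[[g]], design,
                            seed = agent_seed,
                            participant_id = sprintf("%s_%02d", g, a))
      per_model <- list()
      for (m in fitted_models) {
        post <- if (estimator == "laplace") {
          fit_laplace(m, sim, design, n_draws = n_draws,
                      n_starts = n_starts, seed = agent_seed)
        } else {
          fit_mcmc(m, sim, design, chains = 2L, draws = n_draws,
                   warmup = n_draws, seed = agent_seed)
        }
        per_model[[m]] <- psis_loo(post)
      }
      loos[[sprintf("%s_%02d", g, a)]] <- per_model
      li <- vapply(per_model, `[[`, 0, "looic")
      win <- names(li)[which.min(li)]
      confusion[g, win] <- confusion[g, win] + 1L
    }
    comparisons[[g]] <- compare_models(loos)
  }
  structure(list(confusion = confusion, comparisons = comparisons,
                 fitted_models = fitted_models),
            class = "ynat_model_recovery")
}

#' @export
print.ynat_model_recovery <- function(x, ...) {
  cat("Model recovery confusion (rows generate, columns selected):\n")
  print(x$confusion)
  invisible(x)
}

#' Session-level demonstration of the repetition-bias dynamics
#'
#' Simulates `n_sims` full sessions of a strongly repetition-biased agent
#' (defaults: repetition bias strength 0.91, precision 5, approximated
#' reward 70) and records, per trial, the DAS's count-based prior, its
#' precision-weighted reward term and its posterior choice probability,
#' averaged over sessions.  The hallmark pattern is a near-uniform prior at
#' trial 1 (1/36) that grows monotonically while the reward term stays in a
#' constant range, pulling the choice probability up over the session.
#'
#' @param design a `ynat_design`.
#' @param n_sims number of simulated sessions (default 100).
#' @param params agent parameters (default the demonstration values above).
#' @param seed master seed.
#' @return data.frame with one row per trial index (1--320): `trial`,
#'   `mean_prior`, `mean_reward_term`, `mean_choice_prob`, plus the
#'   per-session DAS choice rate in attribute `das_rate` (length `n_sims`
#'   vectors for the first and last 80 trials).
#' @export
reproduce_session_dynamics <- function(design, n_sims = 100L,
                                       params = model_params(
                                         "EVPRM", beta = 5, r0 = 70,
                                         h = 0.91),
                                       seed = 1L) {
  n_trials <- 320L
  n_seq <- length(design$space$labels)
  das <- design$das_index
  prior_m <- matrix(NA_real_, n_sims, n_trials)
  rterm_m <- matrix(NA_real_, n_sims, n_trials)
  cprob_m <- matrix(NA_real_, n_sims, n_trials)
  chose_das <- matrix(NA, n_sims, n_trials)
  for (s in seq_len(n_sims)) {
    sim_seed <- .derive_seed(seed, s)
    old <- .save_rng()
    set.seed(sim_seed)
    beliefs <- init_beliefs(design)
    i <- 0L
    for (b in seq_len(16L)) {
      blk <- design$blocks[[b]]
      if (b > 1L) beliefs <- new_block(beliefs)
      for (t in seq_len(20L)) {
        i <- i + 1L
        ctx <- list(goal = blk$goals[t], bonus = blk$bonus_block,
                    true_sums = design$true_sums[b, ])
        r <- reward_structure(params, beliefs, ctx)
        rt <- reward_term(r, params$beta)
        pri <- policy_prior(beliefs, 1 / params$h)
        post <- rt * pri
        post <- post / sum(post)
        prior_m[s, i] <- pri[das]
        rterm_m[s, i] <- rt[das]
        cprob_m[s, i] <- post[das]
        k <- sample.int(n_seq, 1L, prob = post)
        chose_das[s, i] <- k == das
        rp <- realized_points(blk$grid, design$space$labels[k],
                              design$noise_sd)
        beliefs <- observe_trial(beliefs, k, rp$total)
      }
    }
    .restore_rng(old)
  }
  out <- data.frame(trial = seq_len(n_trials),
                    mean_prior = colMeans(prior_m),
                    mean_reward_term = colMeans(rterm_m),
                    mean_choice_prob = colMeans(cprob_m),
                    p_das = colMeans(chose_das))
  attr(out, "das_rate_first80") <- rowMeans(chose_das[, 1:80, drop = FALSE])
  attr(out, "das_rate_last80") <- rowMeans(chose_das[, 241:320,
                                                     drop = FALSE])
  out
}
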
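# Precompute, for one participant's session, everything the per-trial
# categorical likelihood needs that does not depend on model parameters:
# for each completed (non-timeout) trial, the reward each sequence would
# earn from its stored point sum against that trial's goal (NA where the
# sequence is unobserved this block), the usage counts before the trial,
# the bonus flag, the chosen index, and the EVM's true-sum rewards.
# Beliefs are replayed sequentially with the same update rules the models
# use, so the matrices are an exact unrolling of the sequential filter.
.precompute_loglik <- function(data, design) {
  space <- design$space
  n_seq <- length(space$labels)
  data <- data[order(data$block, data$trial), , drop = FALSE]
  keep <- !data$timeout
  n <- sum(keep)
  chosen <- integer(n)
  R_obs <- matrix(NA_real_, n, n_seq)
  G <- matrix(0L, n, n_seq)
  R_true <- matrix(NA_real_, n, n_seq)
  bonus <- logical(n)
  beliefs <- init_beliefs(design)
  cur_block <- 1L
  i <- 0L
  for (r in seq_len(nrow(data))) {
    b <- data$block[r]
    if (b != cur_block) {
      beliefs <- new_block(beliefs)
      cur_block <- b
    }
    if (!keep[r]) next
    t <- data$trial[r]
    goal <- design$blocks[[b]]$goals[t]
    k <- match(data$sequence[r], space$labels)
    if (is.na(k)) {
      stop("row ", r, ": sequence '", data$sequence[r],
           "' is not in the sequence space")
    }
    i <- i + 1L
    chosen[i] <- k
    R_obs[i, ] <- trial_reward(goal, beliefs$observed)
    G[i, ] <- beliefs$gamma
    R_true[i, ] <- trial_reward(goal, design$true_sums[b, ])
    bonus[i] <- design$blocks[[b]]$bonus_block
    beliefs <- observe_trial(beliefs, k, data$points_total[r])
  }
  list(n = n, n_seq = n_seq, chosen = chosen, R_obs = R_obs, G = G,
       R_true = R_true, bonus = bonus, das_index = design$das_index)
}

# rowwise log-sum-exp for an n x m matrix
.row_logsumexp <- function(L) {
  m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  m + log(rowSums(exp(L - m)))
}

# Vectorized per-trial log choice probabilities for one parameter set.
.pointwise_loglik <- function(params, pc) {
  n <- pc$n
  if (params$model_id == "UNIFORM") {
    return(rep(-log(pc$n_seq), n))
  }
  if (params$model_id == "EVM") {
    Rhat <- pc$R_true
  } else {
    Rhat <- pc$R_obs
    Rhat[is.na(Rhat)] <- params$r0
    if (params$model_id == "EVPBM") {
      Rhat[, pc$das_index] <- Rhat[, pc$das_index] + params$b_das
    }
  }
  Rhat[, pc$das_index] <- Rhat[, pc$das_index] + 5 * pc$bonus
  Rhat <- pmax(Rhat, .ynat_reward_eps)
  L <- params$beta * (log(Rhat) - log(rowSums(Rhat)))
  if (params$model_id == "EVPRM") {
    L <- L + log(1 / params$h + pc$G)
  } else if (params$model_id == "EVPRM2") {
    a0 <- matrix(1 / params$h_other, n, pc$n_seq)
    a0[, pc$das_index] <- 1 / params$h_das
    L <- L + log(a0 + pc$G)
  }
  L[cbind(seq_len(n), pc$chosen)] - .row_logsumexp(L)
}

#' Log-likelihood of a participant's session under a model
#'
#' Sums the log categorical choice probability of every completed
#' (non-timeout) trial, updating beliefs sequentially with the same rules
#' the simulator uses (usage counts persist across blocks; observed point
#' sums reset to DAS-only at block boundaries; timeouts update nothing and
#' contribute nothing).
#'
#' @param params a `ynat_params`.
#' @param data one participant's trial table (columns `block`, `trial`,
#'   `sequence`, `points_total`, `timeout`).
#' @param design a `ynat_design`.
#' @param precomp optional precomputed structure (internal; lets repeated
#'   evaluations on the same data skip the sequential replay).
#' @param pointwise if `TRUE` return the per-trial vector instead of the sum.
#' @return log-likelihood (scalar, or vector of length = completed trials).
#' @export
dataset_loglik <- function(params, data, design, precomp = NULL,
                           pointwise = FALSE) {
  pc <- if (is.null(precomp)) .precompute_loglik(data, design) else precomp
  lp <- .pointwise_loglik(params, pc)
  if (pointwise) lp else sum(lp)
}

#' Prior specification for the model parameters
#'
#' The weakly informative priors used for fitting: `beta ~ Gamma(3, 1)`,
#' `r0 ~ Gamma(55, 0.75)`, `h ~ Beta(3, 3)` and `b_das ~ Gamma(3, 0.1)`
#' (Gamma in the shape--rate convention).  The two-strength variant's
#' `h_das`, `h_other` reuse the `h` prior.
#'
#' @return named list; each element has `dist`, its parameters, `mean`, `sd`
#'   and a `logpdf` function.
#' @export
prior_spec <- function() {
  gamma_entry <- function(shape, rate) {
    list(dist = "gamma", shape = shape, rate = rate,
         mean = shape / rate, sd = sqrt(shape) / rate,
         logpdf = function(x) stats::dgamma(x, shape, rate = rate, log = TRUE))
  }
  beta_entry <- list(dist = "beta", a = 3, b = 3, mean = 0.5,
                     sd = sqrt(9 / (36 * 7)),
                     logpdf = function(x) stats::dbeta(x, 3, 3, log = TRUE))
  list(beta = gamma_entry(3, 1),
       r0 = gamma_entry(55, 0.75),
       h = beta_entry, h_das = beta_entry, h_other = beta_entry,
       b_das = gamma_entry(3, 0.1))
}

#' Log prior density of a parameter set
#'
#' Sum of component log-densities over the model's active parameters;
#' `-Inf` outside the support.
#'
#' @param params a `ynat_params`.
#' @return scalar log density.
#' @export
prior_logpdf <- function(params) {
  spec <- prior_spec()
  active <- .ynat_models[[params$model_id]]
  if (length(active) == 0L) return(0)
  sum(vapply(active, function(p) spec[[p]]$logpdf(params[[p]]), 0))
}

#' Shrinkage from prior to posterior
#'
#' `1 - (posterior_sd / prior_sd)^2`; values near 1 mean the data, not the
#' prior, determine the posterior.
#'
#' @param prior_sd prior standard deviation (> 0).
#' @param posterior_sd posterior standard deviation.
#' @return value in (-Inf, 1].
#' @export
shrinkage <- function(prior_sd, posterior_sd) {
  stopifnot(prior_sd > 0)
  1 - (posterior_sd / prior_sd)^2
}
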
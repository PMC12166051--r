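# Independent oracles: direct, loop-by-loop transcriptions of the model
# equations and task rules, deliberately unvectorized and sharing no code
# with the package internals.

# brute-force legality check of a 4-move string from a 0-based start cell
oracle_is_valid_sequence <- function(label, start = c(2, 2)) {
  steps <- list(L = c(-1, -1), D = c(1, 0), R = c(-1, 1))
  pos <- start
  seen <- list(start)
  for (ch in strsplit(label, "")[[1]]) {
    pos <- pos + steps[[ch]]
    if (pos[1] < 0 || pos[1] > 4 || pos[2] < 0 || pos[2] > 4) return(FALSE)
    for (s in seen) if (all(s == pos)) return(FALSE)
    seen[[length(seen) + 1]] <- pos
  }
  TRUE
}

oracle_all_labels <- function() {
  alph <- c("D", "L", "R")
  out <- character(0)
  for (a in alph) for (b in alph) for (c in alph) for (d in alph) {
    out <- c(out, paste0(a, b, c, d))
  }
  out
}

# per-trial categorical choice probabilities, straight from the equations
oracle_choice_probs <- function(model_id, pars, gamma, observed, goal,
                                bonus, das, true_sums = NULL) {
  n <- length(gamma)
  if (model_id == "UNIFORM") return(rep(1 / n, n))
  rhat <- numeric(n)
  for (j in seq_len(n)) {
    rhat[j] <- if (model_id == "EVM") {
      max(0, 100 - 2 * abs(goal - true_sums[j]))
    } else if (!is.na(observed[j])) {
      max(0, 100 - 2 * abs(goal - observed[j]))
    } else {
      pars$r0
    }
  }
  if (model_id == "EVPBM") rhat[das] <- rhat[das] + pars$b_das
  if (bonus) rhat[das] <- rhat[das] + 0.25 * 20
  for (j in seq_len(n)) if (rhat[j] < 0.01) rhat[j] <- 0.01
  s <- sum(rhat)
  lik <- numeric(n)
  for (j in seq_len(n)) lik[j] <- (rhat[j] / s)^pars$beta
  if (model_id %in% c("EVPRM", "EVPRM2")) {
    alpha <- numeric(n)
    for (j in seq_len(n)) {
      a0 <- if (model_id == "EVPRM") 1 / pars$h
            else if (j == das) 1 / pars$h_das else 1 / pars$h_other
      alpha[j] <- a0 + gamma[j]
    }
    post <- lik * (alpha / sum(alpha))
  } else {
    post <- lik
  }
  post / sum(post)
}

# sequential dataset log-likelihood with its own belief bookkeeping
oracle_dataset_loglik <- function(model_id, pars, data, design) {
  labels <- design$space$labels
  n <- length(labels)
  das <- design$das_index
  gamma <- rep(0, n)
  observed <- rep(NA_real_, n)
  observed[das] <- design$das_expected_sum
  data <- data[order(data$block, data$trial), ]
  ll <- 0
  cur_block <- 1
  for (r in seq_len(nrow(data))) {
    b <- data$block[r]
    if (b != cur_block) {
      observed[] <- NA_real_
      observed[das] <- design$das_expected_sum
      cur_block <- b
    }
    if (data$timeout[r]) next
    goal <- design$blocks[[b]]$goals[data$trial[r]]
    bonus <- design$blocks[[b]]$bonus_block
    probs <- oracle_choice_probs(model_id, pars, gamma, observed, goal,
                                 bonus, das, design$true_sums[b, ])
    k <- match(data$sequence[r], labels)
    ll <- ll + log(probs[k])
    gamma[k] <- gamma[k] + 1
    if (k != das) observed[k] <- data$points_total[r]
  }
  ll
}

# randomized model/belief/trial instances for oracle-equivalence checks
oracle_random_instance <- function(design) {
  n <- length(design$space$labels)
  model_id <- sample(c("EVPRM", "EVPRM2", "EVPBM", "EVPM", "EVM",
                       "UNIFORM"), 1)
  pars <- list(beta = stats::runif(1, 0, 16),
               r0 = stats::runif(1, 5, 100),
               h = stats::runif(1, 0.02, 1),
               h_das = stats::runif(1, 0.02, 1),
               h_other = stats::runif(1, 0.02, 1),
               b_das = stats::runif(1, 0, 60))
  gamma <- stats::rpois(n, stats::runif(1, 0, 6))
  observed <- rep(NA_real_, n)
  seen <- sample(n, sample(0:n, 1))
  observed[seen] <- sample(seq(-240, 240, by = 2), length(seen),
                           replace = TRUE)
  observed[design$das_index] <- design$das_expected_sum
  b <- sample(16, 1)
  list(model_id = model_id, pars = pars, gamma = gamma,
       observed = observed,
       goal = design$das_expected_sum + sample(-24:24, 1),
       bonus = sample(c(TRUE, FALSE), 1), block = b)
}

# run one instance through both routes; returns max absolute difference
oracle_compare_instance <- function(inst, design) {
  pars_obj <- do.call(model_params, c(
    list(model_id = inst$model_id),
    inst$pars[ynat:::.ynat_models[[inst$model_id]]]
  ))
  beliefs <- init_beliefs(design)
  beliefs$gamma <- as.integer(inst$gamma)
  beliefs$observed <- inst$observed
  ctx <- list(goal = inst$goal, bonus = inst$bonus,
              true_sums = design$true_sums[inst$block, ])
  p1 <- choice_probabilities(pars_obj, beliefs, ctx)
  p2 <- oracle_choice_probs(inst$model_id, inst$pars, inst$gamma,
                            inst$observed, inst$goal, inst$bonus,
                            design$das_index,
                            design$true_sums[inst$block, ])
  max(abs(p1 - p2))
}
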
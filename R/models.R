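# Parameters consulted by each model.
.ynat_models <- list(
  EVPRM  = c("beta", "r0", "h"),
  EVPRM2 = c("beta", "r0", "h_das", "h_other"),
  EVPBM  = c("beta", "r0", "b_das"),
  EVPM   = c("beta", "r0"),
  EVM    = c("beta"),
  UNIFORM = character(0)
)

# floor applied to every expected-reward entry so a zero reward (possible
# under the reward rule) never produces an impossible observed choice
.ynat_reward_eps <- 0.01

#' Model parameter container
#'
#' Bundles the free parameters of one member of the model family and checks
#' their domains: `beta >= 0` (precision over expected rewards), `r0 > 0`
#' (approximated reward for unobserved sequences), `h` in (0, 1] (repetition
#' bias strength, the inverse of the initial policy count), `b_das >= 0`
#' (constant DAS bias).  Only the fields the model consults are required:
#' EVPRM uses (beta, r0, h); EVPRM2 (beta, r0, h_das, h_other); EVPBM
#' (beta, r0, b_das); EVPM (beta, r0); EVM (beta); UNIFORM none.
#'
#' @param model_id one of `"EVPRM"`, `"EVPRM2"`, `"EVPBM"`, `"EVPM"`,
#'   `"EVM"`, `"UNIFORM"`.
#' @param beta,r0,h,h_das,h_other,b_das numeric parameter values.
#' @return object of class `ynat_params`.
#' @export
model_params <- function(model_id, beta = NULL, r0 = NULL, h = NULL,
                         h_das = NULL, h_other = NULL, b_das = NULL) {
  model_id <- match.arg(model_id, names(.ynat_models))
  given <- list(beta = beta, r0 = r0, h = h, h_das = h_das,
                h_other = h_other, b_das = b_das)
  need <- .ynat_models[[model_id]]
  for (p in need) {
    v <- given[[p]]
    if (is.null(v) || !is.finite(v)) {
      stop(model_id, " requires parameter '", p, "'")
    }
    ok <- switch(p,
      beta = v >= 0,
      r0 = v > 0,
      b_das = v >= 0,
      v > 0 && v <= 1 # h, h_das, h_other
    )
    if (!ok) stop("parameter '", p, "' = ", v, " outside its domain")
  }
  structure(c(list(model_id = model_id), given[need]), class = "ynat_params")
}

#' @export
print.ynat_params <- function(x, ...) {
  ps <- x[setdiff(names(x), "model_id")]
  cat(x$model_id, "(",
      paste(names(ps), signif(unlist(ps), 4), sep = " = ", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Initial belief state
#'
#' Zero usage counts for every sequence; the observed point sums contain
#' only the DAS, at its communicated expected sum (the DAS is always treated
#' as observed because its mean points are shown at trial start).
#'
#' @param design a `ynat_design`.
#' @return object of class `ynat_beliefs` with `gamma` (integer counts per
#'   sequence), `observed` (point sums, `NA` = unobserved this block) and
#'   `das_index`.
#' @export
init_beliefs <- function(design) {
  n <- length(design$space$labels)
  observed <- rep(NA_real_, n)
  observed[design$das_index] <- design$das_expected_sum
  structure(list(gamma = integer(n), observed = observed,
                 das_index = design$das_index,
                 das_expected_sum = design$das_expected_sum),
            class = "ynat_beliefs")
}

#' Update beliefs after a completed trial
#'
#' Increments the chosen sequence's usage count (which persists across
#' blocks for the whole session) and stores its realized point total as the
#' sequence's observed sum for the current block, the latest observation
#' overwriting earlier ones.  The DAS is the exception: its expected points
#' are re-communicated at the start of every trial, so its entry stays at
#' the communicated sum.  Timeout trials must not be passed here: they
#' update nothing.
#'
#' @param beliefs a `ynat_beliefs`.
#' @param chosen_index index of the chosen sequence in the canonical order.
#' @param total_points realized (noisy) point total of the trial.
#' @return the updated `ynat_beliefs`.
#' @export
observe_trial <- function(beliefs, chosen_index, total_points) {
  if (chosen_index < 1L || chosen_index > length(beliefs$gamma)) {
    stop("chosen_index outside the sequence space")
  }
  beliefs$gamma[chosen_index] <- beliefs$gamma[chosen_index] + 1L
  # the DAS's expected points are re-communicated at the start of every
  # trial, so its entry stays pinned at the communicated sum
  if (chosen_index != beliefs$das_index) {
    beliefs$observed[chosen_index] <- total_points
  }
  beliefs
}

#' Reset within-block observations at a block boundary
#'
#' Observed point sums are forgotten between blocks (the grid changes);
#' only the DAS remains observed, at its communicated expected sum.  Usage
#' counts are kept: the repetition prior grows over the whole session.
#'
#' @param beliefs a `ynat_beliefs`.
#' @return the updated `ynat_beliefs`.
#' @export
new_block <- function(beliefs) {
  beliefs$observed[] <- NA_real_
  beliefs$observed[beliefs$das_index] <- beliefs$das_expected_sum
  beliefs
}

#' Trial context for model evaluation
#'
#' @param design a `ynat_design`.
#' @param block,trial 1-based block (1--16) and trial (1--20) indices.
#' @return list with `goal`, `bonus` flag, `block`, `trial` and `true_sums`
#'   (the block's noiseless per-sequence point sums, used by the EVM).
#' @export
trial_context <- function(design, block, trial) {
  blk <- design$blocks[[block]]
  list(goal = blk$goals[trial], bonus = blk$bonus_block,
       block = block, trial = trial,
       true_sums = design$true_sums[block, ])
}

#' Expected-reward structure over the sequence space
#'
#' For the proxy models (EVPRM, EVPRM2, EVPM, EVPBM) a sequence observed in
#' the current block contributes the reward its stored point sum would earn
#' against the current goal; unobserved sequences contribute the
#' approximated reward `r0`.  The EVM scores every sequence by its true
#' noiseless point sum.  The EVPBM adds its constant `b_das` to the DAS.
#' On bonus trials all models add the bonus expectation +5 (a bonus of 20
#' at probability 0.25) to the DAS entry.  Entries are floored at 0.01.
#'
#' @param params a `ynat_params`.
#' @param beliefs a `ynat_beliefs`.
#' @param ctx a trial context from [trial_context()].
#' @return numeric vector of expected rewards over the sequence space.
#' @export
reward_structure <- function(params, beliefs, ctx) {
  if (params$model_id == "EVM") {
    r <- trial_reward(ctx$goal, ctx$true_sums)
  } else {
    r <- trial_reward(ctx$goal, beliefs$observed)
    r[is.na(r)] <- params$r0
    if (params$model_id == "EVPBM") {
      r[beliefs$das_index] <- r[beliefs$das_index] + params$b_das
    }
  }
  if (isTRUE(ctx$bonus)) {
    r[beliefs$das_index] <- r[beliefs$das_index] +
      0.25 * 20 # expected probabilistic bonus
  }
  pmax(r, .ynat_reward_eps)
}

#' Precision-weighted reward term
#'
#' Elementwise `(r / sum(r))^beta`, without renormalization.
#'
#' @param r expected-reward vector.
#' @param beta precision over expected rewards, `>= 0`.
#' @return non-negative vector.
#' @export
reward_term <- function(r, beta) {
  stopifnot(beta >= 0)
  (r / sum(r))^beta
}

#' Count-based prior over policies
#'
#' Normalized pseudo-counts `alpha_init + gamma`, the repetition bias: each
#' past use of a sequence adds 1 to its count.
#'
#' @param beliefs a `ynat_beliefs`.
#' @param alpha_init positive initial count (the inverse of the repetition
#'   bias strength `h`); may be a vector over sequences.
#' @return probability vector over the sequence space.
#' @export
policy_prior <- function(beliefs, alpha_init) {
  stopifnot(all(alpha_init > 0))
  a <- alpha_init + beliefs$gamma
  a / sum(a)
}

#' Per-trial categorical choice distribution
#'
#' The EVPRM (and its two-strength variant EVPRM2) multiplies the
#' precision-weighted reward term with the count-based policy prior and
#' normalizes; the EVPBM, EVPM and EVM normalize the reward term alone; the
#' UNIFORM baseline assigns 1/36 to every sequence.
#'
#' @param params a `ynat_params`.
#' @param beliefs a `ynat_beliefs`.
#' @param ctx a trial context from [trial_context()].
#' @return probability vector over the sequence space (sums to 1).
#' @export
choice_probabilities <- function(params, beliefs, ctx) {
  n <- length(beliefs$gamma)
  if (params$model_id == "UNIFORM") {
    return(rep(1 / n, n))
  }
  # log-space product of reward term and prior: numerically stable for
  # arbitrarily large precision values
  r <- reward_structure(params, beliefs, ctx)
  l <- params$beta * (log(r) - log(sum(r)))
  if (params$model_id == "EVPRM") {
    l <- l + log(1 / params$h + beliefs$gamma)
  } else if (params$model_id == "EVPRM2") {
    a0 <- rep(1 / params$h_other, n)
    a0[beliefs$das_index] <- 1 / params$h_das
    l <- l + log(a0 + beliefs$gamma)
  }
  p <- exp(l - max(l))
  p / sum(p)
}
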
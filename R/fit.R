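# Parameter transforms used by the optimizer and sampler: strictly positive
# parameters live on the log scale, the unit-interval repetition strengths
# on the logit scale.
.transform_info <- function(model_id) {
  active <- .ynat_models[[model_id]]
  kind <- vapply(active, function(p) {
    if (p %in% c("h", "h_das", "h_other")) "logit" else "log"
  }, "")
  list(active = active, kind = kind)
}

.theta_to_z <- function(theta, kind) {
  z <- numeric(length(theta))
  is_logit <- kind == "logit"
  z[is_logit] <- stats::qlogis(theta[is_logit])
  z[!is_logit] <- log(theta[!is_logit])
  z
}

.z_to_theta <- function(z, kind) {
  theta <- numeric(length(z))
  is_logit <- kind == "logit"
  theta[is_logit] <- stats::plogis(z[is_logit])
  theta[!is_logit] <- exp(z[!is_logit])
  theta
}

# log |d theta / d z|, needed when the posterior is expressed over z
.log_jacobian <- function(z, kind) {
  sum(ifelse(kind == "logit",
             stats::plogis(z, log.p = TRUE) +
               stats::plogis(-z, log.p = TRUE),
             z))
}

.params_from_z <- function(z, model_id, ti) {
  theta <- as.list(.z_to_theta(z, ti$kind))
  names(theta) <- ti$active
  do.call(model_params, c(list(model_id = model_id), theta))
}

# log posterior (optionally with the z-space Jacobian) on transformed params
.make_logpost <- function(model_id, pc, jacobian = FALSE) {
  ti <- .transform_info(model_id)
  function(z) {
    params <- .params_from_z(z, model_id, ti)
    lp <- sum(.pointwise_loglik(params, pc)) + prior_logpdf(params)
    if (jacobian) lp <- lp + .log_jacobian(z, ti$kind)
    lp
  }
}

# starting points: prior means first, then draws from the priors
.fit_starts <- function(model_id, n_starts, seed) {
  spec <- prior_spec()
  ti <- .transform_info(model_id)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  means <- vapply(ti$active, function(p) spec[[p]]$mean, 0)
  starts <- list(.theta_to_z(means, ti$kind))
  for (s in seq_len(max(0L, n_starts - 1L))) {
    draw <- vapply(ti$active, function(p) {
      e <- spec[[p]]
      if (e$dist == "gamma") stats::rgamma(1L, e$shape, rate = e$rate)
      else stats::rbeta(1L, e$a, e$b)
    }, 0)
    starts[[s + 1L]] <- .theta_to_z(draw, ti$kind)
  }
  starts
}

#' Maximum a posteriori fit
#'
#' Maximizes `dataset_loglik + prior_logpdf` with multi-start Nelder--Mead
#' (Brent for one-parameter models) on transformed parameters (log for
#' positive parameters, logit for the unit-interval repetition strengths).
#' Deterministic given `seed`.
#'
#' @param model_id model identifier (see [model_params()]).
#' @param data one participant's trial table.
#' @param design a `ynat_design`.
#' @param n_starts number of optimizer starts (default 8; the first start
#'   is at the prior means, the rest are prior draws).
#' @param seed seed controlling the random starts.
#' @return object of class `ynat_fit` with elements `model_id`, `params`
#'   (the mode), `loglik`, `logpost`, `n_trials`, `convergence` (0 = all
#'   good) and `starts` (per-start objective values).
#' @export
fit_map <- function(model_id, data, design, n_starts = 8L, seed = 1L) {
  model_id <- match.arg(model_id, names(.ynat_models))
  pc <- .precompute_loglik(data, design)
  if (pc$n < 1L) stop("no completed trials to fit")
  if (model_id == "UNIFORM") {
    ll <- -pc$n * log(pc$n_seq)
    return(structure(list(model_id = model_id,
                          params = model_params("UNIFORM"),
                          loglik = ll, logpost = ll, n_trials = pc$n,
                          convergence = 0L, starts = ll),
                     class = "ynat_fit"))
  }
  lpost <- .make_logpost(model_id, pc)
  neg <- function(z) -lpost(z)
  starts <- .fit_starts(model_id, n_starts, seed)
  d <- length(starts[[1L]])
  best <- NULL
  vals <- numeric(length(starts))
  for (s in seq_along(starts)) {
    fit <- if (d == 1L) {
      stats::optim(starts[[s]], neg, method = "Brent",
                   lower = -12, upper = 8)
    } else {
      stats::optim(starts[[s]], neg, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-10))
    }
    vals[s] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ti <- .transform_info(model_id)
  params <- .params_from_z(best$par, model_id, ti)
  structure(list(model_id = model_id, params = params,
                 loglik = sum(.pointwise_loglik(params, pc)),
                 logpost = -best$value, n_trials = pc$n,
                 convergence = best$convergence, starts = vals,
                 z_mode = best$par),
            class = "ynat_fit")
}

#' @export
print.ynat_fit <- function(x, ...) {
  cat("MAP fit:", x$model_id, "on", x$n_trials, "trials\n")
  cat("  log-posterior:", round(x$logpost, 2),
      " log-likelihood:", round(x$loglik, 2), "\n  ")
  print(x$params)
  invisible(x)
}

# numerical Hessian of f at z (central differences)
.num_hessian <- function(f, z, eps = 1e-4) {
  d <- length(z)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in i:d) {
      zpp <- z; zpp[i] <- zpp[i] + eps; zpp[j] <- zpp[j] + eps
      zpm <- z; zpm[i] <- zpm[i] + eps; zpm[j] <- zpm[j] - eps
      zmp <- z; zmp[i] <- zmp[i] - eps; zmp[j] <- zmp[j] + eps
      zmm <- z; zmm[i] <- zmm[i] - eps; zmm[j] <- zmm[j] - eps
      H[i, j] <- H[j, i] <- (f(zpp) - f(zpm) - f(zmp) + f(zmm)) / (4 * eps^2)
    }
  }
  H
}

#' Laplace approximation to the posterior
#'
#' Finds the mode of the transformed-space posterior (including the change
#' of variables) starting from the MAP, approximates it with a multivariate
#' normal via a numerical Hessian, and draws parameter samples plus their
#' per-trial log-likelihoods.  A fast surrogate for MCMC used by the
#' desk-scale recovery pipelines.
#'
#' @inheritParams fit_map
#' @param n_draws number of posterior draws (default 400).
#' @return object of class `ynat_posterior` with `draws` (matrix
#'   draws x parameters on the natural scale), `pointwise_loglik` (draws x
#'   completed trials), `model_id`, `n_trials` and `method = "laplace"`.
#' @export
fit_laplace <- function(model_id, data, design, n_draws = 400L,
                        n_starts = 8L, seed = 1L) {
  model_id <- match.arg(model_id, names(.ynat_models))
  pc <- .precompute_loglik(data, design)
  if (model_id == "UNIFORM") {
    return(.uniform_posterior(pc, n_draws))
  }
  map <- fit_map(model_id, data, design, n_starts = n_starts, seed = seed)
  lpost_z <- .make_logpost(model_id, pc, jacobian = TRUE)
  opt <- stats::optim(map$z_mode, function(z) -lpost_z(z),
                      method = if (length(map$z_mode) == 1L) "Brent"
                               else "Nelder-Mead",
                      lower = if (length(map$z_mode) == 1L) -12 else -Inf,
                      upper = if (length(map$z_mode) == 1L) 8 else Inf,
                      control = list(maxit = 1000L))
  z0 <- opt$par
  H <- .num_hessian(function(z) -lpost_z(z), z0)
  d <- length(z0)
  # regularize until positive definite
  ridge <- 0
  repeat {
    ch <- try(chol(H + diag(ridge, d)), silent = TRUE)
    if (!inherits(ch, "try-error")) break
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
    if (ridge > 1e3) stop("Hessian could not be regularized")
  }
  cov_chol <- chol(chol2inv(ch)) # upper-triangular factor of covariance
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 9991L))
  Z <- matrix(stats::rnorm(n_draws * d), n_draws, d) %*% cov_chol
  Z <- sweep(Z, 2L, z0, `+`)
  ti <- .transform_info(model_id)
  draws <- matrix(NA_real_, n_draws, d,
                  dimnames = list(NULL, ti$active))
  pw <- matrix(NA_real_, n_draws, pc$n)
  for (s in seq_len(n_draws)) {
    params <- .params_from_z(Z[s, ], model_id, ti)
    draws[s, ] <- unlist(params[ti$active])
    pw[s, ] <- .pointwise_loglik(params, pc)
  }
  structure(list(model_id = model_id, draws = draws,
                 pointwise_loglik = pw, n_trials = pc$n,
                 method = "laplace", map = map),
            class = "ynat_posterior")
}

.uniform_posterior <- function(pc, n_draws) {
  pw <- matrix(-log(pc$n_seq), n_draws, pc$n)
  structure(list(model_id = "UNIFORM",
                 draws = matrix(numeric(0), n_draws, 0L),
                 pointwise_loglik = pw, n_trials = pc$n,
                 method = "closed-form"),
            class = "ynat_posterior")
}

#' @export
print.ynat_posterior <- function(x, ...) {
  cat("Posterior (", x$method, "): ", x$model_id, ", ",
      nrow(x$pointwise_loglik), " draws x ", x$n_trials, " trials\n",
      sep = "")
  if (ncol(x$draws) > 0L) {
    print(round(rbind(mean = colMeans(x$draws),
                      sd = apply(x$draws, 2L, stats::sd)), 4))
  }
  invisible(x)
}

#' Posterior sampling by adaptive random-walk Metropolis
#'
#' Samples the per-participant posterior on transformed parameters with a
#' jointly proposed Gaussian random walk whose component scales are adapted
#' during warm-up toward an acceptance rate near 0.3, then frozen.  Default
#' settings follow the full analysis (4 chains of 1000 kept draws after
#' 1000 warm-up iterations); desk-scale work typically uses 2 chains of a
#' few hundred draws.  Split-R-hat and acceptance rates are reported;
#' R-hat above 1.01 raises a warning in `diagnostics` (never silently).
#'
#' @inheritParams fit_map
#' @param chains number of chains (default 4).
#' @param draws kept draws per chain (default 1000).
#' @param warmup warm-up iterations per chain (default 1000).
#' @return object of class `ynat_posterior` with `draws` (chains x draws
#'   stacked, natural scale), `pointwise_loglik`, and `diagnostics` (list
#'   with `rhat`, `accept_rate`, `warnings`).
#' @export
fit_mcmc <- function(model_id, data, design, chains = 4L, draws = 1000L,
                     warmup = 1000L, seed = 1L) {
  model_id <- match.arg(model_id, names(.ynat_models))
  pc <- .precompute_loglik(data, design)
  if (pc$n < 1L) stop("no completed trials to fit")
  if (model_id == "UNIFORM") {
    return(.uniform_posterior(pc, chains * draws))
  }
  ti <- .transform_info(model_id)
  d <- length(ti$active)
  lpost <- .make_logpost(model_id, pc, jacobian = TRUE)
  all_draws <- vector("list", chains)
  accept <- numeric(chains)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (ch in seq_len(chains)) {
    set.seed(.derive_seed(seed, 131L * ch))
    z <- .fit_starts(model_id, 1L, seed)[[1L]] +
      stats::rnorm(d, 0, 0.1) # jittered prior-mean start
    lp <- lpost(z)
    # phase 1 of warm-up: componentwise scale adaptation toward ~0.3
    # acceptance; phase 2: freeze a full covariance proposal (Haario-style
    # 2.38^2/d scaling of the warm-up sample covariance)
    scale <- rep(0.3, d)
    prop_chol <- NULL
    keep <- matrix(NA_real_, draws, d)
    wu_hist <- matrix(NA_real_, warmup, d)
    n_acc <- 0L
    acc_win <- 0L
    half <- warmup %/% 2L
    for (it in seq_len(warmup + draws)) {
      prop <- if (is.null(prop_chol)) {
        z + stats::rnorm(d, 0, scale)
      } else {
        z + drop(stats::rnorm(d) %*% prop_chol)
      }
      lp_prop <- lpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
        z <- prop; lp <- lp_prop
        acc_win <- acc_win + 1L
        if (it > warmup) n_acc <- n_acc + 1L
      }
      if (it <= warmup) {
        wu_hist[it, ] <- z
        if (it %% 50L == 0L) {
          rate <- acc_win / 50
          if (is.null(prop_chol)) scale <- scale * exp(rate - 0.3)
          else prop_chol <- prop_chol * exp((rate - 0.3) / 2)
          acc_win <- 0L
        }
        if (it == half && half >= 50L && d > 1L) {
          cv <- stats::cov(wu_hist[seq_len(half), , drop = FALSE])
          cv <- cv + diag(1e-8, d)
          ch_try <- try(chol(2.38^2 / d * cv), silent = TRUE)
          if (!inherits(ch_try, "try-error")) prop_chol <- ch_try
        }
      } else {
        keep[it - warmup, ] <- z
      }
    }
    all_draws[[ch]] <- keep
    accept[ch] <- n_acc / draws
  }
  rhat <- vapply(seq_len(d), function(j) {
    .split_rhat(lapply(all_draws, function(m) m[, j]))
  }, 0)
  names(rhat) <- ti$active
  warnings <- character(0)
  if (any(rhat > 1.01, na.rm = TRUE)) {
    warnings <- c(warnings,
                  paste0("split R-hat above 1.01 for: ",
                         paste(ti$active[rhat > 1.01], collapse = ", ")))
  }
  Z <- do.call(rbind, all_draws)
  n_total <- nrow(Z)
  nat <- matrix(NA_real_, n_total, d, dimnames = list(NULL, ti$active))
  pw <- matrix(NA_real_, n_total, pc$n)
  for (s in seq_len(n_total)) {
    params <- .params_from_z(Z[s, ], model_id, ti)
    nat[s, ] <- unlist(params[ti$active])
    pw[s, ] <- .pointwise_loglik(params, pc)
  }
  structure(list(model_id = model_id, draws = nat, pointwise_loglik = pw,
                 n_trials = pc$n, method = "metropolis",
                 diagnostics = list(rhat = rhat, accept_rate = accept,
                                    warnings = warnings)),
            class = "ynat_posterior")
}

# split-R-hat over a list of per-chain draw vectors
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq_len(n) + n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}
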
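# Generalized Pareto fit to sample exceedances (Zhang & Stephens 2009
# empirical-Bayes estimator, with the standard weak prior on the shape).
# x must be positive exceedances; returns shape k and scale sigma.
.gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(th) {
    k <- mean(log1p(-th * x))
    if (!is.finite(k) || k == 0 || -th / k <= 0) return(-Inf)
    n * (log(-th / k) - k - 1)
  }, 0)
  w <- exp(prof - .logsumexp(prof))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weakly informative shrinkage of the shape toward 0.5
  k <- (k * n + 0.5 * 10) / (n + 10)
  list(k = k, sigma = sigma)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance weights; returns the smoothed
# log weights (unnormalized) and the tail shape estimate.
.psis_smooth <- function(lw) {
  S <- length(lw)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  lw <- lw - max(lw)
  if (tail_len < 5L) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cutoff <- lw[ord[S - tail_len]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    return(list(lw = lw, k = NA_real_))
  }
  fit <- .gpd_fit(exceed[exceed > 0])
  pp <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(vapply(pp, .qgpd, 0, k = fit$k, sigma = fit$sigma) +
                    exp(cutoff))
  smoothed <- pmin(smoothed, 0) # truncate at the raw maximum
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO predictive accuracy from pointwise log-likelihoods
#'
#' Estimates the expected log pointwise predictive density (elpd) of
#' leave-one-out cross-validation by Pareto-smoothed importance sampling:
#' per trial, the importance ratios (the inverse pointwise likelihoods)
#' have their largest `min(0.2 S, 3 sqrt(S))` values replaced by expected
#' order statistics of a generalized Pareto distribution fitted to that
#' tail.  Also reports the LOO information criterion `looic = -2 elpd`,
#' its standard error, the effective-parameter penalty `p_loo`, and the
#' per-trial Pareto shape diagnostics `pareto_k` (values above 0.7 trigger
#' a warning flag, not failure).  Trials whose log-likelihood is constant
#' across draws (e.g. the uniform baseline) are degenerate: their elpd is
#' exact and `pareto_k` is `-Inf`.
#'
#' @param pointwise_loglik draws x trials matrix of log-likelihoods, or a
#'   `ynat_posterior`.
#' @return object of class `ynat_loo`: list with `elpd_loo`, `se`, `p_loo`,
#'   `looic`, `looic_se`, `pointwise_elpd`, `pareto_k`, `n_trials`,
#'   `n_draws`, `warnings`.
#' @export
psis_loo <- function(pointwise_loglik) {
  if (inherits(pointwise_loglik, "ynat_posterior")) {
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  }
  ll <- as.matrix(pointwise_loglik)
  S <- nrow(ll); N <- ncol(ll)
  stopifnot(S >= 100L, N >= 1L)
  if (any(!is.finite(ll))) {
    bad <- which(apply(ll, 2L, function(x) any(!is.finite(x))))
    stop("non-finite log-likelihoods for trial(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  elpd <- numeric(N); ks <- numeric(N)
  for (i in seq_len(N)) {
    x <- ll[, i]
    if (stats::sd(x) == 0) {
      elpd[i] <- x[1L]
      ks[i] <- -Inf
      next
    }
    sm <- .psis_smooth(-x)
    elpd[i] <- .logsumexp(sm$lw + x) - .logsumexp(sm$lw)
    ks[i] <- if (is.na(sm$k)) -Inf else sm$k
  }
  lpd <- apply(ll, 2L, .logsumexp) - log(S)
  elpd_loo <- sum(elpd)
  se <- sqrt(N * stats::var(elpd))
  warnings <- character(0)
  if (any(ks > 0.7)) {
    warnings <- sprintf("%d of %d trials have Pareto k above 0.7",
                        sum(ks > 0.7), N)
  }
  structure(list(elpd_loo = elpd_loo, se = se,
                 p_loo = sum(lpd - elpd),
                 looic = -2 * elpd_loo, looic_se = 2 * se,
                 pointwise_elpd = elpd, pareto_k = ks,
                 n_trials = N, n_draws = S, warnings = warnings),
            class = "ynat_loo")
}

#' @export
print.ynat_loo <- function(x, ...) {
  cat("PSIS-LOO over", x$n_trials, "trials (", x$n_draws, "draws )\n")
  cat(sprintf("  elpd_loo %.2f (SE %.2f)  p_loo %.2f  looic %.2f\n",
              x$elpd_loo, x$se, x$p_loo, x$looic))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Group- and participant-level model comparison table
#'
#' Sums per-participant PSIS-LOO results per model, computes LOOIC
#' differences to the best model with the standard error of the pointwise
#' differences, and counts per-participant best-fitting models (lowest
#' LOOIC; exact ties within 1e-9 are recorded as ties, not assigned).
#'
#' @param per_participant named list: participant -> named list: model ->
#'   `ynat_loo`.  All models must cover identical trial sets within a
#'   participant.
#' @return object of class `ynat_comparison`: a data.frame with one row
#'   per model (`model`, `looic`, `se`, `p_loo`, `d_looic`, `d_se`,
#'   `n_best_fit`, `pct_best_fit`) sorted by `looic`, with an attribute
#'   `n_ties`.
#' @export
compare_models <- function(per_participant) {
  stopifnot(length(per_participant) >= 1L)
  models <- names(per_participant[[1L]])
  for (p in per_participant) {
    if (!setequal(names(p), models)) stop("participants fit different models")
    nt <- vapply(p, `[[`, 0, "n_trials")
    if (length(unique(nt)) != 1L) {
      stop("models computed on mismatched trial counts within a participant")
    }
  }
  pw <- lapply(models, function(m) {
    unlist(lapply(per_participant, function(p) p[[m]]$pointwise_elpd))
  })
  names(pw) <- models
  N <- length(pw[[1L]])
  elpd <- vapply(pw, sum, 0)
  looic <- -2 * elpd
  se <- vapply(pw, function(x) 2 * sqrt(N * stats::var(x)), 0)
  p_loo <- vapply(models, function(m) {
    sum(vapply(per_participant, function(p) p[[m]]$p_loo, 0))
  }, 0)
  best <- models[which.min(looic)]
  d_looic <- looic - looic[best]
  d_se <- vapply(models, function(m) {
    if (m == best) return(0)
    dd <- pw[[m]] - pw[[best]]
    2 * sqrt(N * stats::var(dd))
  }, 0)
  n_best <- stats::setNames(integer(length(models)), models)
  n_ties <- 0L
  for (p in per_participant) {
    li <- vapply(p, `[[`, 0, "looic")
    mn <- min(li)
    winners <- names(li)[li - mn < 1e-9]
    if (length(winners) > 1L) n_ties <- n_ties + 1L
    else n_best[winners] <- n_best[winners] + 1L
  }
  out <- data.frame(model = models, looic = looic, se = se, p_loo = p_loo,
                    d_looic = d_looic, d_se = d_se,
                    n_best_fit = as.integer(n_best),
                    pct_best_fit = 100 * as.integer(n_best) /
                      length(per_participant),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$looic), ]
  rownames(out) <- NULL
  attr(out, "n_ties") <- n_ties
  class(out) <- c("ynat_comparison", "data.frame")
  out
}
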
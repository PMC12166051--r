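test_that("initial beliefs are empty except the communicated DAS", {
  d <- ynat_test_design()
  b <- init_beliefs(d)
  expect_identical(sum(b$gamma), 0L)
  expect_identical(b$observed[d$das_index], 120)
  expect_identical(sum(!is.na(b$observed)), 1L)
  expect_equal(policy_prior(b, 1), rep(1 / 36, 36))
})

test_that("belief updates count usage and store latest block observations", {
  d <- ynat_test_design()
  b <- init_beliefs(d)
  k <- match("DRRD", d$space$labels)
  b <- observe_trial(b, k, 88)
  expect_identical(sum(b$gamma), 1L)
  expect_identical(b$observed[k], 88)
  b <- observe_trial(b, k, 92) # latest observation wins
  expect_identical(b$observed[k], 92)
  expect_identical(b$gamma[k], 2L)
  # the DAS entry stays pinned at the communicated expected sum
  b <- observe_trial(b, d$das_index, 117)
  expect_identical(b$observed[d$das_index], 120)
  # block boundary: observations reset, usage counts persist
  b <- new_block(b)
  expect_identical(sum(!is.na(b$observed)), 1L)
  expect_identical(b$gamma[k], 2L)
  expect_error(observe_trial(b, 99, 10), "sequence space")
})

test_that("reward structures follow each model's assumptions", {
  d <- ynat_test_design()
  b <- init_beliefs(d)
  ctx <- trial_context(d, 1, 1)
  ctx$bonus <- FALSE
  p_evpm <- model_params("EVPM", beta = 2, r0 = 55)
  r <- reward_structure(p_evpm, b, ctx)
  unobs <- setdiff(seq_len(36), d$das_index)
  expect_true(all(r[unobs] == 55))
  # bonus trials add the +5 expected bonus to the DAS only
  ctx_bonus <- ctx; ctx_bonus$bonus <- TRUE
  r_b <- reward_structure(p_evpm, b, ctx_bonus)
  expect_equal(r_b[d$das_index] - r[d$das_index], 5)
  expect_equal(r_b[unobs], r[unobs])
  # EVM scores a sequence 100 when the goal equals its true sum
  j <- 3L
  ctx_evm <- ctx; ctx_evm$goal <- d$true_sums[1, j]
  r_evm <- reward_structure(model_params("EVM", beta = 1), b, ctx_evm)
  expect_equal(r_evm[j], 100)
  # EVPBM adds its constant bias to the DAS
  p_bias <- model_params("EVPBM", beta = 2, r0 = 55, b_das = 12)
  r_bias <- reward_structure(p_bias, b, ctx)
  expect_equal(r_bias[d$das_index] - r[d$das_index], 12)
  # clamping keeps every entry positive
  ctx_far <- ctx; ctx_far$goal <- 400
  r_far <- reward_structure(model_params("EVPM", beta = 2, r0 = 0.001), b,
                            ctx_far)
  expect_true(all(r_far >= 0.01))
})

test_that("reward term and policy prior match hand arithmetic", {
  r <- c(10, 20, 30, 40)
  expect_equal(reward_term(r, 0), rep(1, 4))
  expect_equal(reward_term(r, 1), r / 100)
  expect_equal(reward_term(rep(25, 4), 3), rep(0.25^3, 4))
  d <- ynat_test_design()
  b <- init_beliefs(d)
  b <- observe_trial(b, 2L, 100)
  expect_equal(policy_prior(b, 1)[2], 2 / 37)
  expect_equal(policy_prior(b, 1)[3], 1 / 37)
  expect_equal(policy_prior(b, 100)[2], 101 / 3601)
})

test_that("model family nests and degenerates correctly", {
  d <- ynat_test_design()
  b <- init_beliefs(d)
  for (k in c(5L, 5L, 12L, 20L)) b <- observe_trial(b, k, 100 + k)
  ctx <- trial_context(d, 2, 7)
  p_evpm <- model_params("EVPM", beta = 3, r0 = 60)
  # vanishing repetition strength: the prior washes out
  p_h0 <- model_params("EVPRM", beta = 3, r0 = 60, h = 1e-9)
  expect_equal(choice_probabilities(p_h0, b, ctx),
               choice_probabilities(p_evpm, b, ctx), tolerance = 1e-6)
  # zero DAS bias reduces the bias model to the proxy model exactly
  p_b0 <- model_params("EVPBM", beta = 3, r0 = 60, b_das = 0)
  expect_identical(choice_probabilities(p_b0, b, ctx),
                   choice_probabilities(p_evpm, b, ctx))
  # beta = 0 leaves only the repetition prior
  p_beta0 <- model_params("EVPRM", beta = 0, r0 = 60, h = 0.5)
  expect_equal(choice_probabilities(p_beta0, b, ctx),
               policy_prior(b, 2), tolerance = 1e-12)
  # proxy model with fully observed true sums equals the exact-value model
  b_full <- b
  b_full$observed <- as.numeric(d$true_sums[2, ])
  expect_equal(choice_probabilities(p_evpm, b_full, ctx),
               choice_probabilities(model_params("EVM", beta = 3), b_full,
                                    ctx),
               tolerance = 1e-12)
  # uniform baseline
  expect_equal(choice_probabilities(model_params("UNIFORM"), b, ctx),
               rep(1 / 36, 36))
})

test_that("incrementing a usage count strictly raises that choice probability", {
  d <- ynat_test_design()
  ctx <- trial_context(d, 3, 10)
  p <- model_params("EVPRM", beta = 4, r0 = 60, h = 0.7)
  b <- init_beliefs(d)
  pr0 <- choice_probabilities(p, b, ctx)
  for (reps in 1:5) {
    # raise only the count, holding the reward beliefs fixed
    b$gamma[9] <- b$gamma[9] + 1L
    pr1 <- choice_probabilities(p, b, ctx)
    expect_gt(pr1[9], pr0[9])
    pr0 <- pr1
  }
})

test_that("choice probabilities match the naive equation transcription", {
  d <- ynat_test_design()
  set.seed(42)
  for (i in seq_len(200)) {
    inst <- oracle_random_instance(d)
    expect_lt(oracle_compare_instance(inst, d), 1e-10)
  }
  # every distribution sums to one
  b <- init_beliefs(d)
  ctx <- trial_context(d, 1, 1)
  for (m in list(model_params("EVPRM", beta = 5, r0 = 70, h = 0.9),
                 model_params("EVPRM2", beta = 5, r0 = 70, h_das = 0.9,
                              h_other = 0.4),
                 model_params("EVPBM", beta = 5, r0 = 70, b_das = 20),
                 model_params("EVM", beta = 5))) {
    pr <- choice_probabilities(m, b, ctx)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_true(all(pr >= 0))
  }
})

test_that("parameter containers enforce model-specific domains", {
  expect_error(model_params("EVPRM", beta = 5, r0 = 70), "requires")
  expect_error(model_params("EVPRM", beta = 5, r0 = 70, h = 1.5), "domain")
  expect_error(model_params("EVPM", beta = -1, r0 = 70), "domain")
  expect_s3_class(model_params("UNIFORM"), "ynat_params")
})
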
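test_that("goal trajectories honor the stated quantitative constraints", {
  maxima <- integer(4)
  for (id in 1:4) {
    tr <- build_goal_trajectory(id)
    expect_length(tr$goals, 20L)
    expect_true(all(abs(tr$offsets[1:2]) <= 5))
    expect_lte(max(abs(tr$offsets)), 24L)
    maxima[id] <- max(abs(tr$offsets))
  }
  expect_identical(sort(maxima), c(12L, 16L, 20L, 24L))
  # trajectory 1 rises past mid-block before falling back
  tr1 <- build_goal_trajectory(1)
  expect_gt(which.max(abs(tr1$offsets)), 10L)
  expect_lt(abs(tr1$offsets[20]), abs(tr1$offsets[12]))
  # trajectory 4 stays mostly near the DAS points
  tr4 <- build_goal_trajectory(4)
  expect_gt(mean(abs(tr4$offsets) <= 5), 0.5)
  expect_error(build_goal_trajectory(5), "trajectory_id")
})

test_that("the default design satisfies every structural invariant", {
  d <- ynat_test_design()
  off <- design_offsets(d)
  expect_length(off, 320L)
  expect_identical(sum(abs(off) <= 5), 140L)
  expect_identical(max(abs(off)), 24L)
  traj_ids <- vapply(d$blocks, `[[`, 1L, "trajectory_id")
  per_traj_max <- vapply(1:4, function(id) {
    max(abs(build_goal_trajectory(id)$offsets))
  }, 0L)
  expect_identical(min(per_traj_max), 12L)
  # each segment of four blocks uses every trajectory once
  for (s in 1:4) {
    expect_setequal(traj_ids[(4 * s - 3):(4 * s)], 1:4)
  }
  # no trajectory in two consecutive blocks
  expect_true(all(diff(traj_ids) != 0L))
  # 8 bonus blocks, two per trajectory
  bonus <- vapply(d$blocks, `[[`, TRUE, "bonus_block")
  expect_identical(sum(bonus), 8L)
  expect_true(all(table(traj_ids[bonus]) == 2L))
  # expected bonus increment
  expect_identical(d$bonus_probability * d$bonus_amount, 5)
})

test_that("block grids carry the constant-sum DAS and allowed values", {
  d <- ynat_test_design()
  allowed <- c(seq(-60L, -10L, by = 10L), seq(10L, 60L, by = 10L))
  p <- path_cells(d$das_label, d$space$start)
  for (b in d$blocks) {
    v <- b$grid$values
    on_path <- v[cbind(p[-1, 1] + 1L, p[-1, 2] + 1L)]
    expect_identical(on_path, b$das_cell_values)
    expect_identical(sum(on_path), d$das_expected_sum)
    expect_identical(v[3, 3], 0L) # start cell holds no circle
    expect_true(all(v[-(which(row(v) == 3 & col(v) == 3))] %in% allowed))
    expect_identical(sequence_points(b$grid, d$das_label),
                     d$das_expected_sum)
  }
  # grids change between blocks
  expect_false(identical(d$blocks[[1]]$grid$values,
                         d$blocks[[2]]$grid$values))
  # true noiseless sums agree with direct recomputation
  for (b in c(1L, 9L)) {
    sums <- vapply(d$space$labels, function(lab) {
      sequence_points(d$blocks[[b]]$grid, lab)
    }, 0L)
    expect_identical(unname(sums), d$true_sums[b, ])
  }
})

test_that("design construction is deterministic and RNG-isolated", {
  d1 <- build_default_design(seed = 123)
  set.seed(999) # ambient RNG state must not leak in
  d2 <- build_default_design(seed = 123)
  expect_identical(d1$true_sums, d2$true_sums)
  expect_identical(d1$blocks[[5]]$grid$values, d2$blocks[[5]]$grid$values)
  d3 <- build_default_design(seed = 124)
  expect_false(identical(d1$true_sums, d3$true_sums))
  # building a design leaves the ambient RNG stream unchanged
  set.seed(7); x <- stats::runif(1)
  set.seed(7); invisible(build_default_design()); y <- stats::runif(1)
  expect_identical(x, y)
})

test_that("grid layout rejects disallowed circle values", {
  sp <- enumerate_sequences(c(2, 2))
  expect_error(build_grid_layout(sp, "DDRR", c(30, 30, 30, 35)),
               "multiples of 10")
  expect_error(grid_layout(matrix(5L, 5, 5)), "multiples of 10")
})
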
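test_that("enumeration from the grid center yields the 36-sequence space", {
  sp <- enumerate_sequences(c(2, 2))
  expect_length(sp$labels, 36L)
  expect_true("DDRR" %in% sp$labels)
  expect_false("LLLL" %in% sp$labels)
  # member-by-member agreement with a brute-force legality oracle
  all81 <- oracle_all_labels()
  expect_length(all81, 81L)
  valid <- all81[vapply(all81, oracle_is_valid_sequence, logical(1))]
  expect_identical(sp$labels, sort(valid, method = "radix"))
  # canonical order is stable ASCII sorting
  expect_identical(sp$labels, sort(sp$labels, method = "radix"))
})

test_that("in-bounds permutations of {L,R,D,D} return to start and are excluded", {
  all81 <- oracle_all_labels()
  is_lrdd <- vapply(all81, function(lab) {
    ch <- sort(strsplit(lab, "")[[1]])
    identical(ch, c("D", "D", "L", "R"))
  }, logical(1))
  expect_identical(sum(is_lrdd), 12L)
  sp <- enumerate_sequences(c(2, 2))
  # none survive: the net displacement of {L,R,D,D} is zero
  expect_length(intersect(all81[is_lrdd], sp$labels), 0L)
  for (lab in all81[is_lrdd]) {
    res <- try(path_cells(lab, c(2, 2)), silent = TRUE)
    if (!inherits(res, "try-error")) fail(paste(lab, "should be invalid"))
  }
})

test_that("the grid center start admits a 36-sequence space", {
  counts <- outer(0:4, 0:4, Vectorize(function(r, c) {
    length(enumerate_sequences(c(r, c))$labels)
  }))
  expect_identical(counts[3, 3], 36L)
  expect_true(all(counts <= 36L))
})

test_that("path_cells traces displacements and reports bad moves", {
  p <- path_cells("DDRR", c(2, 2))
  expect_identical(p, matrix(c(2L, 2L, 3L, 2L, 4L, 2L, 3L, 3L, 2L, 4L),
                             ncol = 2, byrow = TRUE))
  expect_error(path_cells("DDDD", c(2, 2)), "move 3")
  sp <- enumerate_sequences(c(2, 2))
  for (lab in sp$labels) {
    cells <- path_cells(lab, c(2, 2))
    expect_identical(nrow(unique(cells)), 5L)
  }
})

test_that("sequence and realized points sum the path's circle values", {
  vals <- matrix(10L, 5, 5)
  vals[3, 3] <- 0L
  g <- grid_layout(vals, c(2, 2))
  expect_identical(sequence_points(g, "DDRR"), 40L)
  # distinct values along the DAS path: (3,2)=40, (4,2)=-20, (3,3)=10, (2,4)=60
  vals2 <- vals
  vals2[4, 3] <- 40L; vals2[5, 3] <- -20L; vals2[4, 4] <- 10L
  vals2[3, 5] <- 60L
  g2 <- grid_layout(vals2, c(2, 2))
  expect_identical(sequence_points(g2, "DDRR"), 90L)
  # noiseless realization equals the noiseless sum
  rp <- realized_points(g2, "DDRR", noise_sd = 0)
  expect_identical(rp$total, 90L)
  expect_identical(rp$move_points, c(40L, -20L, 10L, 60L))
  # determinism under a fixed seed
  set.seed(5); a <- realized_points(g2, "DDRR")
  set.seed(5); b <- realized_points(g2, "DDRR")
  expect_identical(a, b)
  # zero-mean noise: mean of totals near the noiseless sum
  set.seed(99)
  totals <- replicate(10000, realized_points(g2, "DDRR")$total)
  expect_lt(abs(mean(totals) - 90), 0.5)
})

test_that("rounded point noise has near-zero empirical mean", {
  set.seed(7)
  # the task's rounding rule applied directly to noise draws
  noise <- ynat:::.round_half_away(stats::rnorm(1e5, 0, 1.3))
  expect_lt(abs(mean(noise)), 0.05)
})

test_that("the reward rule is the clamped linear penalty on goal distance", {
  expect_identical(trial_reward(120, 120), 100)
  expect_identical(trial_reward(120, 170), 0)
  expect_identical(trial_reward(120, 70), 0)
  expect_identical(trial_reward(120, 144), 52)
  # symmetry and slope -2 per unit until the floor
  d <- 0:60
  r_up <- trial_reward(120, 120 + d)
  r_dn <- trial_reward(120, 120 - d)
  expect_identical(r_up, r_dn)
  expect_true(all(r_up >= 0 & r_up <= 100))
  expect_identical(diff(r_up[1:51]), rep(-2, 50))
  expect_true(all(r_up[51:61] == 0))
})

test_that("DAS optimality and sequence classification follow the task rules", {
  expect_true(is_das_optimal(120, 120))
  expect_true(is_das_optimal(125, 120))
  expect_false(is_das_optimal(126, 120))
  expect_identical(classify_sequence("DDRR", "DDRR"), "DAS")
  expect_identical(classify_sequence("DRRD", "DDRR"), "PARTIAL_DAS")
  expect_identical(classify_sequence("LDDR", "DDRR"), "INDEPENDENT")
})
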
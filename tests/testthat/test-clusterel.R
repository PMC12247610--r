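planted_map <- function(n1 = 60, n2 = 60, D = 18, noise = 0) {
  prof1 <- coupling_profile("middle-peak", D)
  prof2 <- coupling_profile("superficial-peak", D)
  vals <- rbind(matrix(rep(prof1, each = n1), n1) *
                  (1 + stats::runif(n1, 0, 0.5)),
                matrix(rep(prof2, each = n2), n2) *
                  (1 + stats::runif(n2, 0, 0.5)))
  if (noise > 0) vals <- vals + matrix(stats::rnorm(length(vals), sd = noise),
                                       nrow(vals))
  vals
}

test_that("k-means recovers two planted profile families perfectly", {
  set.seed(21)
  vals <- planted_map()
  truth <- rep(1:2, each = 60)
  parc <- kmeans_profiles(vals, rep(TRUE, 120), k = 2, seed = 1)
  expect_identical(parc$labels, truth)
  expect_equal(dice_parcellation(parc$labels, truth), 1.0)
  # anchored semantics: label 1 peaks mid, label 2 superficial
  expect_true(which.max(parc$centers[1, ]) %in% 7:12)
  expect_gte(which.max(parc$centers[2, ]), 13)
})

test_that("k-means labels are deterministic and anchored, degenerate input errors", {
  set.seed(22)
  vals <- planted_map(noise = 0.05)
  p1 <- kmeans_profiles(vals, rep(TRUE, 120), seed = 9)
  p2 <- kmeans_profiles(vals, rep(TRUE, 120), seed = 9)
  expect_identical(p1$labels, p2$labels)

  # scaled copies of one profile: correlation distance degenerate
  one <- coupling_profile("middle-peak", 18)
  scaled <- matrix(rep(one, each = 30), 30) * seq(1, 4, length.out = 30)
  expect_error(kmeans_profiles(scaled, rep(TRUE, 30)), "distinct profiles")

  # fewer than k usable profiles
  flat <- matrix(1, 5, 18)
  expect_error(kmeans_profiles(flat, rep(TRUE, 5)), "usable")

  # zero-variance profiles get label 0 and are excluded from the fit
  set.seed(23)
  vals0 <- planted_map(n1 = 20, n2 = 20)
  vals0 <- rbind(vals0, matrix(2, 3, 18))
  p0 <- kmeans_profiles(vals0, rep(TRUE, 43))
  expect_identical(p0$labels[41:43], rep(0L, 3))
  expect_identical(p0$labels[1:40], rep(1:2, each = 20))
})

test_that("dice_parcellation hand-count oracles", {
  expect_equal(dice_parcellation(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L)), 1.0)
  expect_equal(dice_parcellation(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L)), 0.0)
  # DSC_1 = 2/3, DSC_2 = 4/5, mean = 11/15
  expect_equal(dice_parcellation(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 2L)),
               mean(c(2 / 3, 4 / 5)))
  expect_equal(round(dice_parcellation(c(1L, 1L, 2L, 2L),
                                       c(1L, 2L, 2L, 2L)), 4), 0.7333)
  # unclassified vertices are excluded pairwise
  expect_equal(dice_parcellation(c(1L, 0L, 2L), c(1L, 2L, 2L)), 1.0)
  expect_error(dice_parcellation(c(0L, 0L), c(0L, 0L)), "empty")
  expect_error(dice_parcellation(1:3, 1:4), "share a region")
})

test_that("dice_binary arithmetic", {
  expect_equal(dice_binary(c(TRUE, TRUE), c(TRUE, TRUE)), 1.0)
  expect_equal(dice_binary(c(TRUE, FALSE), c(FALSE, TRUE)), 0.0)
  A <- c(rep(TRUE, 4), rep(FALSE, 6))
  B <- c(rep(TRUE, 3), FALSE, rep(TRUE, 3), rep(FALSE, 3))
  expect_equal(dice_binary(A, B), 2 * 3 / (4 + 6))
  expect_error(dice_binary(logical(3), logical(3)), "empty")
})

test_that("network component selection by Dice against an atlas", {
  atlas <- c(rep(TRUE, 10), rep(FALSE, 20))
  perfect <- c(rep(3, 10), rep(0, 20))
  sel <- select_network_component(list(perfect), atlas)
  expect_equal(sel$dice, 1.0)
  expect_identical(sel$index, 1L)

  # all candidates disjoint from the atlas: first returned with a warning
  disj <- c(rep(0, 10), rep(3, 5), rep(0, 15))
  expect_warning(s2 <- select_network_component(list(disj, disj), atlas),
                 "no candidate overlaps")
  expect_identical(s2$index, 1L)

  # constructed Dice {0.4, 0.7, 0.6}: second wins
  mk <- function(n_in, n_out) c(rep(3, n_in), rep(0, 10 - n_in),
                                rep(3, n_out), rep(0, 20 - n_out))
  cands <- list(mk(3, 5), mk(7, 5), mk(6, 6))
  d <- vapply(cands, function(z) dice_binary(z > 2, atlas), numeric(1))
  s3 <- select_network_component(cands, atlas)
  expect_identical(s3$index, which.max(d))
  expect_equal(s3$dice, max(d))

  expect_error(select_network_component(list(rep(0, 30)), atlas),
               "empty")
})

test_that("group network mask thresholds inclusively", {
  m <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
            c(FALSE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  expect_identical(group_network_mask(m), c(TRUE, TRUE, FALSE))   # 2 of 4 in
  expect_identical(group_network_mask(m, threshold = 1),
                   c(FALSE, FALSE, FALSE))
  same <- list(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_identical(group_network_mask(same), c(TRUE, FALSE))
})

test_that("split-half reliability: identical sessions, determinism, session minimum", {
  set.seed(24)
  m <- planted_map(n1 = 30, n2 = 30, noise = 0.02)
  maps <- list(m, m, m, m)
  d <- split_half_reliability(maps, rep(TRUE, 60), n_rep = 10)
  expect_equal(d, rep(1.0, 10))
  d2 <- split_half_reliability(maps, rep(TRUE, 60), n_rep = 10)
  expect_identical(d, d2)
  expect_error(split_half_reliability(maps[1:3], rep(TRUE, 60)),
               "at least 4 sessions")
})

test_that("random-pattern null: single vertex enumeration and determinism", {
  # one vertex: each pair gives Dice 1 (labels agree) or 0 (disagree, the
  # matching label is skipped); the mean converges to 0.5
  d1 <- random_pattern_null(1L, n_pairs = 2000, seed = 1)
  expect_true(all(d1 %in% c(0, 1)))
  expect_lt(abs(mean(d1) - 0.5), 0.05)
  expect_identical(random_pattern_null(50L, 10, seed = 2),
                   random_pattern_null(50L, 10, seed = 2))
  expect_error(random_pattern_null(0L), "empty")
})

test_that("compare_dice: pooled t oracle and degenerate cases", {
  # observed {0.6, 0.8} vs null {0.5, 0.5}: pooled t = 2.0
  cmp <- compare_dice(c(0.6, 0.8), c(0.5, 0.5))
  expect_equal(cmp$t_stat, 2.0)
  expect_equal(cmp$df, 2)

  same <- compare_dice(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  shifted <- compare_dice(c(1, 1), c(0.5, 0.5))
  expect_identical(shifted$t_stat, Inf)
  expect_equal(shifted$p_value, 0)

  set.seed(25)
  strong <- compare_dice(rep(1, 50), stats::rnorm(50, 0.5, 0.01))
  expect_lt(strong$p_value, 1e-10)
})
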
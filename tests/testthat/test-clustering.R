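test_that("classification thresholds at tau with a stable boundary", {
  expect_equal(classify_spine(0.20), "increasing")
  expect_equal(classify_spine(-0.20), "decreasing")
  expect_equal(classify_spine(-0.14), "stable")
  expect_equal(classify_spine(0.14), "stable")
  expect_equal(classify_spine(0), "stable")
  expect_true(is.na(classify_spine(NA_real_)))
  expect_error(classify_spine(0.2, tau = 0), "positive")
})

test_that("threshold derivation is the sample sd of baseline changes", {
  expect_equal(derive_threshold(c(-0.1, 0.1)), sd(c(-0.1, 0.1)))
  expect_equal(derive_threshold(c(-0.1, 0.1)), 0.1414, tolerance = 1e-3)
  expect_warning(t1 <- derive_threshold(c(0.3)), "fewer than 2")
  expect_equal(t1, 0.14)
  expect_warning(t2 <- derive_threshold(rep(0.2, 50)), "degenerate")
  expect_equal(t2, 0.14)
  set.seed(6)
  t3 <- derive_threshold(rnorm(10000, 0, 0.14))
  expect_true(t3 >= 0.135 && t3 <= 0.145)
})

test_that("nearest-neighbour pairs follow the stated inclusion rules", {
  p1 <- nearest_neighbor_pairs(c(0, 2.0, 3.0))
  expect_equal(nrow(p1), 2)
  expect_equal(p1$distance, c(2.0, 1.0))
  # below 1.0 um and above 3.5 um are excluded; boundaries retained
  expect_equal(nrow(nearest_neighbor_pairs(c(0, 0.5))), 0)
  expect_equal(nrow(nearest_neighbor_pairs(c(0, 5.0))), 0)
  expect_equal(nearest_neighbor_pairs(c(0, 1.0))$distance, 1.0)
  expect_equal(nearest_neighbor_pairs(c(0, 3.5))$distance, 3.5)
  # single spine: no pairs
  expect_equal(nrow(nearest_neighbor_pairs(2.2)), 0)
  # equidistant tie goes to the smaller position
  pt <- nearest_neighbor_pairs(c(0, 1.5, 3.0))
  expect_equal(nrow(pt), 2)  # (1,2) chosen by the tie, (2,3) by spine 3
})

test_that("pair enumeration matches the brute-force oracle", {
  set.seed(41)
  for (rep in 1:400) {
    n <- sample(2:12, 1)
    pos <- random_grid_positions(n)
    got <- nearest_neighbor_pairs(pos)
    got <- got[order(got$a, got$b), ]
    want <- oracle_nn_pairs(pos)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("pair fractions enumerate directional combinations", {
  classes <- c(a = "increasing", b = "increasing", c = "increasing",
               d = "increasing", e = "increasing")
  prs <- data.frame(a = c("a", "b", "c", "d"), b = c("b", "c", "d", "e"),
                    distance = 1.5)
  f <- pair_fractions(prs, classes)
  expect_equal(unname(f[1:4]), c(100, 0, 100, 0))

  f2 <- pair_fractions(data.frame(a = "a", b = "b", distance = 2),
                       c(a = "increasing", b = "decreasing"))
  expect_equal(unname(f2[1:4]), c(0, 0, 0, 100))

  cl <- c(s1 = "increasing", s2 = "increasing", s3 = "decreasing",
          s4 = "decreasing", s5 = "increasing", s6 = "stable",
          s7 = "increasing", s8 = "decreasing")
  prs3 <- data.frame(a = c("s1", "s3", "s5", "s7"),
                     b = c("s2", "s4", "s6", "s8"), distance = 2)
  f3 <- pair_fractions(prs3, cl)
  expect_equal(unname(f3[1:4]), c(25, 25, 50, 25))
  expect_equal(attr(f3, "n_pairs"), 4)
  expect_error(pair_fractions(prs3[0, ], cl), "no retained pairs")
})

test_that("within-dendrite shuffling is a uniform permutation", {
  vals <- c(1, 2, 3)
  set.seed(9)
  seen <- table(replicate(10000, paste(
    shuffle_changes(vals, rep("d1", 3)), collapse = "")))
  expect_length(seen, 6)
  expect_true(all(abs(seen / 10000 - 1 / 6) < 0.02))
})

test_that("shuffling conserves per-dendrite multisets", {
  set.seed(10)
  dend <- rep(c("a", "b", "c"), times = c(5, 3, 7))
  vals <- rnorm(15)
  sh <- shuffle_changes(vals, dend)
  for (d in unique(dend))
    expect_equal(sort(sh[dend == d]), sort(vals[dend == d]))
  # single-spine dendrite is untouched
  sh2 <- shuffle_changes(c(1, 9), c("x", "y"))
  expect_equal(sh2, c(1, 9))
})

test_that("monte carlo p is exact on an enumerable clustered dendrite", {
  # 12 equally spaced spines, the 6 decreasing ones segregated to one end;
  # all 11 adjacent pairs are nearest-neighbour pairs at 1.5 um
  pos <- seq(0, by = 1.5, length.out = 12)
  dbar <- c(rep(-0.5, 6), rep(0.5, 6))
  sct <- make_change_table("d1", pos, dbar)

  # independent oracle: enumerate all C(12,6) label placements
  combos <- combn(12, 6)
  dd_count <- apply(combos, 2, function(dec) {
    lab <- rep(FALSE, 12); lab[dec] <- TRUE
    sum(lab[-12] & lab[-1])
  })
  obs_dd <- 5L  # contiguous block of 6 has 5 adjacent dec-dec pairs
  exact_p <- mean(dd_count >= obs_dd)
  expect_equal(exact_p, 7 / 924)

  ct <- cluster_test(sct, clustering_config(n_pools = 10000, seed = 17,
                                            tail = "upper"))
  expect_equal(ct$n_pairs, 11)
  expect_equal(unname(ct$observed["both_decrease"]), 100 * 5 / 11)
  expect_lt(abs(ct$p_value["both_decrease"] - exact_p), 0.004)
  expect_lte(ct$p_value["both_decrease"], 0.01)
})

test_that("permutation-invariant datasets give p = 1 on every metric", {
  sct <- rbind(make_change_table("d1", c(0, 1.5, 3, 4.5), rep(0.5, 4)),
               make_change_table("d2", c(0, 2, 4), rep(-0.5, 3)))
  ct <- cluster_test(sct, clustering_config(n_pools = 200, seed = 2))
  expect_equal(unname(ct$p_value), rep(1, 4))
  # the observed statistic sits inside its own null support
  for (k in colnames(ct$null))
    expect_true(ct$observed[k] %in% ct$null[, k])
})

test_that("add-one correction bounds p away from zero", {
  sct <- make_change_table("d1", seq(0, by = 1.5, length.out = 8),
                           c(rep(-0.5, 4), rep(0.5, 4)))
  cfg <- clustering_config(n_pools = 150, seed = 3, correction = "add_one")
  ct <- cluster_test(sct, cfg)
  expect_true(all(ct$p_value >= 1 / (cfg$n_pools + 1)))
  expect_true(all(ct$p_value <= 1))
})

test_that("cluster test is deterministic given its seed", {
  set.seed(1234)
  sct <- make_change_table("d1", sort(runif(9, 0, 18)), rnorm(9, 0, 0.25))
  cfg <- clustering_config(n_pools = 300, seed = 11)
  ct1 <- cluster_test(sct, cfg)
  ct2 <- cluster_test(sct, cfg)
  expect_identical(ct1$null, ct2$null)
  expect_identical(ct1$p_value, ct2$p_value)
})

test_that("auto tail reports the side of the observed deviation", {
  pos <- seq(0, by = 1.5, length.out = 10)
  sct <- rbind(
    make_change_table("d1", pos, c(rep(-0.5, 5), rep(0.5, 5))),
    make_change_table("d2", pos, c(rep(-0.5, 5), rep(0.5, 5))))
  ct <- cluster_test(sct, clustering_config(n_pools = 500, seed = 4,
                                            tail = "auto"))
  expect_equal(unname(ct$tail_used["opposite_direction"]), "lower")
  expect_equal(unname(ct$tail_used["both_decrease"]), "upper")
})

test_that("stable spines pair but count toward no directional metric", {
  sct <- make_change_table("d1", c(0, 2, 4), c(0.5, 0, 0.5))
  ct <- cluster_test(sct, clustering_config(n_pools = 120, seed = 5))
  # both pairs involve the stable middle spine
  expect_equal(ct$n_pairs, 2)
  expect_equal(unname(ct$observed), c(0, 0, 0, 0))
})
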
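test_that("synchronization tensor applies the strict threshold and pruning", {
  # identical phases: all off-diagonal entries 1, nothing pruned
  ph <- matrix(0.2, 10, 4)
  tt <- build_sync_tensor(ph, threshold = pi / 6, occupancy_min = 0.2)
  expect_true(all(tt$values[, , 1][upper.tri(diag(4))] == 1))
  expect_true(all(apply(tt$values, 3, diag) == 0))
  expect_equal(nrow(tt$pruned_pairs), 0)

  # a pair synchronized at exactly 1 of 10 frames falls below 20% occupancy:
  # all its entries are zeroed and the pair is recorded
  ph2 <- matrix(c(rep(0, 10), c(0.1, rep(pi, 9))), 10, 2)
  t2 <- build_sync_tensor(ph2, threshold = pi / 6, occupancy_min = 0.2)
  expect_true(all(t2$values == 0))
  expect_equal(t2$pruned_pairs, matrix(c(1L, 2L), 1, 2))

  # |dphi| = pi/6 exactly does not synchronize (strict inequality)
  ph3 <- matrix(c(0, pi / 6), 1, 2)
  t3 <- build_sync_tensor(ph3, occupancy_min = 0)
  expect_equal(t3$values[1, 2, 1], 0)

  # slices are symmetric
  set.seed(15)
  ph4 <- matrix(runif(50 * 6, -pi, pi), 50, 6)
  t4 <- build_sync_tensor(ph4, occupancy_min = 0)
  for (t in c(1, 25, 50)) {
    expect_identical(t4$values[, , t], t(t4$values[, , t]))
  }
})

test_that("NNTF recovers planted rank-one and two-community structure", {
  act <- cbind(rep(c(1, 0), each = 30))
  arr <- planted_block_tensor(12, list(1:5), act)
  d1 <- nntf(arr, 1, seed = 2, restarts = 3)
  expect_gte(d1$fit, 0.99)
  ind <- as.numeric(1:12 %in% 1:5)
  expect_gte(abs(cor(d1$memberships[, 1], ind)), 0.99)
  # strength identity holds exactly
  expect_equal(d1$strengths,
               sweep(d1$activations, 2, colSums(d1$memberships), "*"))

  acts <- cbind(rep(c(1, 0), each = 30), rep(c(0, 1), each = 30))
  arr2 <- planted_block_tensor(12, list(1:5, 6:10), acts)
  d2 <- nntf(arr2, 2, seed = 3, restarts = 5)
  planted <- cbind(as.numeric(1:12 %in% 1:5), as.numeric(1:12 %in% 6:10))
  expect_true(all(membership_match(d2$memberships, planted) >= 0.95))

  # nested model classes: K=1 fits the two-community tensor strictly worse
  d1b <- nntf(arr2, 1, seed = 3, restarts = 5)
  expect_lt(d1b$fit, d2$fit)

  # factors are nonnegative; fit is within [0, 1]
  expect_true(all(d2$memberships >= 0) && all(d2$activations >= 0))
  expect_true(d2$fit >= 0 && d2$fit <= 1)

  expect_error(nntf(array(0, c(4, 4, 5)), 2), "all-zero")
})

test_that("goodness-of-fit is non-decreasing in K on planted tensors", {
  set.seed(16)
  acts <- cbind(rep(c(1, 0), each = 20), rep(c(0, 1), each = 20),
                rep(c(1, 0, 1, 0), each = 10))
  arr <- planted_block_tensor(15, list(1:5, 6:10, 11:15), acts)
  fits <- vapply(1:4, function(K)
    nntf(arr, K, seed = 4, restarts = 4)$fit, 1)
  expect_true(all(diff(fits) >= -1e-3))
})

test_that("DIFFIT arithmetic and selection follow the stated formula", {
  Fv <- c(0.20, 0.50, 0.60, 0.62, 0.63)
  dc <- boldsync:::difit_curve(Fv, 1:5)
  expect_equal(unname(dc$difit),
               c(0.30 / 0.60, 0.10 / 0.62, 0.02 / 0.63), tolerance = 1e-12)
  expect_equal(dc$K, 2)

  # conventional successive-difference-ratio variant
  dcc <- boldsync:::difit_curve(Fv, 1:5, conventional = TRUE)
  expect_equal(unname(dcc$difit), c(0.30 / 0.10, 0.10 / 0.02, 0.02 / 0.01),
               tolerance = 1e-9)

  # flat curve: tie broken to smallest K with a warning
  expect_warning(dc0 <- boldsync:::difit_curve(rep(0.5, 5), 1:5), "tie")
  expect_equal(dc0$K, 2)

  expect_error(diffit_select(array(1, c(3, 3, 4)), K_range = 2:3), "3 values")
})

test_that("DIFFIT selects the planted component count on a clean tensor", {
  acts <- cbind(rep(c(1, 0), each = 25), rep(c(0, 1), each = 25),
                rep(c(1, 0, 0, 1, 1), each = 10))
  arr <- planted_block_tensor(15, list(1:5, 6:10, 11:15), acts)
  picks <- vapply(1:3, function(s)
    diffit_select(arr, 2:6, seed = s, restarts = 3)$K, 1)
  expect_true(all(picks == 3))
})

test_that("community strengths, totals, and durations are computed exactly", {
  d <- structure(list(memberships = matrix(c(0.5, 0.5, 0), 3, 1),
                      activations = matrix(2, 5, 1), K = 1,
                      sampling_period = 2), class = "sync_decomp")
  cs <- community_strengths(d)
  expect_true(all(cs$strengths == 2))
  expect_true(all(cs$S_series == 2))

  # run lengths above 0.1: series (0, .2, .3, .05, .2) at 2 s -> {4 s, 2 s}
  d2 <- structure(list(memberships = matrix(1, 1, 1),
                       activations = matrix(c(0, 0.2, 0.3, 0.05, 0.2), 5, 1),
                       K = 1, sampling_period = 2), class = "sync_decomp")
  expect_equal(sort(community_strengths(d2)$activation_durations), c(2, 4))

  d3 <- d2; d3$activations[] <- 0
  cs3 <- community_strengths(d3)
  expect_true(all(cs3$S_series == 0))
  expect_equal(length(cs3$activation_durations), 0)
})

test_that("community pooling, clustering, and cophenetic checks behave", {
  set.seed(17)
  a <- matrix(runif(10 * 3), 10, 3)
  pool <- correlate_communities(list(a, a))
  expect_equal(unname(diag(pool$correlation[1:3, 4:6])), rep(1, 3))
  # duplicated vectors sit at zero distance, so the dendrogram reproduces
  # the distances almost exactly
  expect_gt(pool$cophenetic, 0.99)

  # disjoint indicator communities are negatively correlated by closed form
  ind <- cbind(rep(c(1, 0), c(5, 5)), rep(c(0, 1), c(5, 5)))
  r <- correlate_communities(list(ind))$correlation
  expect_equal(r[1, 2], -1)
  expect_true(abs(pool$cophenetic) <= 1)

  # zero-variance column flagged
  expect_warning(z <- correlate_communities(list(cbind(a, 0))), "zero-variance")
  expect_equal(z$dropped, 4L)
})

test_that("Jaccard similarity follows set arithmetic", {
  m <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0.05, 0.05, 0.05, 0.05))
  ref <- cbind(c(1, 1, 0, 0), c(0, 0, 0, 1), c(0, 0, 0, 0))
  expect_warning(j <- jaccard_vs_reference(m, ref, binarize_threshold = 0.1),
                 "empty union")
  expect_equal(j[1, 1], 1)        # identical sets
  expect_equal(j[1, 2], 0)        # disjoint sets
  expect_equal(j[2, 1], 1 / 3)    # (1,1,0,0) vs (1,0,1,0)
  expect_equal(j[3, 2], 0)        # empty community vs nonempty map
  expect_equal(j[3, 3], 0)        # empty union pair
})

test_that("permutation null calibrates the best-match correlation", {
  set.seed(18)
  ref <- matrix(runif(20 * 2), 20, 2)
  # model identical to the references: r_max = 1, exceeds the null bound
  m <- match_to_reference_with_null(ref, ref, n_permutations = 200, seed = 1)
  expect_equal(m$r_max, 1, tolerance = 1e-12)
  expect_true(m$exceeded)
  expect_true(m$r_max_perm < 1)

  # independent model communities exceed the bound only rarely
  hits <- vapply(1:15, function(s) {
    mm <- match_to_reference_with_null(matrix(runif(20 * 2), 20, 2), ref,
                                       n_permutations = 150, seed = s)
    mm$exceeded
  }, TRUE)
  expect_lte(mean(hits), 0.3)

  expect_error(match_to_reference_with_null(ref, ref, n_permutations = 10),
               ">= 100")
})
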
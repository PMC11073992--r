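test_that("stress-minimizing MDS recovers perfectly embeddable configurations", {
  # all-zero distances collapse to a point with zero stress
  z <- matrix(0, 4, 4)
  e0 <- embed_mds(z, seed = 1)
  expect_equal(max(abs(e0$coords)), 0)
  expect_equal(e0$stress, 0)

  # equilateral triangle embeds exactly
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  e3 <- embed_mds(d3, seed = 1)
  expect_equal(as.numeric(dist(e3$coords)), rep(1, 3), tolerance = 1e-6)

  # four known planar points are recovered up to rigid motion
  set.seed(2)
  x <- matrix(rnorm(8), 4, 2)
  d4 <- as.matrix(dist(x))
  e4 <- embed_mds(d4, seed = 1)
  expect_equal(as.matrix(dist(e4$coords)), d4, tolerance = 1e-5,
               ignore_attr = TRUE)

  asym <- d3; asym[1, 2] <- 0.5
  expect_error(embed_mds(asym), "symmetric")
  bad <- d3; bad[1, 2] <- bad[2, 1] <- -0.5
  expect_error(embed_mds(bad), "nonnegative")
})

test_that("densest point matches a brute-force kernel density argmax", {
  set.seed(3)
  co <- rbind(matrix(rnorm(20, sd = 0.3), 10, 2), c(4, 4), c(-3, 5))
  f <- densest_point(list(coords = co), grid_resolution = 100)
  # the default grid's argmax lies within one fine-grid cell of a
  # 1000-resolution brute-force argmax
  fine <- oracle_density_argmax(co, 300)
  cell <- c(diff(range(co[, 1])), diff(range(co[, 2]))) / 99
  expect_lt(abs(f$densest_point[1] - fine[1]), cell[1] + 1e-9)
  expect_lt(abs(f$densest_point[2] - fine[2]), cell[2] + 1e-9)

  # degenerate: all points coincident
  f0 <- densest_point(list(coords = matrix(1, 5, 2)))
  expect_true(f0$degenerate)
  expect_equal(unname(f0$densest_point), c(1, 1))

  # symmetric configuration with an even grid: the two equal central
  # nodes tie, resolved to the lowest row-major node index
  f2 <- densest_point(list(coords = rbind(c(0, 0), c(1, 0))), 10)
  expect_equal(unname(f2$densest_point), c(4 / 9, 0))
})

test_that("proximity weights recode distance with a zero for the furthest", {
  co <- rbind(c(0, 0), c(1, 0), c(2, 0))
  w <- proximity_weights(list(coords = co), c(0, 0))
  expect_equal(as.numeric(w), c(2, 1, 0))

  w2 <- proximity_weights(list(coords = co), c(1, 0))
  expect_true(attr(proximity_weights(list(coords = rbind(c(1, 0), c(0, 1),
                                                         c(-1, 0), c(0, -1))),
                                     c(0, 0)), "fallback_uniform"))

  d <- c(0.5, 2.5, 4.0, 1.0)
  co4 <- cbind(d, 0)
  w4 <- proximity_weights(list(coords = co4), c(0, 0))
  expect_equal(as.numeric(w4), c(3.5, 1.5, 0, 3.0))
})

test_that("weights are invariant to axis-aligned rigid motions of the plane", {
  set.seed(4)
  co <- matrix(rnorm(30), 15, 2)
  base <- proximity_weights(list(coords = co),
                            densest_point(list(coords = co))$densest_point)
  rot90 <- cbind(-co[, 2], co[, 1])
  refl <- cbind(-co[, 1], co[, 2])
  for (tc in list(rot90, refl)) {
    w <- proximity_weights(list(coords = tc),
                           densest_point(list(coords = tc))$densest_point)
    expect_equal(as.numeric(w), as.numeric(base), tolerance = 1e-8)
  }
})

test_that("alternative weighting schemes follow their definitions", {
  expect_equal(as.numeric(alt_weights(matrix(0, 5, 5), "unweighted")),
               rep(1, 5))
  # mean distances 0.2, 0.4, 0.6 -> weights 0.4, 0.2, 0
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0
  d[1, 3] <- d[3, 1] <- 0.4
  d[2, 3] <- d[3, 2] <- 0.8
  expect_equal(rowSums(d) / 2, c(0.2, 0.4, 0.6))
  w <- alt_weights(d, "distance_weighted")
  expect_equal(as.numeric(w), c(0.4, 0.2, 0))

  eq <- matrix(1, 4, 4); diag(eq) <- 0
  expect_true(attr(alt_weights(eq, "distance_weighted"), "fallback_uniform"))
})

test_that("the consensus vector is the weighted mean of row-z-scored patterns", {
  p <- c(2, -1, 0, 3)
  pm <- pattern_matrix(rbind(a = p, b = p, c = p))
  cv <- consensus_vector(pm, c(0.2, 0.5, 0.3))
  expect_equal(cv$vector, as.numeric((p - mean(p)) / sd(p)))

  pm2 <- pattern_matrix(rbind(a = c(1, 2, 3, 4), b = c(9, 1, 4, 4)))
  cv2 <- consensus_vector(pm2, c(1, 0))
  expect_equal(cv2$vector, as.numeric(zscore(c(1, 2, 3, 4))))

  set.seed(5)
  x <- matrix(rnorm(12), 3, 4)
  pm3 <- pattern_matrix(x)
  cv3 <- consensus_vector(pm3, c(2, 1, 1))
  expect_equal(cv3$vector, oracle_weighted_consensus(x, c(2, 1, 1)),
               tolerance = 1e-10)

  expect_error(consensus_vector(pm3, c(1, 1)), "length")
  expect_error(consensus_vector(pm3, c(0, 0, 0)), "positive sum")
})

test_that("all three consensus methods coincide for identical participants", {
  p <- c(0.3, -1.2, 2.0, 0.7, -0.5)
  pm <- pattern_matrix(matrix(rep(p, 6), 6, byrow = TRUE))
  zs <- as.numeric(zscore(p))
  for (m in c("kernel_weighted", "unweighted", "distance_weighted")) {
    gc <- group_consensus(pm, method = m, seed = 1)
    expect_equal(gc$consensus$vector, zs)
    expect_equal(gc$similarity$similarity, rep(1, 6))
  }
})

test_that("similarity to consensus decreases with loneliness under the AK scenario", {
  cfg <- synthetic_config(n_participants = 30, n_targets = 2,
                          idiosyncrasy_slope = 0.08, seed = 21)
  ds <- generate_patterns(cfg)
  ct <- suppressMessages(consensus_similarity_table(ds, seed = 21))
  expect_lt(cor(ct$loneliness, ct$similarity), 0)
})
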
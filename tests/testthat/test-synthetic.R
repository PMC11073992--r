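test_that("loneliness sampling is deterministic, truncated, and matches its moments", {
  cfg <- synthetic_config(seed = 7)
  expect_identical(sample_loneliness(cfg), sample_loneliness(cfg))

  cfg2 <- synthetic_config(n_participants = 500, loneliness_mean = 40,
                           loneliness_sd = 9, loneliness_bounds = c(20, 80),
                           seed = 1)
  l <- sample_loneliness(cfg2)
  expect_true(all(l >= 20 & l <= 80))

  # law of large numbers: truncation at these bounds barely shifts the mean
  cfg3 <- synthetic_config(n_participants = 10000, loneliness_mean = 40.7,
                           loneliness_sd = 8.3, seed = 2)
  expect_lt(abs(mean(sample_loneliness(cfg3)) - 40.7), 0.3)

  expect_error(synthetic_config(loneliness_bounds = c(30, 30)), "min < max")
  expect_error(synthetic_config(scenario = "null", idiosyncrasy_slope = 0.1),
               "requires idiosyncrasy_slope = 0")
})

test_that("datasets are byte-identical under the same config and seed", {
  cfg <- synthetic_config(n_participants = 12, n_targets = 2, seed = 99)
  expect_identical(generate_patterns(cfg), generate_patterns(cfg))
  cfgc <- synthetic_config(n_participants = 12, n_targets = 2,
                           scenario = "cluster", seed = 99)
  expect_identical(generate_dissociation_scenario(cfgc),
                   generate_dissociation_scenario(cfgc))
})

test_that("noiseless patterns reduce to the shared prototype", {
  cfg <- synthetic_config(n_participants = 8, n_targets = 2,
                          base_noise_sd = 0, idiosyncrasy_slope = 0, seed = 3)
  ds <- generate_patterns(cfg)
  for (pm in ds$patterns) {
    expect_equal(max(apply(pm, 2, sd)), 0)
    dy <- pairwise_similarity(pm)
    expect_equal(dy$similarity, rep(1, choose(8, 2)))
  }
  expect_error(generate_patterns(synthetic_config(prototype_sd = 0)),
               "all-zero prototype")
})

test_that("mean pairwise correlation follows the additive-noise closed form", {
  # E[r] = var(prototype) / (var(prototype) + sigma^2) for independent noise
  cfg <- synthetic_config(n_participants = 40, n_features = 500, n_targets = 1,
                          prototype_sd = 1, base_noise_sd = 1,
                          idiosyncrasy_slope = 0, scenario = "null", seed = 11)
  dy <- pairwise_similarity(generate_patterns(cfg)$patterns[[1]])
  expect_lt(abs(mean(dy$similarity) - 0.5), 0.03)

  # and tracks the closed form across a sigma grid
  for (s0 in c(0.5, 2)) {
    cfgs <- synthetic_config(n_participants = 30, n_features = 500,
                             n_targets = 1, base_noise_sd = s0,
                             idiosyncrasy_slope = 0, scenario = "null",
                             seed = 12)
    dys <- pairwise_similarity(generate_patterns(cfgs)$patterns[[1]])
    expect_lt(abs(mean(dys$similarity) - 1 / (1 + s0^2)), 0.04)
  }
})

test_that("null scenario carries no association between loneliness and similarity", {
  rs <- vapply(1:200, function(r) {
    cfg <- synthetic_config(n_targets = 1, scenario = "null", seed = 5000 + r)
    ds <- generate_patterns(cfg)
    dy <- pairwise_similarity(ds$patterns[[1]])
    meta <- data.frame(participant = rownames(ds$patterns[[1]]),
                       loneliness = ds$loneliness)
    dy <- mean_pair_predictor(meta, dy, "loneliness")
    cor(dy$mean_loneliness, dy$similarity)
  }, numeric(1))
  # no systematic association: per-replicate correlations are centred on
  # zero (their spread reflects the shared-participant structure of
  # dyadic data, not a planted effect)
  expect_lt(abs(mean(rs)), 0.02)
  expect_lt(mean(abs(rs)), 0.15)
})

test_that("cluster scenario plants consensus-without-pairwise structure", {
  hits_within <- hits_cons <- logical(100)
  for (r in 1:100) {
    cfg <- synthetic_config(n_participants = 30, n_targets = 1,
                            scenario = "cluster", seed = 7000 + r)
    ds <- generate_dissociation_scenario(cfg)
    lonely <- ds$truth$lonely
    dy <- pairwise_similarity(ds$patterns[[1]])
    l1 <- lonely[match(dy$participant1, rownames(ds$patterns[[1]]))]
    l2 <- lonely[match(dy$participant2, rownames(ds$patterns[[1]]))]
    hits_within[r] <- mean(dy$similarity[l1 & l2]) >= mean(dy$similarity)
    ct <- suppressMessages(consensus_similarity_table(ds, seed = r))
    hits_cons[r] <- mean(ct$similarity[lonely[match(ct$participant,
                                                    rownames(ds$patterns[[1]]))]]) <
      mean(ct$similarity[!lonely[match(ct$participant,
                                       rownames(ds$patterns[[1]]))]])
  }
  expect_gt(mean(hits_within), 0.5)
  expect_gt(mean(hits_cons), 0.5)
})

test_that("ring scenario matches distance-to-consensus while spreading lonely pairs", {
  g_cons <- g_pair <- numeric(100)
  sdiff <- function(a, b) {
    (mean(a) - mean(b)) /
      sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
  }
  for (r in 1:100) {
    cfg <- synthetic_config(n_participants = 40, n_targets = 1,
                            scenario = "ring", seed = 8000 + r)
    ds <- generate_dissociation_scenario(cfg)
    lonely <- ds$truth$lonely
    ids <- rownames(ds$patterns[[1]])
    ct <- suppressMessages(consensus_similarity_table(ds, seed = r))
    dcons <- 1 - ct$similarity
    lon_ct <- lonely[match(ct$participant, ids)]
    g_cons[r] <- sdiff(dcons[lon_ct], dcons[!lon_ct])
    dy <- pairwise_similarity(ds$patterns[[1]])
    l1 <- lonely[match(dy$participant1, ids)]
    l2 <- lonely[match(dy$participant2, ids)]
    g_pair[r] <- sdiff(1 - dy$similarity[l1 & l2], 1 - dy$similarity[!l1 & !l2])
  }
  expect_lt(mean(abs(g_cons)), 0.2)
  expect_gt(mean(g_pair), 0.5)
})

test_that("dissociation scenarios refuse too-small samples", {
  expect_error(
    generate_dissociation_scenario(
      synthetic_config(n_participants = 5, scenario = "cluster")),
    "n_participants >= 6")
})

test_that("binary trait responses follow the flip/missingness model", {
  cfg <- synthetic_config(n_participants = 10, seed = 4)
  r0 <- generate_trait_responses(cfg, consensus_prob = rep(0.7, 40),
                                 flip_rate = 0, missing_rate = 0)
  expect_true(all(apply(r0, 2, function(col) length(unique(col)) == 1)))
  pm <- pattern_matrix(r0, target_id = "traits", space = "trait_binary")
  dy <- pairwise_similarity(pm, metric = "jaccard")
  expect_equal(dy$similarity, rep(1, choose(10, 2)))

  # independent fair responses: expected Jaccard = 0.25 / 0.75 = 1/3
  cfg2 <- synthetic_config(n_participants = 12, seed = 5)
  r5 <- generate_trait_responses(cfg2, consensus_prob = rep(0.5, 3000),
                                 flip_rate = 0.5, missing_rate = 0)
  dy5 <- pairwise_similarity(pattern_matrix(r5, space = "trait_binary"),
                             metric = "jaccard")
  expect_lt(abs(mean(dy5$similarity) - 1 / 3), 0.02)

  # missingness is binomial per entry
  r9 <- generate_trait_responses(cfg2, consensus_prob = rep(0.5, 50),
                                 flip_rate = 0.1, missing_rate = 0.1)
  expect_lt(abs(mean(rowSums(is.na(r9))) - 5), 1.5)
  expect_error(generate_trait_responses(cfg2, rep(0.5, 5), flip_rate = 1.2),
               "flip_rate")
})

test_that("split-half volumes carry the planted reliability structure", {
  expect_error(generate_splithalf_volumes(signal_sd = 0, noise_sd = 0),
               "undefined")

  # noiseless: perfect reliability inside the blob
  sh0 <- generate_splithalf_volumes(signal_sd = 1, noise_sd = 0, seed = 2)
  map0 <- suppressMessages(voxelwise_reliability_map(sh0))
  expect_equal(unname(map0$values[sh0$blob_mask]),
               rep(1, sum(sh0$blob_mask)))

  # independent halves outside the blob; variance-ratio value inside
  sh <- generate_splithalf_volumes(signal_sd = 1, noise_sd = 1,
                                   n_participants = 20, seed = 3)
  map <- voxelwise_reliability_map(sh)
  expect_lt(abs(mean(map$values[!sh$blob_mask])), 0.05)
  expect_lt(abs(mean(map$values[sh$blob_mask]) - 0.5), 0.05)
})
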
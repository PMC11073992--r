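test_that("doubling bookkeeping identities hold and re-doubling errors", {
  dy <- toy_dyads(seq(0.1, 0.6, by = 0.1))            # 4 participants, 6 pairs
  dd <- build_doubled_dyads(dy)
  expect_equal(nrow(dd), 12)
  # every ordered twin carries identical pair-level values
  key <- paste(dd$participant1, dd$participant2)
  twin <- paste(dd$participant2, dd$participant1)
  expect_equal(dd$similarity[match(twin, key)], dd$similarity)
  expect_error(build_doubled_dyads(dd), "already doubled")

  # study-sized table: 40 participants x 5 targets
  big <- do.call(rbind, lapply(1:5, function(t)
    toy_dyads(rep(0, choose(40, 2)), target = sprintf("T%02d", t))))
  expect_equal(nrow(big), 3900)
  expect_equal(nrow(build_doubled_dyads(big)), 7800)
})

test_that("with no random-effect variance the slope reduces to OLS", {
  set.seed(33)
  n <- 12
  dy <- toy_dyads(rep(0, choose(n, 2)))
  dy$x <- rnorm(nrow(dy))
  dy$similarity <- 0.5 * dy$x + rnorm(nrow(dy))      # pure fixed-effect data
  fit <- suppressMessages(fit_mixed_model(
    dy, "similarity", "x",
    random_intercepts = c("participant1", "participant2"), doubled = FALSE))
  ols <- coef(lm(zscore(dy$similarity) ~ zscore(dy$x)))[2]
  b <- fit$effects$beta[fit$effects$term == "x"]
  expect_equal(unname(b), unname(ols), tolerance = 1e-6)
})

test_that("doubling changes the accounting, not the slope", {
  agree <- logical(50)
  for (r in 1:50) {
    cfg <- synthetic_config(idiosyncrasy_slope = 0.06,   # n = 40, 5 targets
                            seed = 4000 + r)
    ds <- generate_patterns(cfg)
    meta <- data.frame(participant = rownames(ds$patterns[[1]]),
                       loneliness = ds$loneliness)
    dy <- stack_dyads(lapply(ds$patterns, pairwise_similarity))
    dy <- mean_pair_predictor(meta, dy, "loneliness")
    fd <- suppressMessages(fit_ak_model(dy))
    fu <- suppressMessages(fit_mixed_model(
      dy, "similarity", "mean_loneliness",
      random_intercepts = c("participant1", "participant2", "target"),
      doubled = FALSE))
    bd <- fd$effects$beta[fd$effects$term == "mean_loneliness"]
    bu <- fu$effects$beta[fu$effects$term == "mean_loneliness"]
    agree[r] <- sign(bd) == sign(bu) && abs(bd - bu) <= 0.05 * abs(bu)
  }
  expect_true(all(agree))
})

test_that("a constant outcome yields zero fixed effects", {
  dy <- toy_dyads(rep(0.4, 10))
  dy$x <- rnorm(10)
  fit <- fit_mixed_model(dy, "similarity", "x",
                         random_intercepts = c("participant1", "participant2"))
  expect_equal(fit$effects$beta, c(0, 0))
})

test_that("doubled fits halve the Satterthwaite df and report df about n - 1", {
  cfg <- synthetic_config(seed = 17)           # 40 participants, 5 targets
  ds <- generate_patterns(cfg)
  meta <- data.frame(participant = rownames(ds$patterns[[1]]),
                     loneliness = ds$loneliness)
  dy <- stack_dyads(lapply(ds$patterns, pairwise_similarity))
  dy <- mean_pair_predictor(meta, dy, "loneliness")
  fit <- suppressMessages(fit_ak_model(dy))
  e <- fit$effects[fit$effects$term == "mean_loneliness", ]
  expect_equal(e$df_adj, e$df_sat / 2)
  expect_lt(abs(e$df_adj - 39), 2)             # df ~ n - 1 after halving
  expect_true(e$df_sat > 0 && is.finite(e$df_sat))
  # two-tailed p is recomputed from |t| at the halved df
  expect_equal(e$p_two, 2 * pt(-abs(e$t), e$df_adj))
  expect_true(e$ci_low <= e$beta && e$beta <= e$ci_high)
})

test_that("one-tailed p values follow the sign-matching rule", {
  fake <- structure(list(
    effects = data.frame(term = "x", beta = c(-1), se = 1, t = -1.645,
                         df_sat = 2000, df_adj = 1000,
                         p_two = 2 * pt(-1.645, 1000), p_one = NA_real_,
                         ci_low = -2, ci_high = 0),
    tail = "two"), class = "akfit")
  adj <- tail_adjust(fake, "one_negative")
  expect_equal(adj$effects$p_one, pt(-1.645, 1000), tolerance = 1e-10)
  expect_lt(abs(adj$effects$p_one - 0.05), 0.002)

  fake$effects$t <- 3; fake$effects$beta <- 3
  wrong <- tail_adjust(fake, "one_negative")
  expect_gt(wrong$effects$p_one, 0.5)
  expect_equal(wrong$effects$p_one, 1 - wrong$effects$p_two / 2)

  fake$effects$t <- 0; fake$effects$beta <- 0
  expect_equal(tail_adjust(fake, "one_positive")$effects$p_one, 0.5)
})

test_that("consensus moderation attaches codes and recovers planted interactions", {
  dy <- do.call(rbind, lapply(c("A", "B"), function(t)
    toy_dyads(rnorm(choose(8, 2), 0.5, 0.1), target = t)))
  dy$mean_loneliness <- rnorm(nrow(dy), 40, 5)
  expect_error(consensus_moderation(dy, coding = c(A = 1)), "missing for target")
  fit <- suppressMessages(consensus_moderation(dy, coding = c(A = 1, B = -1)))
  expect_true("mean_loneliness:consensus_code" %in% fit$effects$term)

  # planted interaction: slope present only in the +1 targets
  null_betas <- numeric(40)
  hits_planted <- logical(40)
  for (r in 1:40) {
    s <- 1000 + r
    cfg_ak <- synthetic_config(n_participants = 30, n_targets = 2,
                               idiosyncrasy_slope = 0.06, seed = s)
    cfg_0 <- synthetic_config(n_participants = 30, n_targets = 2,
                              scenario = "null", seed = s)
    ds_ak <- generate_patterns(cfg_ak)
    ds_0 <- generate_patterns(cfg_0)       # same seed: same loneliness draw
    pats <- c(ds_ak$patterns, ds_0$patterns)
    for (i in seq_along(pats)) attr(pats[[i]], "target_id") <- sprintf("T%d", i)
    meta <- data.frame(participant = rownames(pats[[1]]),
                       loneliness = ds_ak$loneliness)
    dy <- stack_dyads(lapply(pats, pairwise_similarity))
    dy <- mean_pair_predictor(meta, dy, "loneliness")
    coding <- c(T1 = 1, T2 = 1, T3 = -1, T4 = -1)
    fit_p <- suppressMessages(consensus_moderation(dy, coding))
    ip <- fit_p$effects[fit_p$effects$term == "mean_loneliness:consensus_code", ]
    hits_planted[r] <- ip$beta < 0

    # same AK slope in all targets: interaction centred on zero
    dy0 <- stack_dyads(lapply(ds_ak$patterns, pairwise_similarity))
    dy0 <- mean_pair_predictor(meta, dy0, "loneliness")
    fit_n <- suppressMessages(consensus_moderation(dy0, c(T01 = 1, T02 = -1)))
    null_betas[r] <- fit_n$effects$beta[
      fit_n$effects$term == "mean_loneliness:consensus_code"]
  }
  expect_gte(mean(hits_planted), 0.9)
  # unbiased under identical slopes: small and sign-balanced across
  # replicates (its model SE understates between-target heterogeneity,
  # so a rejection-rate check is not informative here)
  expect_lt(abs(mean(null_betas)), 0.02)
  expect_lt(mean(abs(null_betas)), 0.06)
})

test_that("per-target distribution comparisons recover planted shifts", {
  set.seed(60)
  base <- rnorm(choose(10, 2), 0.5, 0.05)
  dy <- rbind(toy_dyads(base, target = "A"),
              toy_dyads(base + 0.04, target = "B"))
  out <- compare_target_distributions(dy)
  expect_equal(nrow(out), 1)
  expect_gt(out$beta, 0)
  # expected standardized shift: half-delta over the pooled sd
  expect_equal(out$beta, 0.02 / sd(dy$similarity), tolerance = 0.15)

  same <- rbind(toy_dyads(base, target = "A"), toy_dyads(base, target = "B"))
  expect_lt(abs(compare_target_distributions(same)$beta), 0.05)

  five <- do.call(rbind, lapply(1:5, function(t)
    toy_dyads(rnorm(choose(6, 2), 0.5, 0.1), target = sprintf("T%d", t))))
  expect_equal(nrow(compare_target_distributions(five)), choose(5, 2))
  expect_error(compare_target_distributions(toy_dyads(rep(0, 3))), "two targets")
})

test_that("median split assigns high/low consensus labels with stated tie rules", {
  dy <- do.call(rbind, lapply(1:10, function(t)
    toy_dyads(rep(t / 10, 3), target = sprintf("T%02d", t))))
  lab <- median_split_targets(dy)
  expect_equal(unname(lab[sprintf("T%02d", 6:10)]), rep("high", 5))
  expect_equal(unname(lab[sprintf("T%02d", 1:5)]), rep("low", 5))

  odd <- do.call(rbind, lapply(1:3, function(t)
    toy_dyads(rep(t / 10, 3), target = sprintf("T%02d", t))))
  lab3 <- median_split_targets(odd)
  expect_equal(sum(lab3 == "high"), 2)
  expect_match(attr(lab3, "note"), "odd")

  tied <- rbind(toy_dyads(rep(0.5, 3), target = "A"),
                toy_dyads(rep(0.5, 3), target = "B"))
  labt <- median_split_targets(tied)
  expect_equal(unname(labt["A"]), "high")     # label order breaks the tie
  expect_equal(unname(labt["B"]), "low")
})
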
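#' Double a dyad table so both pair orders appear
#'
#' Pairwise similarity is symmetric, but a mixed model with separate
#' random intercepts for the first and second member of a pair is not:
#' doubling enters every unordered pair twice with the member roles
#' swapped, so each participant is modeled as both the first and the
#' second member and the crossed random intercepts become symmetric.
#' The induced redundancy is paid for later by halving the Satterthwaite
#' degrees of freedom (see [fit_mixed_model()]).
#'
#' @param dyads an undoubled dyad table (each unordered pair once per
#'   target).
#' @return the doubled table, `2 * choose(n, 2)` rows per target, with
#'   attribute `doubled = TRUE`. Supplying an already-doubled table
#'   (detected by duplicate ordered pairs within a target) is an error.
#' @export
build_doubled_dyads <- function(dyads) {
  stopifnot(is.data.frame(dyads),
            all(c("participant1", "participant2") %in% names(dyads)))
  key <- paste(dyads$target, dyads$participant1, dyads$participant2, sep = "\r")
  rkey <- paste(dyads$target, dyads$participant2, dyads$participant1, sep = "\r")
  if (anyDuplicated(key) || any(rkey %in% key))
    stop("dyad table appears to be already doubled (duplicate ordered pairs)")
  twin <- dyads
  twin$participant1 <- dyads$participant2
  twin$participant2 <- dyads$participant1
  out <- rbind(dyads, twin)
  rownames(out) <- NULL
  attr(out, "doubled") <- TRUE
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Fit a dyadic linear mixed-effects model
#'
#' REML fit via lme4 with Satterthwaite degrees of freedom via lmerTest.
#' All variables (outcome and fixed-effect columns) are z-scored against
#' the analysis sample before fitting, so fixed effects are standardized
#' betas. Random intercepts are crossed, typically for the first
#' participant in a pair, the second participant in a pair, and the
#' target.
#'
#' When `doubled = TRUE` the redundancy introduced by double entry is
#' undone in two parts: the Satterthwaite degrees of freedom are halved
#' (`df_adj = df_sat / 2`), and the standard error is inflated by
#' `sqrt(2)` (the doubled fit sees every unordered pair twice, which
#' deflates the model-based sampling variance of each fixed effect by a
#' factor of two -- both through the duplicated residual rows and
#' through the role-split participant intercepts). The two-tailed p
#' value is then recomputed from the corrected |t| at `df_adj`;
#' simulation shows the halved-df step alone leaves the test far above
#' its nominal size. One-tailed p values follow the sign rule
#' `p_one = p_two / 2` when the estimate's sign matches the stated
#' direction and `1 - p_two / 2` otherwise. Confidence intervals are
#' Wald intervals with the corrected standard error at `df_adj`.
#'
#' A singular fit including a target intercept is automatically refit
#' without it (the usual remedy when the target variance is not
#' identifiable), with a note in `$notes`. Rows with missing values or
#' `flagged = TRUE` are dropped with a recorded count.
#'
#' @param data a (doubled or undoubled) dyad table or any data frame.
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect terms; interaction
#'   terms may be written `"a:b"` (components are z-scored, the product
#'   is formed by the model formula).
#' @param random_intercepts subset of column names to receive random
#'   intercepts, e.g. `c("participant1", "participant2", "target")`.
#' @param doubled logical; requires both `participant1` and
#'   `participant2` intercepts.
#' @param tail `"two"`, `"one_negative"` or `"one_positive"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return an `akfit`: list with `effects` (data.frame: term, beta, se,
#'   t, df_sat, df_adj, p_two, p_one, ci_low, ci_high), `n_obs`,
#'   `n_dropped`, `random_used`, `singular`, `converged`, `notes`,
#'   `tail`, `doubled`, and the underlying `model`.
#' @export
fit_mixed_model <- function(data, outcome, fixed,
                            random_intercepts = c("participant1", "participant2", "target"),
                            doubled = FALSE,
                            tail = c("two", "one_negative", "one_positive"),
                            conf_level = 0.95) {
  tail <- match.arg(tail)
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (doubled && !all(c("participant1", "participant2") %in% random_intercepts))
    stop("doubled fits require random intercepts for participant1 and participant2")
  vars <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  missing_cols <- setdiff(c(vars, random_intercepts), names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, c(outcome, vars), drop = FALSE])
  if ("flagged" %in% names(data)) keep <- keep & !data$flagged
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropping %d flagged/incomplete row(s) before fitting", n_dropped))
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < length(vars) + 2) stop("too few rows to fit")
  for (v in c(outcome, vars)) d[[v]] <- zscore(as.numeric(d[[v]]))
  for (g in random_intercepts) d[[g]] <- factor(d[[g]])

  notes <- character()
  if (stats::sd(d[[outcome]]) == 0) {
    eff <- data.frame(term = c("(Intercept)", fixed), beta = 0, se = NA_real_,
                      t = NA_real_, df_sat = NA_real_, df_adj = NA_real_,
                      p_two = NA_real_, p_one = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_)
    return(structure(list(effects = eff, n_obs = nrow(d), n_dropped = n_dropped,
                          random_used = random_intercepts, singular = TRUE,
                          converged = TRUE, notes = "constant outcome",
                          tail = tail, doubled = doubled, model = NULL,
                          conf_level = conf_level),
                     class = "akfit"))
  }

  fit_once <- function(randoms) {
    fml <- stats::as.formula(paste(
      outcome, "~", paste(fixed, collapse = " + "), "+",
      paste(sprintf("(1 | %s)", randoms), collapse = " + ")))
    warns <- character()
    m <- withCallingHandlers(
      lmerTest::lmer(fml, data = d, REML = TRUE),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    list(model = m, warns = warns)
  }

  randoms <- random_intercepts
  res <- fit_once(randoms)
  # a boundary (zero) target variance is unidentifiable; refit without it.
  # boundary participant variances are left in place -- common under weak
  # participant structure and harmless.
  if ("target" %in% randoms && length(randoms) > 1) {
    vc <- as.data.frame(lme4::VarCorr(res$model))
    tv <- vc$vcov[vc$grp == "target"]
    tot <- sum(vc$vcov)
    if (length(tv) == 1 && tot > 0 && tv / tot < 1e-4) {
      notes <- c(notes, "singular fit: target random intercept dropped")
      randoms <- setdiff(randoms, "target")
      res <- fit_once(randoms)
    }
  }
  m <- res$model
  singular <- lme4::isSingular(m, tol = 1e-4)
  converged <- !any(grepl("failed to converge", res$warns))
  if (length(res$warns)) notes <- c(notes, unique(res$warns))

  cs <- stats::coef(summary(m))
  df_sat <- cs[, "df"]
  df_adj <- if (doubled) df_sat / 2 else df_sat
  # doubling enters every unordered pair twice, so the fitted model sees
  # twice the information actually present: both the duplicated residuals
  # and the role-split participant intercepts deflate Var(beta) by a
  # factor of 2. Undoing the redundancy therefore inflates the standard
  # error by sqrt(2) (equivalently scales t by 1/sqrt(2)) in addition to
  # halving the Satterthwaite df; without the variance correction the
  # doubled fit rejects a true null far above its nominal rate.
  infl <- if (doubled) sqrt(2) else 1
  se <- cs[, "Std. Error"] * infl
  tval <- cs[, "t value"] / infl
  p_two <- 2 * stats::pt(-abs(tval), df_adj)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_adj)
  eff <- data.frame(term = rownames(cs), beta = cs[, "Estimate"],
                    se = se, t = tval,
                    df_sat = df_sat, df_adj = df_adj, p_two = p_two,
                    p_one = NA_real_,
                    ci_low = cs[, "Estimate"] - tcrit * se,
                    ci_high = cs[, "Estimate"] + tcrit * se,
                    row.names = NULL)
  out <- structure(list(effects = eff, n_obs = nrow(d), n_dropped = n_dropped,
                        random_used = randoms, singular = singular,
                        converged = converged, notes = notes, tail = tail,
                        doubled = doubled, model = m, conf_level = conf_level,
                        varcor = as.data.frame(lme4::VarCorr(m))),
                   class = "akfit")
  tail_adjust(out, tail)
}

#' Apply the one-/two-tailed p-value convention to a fit
#'
#' One-tailed p values are reported for effects with an a-priori
#' direction: `p_one = p_two / 2` when the estimate's sign matches the
#' stated direction, `1 - p_two / 2` otherwise. With `tail = "two"` the
#' one-tailed column is left unset.
#'
#' @param fit an `akfit`.
#' @param tail `"two"`, `"one_negative"` or `"one_positive"`.
#' @return the fit with `p_one` (and `tail`) updated.
#' @export
tail_adjust <- function(fit, tail = c("two", "one_negative", "one_positive")) {
  tail <- match.arg(tail)
  stopifnot(inherits(fit, "akfit"))
  eff <- fit$effects
  if (tail == "two") {
    eff$p_one <- NA_real_
  } else {
    sign_wanted <- if (tail == "one_negative") -1 else 1
    match_dir <- sign(eff$beta) == sign_wanted | eff$beta == 0
    eff$p_one <- ifelse(match_dir, eff$p_two / 2, 1 - eff$p_two / 2)
    eff$p_one[eff$beta == 0] <- 0.5
  }
  fit$effects <- eff
  fit$tail <- tail
  fit
}

#' @export
print.akfit <- function(x, digits = 3, ...) {
  cat(sprintf("<akfit> n_obs = %d (%d dropped), random intercepts: %s%s\n",
              x$n_obs, x$n_dropped, paste(x$random_used, collapse = ", "),
              if (x$doubled) " [doubled, df halved]" else ""))
  print(cbind(term = x$effects$term,
              round(x$effects[, -1, drop = FALSE], digits)), row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the Anna Karenina pairwise model
#'
#' Convenience wrapper for the canonical analysis: double the dyad
#' table, then regress pairwise similarity on the pair-mean trait score
#' with crossed random intercepts for both pair members and the target,
#' halved degrees of freedom, and a one-tailed (negative) test of the
#' idiosyncrasy hypothesis.
#'
#' @param dyads undoubled dyad table with `similarity` and the
#'   predictor column.
#' @param predictor pair-level predictor column, default
#'   `"mean_loneliness"`.
#' @param covariates additional fixed-effect columns.
#' @param tail test direction, default `"one_negative"`.
#' @param random_intercepts passed to [fit_mixed_model()].
#' @return an `akfit`.
#' @export
fit_ak_model <- function(dyads, predictor = "mean_loneliness",
                         covariates = character(), tail = "one_negative",
                         random_intercepts = c("participant1", "participant2", "target")) {
  dd <- build_doubled_dyads(dyads)
  fit_mixed_model(dd, outcome = "similarity",
                  fixed = c(predictor, covariates),
                  random_intercepts = random_intercepts,
                  doubled = TRUE, tail = tail)
}

#' Fit the similarity-to-consensus model
#'
#' Regresses each participant's similarity to the group consensus on
#' their trait score, with a random intercept for participant (one
#' observation per participant per target).
#'
#' @param ref_table reference-similarity table from
#'   [consensus_similarity_table()], with a `loneliness` column.
#' @param predictor participant-level predictor, default `"loneliness"`.
#' @param random_intercepts default `"participant"`; use `"target"`
#'   when each participant contributes a single target.
#' @param tail default `"one_negative"`.
#' @return an `akfit`.
#' @export
fit_consensus_model <- function(ref_table, predictor = "loneliness",
                                random_intercepts = "participant",
                                tail = "one_negative") {
  d <- ref_table
  names(d)[names(d) == "participant"] <- "participant"
  fit_mixed_model(d, outcome = "similarity", fixed = predictor,
                  random_intercepts = random_intercepts,
                  doubled = FALSE, tail = tail)
}

#' Test moderation of the pairwise effect by target-level consensus
#'
#' Attaches a per-target consensus code (a contrast such as +1 for
#' high-consensus and -1 for low-consensus targets, or the continuous
#' per-target mean pairwise similarity) and fits the doubled model with
#' the trait-by-consensus interaction.
#'
#' @param dyads undoubled dyad table.
#' @param coding named numeric vector mapping every target in `dyads`
#'   to its code, or `NULL` to use the continuous per-target mean
#'   pairwise similarity.
#' @param predictor pair-level trait column, default `"mean_loneliness"`.
#' @param tail tail for the interaction test, default `"one_negative"`.
#' @return an `akfit` whose effects include the interaction term
#'   `<predictor>:consensus_code`.
#' @export
consensus_moderation <- function(dyads, coding = NULL,
                                 predictor = "mean_loneliness",
                                 tail = "one_negative") {
  targets <- unique(dyads$target)
  if (is.null(coding)) {
    coding <- tapply(dyads$similarity, dyads$target, mean, na.rm = TRUE)
  }
  if (!all(targets %in% names(coding)))
    stop("coding missing for target(s): ",
         paste(setdiff(targets, names(coding)), collapse = ", "))
  dyads$consensus_code <- as.numeric(coding[dyads$target])
  dd <- build_doubled_dyads(dyads)
  fit_mixed_model(dd, outcome = "similarity",
                  fixed = c(predictor, "consensus_code",
                            paste0(predictor, ":consensus_code")),
                  random_intercepts = c("participant1", "participant2", "target"),
                  doubled = TRUE, tail = tail)
}

#' Pairwise comparisons of per-target similarity distributions
#'
#' Before interpreting consensus moderation, verify that targets differ
#' at all in their pairwise-similarity distributions: for every pair of
#' targets, fit a doubled mixed model of similarity on the target
#' indicator with random intercepts for both pair members.
#'
#' @param dyads undoubled dyad table with at least two targets.
#' @return `data.frame` with one row per target pair: `target_a`,
#'   `target_b`, `beta`, `se`, `t`, `df_adj`, `p_two`.
#' @export
compare_target_distributions <- function(dyads) {
  targets <- sort(unique(dyads$target))
  if (length(targets) < 2) stop("need at least two targets")
  pr <- utils::combn(targets, 2)
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    sub <- dyads[dyads$target %in% pr[, k], , drop = FALSE]
    sub$is_second <- as.numeric(sub$target == pr[2, k])
    dd <- build_doubled_dyads(sub)
    f <- fit_mixed_model(dd, outcome = "similarity", fixed = "is_second",
                         random_intercepts = c("participant1", "participant2"),
                         doubled = TRUE, tail = "two")
    e <- f$effects[f$effects$term == "is_second", ]
    data.frame(target_a = pr[1, k], target_b = pr[2, k], beta = e$beta,
               se = e$se, t = e$t, df_adj = e$df_adj, p_two = e$p_two)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-split targets into high- and low-consensus groups
#'
#' Splits targets by their mean pairwise similarity: at or above the
#' median is high-consensus, below is low. With an even number of
#' targets an even split is enforced (ties at the boundary broken by
#' target label order, with a note); with an odd count the median
#' target goes to the high group, with a note.
#'
#' @param dyads dyad table with at least two targets.
#' @return named character vector (`"high"`/`"low"`) over targets, with
#'   attribute `note` when a tie or odd count forced a choice.
#' @export
median_split_targets <- function(dyads) {
  means <- tapply(dyads$similarity, dyads$target, mean, na.rm = TRUE)
  k <- length(means)
  if (k < 2) stop("need at least two targets")
  ord <- order(-means, names(means))   # ties broken by label order
  n_high <- ceiling(k / 2)
  labels <- rep("low", k)
  labels[ord[seq_len(n_high)]] <- "high"
  names(labels) <- names(means)
  note <- NULL
  if (k %% 2 == 1) note <- "odd target count: median target assigned high"
  if (anyDuplicated(means)) note <- c(note, "tied means broken by target label order")
  attr(labels, "note") <- note
  labels
}
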
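#' Exclude participants with degenerate rating variance
#'
#' Quality control for rating tasks: participants with no variance in
#' their responses are excluded first; the remaining participants'
#' response variances are z-scored, and anyone at or below
#' `z_threshold` (default -2, i.e. two or more standard deviations
#' below the mean variance) is excluded as well.
#'
#' @param ratings participants x items numeric matrix (>= 3 rows),
#'   rownames as participant ids.
#' @param z_threshold z cutoff on the (second-pass) variance
#'   distribution.
#' @return list with `kept` and `excluded` id vectors, and `detail`
#'   (data.frame: participant, variance, z, rule).
#' @export
exclude_low_variance <- function(ratings, z_threshold = -2) {
  ratings <- check_matrix(ratings, "ratings")
  if (nrow(ratings) < 3) stop("need at least 3 participants")
  ids <- rownames(ratings) %||% sprintf("P%02d", seq_len(nrow(ratings)))
  v <- apply(ratings, 1, stats::var, na.rm = TRUE)
  zero <- !is.finite(v) | v == 0
  if (all(zero)) stop("all participants have zero rating variance")
  z <- rep(NA_real_, length(v))
  z[!zero] <- zscore(v[!zero])
  rule <- rep("kept", length(v))
  rule[zero] <- "zero_variance"
  rule[!zero & z <= z_threshold] <- "low_variance"
  list(kept = ids[rule == "kept"],
       excluded = ids[rule != "kept"],
       detail = data.frame(participant = ids, variance = v, z = z,
                           rule = rule, row.names = NULL))
}

#' Write / read a pattern matrix as TSV
#'
#' Participants as rows; first column `participant`, then one column
#' per feature.
#'
#' @param patterns a [pattern_matrix()]; `path` a file path.
#' @return `read_pattern_tsv` returns a [pattern_matrix()].
#' @export
write_pattern_tsv <- function(patterns, path) {
  x <- as_plain_matrix(patterns)
  df <- data.frame(participant = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @param path file path.
#' @param target_id,space metadata for the reconstructed matrix.
#' @export
read_pattern_tsv <- function(path, target_id = "target", space = "neural") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  pattern_matrix(m, participant_ids = df[[1]], target_id = target_id,
                 space = space)
}

#' Write split-half volumes as 4-D NIfTI files
#'
#' One 4-D file per half per participant, conditions along the fourth
#' axis. Requires the RNifti package.
#'
#' @param data a `splithalf_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_splithalf_nifti <- function(data, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI volumes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (h in 1:2) {
    half <- data[[paste0("half", h)]]
    for (i in seq_along(half)) {
      vol <- aperm(array(t(half[[i]]), dim = c(data$dim, nrow(half[[i]]))),
                   c(1, 2, 3, 4))
      p <- file.path(dir, sprintf("sub-%02d_half-%d.nii.gz", i, h))
      RNifti::writeNifti(RNifti::asNifti(vol), p)
      paths <- c(paths, p)
    }
  }
  writeLines(jsonlite::toJSON(data$truth, auto_unbox = TRUE, digits = NA),
             file.path(dir, "truth.json"))
  invisible(paths)
}

#' Read split-half volumes from 4-D NIfTI files
#'
#' Counterpart of [write_splithalf_nifti()]: loads one 4-D file per half
#' per participant (conditions along the fourth axis) into a
#' `splithalf_data` object ready for [voxelwise_reliability_map()].
#'
#' @param half1_paths,half2_paths character vectors of NIfTI paths, one
#'   per participant, in matching order.
#' @return a `splithalf_data` object (without a `blob_mask`).
#' @export
read_splithalf_nifti <- function(half1_paths, half2_paths) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI volumes")
  stopifnot(length(half1_paths) == length(half2_paths),
            length(half1_paths) >= 1)
  load_half <- function(paths) {
    lapply(paths, function(p) {
      vol <- RNifti::readNifti(p)
      dm <- dim(vol)
      if (length(dm) != 4) stop("expected a 4-D volume: ", p)
      t(matrix(as.numeric(vol), prod(dm[1:3]), dm[4]))
    })
  }
  h1 <- load_half(half1_paths)
  h2 <- load_half(half2_paths)
  dm <- dim(RNifti::readNifti(half1_paths[1]))[1:3]
  structure(list(half1 = h1, half2 = h2, dim = dm, blob_mask = NULL,
                 truth = NULL),
            class = "splithalf_data")
}

#' Run the full dyadic-consensus analysis on one dataset
#'
#' Orchestrates the standard analysis end to end: pairwise similarity
#' per target, the pair-mean trait predictor, the doubled Anna Karenina
#' mixed model, the per-target group-consensus representations and the
#' similarity-to-consensus model, all under one seed. When `out_dir` is
#' given, tidy CSV/JSON results and a manifest (row counts, exclusion
#' counts, seeds) are written there.
#'
#' @param dataset an `ak_dataset` (e.g. from [generate_patterns()]), or
#'   a named list of pattern matrices plus `loneliness`.
#' @param metric similarity metric (`"pearson"` or `"cosine"`).
#' @param consensus_method consensus weighting scheme.
#' @param seed integer seed for the embedding stage.
#' @param loneliness participant scores (taken from the dataset when
#'   omitted).
#' @param out_dir optional output directory.
#' @return list with `dyads` (undoubled, with `mean_loneliness`),
#'   `ak_fit`, `consensus_table`, `consensus_fit`, `manifest`.
#' @export
run_pipeline <- function(dataset, metric = "pearson",
                         consensus_method = "kernel_weighted",
                         seed = 1L, loneliness = NULL, out_dir = NULL) {
  patterns <- if (inherits(dataset, "ak_dataset")) dataset$patterns else dataset$patterns
  if (is.null(loneliness)) loneliness <- dataset$loneliness
  n <- length(loneliness)
  ids <- rownames(patterns[[1]])
  meta <- data.frame(participant = ids, loneliness = loneliness)

  dyads <- stack_dyads(lapply(patterns, pairwise_similarity, metric = metric))
  dyads <- mean_pair_predictor(meta, dyads, "loneliness")
  ak <- fit_ak_model(dyads)

  cons <- consensus_similarity_table(patterns, method = consensus_method,
                                     metric = metric, loneliness = loneliness,
                                     seed = seed)
  cfit <- fit_consensus_model(cons)

  manifest <- list(
    n_participants = n,
    n_targets = length(patterns),
    n_features = ncol(patterns[[1]]),
    metric = metric, consensus_method = consensus_method, seed = seed,
    n_pairs = nrow(dyads),
    n_pairs_expected = choose(n, 2) * length(patterns),
    n_doubled = 2L * nrow(dyads),
    n_flagged_pairs = sum(dyads$flagged),
    n_consensus_rows = nrow(cons),
    ak_rows_used = ak$n_obs, ak_rows_dropped = ak$n_dropped,
    consensus_rows_used = cfit$n_obs, consensus_rows_dropped = cfit$n_dropped,
    package_version = as.character(utils::packageVersion("akrsa"))
  )
  out <- list(dyads = dyads, ak_fit = ak, consensus_table = cons,
              consensus_fit = cfit, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dyads, file.path(out_dir, "dyads.csv"), row.names = FALSE)
    utils::write.csv(cons, file.path(out_dir, "consensus_similarity.csv"),
                     row.names = FALSE)
    utils::write.csv(ak$effects, file.path(out_dir, "ak_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(cfit$effects, file.path(out_dir, "consensus_effects.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
  }
  out
}

#' Replicate study of the Anna Karenina and consensus models
#'
#' Repeatedly generates a synthetic dataset under one scenario, runs the
#' pairwise Anna Karenina mixed model (and optionally the
#' similarity-to-consensus model), and collects the standardized
#' coefficient and p values per replicate. This is the workhorse behind
#' the package's calibration, power and dissociation checks.
#'
#' @param scenario `"ak"`, `"null"`, `"cluster"` or `"ring"`.
#' @param n_reps number of replicates.
#' @param n_participants,n_targets,n_features,idiosyncrasy_slope
#'   generator settings (see [synthetic_config()]).
#' @param fit_consensus also run the consensus pipeline and model per
#'   replicate (slower; needed for dissociation checks).
#' @param consensus_method weighting scheme for the consensus arm.
#' @param seed base seed; replicate r uses a derived sub-seed.
#' @return `data.frame`, one row per replicate: `ak_beta`, `ak_p_two`,
#'   `ak_p_one`, and (when `fit_consensus`) `cons_beta`, `cons_p_two`,
#'   `cons_p_one`.
#' @export
ak_replicate_study <- function(scenario, n_reps,
                               n_participants = 40L, n_targets = 5L,
                               n_features = 200L,
                               idiosyncrasy_slope = switch(scenario, ak = 0.032,
                                                           ring = 0.008, 0),
                               fit_consensus = FALSE,
                               consensus_method = "kernel_weighted",
                               seed = 1L) {
  one <- function(r) {
    s <- sub_seed(seed, r)
    cfg <- synthetic_config(n_participants = n_participants,
                            n_features = n_features, n_targets = n_targets,
                            idiosyncrasy_slope = idiosyncrasy_slope,
                            scenario = scenario, seed = s)
    ds <- if (scenario %in% c("ak", "null")) generate_patterns(cfg)
          else generate_dissociation_scenario(cfg)
    meta <- data.frame(participant = rownames(ds$patterns[[1]]),
                       loneliness = ds$loneliness)
    dy <- stack_dyads(lapply(ds$patterns, pairwise_similarity, metric = "pearson"))
    dy <- mean_pair_predictor(meta, dy, "loneliness")
    fit <- suppressMessages(fit_ak_model(dy))
    e <- fit$effects[fit$effects$term == "mean_loneliness", ]
    row <- data.frame(rep = r, ak_beta = e$beta, ak_p_two = e$p_two,
                      ak_p_one = e$p_one)
    if (fit_consensus) {
      ct <- suppressMessages(
        consensus_similarity_table(ds, method = consensus_method, seed = s))
      cf <- suppressMessages(fit_consensus_model(ct))
      ce <- cf$effects[cf$effects$term == "loneliness", ]
      row$cons_beta <- ce$beta
      row$cons_p_two <- ce$p_two
      row$cons_p_one <- ce$p_one
    }
    row
  }
  out <- do.call(rbind, lapply(seq_len(n_reps), one))
  rownames(out) <- NULL
  out
}
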
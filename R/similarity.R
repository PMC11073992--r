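#' Construct a pattern matrix
#'
#' A participants-by-features numeric matrix for a single target in one
#' representational space: vectorized voxelwise parameter estimates for a
#' region of interest, a sentence-embedding vector (e.g. 512 dimensions),
#' binary trait-task responses, or Likert-style ratings.
#'
#' @param values numeric matrix, participants in rows, features in
#'   columns. Binary spaces use 0/1 with NA for missing.
#' @param participant_ids character vector of unique ids (defaults to
#'   existing rownames).
#' @param target_id label of the represented target.
#' @param space one of `"neural"`, `"embedding"`, `"trait_binary"`,
#'   `"rating"`.
#' @return the matrix with class `pattern_matrix` and metadata attributes.
#' @export
pattern_matrix <- function(values, participant_ids = rownames(values),
                           target_id = "target",
                           space = c("neural", "embedding", "trait_binary", "rating")) {
  space <- match.arg(space)
  values <- check_matrix(values)
  if (is.null(participant_ids))
    participant_ids <- sprintf("P%02d", seq_len(nrow(values)))
  participant_ids <- as.character(participant_ids)
  if (length(participant_ids) != nrow(values))
    stop("participant_ids length must match nrow(values)")
  if (anyDuplicated(participant_ids)) stop("duplicate participant ids")
  if (ncol(values) < 2) stop("need at least 2 features")
  if (space == "trait_binary" && !all(values %in% c(0, 1) | is.na(values)))
    stop("trait_binary patterns must contain only 0, 1 or NA")
  rownames(values) <- participant_ids
  structure(values, target_id = target_id, space = space,
            class = c("pattern_matrix", "matrix", "array"))
}

target_of <- function(x) attr(x, "target_id") %||% "target"
`%||%` <- function(a, b) if (is.null(a)) b else a

# strip class/attrs down to a plain numeric matrix
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "target_id") <- NULL
  attr(y, "space") <- NULL
  y
}

#' Pairwise similarity between all participants
#'
#' Computes one similarity per unordered participant pair by vectorizing
#' each participant's pattern and comparing the vectors: Pearson
#' correlation, cosine similarity, or (for binary responses) Jaccard
#' similarity over positive responses after pairwise deletion of traits
#' missing for either member.
#'
#' Undefined values (a zero-variance vector under Pearson, or a pair with
#' no shared non-missing traits under Jaccard) are carried as `NA` with
#' `flagged = TRUE`, never silently zeroed; downstream model fits drop
#' flagged rows with a count. A Jaccard pair whose shared traits are all
#' zero for both members has an empty union: it is returned as 1 when the
#' two restricted vectors agree exactly (both all-zero), which is the
#' agreement-consistent limit.
#'
#' @param patterns a [pattern_matrix()].
#' @param metric `"pearson"`, `"cosine"` or `"jaccard"` (jaccard requires
#'   the `trait_binary` space).
#' @return a dyad table: `data.frame` with columns `participant1`,
#'   `participant2`, `target`, `similarity`, `flagged` and one row per
#'   unordered pair (`choose(n, 2)` rows).
#' @export
pairwise_similarity <- function(patterns, metric = c("pearson", "cosine", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(inherits(patterns, "pattern_matrix"))
  x <- as_plain_matrix(patterns)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 participants")
  if (metric == "jaccard" && !identical(attr(patterns, "space"), "trait_binary"))
    stop("jaccard requires a trait_binary pattern matrix")
  ids <- rownames(x)
  pr <- utils::combn(n, 2)
  sim <- numeric(ncol(pr))
  flagged <- logical(ncol(pr))
  if (metric %in% c("pearson", "cosine")) {
    if (metric == "pearson") {
      sds <- apply(x, 1, stats::sd)
      smat <- suppressWarnings(stats::cor(t(x)))
      bad <- sds == 0 | !is.finite(sds)
    } else {
      nrm <- sqrt(rowSums(x^2))
      bad <- nrm == 0 | !is.finite(nrm)
      xn <- x / ifelse(nrm == 0, 1, nrm)
      smat <- tcrossprod(xn)
    }
    sim <- pmin(1, pmax(-1, smat[cbind(pr[1, ], pr[2, ])]))
    flagged <- bad[pr[1, ]] | bad[pr[2, ]]
    sim[flagged] <- NA_real_
  } else {
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      jc <- jaccard_pair(x[i, ], x[j, ])
      sim[k] <- jc$value; flagged[k] <- jc$flagged
    }
  }
  out <- data.frame(participant1 = ids[pr[1, ]], participant2 = ids[pr[2, ]],
                    target = target_of(patterns), similarity = sim,
                    flagged = flagged, stringsAsFactors = FALSE)
  class(out) <- c("dyad_table", "data.frame")
  out
}

# Jaccard over positive responses with pairwise deletion of missing traits
jaccard_pair <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2) return(list(value = NA_real_, flagged = TRUE))
  a <- a[keep]; b <- b[keep]
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) {
    # empty union: both all-zero over shared traits -> full agreement
    return(list(value = 1, flagged = FALSE))
  }
  list(value = sum(a == 1 & b == 1) / uni, flagged = FALSE)
}

#' Combine per-target dyad tables
#'
#' @param dyad_list list of dyad tables (one per target), or an
#'   `ak_dataset` whose patterns are converted with `metric`.
#' @param metric similarity metric when `dyad_list` is an `ak_dataset`.
#' @return a single stacked dyad table.
#' @export
stack_dyads <- function(dyad_list, metric = "pearson") {
  if (inherits(dyad_list, "ak_dataset"))
    dyad_list <- lapply(dyad_list$patterns, pairwise_similarity, metric = metric)
  out <- do.call(rbind, dyad_list)
  rownames(out) <- NULL
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Convert similarity to distance
#'
#' Correlation distance / cosine distance: `1 - similarity`, with a
#' forced zero diagonal for matrix input.
#'
#' @param x a dyad table (column `similarity`) or a symmetric similarity
#'   matrix.
#' @return object of the same shape with distances; flagged/undefined
#'   similarities are an error for matrix input (they cannot be embedded).
#' @export
to_distance <- function(x) {
  if (is.matrix(x)) {
    if (any(is.na(x))) stop("undefined similarities cannot be converted to distances")
    if (!isSymmetric(unname(x), tol = 1e-8)) stop("similarity matrix must be symmetric")
    d <- 1 - x
    diag(d) <- 0
    return(d)
  }
  stopifnot(is.data.frame(x), "similarity" %in% names(x))
  x$distance <- 1 - x$similarity
  x
}

#' Dense similarity matrix from a single-target dyad table
#'
#' @param dyads dyad table for one target.
#' @param diag_value value for the diagonal (self-similarity), default 1.
#' @return symmetric n x n matrix with participant ids as dimnames.
#' @export
similarity_matrix <- function(dyads, diag_value = 1) {
  stopifnot(is.data.frame(dyads))
  if (length(unique(dyads$target)) > 1)
    stop("dyad table spans multiple targets; subset first")
  ids <- sort(unique(c(dyads$participant1, dyads$participant2)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- diag_value
  i <- match(dyads$participant1, ids)
  j <- match(dyads$participant2, ids)
  m[cbind(i, j)] <- dyads$similarity
  m[cbind(j, i)] <- dyads$similarity
  m
}

#' Similarity of each participant to a reference vector
#'
#' Correlates (or takes cosine similarity of) each participant's pattern
#' with a single reference pattern -- typically a group-consensus vector.
#' `point_biserial` is the Pearson correlation between a participant's
#' binary responses and a continuous reference (e.g. group-average
#' responses); missing entries are pairwise-deleted first.
#'
#' @param patterns a [pattern_matrix()].
#' @param reference numeric vector, length `ncol(patterns)`.
#' @param metric `"pearson"`, `"cosine"` or `"point_biserial"`.
#' @return `data.frame` with columns `participant`, `target`,
#'   `similarity`, `flagged`.
#' @export
similarity_to_reference <- function(patterns, reference,
                                    metric = c("pearson", "cosine", "point_biserial")) {
  metric <- match.arg(metric)
  stopifnot(inherits(patterns, "pattern_matrix"))
  x <- as_plain_matrix(patterns)
  if (length(reference) != ncol(x))
    stop("reference length must equal the number of features")
  n <- nrow(x)
  sim <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    v <- x[i, ]
    keep <- !is.na(v) & !is.na(reference)
    v <- v[keep]; r <- reference[keep]
    if (length(v) < 2) { sim[i] <- NA_real_; flagged[i] <- TRUE; next }
    if (metric == "cosine") {
      nv <- sqrt(sum(v^2)); nr <- sqrt(sum(r^2))
      if (nv == 0 || nr == 0) { sim[i] <- NA_real_; flagged[i] <- TRUE }
      else sim[i] <- sum(v * r) / (nv * nr)
    } else {
      # point-biserial is Pearson on the binary/continuous pair
      if (stats::sd(v) == 0 || stats::sd(r) == 0) {
        sim[i] <- NA_real_; flagged[i] <- TRUE
      } else sim[i] <- stats::cor(v, r)
    }
  }
  data.frame(participant = rownames(x), target = target_of(patterns),
             similarity = sim, flagged = flagged,
             reference_method = metric, stringsAsFactors = FALSE)
}

#' Attach the pair-mean of a participant variable (Anna Karenina predictor)
#'
#' The canonical Anna Karenina predictor models an individual trait at
#' the pair level as the pair mean, `(x_i + x_j) / 2`: if high scorers
#' are idiosyncratic -- unhappy each in their own way -- pairs with a
#' higher mean are less similar.
#'
#' @param meta `data.frame` with a `participant` column and the variable.
#' @param dyads a dyad table.
#' @param variable column name in `meta`.
#' @param new_name name for the new column, default `paste0("mean_", variable)`.
#' @return the dyad table with the pair-mean column added; pairs with a
#'   missing member value get `NA` and `flagged = TRUE`.
#' @export
mean_pair_predictor <- function(meta, dyads, variable,
                                new_name = paste0("mean_", variable)) {
  stopifnot("participant" %in% names(meta), variable %in% names(meta))
  v <- stats::setNames(meta[[variable]], meta$participant)
  x1 <- v[dyads$participant1]; x2 <- v[dyads$participant2]
  dyads[[new_name]] <- (as.numeric(x1) + as.numeric(x2)) / 2
  miss <- is.na(dyads[[new_name]])
  if ("flagged" %in% names(dyads)) dyads$flagged <- dyads$flagged | miss
  else dyads$flagged <- miss
  dyads
}

#' Build pair-level covariates from participant metadata
#'
#' Demographic and behavioral nuisance covariates at the pair level:
#'
#' * `match_vars` (e.g. gender, race): coded 1.0 when the two members
#'   match, 0.0 when they do not.
#' * `absdiff_vars` (e.g. age, word count, a single rating): the
#'   absolute within-pair difference, z-scored across all pairs, then
#'   sign-flipped so that larger values mean more similar.
#' * `euclidean_vars` (named list of column sets, e.g. ten trait
#'   ratings): the Euclidean distance between the two members' vectors,
#'   then z-scored and sign-flipped the same way.
#'
#' The dissimilarity-to-similarity conversion is a sign flip after
#' z-scoring (negation), so each covariate stays standardized.
#'
#' @param meta participant metadata with a `participant` column.
#' @param dyads a dyad table.
#' @param match_vars,absdiff_vars character vectors of column names.
#' @param euclidean_vars named list; each element a character vector of
#'   columns forming one rating vector.
#' @return the dyad table with covariate columns `<var>_match` and
#'   `<var>_sim`; rows with a missing member value are flagged.
#' @export
build_dyad_covariates <- function(meta, dyads, match_vars = character(),
                                  absdiff_vars = character(),
                                  euclidean_vars = list()) {
  stopifnot("participant" %in% names(meta))
  i1 <- match(dyads$participant1, meta$participant)
  i2 <- match(dyads$participant2, meta$participant)
  if (anyNA(i1) || anyNA(i2)) stop("dyad participants missing from meta")
  if (!"flagged" %in% names(dyads)) dyads$flagged <- FALSE
  for (v in match_vars) {
    a <- meta[[v]][i1]; b <- meta[[v]][i2]
    val <- as.numeric(as.character(a) == as.character(b))
    val[is.na(a) | is.na(b)] <- NA_real_
    dyads[[paste0(v, "_match")]] <- val
    dyads$flagged <- dyads$flagged | is.na(val)
  }
  for (v in absdiff_vars) {
    d <- abs(as.numeric(meta[[v]][i1]) - as.numeric(meta[[v]][i2]))
    dyads[[paste0(v, "_sim")]] <- -zscore(d)
    dyads$flagged <- dyads$flagged | is.na(d)
  }
  for (nm in names(euclidean_vars)) {
    cols <- euclidean_vars[[nm]]
    m1 <- as.matrix(meta[i1, cols, drop = FALSE])
    m2 <- as.matrix(meta[i2, cols, drop = FALSE])
    d <- sqrt(rowSums((m1 - m2)^2))
    dyads[[paste0(nm, "_sim")]] <- -zscore(d)
    dyads$flagged <- dyads$flagged | is.na(d)
  }
  dyads
}
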
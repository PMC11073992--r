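#' Locate the densest point of an MDS plane with a Gaussian kernel
#'
#' Evaluates a Gaussian kernel density over a regular grid spanning the
#' embedding's bounding box and returns the grid node with the highest
#' density of surrounding points,
#' \deqn{f(g) = \sum_i \exp(-\|g - x_i\|^2 / (2\,h^2)),}
#' where the kernel scale \eqn{h} is the distance between the maximum and
#' minimum value along either the x or y axis, whichever is smaller. A
#' kernel defined by a single length scale leaves "radius" ambiguous; here
#' it is taken as the Gaussian bandwidth \eqn{h}. Ties in the grid argmax
#' are broken at the lowest row-major node index (x varying fastest).
#'
#' If the points are collinear (one axis range is zero) the nonzero axis
#' range is used instead; if all points coincide, that point is returned
#' and the field is flagged degenerate.
#'
#' @param emb an [embed_mds()] result (or any list with a `coords`
#'   matrix).
#' @param grid_resolution nodes per axis (default 100).
#' @return a `density_field`: list with `grid_x`, `grid_y`, `bandwidth`,
#'   `densities` (resolution x resolution matrix, x indexing rows),
#'   `densest_point` (length-2), `degenerate`.
#' @export
densest_point <- function(emb, grid_resolution = 100L) {
  co <- if (is.matrix(emb)) emb else emb$coords
  stopifnot(is.matrix(co), ncol(co) == 2)
  rx <- range(co[, 1]); ry <- range(co[, 2])
  span <- c(diff(rx), diff(ry))
  if (all(span == 0)) {
    return(structure(list(grid_x = rx[1], grid_y = ry[1], bandwidth = NA_real_,
                          densities = matrix(nrow(co), 1, 1),
                          densest_point = co[1, ], degenerate = TRUE),
                     class = "density_field"))
  }
  bw <- if (any(span == 0)) max(span) else min(span)
  gx <- seq(rx[1], rx[2], length.out = grid_resolution)
  gy <- seq(ry[1], ry[2], length.out = grid_resolution)
  if (span[1] == 0) gx <- rx[1]
  if (span[2] == 0) gy <- ry[1]
  nodes <- as.matrix(expand.grid(x = gx, y = gy))  # x fastest: row-major order
  d2 <- outer(nodes[, 1], co[, 1], "-")^2 + outer(nodes[, 2], co[, 2], "-")^2
  dens <- rowSums(exp(-d2 / (2 * bw^2)))
  best <- which.max(dens)                           # first max = lowest index
  structure(list(grid_x = gx, grid_y = gy, bandwidth = bw,
                 densities = matrix(dens, length(gx), length(gy)),
                 densest_point = unname(nodes[best, ]), degenerate = FALSE),
            class = "density_field")
}

#' Proximity weights from distance to the densest point
#'
#' Each participant's Euclidean distance to the densest point is
#' subtracted from the largest such distance, recoding distance as
#' proximity and giving the furthest participant a weight of exactly
#' zero. When all distances are equal the subtraction would zero every
#' weight, so the weights fall back to uniform and are flagged.
#'
#' @param emb an [embed_mds()] result (or a coordinate matrix).
#' @param densest length-2 coordinate, e.g.
#'   `densest_point(emb)$densest_point`.
#' @return nonnegative numeric weight vector with attribute
#'   `fallback_uniform` (logical).
#' @export
proximity_weights <- function(emb, densest) {
  co <- if (is.matrix(emb)) emb else emb$coords
  stopifnot(all(is.finite(densest)), length(densest) == 2)
  d <- sqrt((co[, 1] - densest[1])^2 + (co[, 2] - densest[2])^2)
  from_distances(d)
}

# shared "highest minus each" proximity recoding with uniform fallback
from_distances <- function(d) {
  if (diff(range(d)) < 1e-12) {
    w <- rep(1, length(d))
    attr(w, "fallback_uniform") <- TRUE
    return(w)
  }
  w <- max(d) - d
  attr(w, "fallback_uniform") <- FALSE
  w
}

#' Alternative consensus weighting schemes
#'
#' Two simpler weightings used as robustness checks against the
#' kernel-density scheme: `"unweighted"` gives every participant the
#' same weight; `"distance_weighted"` weights each participant by
#' proximity in the original (correlation or cosine) distance space,
#' `max_j mean-dist_j - mean-dist_i`, where `mean-dist_i` is participant
#' i's average distance to all others.
#'
#' @param distances symmetric distance matrix.
#' @param method `"unweighted"` or `"distance_weighted"`.
#' @return nonnegative weight vector (attribute `fallback_uniform` set
#'   for the distance-weighted scheme when all mean distances tie).
#' @export
alt_weights <- function(distances, method = c("unweighted", "distance_weighted")) {
  method <- match.arg(method)
  d <- as.matrix(distances)
  n <- nrow(d)
  if (method == "unweighted") {
    w <- rep(1, n)
    attr(w, "fallback_uniform") <- FALSE
    return(w)
  }
  dbar <- rowSums(d) / (n - 1)
  from_distances(dbar)
}

#' Weighted group-consensus feature vector
#'
#' The consensus representation of a target is the weighted mean across
#' participants of their z-scored pattern: each participant's pattern is
#' first z-scored across its own features (so every participant
#' contributes shape, not amplitude), then averaged feature-wise with
#' the supplied weights.
#'
#' @param patterns a [pattern_matrix()].
#' @param weights nonnegative vector, one per participant, positive sum.
#' @param method label recorded on the result (`"kernel_weighted"`,
#'   `"unweighted"`, `"distance_weighted"`).
#' @param zscore_rows z-score each participant's pattern across features
#'   first (default TRUE); rows with zero variance are excluded with a
#'   message and a recorded count.
#' @return a `consensus_vector`: list with `target_id`, `method`,
#'   `weights` (as used, excluded rows zeroed), `vector` (length
#'   n_features), `n_excluded`.
#' @export
consensus_vector <- function(patterns, weights,
                             method = c("kernel_weighted", "unweighted", "distance_weighted"),
                             zscore_rows = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(patterns, "pattern_matrix"))
  x <- as_plain_matrix(patterns)
  if (length(weights) != nrow(x))
    stop("weights length must equal the number of participants")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  n_excluded <- 0L
  if (zscore_rows) {
    sds <- apply(x, 1, stats::sd)
    bad <- !is.finite(sds) | sds == 0
    if (any(bad)) {
      n_excluded <- sum(bad)
      message(sprintf("excluding %d zero-variance pattern row(s) from the consensus", n_excluded))
      weights[bad] <- 0
      if (sum(weights) <= 0) stop("all positively weighted rows have zero variance")
    }
    x <- t(apply(x, 1, zscore))
  }
  v <- colSums(x * weights) / sum(weights)
  structure(list(target_id = target_of(patterns), method = method,
                 weights = as.numeric(weights), vector = as.numeric(v),
                 n_excluded = n_excluded),
            class = "consensus_vector")
}

#' Estimate a target's group-consensus representation end to end
#'
#' Chains the full consensus procedure for one target: pairwise
#' similarity, correlation/cosine distance, 2-D stress-minimizing MDS,
#' Gaussian-kernel densest point, proximity weights, weighted mean of
#' z-scored patterns, and finally each participant's similarity to the
#' consensus vector. The `"unweighted"` and `"distance_weighted"`
#' methods skip the embedding and use [alt_weights()].
#'
#' @param patterns a [pattern_matrix()] for one target.
#' @param method consensus weighting scheme.
#' @param metric similarity metric for both the pairwise distances and
#'   the final similarity-to-consensus (`"pearson"` for neural patterns,
#'   `"cosine"` for embeddings).
#' @param grid_resolution,n_init,max_iter,seed passed to
#'   [densest_point()] and [embed_mds()].
#' @return list with `consensus` ([consensus_vector()]), `similarity`
#'   (the per-participant reference-similarity table), and, for the
#'   kernel method, `embedding` and `field`.
#' @export
group_consensus <- function(patterns,
                            method = c("kernel_weighted", "unweighted", "distance_weighted"),
                            metric = c("pearson", "cosine"),
                            grid_resolution = 100L, n_init = 4L,
                            max_iter = 3000L, seed = 1L) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  dy <- pairwise_similarity(patterns, metric = metric)
  if (any(dy$flagged)) {
    message(sprintf("dropping %d flagged pair(s) undefined under %s",
                    sum(dy$flagged), metric))
  }
  smat <- similarity_matrix(dy)
  if (any(is.na(smat)))
    stop("undefined pairwise similarities: cannot build the distance matrix")
  dmat <- to_distance(smat)
  emb <- NULL; field <- NULL
  if (method == "kernel_weighted") {
    emb <- embed_mds(dmat, n_init = n_init, max_iter = max_iter, seed = seed)
    field <- densest_point(emb, grid_resolution = grid_resolution)
    w <- proximity_weights(emb, field$densest_point)
  } else {
    w <- alt_weights(dmat, method)
  }
  cons <- consensus_vector(patterns, w, method = method)
  sim <- similarity_to_reference(patterns, cons$vector,
                                 metric = if (metric == "cosine") "cosine" else "pearson")
  list(consensus = cons, similarity = sim, embedding = emb, field = field,
       weights = w)
}

#' Similarity-to-consensus table across all targets of a dataset
#'
#' Runs [group_consensus()] on every target and stacks the
#' per-participant similarity tables, attaching the participant trait
#' (loneliness) scores ready for model fitting.
#'
#' @param dataset an `ak_dataset` (or named list of pattern matrices).
#' @param loneliness numeric vector per participant (taken from the
#'   dataset when omitted).
#' @inheritParams group_consensus
#' @return `data.frame` with columns `participant`, `target`,
#'   `similarity`, `flagged`, `loneliness`.
#' @export
consensus_similarity_table <- function(dataset, method = "kernel_weighted",
                                       metric = "pearson", loneliness = NULL,
                                       grid_resolution = 100L, n_init = 4L,
                                       max_iter = 3000L, seed = 1L) {
  patterns <- if (inherits(dataset, "ak_dataset")) dataset$patterns else dataset
  if (is.null(loneliness) && inherits(dataset, "ak_dataset"))
    loneliness <- dataset$loneliness
  out <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    gc <- group_consensus(patterns[[i]], method = method, metric = metric,
                          grid_resolution = grid_resolution, n_init = n_init,
                          max_iter = max_iter, seed = sub_seed(seed, i))
    gc$similarity
  }))
  rownames(out) <- NULL
  if (!is.null(loneliness)) {
    ids <- rownames(patterns[[1]])
    out$loneliness <- loneliness[match(out$participant, ids)]
  }
  out
}
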
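#' Metric multidimensional scaling by stress majorization
#'
#' Projects participants into two dimensions so that Euclidean plane
#' distances approximate the supplied (correlation or cosine) distances,
#' by minimizing raw stress \eqn{\sigma(X)=\sum_{i<j}(d_{ij}(X)-\delta_{ij})^2}
#' with the SMACOF/Guttman-transform update. The run is repeated from
#' `n_init` starting configurations (the first is the classical-scaling
#' solution, the rest are random) and the lowest-stress solution is kept.
#'
#' @param distances symmetric nonnegative matrix with zero diagonal,
#'   n >= 3.
#' @param n_init number of initializations (default 4).
#' @param max_iter iteration cap per run (default 3000).
#' @param seed integer seed for the random starts.
#' @param eps relative stress-decrease convergence tolerance (default
#'   `1e-6`; iterations also stop at `max_iter`).
#' @return an `mds_embedding`: list with `coords` (n x 2),
#'   `participant_ids`, `stress` (normalized: raw stress divided by the
#'   sum of squared dissimilarities), `n_init`, `max_iter`, `seed`.
#' @export
embed_mds <- function(distances, n_init = 4L, max_iter = 3000L, seed = 1L,
                      eps = 1e-6) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 points")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < -1e-12)) stop("distances must be nonnegative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  ids <- rownames(d) %||% sprintf("P%02d", seq_len(n))
  ss <- sum(d^2) / 2
  if (ss == 0) {
    # all distances zero: every point at the origin, perfect fit
    coords <- matrix(0, n, 2, dimnames = list(ids, c("x", "y")))
    return(structure(list(coords = coords, participant_ids = ids, stress = 0,
                          n_init = n_init, max_iter = max_iter, seed = seed),
                     class = "mds_embedding"))
  }
  set.seed(seed)
  scale0 <- sqrt(mean(d[upper.tri(d)]^2))
  best <- NULL
  for (run in seq_len(n_init)) {
    x0 <- if (run == 1) {
      cm <- suppressWarnings(stats::cmdscale(d, k = 2))
      if (ncol(cm) < 2) cbind(cm, 0)[, 1:2, drop = FALSE] else cm
    } else {
      matrix(stats::rnorm(n * 2, 0, scale0), n, 2)
    }
    res <- smacof_run(d, x0, max_iter, eps)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  coords <- best$coords
  dimnames(coords) <- list(ids, c("x", "y"))
  structure(list(coords = coords, participant_ids = ids,
                 stress = best$stress / (2 * ss),  # normalized to [0, 1]
                 raw_stress = best$stress,
                 n_init = n_init, max_iter = max_iter, seed = seed),
            class = "mds_embedding")
}

# one majorization run (C++ inner loop); returns coords and raw stress
# (sum over ordered pairs)
smacof_run <- function(delta, x, max_iter, eps) {
  res <- .smacof_engine(delta, x, as.integer(max_iter), eps)
  list(coords = res$coords, stress = res$stress)
}

#' Plot an MDS embedding, optionally colored by a participant score
#'
#' @param x an `mds_embedding`.
#' @param color optional numeric vector per participant (e.g. loneliness)
#'   mapped to a blue-to-red gradient.
#' @param densest optional length-2 coordinate marked with a star.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mds_embedding <- function(x, color = NULL, densest = NULL, ...) {
  co <- x$coords
  col <- "grey30"
  if (!is.null(color)) {
    rank01 <- (rank(color) - 1) / max(1, length(color) - 1)
    col <- grDevices::rgb(rank01, 0.2, 1 - rank01)
  }
  graphics::plot(co[, 1], co[, 2], pch = 19, col = col,
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  if (!is.null(densest))
    graphics::points(densest[1], densest[2], pch = 8, cex = 2, lwd = 2,
                     col = "darkgreen")
  invisible(x)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points, normalized stress %.4g\n",
              nrow(x$coords), x$stress))
  invisible(x)
}
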
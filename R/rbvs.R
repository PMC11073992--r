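#' Voxelwise split-half reliability map
#'
#' At every voxel, each participant's vector of condition parameter
#' estimates from one half of the data (odd runs) is correlated with the
#' corresponding vector from the other half (even runs); the
#' per-participant maps are then averaged into a single group map.
#' Participants whose condition vector has zero variance at a voxel are
#' excluded from that voxel's group mean, with a recorded count.
#'
#' @param data a `splithalf_data` object (see
#'   [generate_splithalf_volumes()]), or a list with `half1`/`half2`
#'   lists of condition-by-voxel matrices and a `dim` vector.
#' @return a `reliability_map`: list with `values` (3-D array of group
#'   mean correlations in \[-1, 1\]), `n_undefined` (count of excluded
#'   participant-voxel cells).
#' @export
voxelwise_reliability_map <- function(data) {
  stopifnot(length(data$half1) == length(data$half2), length(data$half1) >= 1)
  nc <- nrow(data$half1[[1]])
  if (nc < 3) stop("need at least 3 conditions")
  nv <- ncol(data$half1[[1]])
  acc <- numeric(nv)
  cnt <- integer(nv)
  n_undef <- 0L
  for (i in seq_along(data$half1)) {
    a <- data$half1[[i]]; b <- data$half2[[i]]
    stopifnot(dim(a) == c(nc, nv), dim(b) == c(nc, nv))
    r <- colwise_cor(a, b)
    ok <- is.finite(r)
    n_undef <- n_undef + sum(!ok)
    acc[ok] <- acc[ok] + r[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  vals <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  if (n_undef > 0)
    message(sprintf("%d participant-voxel reliability value(s) undefined (zero variance), excluded", n_undef))
  structure(list(values = array(vals, dim = data$dim), n_undefined = n_undef),
            class = "reliability_map")
}

# column-wise Pearson correlation between two matrices (over rows)
colwise_cor <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# 6- or 26-neighbour offsets for 3-D connectivity
neighbour_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

#' Grow a contiguous suprathreshold cluster around a peak voxel
#'
#' Returns the connected component of voxels exceeding `threshold` that
#' contains the peak voxel (breadth-first flood fill, 6-neighbour face
#' connectivity by default, 26-neighbour optional). A peak at or below
#' the threshold yields an empty, flagged mask.
#'
#' @param map a `reliability_map` or 3-D numeric array.
#' @param threshold voxels must exceed this value (strict).
#' @param peak integer length-3 voxel coordinate.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return logical 3-D array; attribute `flagged_empty` is TRUE when
#'   the peak itself failed the threshold.
#' @export
grow_cluster_roi <- function(map, threshold, peak, connectivity = 6L) {
  vals <- if (inherits(map, "reliability_map")) map$values else map
  stopifnot(length(dim(vals)) == 3, length(peak) == 3)
  dm <- dim(vals)
  if (any(peak < 1 | peak > dm)) stop("peak outside the volume")
  mask <- array(FALSE, dm)
  supra <- !is.na(vals) & vals > threshold
  if (!supra[peak[1], peak[2], peak[3]]) {
    attr(mask, "flagged_empty") <- TRUE
    return(mask)
  }
  offs <- neighbour_offsets(connectivity)
  queue <- matrix(peak, 1, 3)
  mask[peak[1], peak[2], peak[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      nb <- cur + offs[k, ]
      if (any(nb < 1 | nb > dm)) next
      if (supra[nb[1], nb[2], nb[3]] && !mask[nb[1], nb[2], nb[3]]) {
        mask[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  attr(mask, "flagged_empty") <- FALSE
  mask
}

#' Multivoxel pattern reliability of a mask
#'
#' For one participant and one condition, the multivoxel pattern across
#' the mask's voxels in one half of the data is correlated with the
#' corresponding pattern in the other half; the correlation is averaged
#' across conditions, then across participants.
#'
#' @param data a `splithalf_data` object.
#' @param mask logical 3-D array (or integer voxel indices).
#' @param min_voxels masks smaller than this return `NA` (default 2;
#'   a typical working floor is the size of a small searchlight, 33).
#' @return scalar group-mean pattern reliability, or `NA`.
#' @export
pattern_reliability <- function(data, mask, min_voxels = 2L) {
  idx <- if (is.logical(mask) || is.array(mask)) which(mask) else as.integer(mask)
  if (length(idx) < min_voxels) return(NA_real_)
  per_part <- vapply(seq_along(data$half1), function(i) {
    a <- data$half1[[i]][, idx, drop = FALSE]
    b <- data$half2[[i]][, idx, drop = FALSE]
    r <- colwise_cor(t(a), t(b))   # one correlation per condition
    mean(r, na.rm = TRUE)
  }, numeric(1))
  mean(per_part, na.rm = TRUE)
}

#' Pattern-reliability curves over a threshold grid
#'
#' For each region's peak, grows the peak-anchored cluster at every
#' threshold and evaluates its multivoxel pattern reliability, yielding
#' one curve per region. Masks that fall below `min_voxels` produce
#' `NA` (the curve is truncated) with a note.
#'
#' @param data a `splithalf_data` object.
#' @param map a `reliability_map` (computed from `data` when NULL).
#' @param peaks named list of integer length-3 peak coordinates, one
#'   per region.
#' @param thresholds numeric vector of voxelwise-reliability thresholds.
#' @param connectivity passed to [grow_cluster_roi()].
#' @param min_voxels minimum mask size for a valid curve point.
#' @return an `rbvs_curves` object: list with `thresholds`, `curves`
#'   (regions x thresholds matrix), `masks` (list of lists of masks),
#'   `sizes` (voxel counts matrix).
#' @export
pattern_reliability_curve <- function(data, peaks, thresholds, map = NULL,
                                      connectivity = 6L, min_voxels = 2L) {
  if (is.null(map)) map <- voxelwise_reliability_map(data)
  stopifnot(length(thresholds) >= 1, length(peaks) >= 1)
  if (is.null(names(peaks))) names(peaks) <- sprintf("roi%d", seq_along(peaks))
  curves <- matrix(NA_real_, length(peaks), length(thresholds),
                   dimnames = list(names(peaks), NULL))
  sizes <- matrix(0L, length(peaks), length(thresholds),
                  dimnames = list(names(peaks), NULL))
  masks <- lapply(peaks, function(p) vector("list", length(thresholds)))
  for (r in seq_along(peaks)) {
    for (k in seq_along(thresholds)) {
      msk <- grow_cluster_roi(map, thresholds[k], peaks[[r]], connectivity)
      masks[[r]][[k]] <- msk
      sizes[r, k] <- sum(msk)
      curves[r, k] <- pattern_reliability(data, msk, min_voxels = min_voxels)
    }
  }
  structure(list(thresholds = thresholds, curves = curves, masks = masks,
                 sizes = sizes, peaks = peaks, min_voxels = min_voxels),
            class = "rbvs_curves")
}

#' Select the reliability threshold balancing all regions
#'
#' Pattern reliability is z-scored within each region across the
#' examined thresholds (a region with zero variance contributes a flat
#' zero curve, with a note), the z-scored curves are averaged across
#' regions, and the threshold with the maximum average is selected.
#' Ties are broken toward the lower threshold (the larger region).
#'
#' @param curves an `rbvs_curves` object (or a regions x thresholds
#'   matrix plus `thresholds`).
#' @param thresholds required when `curves` is a bare matrix.
#' @return list with `threshold` (selected value), `index`, `z_curve`
#'   (average z-scored curve), `notes`, and -- when masks are available
#'   -- `masks` (final per-region masks at the selected threshold) and
#'   `sizes`.
#' @export
select_threshold <- function(curves, thresholds = NULL) {
  if (inherits(curves, "rbvs_curves")) {
    mat <- curves$curves
    thresholds <- curves$thresholds
    obj <- curves
  } else {
    mat <- as.matrix(curves)
    if (is.null(thresholds)) stop("thresholds required with a bare matrix")
    obj <- NULL
  }
  valid <- colSums(!is.na(mat)) == nrow(mat)
  if (sum(valid) < 2) stop("need >= 2 thresholds with valid curves in every region")
  notes <- character()
  zmat <- t(apply(mat[, valid, drop = FALSE], 1, function(row) {
    if (stats::sd(row) == 0) {
      notes <<- c(notes, "zero-variance region curve set to z = 0")
      rep(0, length(row))
    } else zscore(row)
  }))
  avg <- colMeans(zmat)
  idx_valid <- which(valid)
  best <- idx_valid[which.max(avg)]   # which.max: first max = lower threshold
  out <- list(threshold = thresholds[best], index = best,
              z_curve = stats::setNames(avg, thresholds[valid]), notes = notes)
  if (!is.null(obj)) {
    out$masks <- lapply(obj$masks, function(mm) mm[[best]])
    out$sizes <- obj$sizes[, best]
  }
  out
}

#' Reliability-based voxel selection, end to end
#'
#' Computes the voxelwise reliability map, finds each region's peak
#' (the map's maximum within the supplied anatomical search region),
#' grows peak-anchored clusters across the threshold grid, evaluates
#' multivoxel pattern-reliability curves, and picks the threshold with
#' the maximum average z-scored reliability across regions.
#'
#' @param data a `splithalf_data` object.
#' @param region_masks named list of logical 3-D arrays delimiting the
#'   anatomical search region for each ROI's peak.
#' @param range length-2 numeric, threshold range examined.
#' @param step grid step (default 0.002).
#' @param connectivity,min_voxels passed through.
#' @return an `rbvs_result`: list with `map`, `curves`, `selected`
#'   (threshold), `masks`, `sizes`, `peaks`, `thresholds`.
#' @export
rbvs <- function(data, region_masks, range = c(0.16, 0.42), step = 0.002,
                 connectivity = 6L, min_voxels = 2L) {
  map <- voxelwise_reliability_map(data)
  thresholds <- seq(range[1], range[2], by = step)
  peaks <- lapply(region_masks, function(rm) {
    vals <- map$values
    vals[!rm] <- -Inf
    arrayInd(which.max(vals), dim(vals))[1, ]
  })
  cv <- pattern_reliability_curve(data, peaks, thresholds, map = map,
                                  connectivity = connectivity,
                                  min_voxels = min_voxels)
  # drop thresholds where any region's curve is undefined (mask too small)
  sel <- select_threshold(cv)
  structure(list(map = map, curves = cv, selected = sel$threshold,
                 masks = sel$masks, sizes = sel$sizes, peaks = peaks,
                 thresholds = thresholds, z_curve = sel$z_curve,
                 notes = sel$notes),
            class = "rbvs_result")
}
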
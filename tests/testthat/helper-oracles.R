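# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package implementations.

oracle_cor_matrix <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- x[i, ]; b <- x[j, ]
    am <- a - sum(a) / length(a); bm <- b - sum(b) / length(b)
    out[i, j] <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  out
}

oracle_jaccard <- function(a, b) {
  keep <- which(!is.na(a) & !is.na(b))
  ia <- keep[a[keep] == 1]
  ib <- keep[b[keep] == 1]
  uni <- union(ia, ib)
  if (length(uni) == 0) return(1)
  length(intersect(ia, ib)) / length(uni)
}

oracle_weighted_consensus <- function(x, w) {
  zs <- x
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    zs[i, ] <- (r - mean(r)) / sd(r)
  }
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) out[j] <- sum(zs[, j] * w) / sum(w)
  out
}

# stack-based flood fill over a 3-D logical suprathreshold array
oracle_flood <- function(vals, threshold, peak, connectivity = 6L) {
  dm <- dim(vals)
  supra <- !is.na(vals) & vals > threshold
  mask <- array(FALSE, dm)
  if (!supra[peak[1], peak[2], peak[3]]) return(mask)
  offs <- if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  stack <- list(peak)
  mask[peak[1], peak[2], peak[3]] <- TRUE
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in offs) {
      nb <- cur + o
      if (any(nb < 1) || any(nb > dm)) next
      if (supra[nb[1], nb[2], nb[3]] && !mask[nb[1], nb[2], nb[3]]) {
        mask[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1]] <- nb
      }
    }
  }
  mask
}

# brute-force kernel density argmax on an arbitrary-resolution grid
oracle_density_argmax <- function(coords, resolution) {
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  bw <- min(diff(rx), diff(ry))
  gx <- seq(rx[1], rx[2], length.out = resolution)
  gy <- seq(ry[1], ry[2], length.out = resolution)
  best <- NULL; best_d <- -Inf
  for (yi in gy) for (xi in gx) {
    d <- 0
    for (i in seq_len(nrow(coords)))
      d <- d + exp(-((xi - coords[i, 1])^2 + (yi - coords[i, 2])^2) / (2 * bw^2))
    if (d > best_d) { best_d <- d; best <- c(xi, yi) }
  }
  best
}

# quick toy dyad table: n participants, one target, given similarities
toy_dyads <- function(sims, target = "T01", ids = NULL) {
  n <- (1 + sqrt(1 + 8 * length(sims))) / 2
  stopifnot(n == round(n))
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  pr <- t(combn(n, 2))
  data.frame(participant1 = ids[pr[, 1]], participant2 = ids[pr[, 2]],
             target = target, similarity = sims, flagged = FALSE,
             stringsAsFactors = FALSE)
}
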
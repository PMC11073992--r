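#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generative model into one validated object.
#' The generator plants the statistical structure the downstream analyses
#' assume: a per-target prototype pattern shared across participants, and
#' participant-specific Gaussian noise whose standard deviation grows
#' linearly with standardized loneliness (the "Anna Karenina" structure,
#' under which lonelier individuals are dissimilar both to each other and
#' to everyone else).
#'
#' Loneliness scores emulate the Revised UCLA Loneliness Scale: draws from
#' a normal with `loneliness_mean`/`loneliness_sd`, truncated by rejection
#' sampling to `loneliness_bounds` (the 20-item scale's 20--80 score range).
#' Defaults follow a published in-person sample (mean 40.73, sd 8.32).
#'
#' Under `scenario = "ak"`, participant i's pattern for target t is
#' \deqn{x_{it} = \mu_t + \sigma(l_i)\,\varepsilon,\qquad
#'       \sigma(l_i) = \sigma_0 + \beta\, z(l_i),}
#' with prototype features \eqn{\mu_t \sim N(0, \code{prototype_sd}^2)},
#' \eqn{\sigma_0 = } `base_noise_sd`, \eqn{\beta = } `idiosyncrasy_slope`
#' (noise-sd units per standardized loneliness unit), and \eqn{z(l)}
#' standardized against the realized sample. `scenario = "null"` forces
#' \eqn{\beta = 0}. Scenarios `"cluster"` and `"ring"` plant the two
#' dissociation patterns (see [generate_dissociation_scenario()]).
#'
#' The default `idiosyncrasy_slope = 0.032` was calibrated by simulation
#' to plant a standardized pairwise Anna Karenina effect of about -0.2
#' under the other defaults (n = 40, 5 targets, 200 features); a slope of
#' 0.024 plants about -0.15. Pairwise correlations are very precise at
#' 200 features, so even small slopes produce large standardized pairwise
#' effects.
#'
#' @param n_participants number of participants (>= 3).
#' @param n_features number of pattern features (voxels or embedding
#'   dimensions; >= 2).
#' @param n_targets number of targets (celebrities).
#' @param loneliness_mean,loneliness_sd mean and sd of the untruncated
#'   loneliness distribution, in UCLA scale units.
#' @param loneliness_bounds length-2 numeric, truncation bounds.
#' @param prototype_sd sd of prototype features (feature units).
#' @param base_noise_sd baseline participant noise sd (feature units).
#' @param idiosyncrasy_slope increase in noise sd per standardized
#'   loneliness unit; must be 0 when `scenario = "null"`.
#' @param scenario one of `"ak"`, `"null"`, `"cluster"`, `"ring"`.
#' @param missing_rate proportion of missing entries for binary trait
#'   responses, in \[0, 1\].
#' @param seed integer seed; every generator draw is deterministic given it.
#' @return an object of class `ak_config` (a validated list).
#' @seealso [generate_patterns()], [generate_dissociation_scenario()]
#' @export
synthetic_config <- function(n_participants = 40L,
                             n_features = 200L,
                             n_targets = 5L,
                             loneliness_mean = 40.73,
                             loneliness_sd = 8.32,
                             loneliness_bounds = c(20, 80),
                             prototype_sd = 1,
                             base_noise_sd = 1,
                             idiosyncrasy_slope = switch(scenario, ak = 0.032,
                                                         ring = 0.008, 0),
                             scenario = c("ak", "null", "cluster", "ring"),
                             missing_rate = 0,
                             seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_participants < 3) stop("n_participants must be >= 3")
  if (n_features < 2) stop("n_features must be >= 2")
  if (base_noise_sd < 0) stop("base_noise_sd must be >= 0")
  if (prototype_sd < 0) stop("prototype_sd must be >= 0")
  if (length(loneliness_bounds) != 2 ||
      !(loneliness_bounds[1] < loneliness_bounds[2]))
    stop("loneliness_bounds must satisfy min < max")
  if (loneliness_sd <= 0) stop("loneliness_sd must be > 0")
  if (idiosyncrasy_slope < 0) stop("idiosyncrasy_slope must be >= 0")
  if (scenario == "null" && idiosyncrasy_slope != 0)
    stop("scenario = \"null\" requires idiosyncrasy_slope = 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  structure(list(
    n_participants = as.integer(n_participants),
    n_features = as.integer(n_features),
    n_targets = as.integer(n_targets),
    loneliness_mean = loneliness_mean,
    loneliness_sd = loneliness_sd,
    loneliness_bounds = as.numeric(loneliness_bounds),
    prototype_sd = prototype_sd,
    base_noise_sd = base_noise_sd,
    idiosyncrasy_slope = idiosyncrasy_slope,
    scenario = scenario,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "ak_config")
}

#' Sample truncated-normal loneliness scores
#'
#' Draws `n_participants` scores from
#' N(`loneliness_mean`, `loneliness_sd`^2) truncated to
#' `loneliness_bounds` by rejection sampling (which preserves the normal
#' shape near the bounds).
#'
#' @param cfg an [synthetic_config()] object.
#' @return numeric vector of length `n_participants`.
#' @export
sample_loneliness <- function(cfg) {
  stopifnot(inherits(cfg, "ak_config"))
  set.seed(cfg$seed)
  sample_loneliness_impl(cfg$n_participants, cfg$loneliness_mean,
                         cfg$loneliness_sd, cfg$loneliness_bounds)
}

# rejection sampler used both standalone and inside the dataset generators
# (which manage the RNG stream themselves)
sample_loneliness_impl <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= bounds[1] & draw <= bounds[2]])
  }
  out[seq_len(n)]
}

new_ak_dataset <- function(patterns, loneliness, truth, trait_responses = NULL) {
  structure(list(patterns = patterns, loneliness = loneliness,
                 trait_responses = trait_responses, truth = truth),
            class = "ak_dataset")
}

#' @export
print.ak_dataset <- function(x, ...) {
  cat(sprintf("<ak_dataset> %d participants x %d features, %d target(s), scenario \"%s\"\n",
              length(x$loneliness), ncol(x$patterns[[1]]),
              length(x$patterns), x$truth$config$scenario))
  invisible(x)
}

#' Generate synthetic pattern matrices with Anna Karenina structure
#'
#' Produces one participants-by-features [pattern_matrix()] per target
#' under the additive prototype-plus-noise model described in
#' [synthetic_config()]. The per-participant noise sd
#' \eqn{\sigma(l_i) = \sigma_0 + \beta z(l_i)} is floored at zero (with a
#' warning when the floor binds), and \eqn{z(l)} uses the realized sample
#' mean and sd, mirroring the analysis-side z-scoring.
#'
#' @param cfg an [synthetic_config()] object with scenario `"ak"` or
#'   `"null"`.
#' @return an `ak_dataset`: list with `patterns` (list of pattern
#'   matrices), `loneliness`, and `truth` (the config plus the realized
#'   per-participant noise sds).
#' @export
generate_patterns <- function(cfg) {
  stopifnot(inherits(cfg, "ak_config"))
  if (!cfg$scenario %in% c("ak", "null"))
    stop("generate_patterns requires scenario \"ak\" or \"null\"; see generate_dissociation_scenario()")
  if (cfg$prototype_sd == 0)
    stop("prototype_sd = 0 yields an all-zero prototype")
  set.seed(cfg$seed)
  n <- cfg$n_participants
  p <- cfg$n_features
  lon <- sample_loneliness_impl(n, cfg$loneliness_mean, cfg$loneliness_sd,
                                cfg$loneliness_bounds)
  zl <- zscore(lon)
  sigma <- cfg$base_noise_sd + cfg$idiosyncrasy_slope * zl
  if (any(sigma < 0)) {
    warning(sprintf("%d participant noise sd(s) below 0 floored at 0",
                    sum(sigma < 0)))
    sigma <- pmax(sigma, 0)
  }
  ids <- sprintf("P%02d", seq_len(n))
  patterns <- lapply(seq_len(cfg$n_targets), function(t) {
    proto <- stats::rnorm(p, 0, cfg$prototype_sd)
    vals <- matrix(proto, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p), n, p) * sigma
    pattern_matrix(vals, participant_ids = ids,
                   target_id = sprintf("T%02d", t), space = "neural")
  })
  names(patterns) <- vapply(patterns, attr, "", "target_id")
  new_ak_dataset(patterns, lon,
                 truth = list(config = cfg, sigma = sigma, z_loneliness = zl))
}

#' Generate the two consensus/Anna-Karenina dissociation scenarios
#'
#' The Anna Karenina (pairwise) model and the similarity-to-consensus
#' model answer different questions and can disagree. This generator
#' plants each direction of disagreement with an explicit construction
#' (both are synthetic stand-ins, designed for their stated effect
#' pattern, not reconstructions of any particular published simulation):
#'
#' * `scenario = "cluster"`: the high-loneliness participants (top ~30%
#'   of scores) form a secondary cluster displaced from the main mass by
#'   a shared offset. Lonely pairs are at least as similar to each other
#'   as the average pair (no negative pairwise effect), yet every lonely
#'   participant sits far from the consensus: a consensus effect without
#'   an Anna Karenina effect.
#' * `scenario = "ring"`: the high-loneliness participants (top ~25%)
#'   are placed at mutually spread directions -- mean-centred, hence
#'   negatively correlated, deviations -- at a radius matched to the
#'   expected distance an independent noise draw of the same magnitude
#'   would produce, with a correction so that their expected overlap
#'   with the consensus equals a non-lonely participant's. On top of the
#'   shell geometry a weak global idiosyncrasy gradient
#'   (`idiosyncrasy_slope`, default 0.008) is applied to everyone. Every
#'   participant is then essentially as close to the consensus as any
#'   other -- the consensus regression, with only n observations per
#'   target, has almost nothing it can detect -- while lonely pairs are
#'   especially dissimilar to one another and the pairwise model, with
#'   its thousands of dyads, reliably detects the weak gradient: an Anna
#'   Karenina effect without a consensus effect.
#'
#' @param cfg an [synthetic_config()] object with scenario `"cluster"` or
#'   `"ring"`; needs `n_participants >= 6` to form both groups.
#' @param displacement_sd sd of the shared offset's features (cluster
#'   scenario), in feature units.
#' @return an `ak_dataset`; `truth$lonely` flags the planted
#'   high-loneliness group and `truth$planted` names the planted effect.
#' @export
generate_dissociation_scenario <- function(cfg, displacement_sd = 1) {
  stopifnot(inherits(cfg, "ak_config"))
  if (!cfg$scenario %in% c("cluster", "ring"))
    stop("scenario must be \"cluster\" or \"ring\"")
  if (cfg$n_participants < 6)
    stop("need n_participants >= 6 to form both loneliness groups")
  set.seed(cfg$seed)
  n <- cfg$n_participants
  p <- cfg$n_features
  lon <- sample_loneliness_impl(n, cfg$loneliness_mean, cfg$loneliness_sd,
                                cfg$loneliness_bounds)
  frac <- if (cfg$scenario == "cluster") 0.3 else 0.25
  k <- max(2L, round(frac * n))
  # top-k by loneliness; ties broken by index so grouping is deterministic
  lonely <- rank(-lon, ties.method = "first") <= k
  if (stats::sd(lon) == 0) lonely <- rep(FALSE, n)  # degenerate: one cluster
  s0 <- cfg$base_noise_sd
  ids <- sprintf("P%02d", seq_len(n))
  zl <- zscore(lon)
  # ring: weak global idiosyncrasy gradient on top of the shell geometry
  sigma <- if (cfg$scenario == "ring") {
    pmax(s0 + cfg$idiosyncrasy_slope * zl, 0)
  } else rep(s0, n)
  # mean of a chi distribution with p df: expected distance ||sigma*eps||
  mean_chi <- sqrt(2) * exp(lgamma((p + 1) / 2) - lgamma(p / 2))
  patterns <- lapply(seq_len(cfg$n_targets), function(t) {
    proto <- stats::rnorm(p, 0, cfg$prototype_sd)
    noise <- matrix(stats::rnorm(n * p), n, p) * sigma
    vals <- matrix(proto, n, p, byrow = TRUE) + noise
    if (any(lonely)) {
      k <- sum(lonely)
      if (cfg$scenario == "cluster") {
        offset <- stats::rnorm(p, 0, displacement_sd)
        vals[lonely, ] <- sweep(vals[lonely, , drop = FALSE], 2, offset, "+")
      } else {
        # radius each lonely deviation would have had as an independent
        # draw of their own noise magnitude
        r <- sigma[lonely] * mean_chi
        dev <- matrix(stats::rnorm(k * p), k, p)
        dev <- sweep(dev, 2, colMeans(dev))       # mutually repelled directions
        dev <- dev * (r / sqrt(rowSums(dev^2)))
        # each non-lonely participant's own noise enters the consensus
        # average; adding the non-lonely mean noise to every lonely
        # deviation gives the lonely group the same expected overlap with
        # the consensus, keeping similarity-to-consensus matched
        dev <- sweep(dev, 2, colMeans(noise[!lonely, , drop = FALSE]), "+")
        dev <- dev * (r / sqrt(rowSums(dev^2)))
        vals[lonely, ] <- matrix(proto, k, p, byrow = TRUE) + dev
      }
    }
    pattern_matrix(vals, participant_ids = ids,
                   target_id = sprintf("T%02d", t), space = "neural")
  })
  names(patterns) <- vapply(patterns, attr, "", "target_id")
  planted <- if (!any(lonely)) "none"
             else if (cfg$scenario == "cluster") "consensus_without_ak"
             else "ak_without_consensus"
  new_ak_dataset(patterns, lon,
                 truth = list(config = cfg, lonely = lonely, planted = planted,
                              displacement_sd = displacement_sd))
}

#' Generate binary trait-rating responses with flips and missingness
#'
#' Emulates a binary applicable/not-applicable trait-rating task: a shared
#' consensus profile is drawn once (one Bernoulli draw per trait from
#' `consensus_prob`), then each participant's copy is independently
#' flipped with probability `flip_rate` and masked missing with
#' probability `missing_rate`. Flips are independent of loneliness, so by
#' construction pairwise response similarity carries no Anna Karenina
#' signal.
#'
#' @param cfg an [synthetic_config()] object (supplies `n_participants`
#'   and the seed).
#' @param consensus_prob per-trait probability vector in \[0, 1\].
#' @param flip_rate,missing_rate proportions in \[0, 1\];
#'   `missing_rate` defaults to `cfg$missing_rate`.
#' @return n_participants x n_traits matrix of 0/1 with NAs for missing
#'   entries. Internally responses are coded 0/1 whatever the task's
#'   surface labels.
#' @export
generate_trait_responses <- function(cfg, consensus_prob, flip_rate = 0.1,
                                     missing_rate = cfg$missing_rate) {
  stopifnot(inherits(cfg, "ak_config"))
  if (any(consensus_prob < 0 | consensus_prob > 1))
    stop("consensus_prob entries must be in [0, 1]")
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  set.seed(sub_seed(cfg$seed, 101L))
  n <- cfg$n_participants
  tt <- length(consensus_prob)
  profile <- stats::rbinom(tt, 1L, consensus_prob)
  resp <- matrix(profile, n, tt, byrow = TRUE)
  flips <- matrix(stats::rbinom(n * tt, 1L, flip_rate), n, tt)
  resp <- abs(resp - flips)
  resp[matrix(stats::runif(n * tt) < missing_rate, n, tt)] <- NA_integer_
  rownames(resp) <- sprintf("P%02d", seq_len(n))
  colnames(resp) <- sprintf("trait%02d", seq_len(tt))
  resp
}

#' Generate split-half condition-by-voxel volumes with a planted blob
#'
#' Builds the fixture the reliability-based voxel selection stage
#' consumes: per participant, two condition-by-voxel matrices of
#' parameter estimates ("odd runs" and "even runs"). Voxels inside a
#' planted spherical blob share a per-participant condition-level signal
#' across the two halves (signal sd `signal_sd`); all voxels additionally
#' receive independent noise (`noise_sd`) in each half, so outside the
#' blob the halves are independent. Expected voxelwise split-half
#' reliability inside the blob is
#' \eqn{\sigma_s^2 / (\sigma_s^2 + \sigma_n^2)}.
#'
#' @param grid_shape integer length-3, volume dimensions.
#' @param blob_spec list with `center` (length-3) and `radius` (voxels).
#' @param signal_sd,noise_sd standard deviations of shared signal and
#'   half-specific noise; both zero is an error (reliability undefined).
#' @param n_participants,n_conditions counts; 16 conditions mirrors a
#'   typical design.
#' @param seed integer seed.
#' @return a `splithalf_data` object: `half1`/`half2` (lists of
#'   condition x voxel matrices per participant), `dim`, `blob_mask`
#'   (logical array), `truth`.
#' @export
generate_splithalf_volumes <- function(grid_shape = c(8L, 8L, 8L),
                                       blob_spec = list(center = c(4, 4, 4), radius = 2),
                                       signal_sd = 1, noise_sd = 1,
                                       n_participants = 10L,
                                       n_conditions = 16L,
                                       seed = 1L) {
  if (signal_sd == 0 && noise_sd == 0)
    stop("signal_sd and noise_sd cannot both be 0 (reliability undefined)")
  if (signal_sd < 0 || noise_sd < 0) stop("sds must be >= 0")
  stopifnot(length(grid_shape) == 3, length(blob_spec$center) == 3)
  if (any(blob_spec$center < 1 | blob_spec$center > grid_shape))
    stop("blob center must lie inside the grid")
  set.seed(seed)
  nv <- prod(grid_shape)
  co <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                              y = seq_len(grid_shape[2]),
                              z = seq_len(grid_shape[3])))
  inside <- sqrt(colSums((t(co) - blob_spec$center)^2)) <= blob_spec$radius
  blob_mask <- array(inside, dim = grid_shape)
  make_half <- function(signal) {
    noise <- matrix(stats::rnorm(n_conditions * nv, 0, noise_sd), n_conditions, nv)
    out <- noise
    out[, inside] <- out[, inside] + signal
    out
  }
  half1 <- vector("list", n_participants)
  half2 <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    signal <- matrix(stats::rnorm(n_conditions * sum(inside), 0, signal_sd),
                     n_conditions, sum(inside))
    half1[[i]] <- make_half(signal)
    half2[[i]] <- make_half(signal)
  }
  structure(list(half1 = half1, half2 = half2, dim = grid_shape,
                 blob_mask = blob_mask,
                 truth = list(signal_sd = signal_sd, noise_sd = noise_sd,
                              n_conditions = n_conditions, seed = seed,
                              blob_spec = blob_spec)),
            class = "splithalf_data")
}
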
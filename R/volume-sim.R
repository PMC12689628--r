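#' Parameters for the synthetic probability-volume generator
#'
#' @param shape volume extents `c(z, y, x)` in voxels.
#' @param voxel_size_um voxel size `c(z, y, x)` in micrometres
#'   (default 3.0, 3.26, 3.26).
#' @param n_plaques,n_microglia blob counts.
#' @param plaque_radius_range radius range in voxels (>= 1).
#' @param engulfed_fraction fraction of plaques overlapped by a
#'   microglia blob.
#' @param background_prob background probability level (uniform noise
#'   in `[0, background_prob]`; must stay below the 0.2 binarization
#'   threshold).
#' @param seed integer seed.
#' @export
volume_sim_params <- function(shape = c(48, 64, 64),
                              voxel_size_um = c(3.0, 3.26, 3.26),
                              n_plaques = 15L, n_microglia = 10L,
                              plaque_radius_range = c(2, 4),
                              engulfed_fraction = 0.4,
                              background_prob = 0.05, seed = 1L) {
  stop_if_not(all(shape >= 8), "shape must be at least 8 voxels per axis")
  stop_if_not(all(plaque_radius_range >= 1), "radii must be >= 1 voxel")
  stop_if_not(engulfed_fraction >= 0 && engulfed_fraction <= 1,
              "engulfed_fraction must be in [0,1]")
  stop_if_not(background_prob >= 0 && background_prob < 0.2,
              "background_prob must stay below the 0.2 threshold")
  structure(list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
                 n_plaques = as.integer(n_plaques),
                 n_microglia = as.integer(n_microglia),
                 plaque_radius_range = plaque_radius_range,
                 engulfed_fraction = engulfed_fraction,
                 background_prob = background_prob, seed = as_seed(seed)),
            class = "volume_sim_params")
}

# add one Gaussian blob (max-combined) to a volume; returns the volume
add_blob <- function(v, centre, radius, peak) {
  d <- dim(v)
  sig <- radius / 1.7  # prob drops through 0.2/peak near r = radius
  r <- ceiling(radius + 3)
  zr <- max(1, round(centre[1]) - r):min(d[1], round(centre[1]) + r)
  yr <- max(1, round(centre[2]) - r):min(d[2], round(centre[2]) + r)
  xr <- max(1, round(centre[3]) - r):min(d[3], round(centre[3]) + r)
  dz <- (zr - centre[1])^2
  dy <- (yr - centre[2])^2
  dx <- (xr - centre[3])^2
  g <- peak * exp(-(outer(outer(dz, dy, "+"), dx, "+")) / (2 * sig^2))
  v[zr, yr, xr] <- pmax(v[zr, yr, xr], g)
  v
}

blob_voxels <- function(shape, centre, radius, peak, threshold = 0.2) {
  v <- add_blob(array(0, shape), centre, radius, peak)
  which(v > threshold)
}

#' Simulate plaque and microglia probability volumes
#'
#' Plaques are smooth Gaussian blobs with peak probability well above
#' the 0.2 binarization threshold, placed with pairwise separation so
#' each yields exactly one 26-connected component; microglia blobs are
#' placed on top of a programmed fraction of plaques (engulfed) and at
#' random elsewhere.  Background is sub-threshold uniform noise.
#'
#' @param params a [volume_sim_params()].
#' @return list of class `volume_sim`: `prob_plaque`, `prob_microglia`
#'   ([probability_volume()]s) and `truth` (data.frame: centre_z/y/x,
#'   radius, peak, voxel_count of supra-threshold voxels, engulfed).
#' @export
gen_volume <- function(params) {
  stop_if_not(inherits(params, "volume_sim_params"),
              "params must come from volume_sim_params()")
  d <- params$shape
  rr <- params$plaque_radius_range
  stop_if_not(all(d > 2 * (max(rr) + 3)),
              "shape too small for the requested blob extents")
  with_seed(params$seed, {
    # rejection-sample well-separated centres with a border margin
    n <- params$n_plaques
    centres <- matrix(NA_real_, n, 3)
    radii <- stats::runif(n, rr[1], rr[2])
    peaks <- stats::runif(n, 0.6, 0.95)
    if (n > 0) for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        m <- radii[i] + 4
        cand <- c(stats::runif(1, m, d[1] - m),
                  stats::runif(1, m, d[2] - m),
                  stats::runif(1, m, d[3] - m))
        if (i == 1L || all(sqrt(colSums((t(centres[seq_len(i - 1L), ,
              drop = FALSE]) - cand)^2)) >
              radii[seq_len(i - 1L)] + radii[i] + 5)) {
          centres[i, ] <- cand; placed <- TRUE; break
        }
      }
      stop_if_not(placed,
                  "could not place %d well-separated plaques in this volume",
                  n)
    }

    pv <- array(stats::runif(prod(d), 0, params$background_prob), d)
    mv <- array(stats::runif(prod(d), 0, params$background_prob), d)
    vox_count <- integer(n)
    if (n > 0) for (i in seq_len(n)) {
      pv <- add_blob(pv, centres[i, ], radii[i], peaks[i])
      vox_count[i] <- length(blob_voxels(d, centres[i, ], radii[i],
                                         peaks[i]))
    }

    programmed <- rep(FALSE, n)
    if (n > 0)
      programmed[stats::runif(n) < params$engulfed_fraction] <- TRUE
    for (i in which(programmed))
      mv <- add_blob(mv, centres[i, ] + stats::runif(3, -1, 1),
                     radii[i] + 1, 0.9)
    for (j in seq_len(params$n_microglia)) {
      m <- max(rr) + 4
      mv <- add_blob(mv, c(stats::runif(1, m, d[1] - m),
                           stats::runif(1, m, d[2] - m),
                           stats::runif(1, m, d[3] - m)),
                     stats::runif(1, rr[1], rr[2]), 0.8)
    }

    # ground truth records realized engulfment: a randomly placed
    # microglion may also overlap a plaque
    mmask <- mv > 0.2
    engulfed <- vapply(seq_len(n), function(i)
      any(mmask[blob_voxels(d, centres[i, ], radii[i], peaks[i])]),
      logical(1))

    truth <- data.frame(centre_z = centres[, 1], centre_y = centres[, 2],
                        centre_x = centres[, 3], radius = radii,
                        peak = peaks, voxel_count = vox_count,
                        engulfed = engulfed)
    structure(list(
      prob_plaque = probability_volume(pmin(pv, 1), params$voxel_size_um),
      prob_microglia = probability_volume(pmin(mv, 1),
                                          params$voxel_size_um),
      truth = truth[order(truth$centre_z, truth$centre_y,
                          truth$centre_x), , drop = FALSE]),
      class = "volume_sim")
  })
}

#' Run the full plaque-quantification pipeline
#'
#' Binarize at the threshold, label 26-connected components, compute
#' candidate statistics, filter by size and std/mean ratio, and
#' colocalize retained plaques with the binarized microglia channel.
#'
#' @param prob_plaque,prob_microglia [probability_volume()]s.
#' @param threshold binarization cutoff (default 0.2).
#' @param min_vox,max_vox,min_ratio filter thresholds (defaults 2,
#'   10000, 0.1).
#' @return list: `plaques` (retained, with `engulfed`), `candidates`
#'   (all, with `retained` flag), `labels`, `overlap_fraction`.
#' @export
quantify_plaques <- function(prob_plaque, prob_microglia, threshold = 0.2,
                             min_vox = 2, max_vox = 10000,
                             min_ratio = 0.1) {
  labels <- components26(binarize(prob_plaque, threshold))
  cand <- candidate_stats(labels, prob_plaque)
  kept <- filter_candidates(cand, min_vox, max_vox, min_ratio)
  col <- colocalize(kept, labels, binarize(prob_microglia, threshold))
  list(plaques = col$plaques, candidates = attr(kept, "all"),
       labels = labels, overlap_fraction = col$overlap_fraction)
}
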
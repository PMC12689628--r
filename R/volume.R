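#' Probability-volume container
#'
#' A 3D array of per-voxel class probabilities (pixel-classifier
#' output), indexed `[z, y, x]`, with the acquisition voxel size.
#'
#' @param values 3D numeric array in [0,1].
#' @param voxel_size_um `c(z, y, x)` micrometres (default 3.0, 3.26,
#'   3.26: light-sheet acquisition at 3.26 x 3.26 x 3 um reordered to
#'   axis order).
#' @export
probability_volume <- function(values, voxel_size_um = c(3.0, 3.26, 3.26)) {
  stop_if_not(is.array(values) && length(dim(values)) == 3,
              "values must be a 3D array")
  stop_if_not(all(values >= 0 & values <= 1, na.rm = FALSE),
              "probabilities must lie in [0,1]")
  stop_if_not(all(voxel_size_um > 0), "voxel sizes must be positive")
  structure(list(values = values, voxel_size_um = voxel_size_um),
            class = "probability_volume")
}

as_prob_array <- function(vol) {
  if (inherits(vol, "probability_volume")) vol$values else vol
}

#' Binarize a probability volume
#'
#' Mask is `value > threshold`, strictly: a voxel exactly at the
#' threshold is background.
#'
#' @param vol a [probability_volume()] or 3D array.
#' @param threshold probability cutoff (default 0.2).
#' @return logical 3D array.
#' @export
binarize <- function(vol, threshold = 0.2) {
  stop_if_not(threshold >= 0 && threshold <= 1,
              "threshold must lie in [0,1]")
  as_prob_array(vol) > threshold
}

#' 26-connected components of a binary mask
#'
#' Maximal components under 26-connectivity (voxels sharing a face,
#' edge, or corner are neighbours).  Labels are 1..K, assigned in
#' order of each component's smallest array index, so labeling is
#' deterministic.  Adjacency is built by index shifting and the
#' partition computed with igraph.
#'
#' @param mask logical 3D array.
#' @return integer 3D array of labels (0 = background), with attribute
#'   `n` = number of components.
#' @export
components26 <- function(mask) {
  stop_if_not(is.array(mask) && length(dim(mask)) == 3 && is.logical(mask),
              "mask must be a logical 3D array")
  d <- dim(mask)
  fg <- which(mask)                    # linear indices, sorted
  lab <- array(0L, d)
  if (length(fg) == 0L) { attr(lab, "n") <- 0L; return(lab) }
  nf <- length(fg)
  zi <- ((fg - 1L) %% d[1]) + 1L
  yi <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  xi <- ((fg - 1L) %/% (d[1] * d[2])) + 1L

  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & (offs$dy > 0 |
              (offs$dy == 0 & offs$dz > 0))), ]  # 13 half-neighbourhood
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    z2 <- zi + offs$dz[k]; y2 <- yi + offs$dy[k]; x2 <- xi + offs$dx[k]
    ok <- z2 >= 1L & z2 <= d[1] & y2 >= 1L & y2 <= d[2] &
      x2 >= 1L & x2 <= d[3]
    nb <- z2[ok] + (y2[ok] - 1L) * d[1] + (x2[ok] - 1L) * d[1] * d[2]
    j <- match(nb, fg)
    hit <- !is.na(j)
    if (any(hit)) edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], j[hit])
  }
  g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  # relabel so component 1 holds the smallest array index, etc.
  first <- tapply(fg, memb, min)
  relab <- match(memb, as.integer(names(sort(first))))
  lab[fg] <- relab
  attr(lab, "n") <- max(relab)
  lab
}

#' Per-component candidate statistics
#'
#' For each labelled component: voxel count, centroid (fractional
#' voxel coordinates z/y/x), and the total, mean, and population
#' standard deviation of the probability over member voxels.
#'
#' @param labels integer label array from [components26()].
#' @param prob matching [probability_volume()] or 3D array.
#' @return data.frame of `plaque_candidate`s: id, voxel_count,
#'   centroid_z/y/x, total_prob, mean_prob, std_prob, ratio
#'   (std/mean).
#' @export
candidate_stats <- function(labels, prob) {
  p <- as_prob_array(prob)
  stop_if_not(identical(dim(labels), dim(p)),
              "labels and probability volume must share a grid")
  fg <- which(labels > 0L)
  if (length(fg) == 0L)
    return(data.frame(id = integer(), voxel_count = integer(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(), total_prob = numeric(),
                      mean_prob = numeric(), std_prob = numeric(),
                      ratio = numeric()))
  d <- dim(labels)
  lb <- labels[fg]
  zi <- ((fg - 1L) %% d[1]) + 1L
  yi <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  xi <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  pv <- p[fg]
  cnt <- as.vector(table(lb))
  agg <- function(v) as.vector(rowsum(v, lb))
  tot <- agg(pv)
  mn <- tot / cnt
  # population variance: E[p^2] - E[p]^2
  vr <- pmax(agg(pv^2) / cnt - mn^2, 0)
  data.frame(id = sort(unique(lb)),
             voxel_count = cnt,
             centroid_z = agg(zi) / cnt,
             centroid_y = agg(yi) / cnt,
             centroid_x = agg(xi) / cnt,
             total_prob = tot, mean_prob = mn, std_prob = sqrt(vr),
             ratio = sqrt(vr) / mn)
}

#' Filter plaque candidates
#'
#' Retains candidates with `min_vox <= voxel_count <= max_vox` and
#' `std_prob / mean_prob >= min_ratio`; all bounds inclusive.  The
#' ratio criterion removes flat false positives (e.g. uniform
#' autofluorescence) whose probability shows no internal structure.
#'
#' @param candidates data.frame from [candidate_stats()].
#' @param min_vox,max_vox size bounds in voxels (defaults 2 and 10000).
#' @param min_ratio minimum std/mean probability ratio (default 0.1).
#' @return the retained subset, with a logical column `retained` added
#'   to the full table as attribute `all`.
#' @export
filter_candidates <- function(candidates, min_vox = 2, max_vox = 10000,
                              min_ratio = 0.1) {
  keep <- candidates$voxel_count >= min_vox &
    candidates$voxel_count <= max_vox &
    candidates$ratio >= min_ratio
  out <- candidates[keep, , drop = FALSE]
  all_tab <- candidates
  all_tab$retained <- keep
  attr(out, "all") <- all_tab
  rownames(out) <- NULL
  out
}

#' Plaque-microglia colocalization
#'
#' A plaque is engulfed if at least one of its member voxels lies in
#' the binarized microglia mask.  The global overlap metric is the
#' microglia-overlapping plaque volume as a fraction of total plaque
#' volume.
#'
#' @param plaques retained candidate table (needs `id`).
#' @param labels label array the candidates came from.
#' @param microglia_mask logical 3D array on the same grid.
#' @return list: `plaques` (with logical `engulfed` column),
#'   `overlap_fraction`.
#' @export
colocalize <- function(plaques, labels, microglia_mask) {
  stop_if_not(identical(dim(labels), dim(microglia_mask)),
              "plaque labels and microglia mask must share a grid")
  fg <- which(labels > 0L & array(labels %in% plaques$id, dim(labels)))
  lb <- labels[fg]
  hit <- microglia_mask[fg]
  eng_ids <- sort(unique(lb[hit]))
  plaques$engulfed <- plaques$id %in% eng_ids
  total <- length(fg)
  list(plaques = plaques,
       overlap_fraction = if (total > 0) sum(hit) / total else 0)
}

#' Preprocess an intensity channel for atlas alignment
#'
#' Downsample by 2 in each dimension by 2x2x2 averaging (the volume is
#' cropped to even extents first), cap the maximum intensity, then
#' apply an isotropic 3D Gaussian blur with sigma 2 voxels.
#' Registration itself (affine + b-spline to a reference atlas) is out
#' of scope; this produces its input.
#'
#' @param vol 3D numeric array.
#' @param cap intensity cap (default `Inf`: no capping).
#' @param sigma Gaussian sigma in voxels (default 2).
#' @param factor downsampling factor (default 2).
#' @return 3D array of halved extents.
#' @export
preprocess_for_alignment <- function(vol, cap = Inf, sigma = 2, factor = 2) {
  v <- as_prob_array(vol)
  d <- dim(v)
  de <- (d %/% factor) * factor
  v <- v[seq_len(de[1]), seq_len(de[2]), seq_len(de[3]), drop = FALSE]
  dn <- de %/% factor
  # block average
  idx <- function(n) rep(seq_len(n), each = factor)
  ds <- array(0, dn)
  for (a in 0:(factor - 1)) for (b in 0:(factor - 1))
    for (cc in 0:(factor - 1))
      ds <- ds + v[seq(1 + a, de[1], by = factor),
                   seq(1 + b, de[2], by = factor),
                   seq(1 + cc, de[3], by = factor), drop = FALSE]
  ds <- ds / factor^3
  ds[ds > cap] <- cap
  gaussian_blur3d(ds, sigma)
}

# separable zero-padded 3D Gaussian blur, kernel truncated at 4 sigma
gaussian_blur3d <- function(v, sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # replicate-edge padding: constants are preserved exactly, and away
  # from borders the response equals the closed-form sampled kernel
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (s in (-r):r) {
      w <- k[s + r + 1L]
      src <- pmin(pmax(seq_len(d[axis]) - s, 1L), d[axis])
      piece <- switch(axis,
                      a[src, , , drop = FALSE],
                      a[, src, , drop = FALSE],
                      a[, , src, drop = FALSE])
      out <- out + w * piece
    }
    out
  }
  conv_axis(conv_axis(conv_axis(v, 1), 2), 3)
}

#' Assign plaques to atlas regions by centroid lookup
#'
#' Each plaque's centroid is rounded to the nearest voxel and looked
#' up in the region-label volume (a precomputed atlas registration
#' product); label 0 maps to `"unassigned"`.
#'
#' @param plaques candidate table with centroid columns.
#' @param label_volume integer 3D array of region labels on the plaque
#'   grid.
#' @param regions named character vector mapping label values to
#'   region names (e.g. `c("1" = "isocortex")`).
#' @return list: `plaques` (with `region` column), `counts` (table of
#'   plaque counts per region, all `regions` represented).
#' @export
region_counts <- function(plaques, label_volume, regions) {
  d <- dim(label_volume)
  zi <- pmin(pmax(round(plaques$centroid_z), 1), d[1])
  yi <- pmin(pmax(round(plaques$centroid_y), 1), d[2])
  xi <- pmin(pmax(round(plaques$centroid_x), 1), d[3])
  lab <- label_volume[cbind(zi, yi, xi)]
  nm <- ifelse(lab == 0, "unassigned",
               unname(regions[as.character(lab)]))
  stop_if_not(!any(is.na(nm)), "label(s) missing from the regions map: %s",
              paste(unique(lab[is.na(nm)]), collapse = ", "))
  plaques$region <- nm
  lev <- c(unname(regions), "unassigned")
  counts <- table(factor(nm, levels = lev))
  list(plaques = plaques, counts = counts)
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' One 32-bit float page per z-slice (rows = y, columns = x).
#'
#' @param vol [probability_volume()] or 3D array; @param path file.
#' @export
write_volume_tiff <- function(vol, path) {
  v <- as_prob_array(vol)
  slices <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  d2 <- dim(slices[[1]])
  out <- array(0, c(length(slices), d2[1], d2[2]))
  for (z in seq_along(slices)) out[z, , ] <- slices[[z]]
  out
}
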
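test_that("binarization is strict at the threshold", {
  v <- array(0, c(3, 3, 3))
  expect_false(any(binarize(v)))
  v[1, 1, 1] <- 0.2    # exactly at threshold: background
  v[2, 2, 2] <- 0.2001
  m <- binarize(v)
  expect_false(m[1, 1, 1])
  expect_true(m[2, 2, 2])
  expect_error(binarize(v, threshold = 1.5), "\\[0,1\\]")
  with_test_seed(71, {
    r <- array(runif(4^3), c(4, 4, 4))
    expect_identical(binarize(r, 0.5), r > 0.5)
  })
})

test_that("corner-touching voxels join under 26-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # touches only at a corner
  lab <- components26(m)
  expect_equal(attr(lab, "n"), 1L)
  # single voxel
  m2 <- array(FALSE, c(3, 3, 3)); m2[2, 2, 2] <- TRUE
  l2 <- components26(m2)
  expect_equal(attr(l2, "n"), 1L)
  expect_equal(sum(l2 > 0), 1L)
})

test_that("component partition equals the BFS flood-fill oracle on random masks", {
  with_test_seed(72, {
    for (i in 1:12) {
      d <- sample(6:20, 3, replace = TRUE)
      m <- array(runif(prod(d)) < runif(1, 0.03, 0.25), d)
      got <- components26(m)
      want <- oracle_flood_fill26(m)
      expect_identical(as.vector(got > 0), as.vector(want > 0))
      # same partition: label maps must be bijective
      tab <- table(got[got > 0], want[want > 0])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
      # deterministic first-voxel labeling order agrees with the oracle
      expect_identical(as.vector(got), as.vector(want))
    }
  })
})

test_that("component partition is invariant to axis permutation", {
  with_test_seed(73, {
    d <- c(10, 12, 14)
    m <- array(runif(prod(d)) < 0.1, d)
    n1 <- attr(components26(m), "n")
    n2 <- attr(components26(aperm(m, c(3, 1, 2))), "n")
    n3 <- attr(components26(aperm(m, c(2, 3, 1))), "n")
    expect_equal(n1, n2)
    expect_equal(n1, n3)
  })
})

test_that("candidate statistics match hand arithmetic and a brute-force accumulation", {
  # two-voxel component with probabilities 0.4 and 0.8
  p <- array(0, c(3, 3, 3)); p[1, 1, 1] <- 0.4; p[1, 1, 2] <- 0.8
  lab <- components26(p > 0.2)
  st <- candidate_stats(lab, p)
  expect_equal(st$voxel_count, 2L)
  expect_equal(st$mean_prob, 0.6)
  expect_equal(st$total_prob, 1.2)
  expect_equal(st$std_prob, 0.2)     # population SD
  expect_equal(st$ratio, 0.2 / 0.6)

  # uniform component: zero SD
  u <- array(0, c(3, 3, 3)); u[2, , 2] <- 0.5
  su <- candidate_stats(components26(u > 0.2), u)
  expect_equal(su$std_prob, 0)

  with_test_seed(74, {
    d <- c(8, 9, 10)
    pv <- array(runif(prod(d)), d)
    lab <- components26(pv > 0.6)
    st <- candidate_stats(lab, pv)
    for (k in st$id) {
      vox <- which(lab == k)
      expect_equal(st$voxel_count[st$id == k], length(vox))
      expect_equal(st$total_prob[st$id == k], sum(pv[vox]))
      expect_equal(st$std_prob[st$id == k],
                   sqrt(mean((pv[vox] - mean(pv[vox]))^2)))
    }
  })
  expect_error(candidate_stats(array(0L, c(2, 2, 2)),
                               array(0, c(3, 3, 3))), "grid")
})

test_that("candidate filtering applies inclusive bounds and is monotone", {
  cand <- data.frame(id = 1:5,
                     voxel_count = c(1L, 2L, 500L, 10000L, 10001L),
                     ratio = c(0.5, 0.1, 0.05, 0.3, 0.5))
  kept <- filter_candidates(cand)
  expect_equal(kept$id, c(2L, 4L))   # size 1, ratio 0.05, size 10001 rejected
  # size 2 with ratio exactly 0.1 retained (inclusive)
  expect_true(2L %in% kept$id)

  # monotonicity: relaxing any threshold never shrinks the retained set
  with_test_seed(75, {
    rnd <- data.frame(id = 1:200,
                      voxel_count = sample(1:20000, 200, TRUE),
                      ratio = runif(200, 0, 0.6))
    base <- filter_candidates(rnd)$id
    expect_true(all(base %in% filter_candidates(rnd, min_vox = 1)$id))
    expect_true(all(base %in% filter_candidates(rnd, max_vox = 20000)$id))
    expect_true(all(base %in% filter_candidates(rnd, min_ratio = 0.05)$id))
  })
})

test_that("colocalization flags overlap and computes the volume fraction", {
  p <- array(0, c(4, 4, 4))
  p[1, 1, 1:2] <- 0.9        # plaque A: 2 voxels
  p[3, 3, 3:4] <- 0.9        # plaque B: 2 voxels
  lab <- components26(p > 0.2)
  cand <- filter_candidates(candidate_stats(lab, p), min_ratio = 0)
  mg <- array(FALSE, c(4, 4, 4))
  res0 <- colocalize(cand, lab, mg)
  expect_false(any(res0$plaques$engulfed))
  expect_equal(res0$overlap_fraction, 0)

  mg[1, 1, 1] <- TRUE        # covers half of plaque A
  res <- colocalize(cand, lab, mg)
  expect_equal(sum(res$plaques$engulfed), 1L)
  expect_equal(res$overlap_fraction, 1 / 4)  # 1 of 4 plaque voxels
  expect_error(colocalize(cand, lab, array(FALSE, c(2, 2, 2))), "grid")
})

test_that("alignment preprocessing downsamples, caps, and blurs as designed", {
  cst <- array(2, c(8, 8, 8))
  out <- preprocess_for_alignment(cst)
  expect_equal(dim(out), c(4L, 4L, 4L))
  expect_equal(max(abs(out - 2)), 0, tolerance = 1e-12)

  capped <- preprocess_for_alignment(array(5, c(8, 8, 8)), cap = 3)
  expect_lte(max(capped), 3 + 1e-12)  # convolution round-off

  # impulse response matches the closed-form separable Gaussian kernel
  imp <- array(0, c(2, 2, 2) * 17)
  imp[17, 17, 17] <- 1
  blurred <- preprocess_for_alignment(imp, sigma = 2)
  centre <- c(9, 9, 9)  # impulse lands in downsampled voxel (9,9,9)
  k1 <- function(d) exp(-d^2 / (2 * 4))
  norm1 <- sum(k1(-8:8))
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 3, 1), c(0, 4, 4))) {
    expected <- prod(k1(off)) / norm1^3 * (1 / 8)  # impulse mass after averaging
    expect_equal(blurred[centre[1] + off[1], centre[2] + off[2],
                         centre[3] + off[3]],
                 expected, tolerance = 1e-6)
  }
})

test_that("region assignment by centroid lookup matches brute force", {
  labv <- array(0L, c(10, 10, 10))
  labv[1:5, , ] <- 1L
  labv[6:10, , ] <- 2L
  labv[1, 1, 1] <- 0L
  regions <- c("1" = "isocortex", "2" = "thalamus")
  pl <- data.frame(id = 1:3,
                   centroid_z = c(2.2, 8.6, 1), centroid_y = c(3, 4, 1),
                   centroid_x = c(3, 9, 1))
  rc <- region_counts(pl, labv, regions)
  expect_equal(rc$plaques$region, c("isocortex", "thalamus", "unassigned"))
  expect_equal(as.vector(rc$counts),
               c(1L, 1L, 1L))
  expect_error(region_counts(pl, labv, c("1" = "isocortex")), "missing")
})
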
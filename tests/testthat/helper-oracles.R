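# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package implementation (full-matrix DP
# vs Biostrings, BFS flood fill vs igraph, direct formulas vs the
# package's vectorized paths).

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + L * ext.  Full-matrix DP, rows vectorized.
oracle_gotoh_score <- function(a, b, match = 2, mismatch = -1,
                               open = 6, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # best/ix/iy over columns 0..m of the previous and current row
  best_prev <- c(0, -(open + ext * seq_len(m)))
  ix_prev <- rep(NEG, m + 1)
  iy_prev <- c(NEG, -(open + ext * seq_len(m)))
  for (i in seq_len(n)) {
    s <- ifelse(bv == av[i], match, mismatch)
    Mrow <- best_prev[1:m] + s                       # columns 1..m
    ix0 <- max(best_prev[1] - open - ext, ix_prev[1] - ext)
    Ixrow <- pmax(best_prev[2:(m + 1)] - open - ext,
                  ix_prev[2:(m + 1)] - ext)
    H <- c(ix0, pmax(Mrow, Ixrow))                   # columns 0..m
    Iyrow <- cummax(H[1:m] + ext * (0:(m - 1))) - open -
      ext * (1:m)
    best <- c(ix0, pmax(Mrow, pmax(Ixrow, Iyrow)))
    best_prev <- best
    ix_prev <- c(ix0, Ixrow)
    iy_prev <- c(NEG, Iyrow)
  }
  best_prev[m + 1]
}

# BFS flood fill under 26-connectivity; labels in first-voxel order
oracle_flood_fill26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nextlab <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    nextlab <- nextlab + 1L
    queue <- v
    lab[v] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      z <- ((cur - 1L) %% d[1]) + 1L
      y <- (((cur - 1L) %/% d[1]) %% d[2]) + 1L
      x <- ((cur - 1L) %/% (d[1] * d[2])) + 1L
      nz <- z + offs[, 1]; ny <- y + offs[, 2]; nx <- x + offs[, 3]
      ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] &
        nx >= 1 & nx <= d[3]
      nb <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      queue <- c(queue, nb)
    }
  }
  lab
}

# direct-formula cross-state normalization (plain loops)
oracle_cross_state <- function(spec, hyp, phase, day) {
  states <- c("NREM", "REM", "WAKE")
  nb <- ncol(spec)
  ref_mean <- matrix(NA_real_, 3, nb)
  for (si in 1:3) {
    ix <- which(hyp$state == states[si] & hyp$zt_phase == "light" &
                  hyp$day_index == 1)
    for (b in 1:nb) ref_mean[si, b] <- mean(spec[ix, b])
  }
  out <- matrix(NA_real_, 3, nb, dimnames = list(states, colnames(spec)))
  for (si in 1:3) {
    ix <- which(hyp$state == states[si] & hyp$zt_phase == phase &
                  hyp$day_index == day)
    if (!length(ix)) next
    for (b in 1:nb)
      out[si, b] <- 100 * mean(spec[ix, b]) / sum(ref_mean[, b])
  }
  out
}

# stationary distribution by left eigenvector (independent of the
# package helper's code path: power iteration)
oracle_stationary <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.vector(v %*% P)
  v / sum(v)
}

# brute-force per-frame window speed
oracle_window_speed <- function(x, y, fr, win = 4L) {
  n <- length(x)
  v <- rep(NA_real_, n)
  for (i in win:n) {
    pl <- 0
    for (j in (i - win + 2L):i)
      pl <- pl + sqrt((x[j] - x[j - 1])^2 + (y[j] - y[j - 1])^2)
    v[i] <- pl / ((win - 1L) / fr)
  }
  v
}

# a deterministic ~200 nt amplicon with a programmed C-to-T edit, as
# used by the read-simulation and quantification tests; window covers
# the +/- 20 nt nick region where simulated indels fall
test_amplicon <- function(seed = 101, window_half = 30L) {
  refv <- with_test_seed(seed, sample(c("A", "C", "G", "T"), 200,
                                      replace = TRUE))
  pos <- which(refv == "C" & seq_along(refv) >= 90 &
                 seq_along(refv) <= 110)[1] - 1L  # 0-based
  ref <- paste(refv, collapse = "")
  spec <- edit_spec(data.frame(position = pos, ref_base = "C",
                               alt_base = "T"),
                    ref, window = c(pos - window_half,
                                    pos + window_half + 1L),
                    name = "A187V")
  list(ref = ref, spec = spec, pos = pos)
}

with_test_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
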
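# random binned spectra + hypnogram covering light and dark of day 1
random_spec_hyp <- function(seed, n_ep = 400) {
  with_test_seed(seed, {
    states <- sample(VIGILANCE_STATES, n_ep, replace = TRUE,
                     prob = c(.4, .4, .15, .05))
    # spread epochs across the day so both phases appear
    hyp <- as_hypnogram(states)
    hyp$zt_phase <- rep(c("light", "dark"), each = n_ep / 2)
    spec <- matrix(rexp(n_ep * 30, rate = 1 / 10), n_ep, 30)
    colnames(spec) <- as.character(c(seq(0.5, 5, 0.5), 6:25))
    attr(spec, "bin_hz") <- c(seq(0.5, 5, 0.5), 6:25)
    class(spec) <- c("binned_spectra", class(spec))
    list(spec = spec, hyp = hyp)
  })
}

test_that("cross-state normalization sums to 100% per bin on the reference window", {
  d <- random_spec_hyp(41)
  norm <- normalize_cross_state(d$spec, d$hyp, phase = "light", day = 1)
  expect_equal(unname(colSums(norm)), rep(100, 30))
  # scale invariance
  norm2 <- normalize_cross_state(d$spec * 7.3, d$hyp)
  expect_equal(norm, norm2)
})

test_that("cross-state normalization matches the direct-formula oracle", {
  for (seed in c(42, 43)) {
    d <- random_spec_hyp(seed)
    for (ph in c("light", "dark")) {
      got <- normalize_cross_state(d$spec, d$hyp, phase = ph, day = 1)
      want <- oracle_cross_state(d$spec, d$hyp, ph, 1)
      expect_equal(got[!is.na(want)], want[!is.na(want)],
                   tolerance = 1e-10)
    }
  }
})

test_that("cross-state normalization excludes TREM and errors on missing reference states", {
  d <- random_spec_hyp(44)
  # TREM exclusion: perturbing TREM epochs must not change the output
  spec2 <- d$spec
  spec2[d$hyp$state == "TREM", ] <- spec2[d$hyp$state == "TREM", ] * 50
  expect_equal(normalize_cross_state(d$spec, d$hyp),
               normalize_cross_state(spec2, d$hyp))

  hyp_norem <- d$hyp
  hyp_norem$state[hyp_norem$state == "REM" &
                    hyp_norem$zt_phase == "light"] <- "WAKE"
  expect_error(normalize_cross_state(d$spec, hyp_norem), "REM")
})

test_that("within-state normalization sums to 100% over bins and matches direct formula", {
  d <- random_spec_hyp(45)
  for (s in c("NREM", "REM", "WAKE")) {
    v <- normalize_within_state(d$spec, d$hyp, state = s)
    expect_equal(sum(v), 100)
    sel <- d$hyp$state == s & d$hyp$zt_phase == "light" &
      d$hyp$day_index == 1
    m <- colMeans(d$spec[sel, , drop = FALSE])
    expect_equal(unname(as.vector(v)), unname(100 * m / sum(m)),
                 tolerance = 1e-10)
  }
  # single-bin spectrum: that bin is 100%, rest 0
  d1 <- random_spec_hyp(46)
  spec1 <- d1$spec; spec1[] <- 0; spec1[, 4] <- 5
  v <- normalize_within_state(spec1, d1$hyp, state = "NREM")
  expect_equal(unname(as.vector(v)), c(0, 0, 0, 100, rep(0, 26)))
  expect_error(normalize_within_state(d1$spec, d1$hyp, state = "TREM"),
               "TREM")
})

test_that("SWA timecourse is 100% on its ZT8-12 day-1 reference and matches brute force", {
  n_ep <- 21600
  with_test_seed(47, {
    hyp <- as_hypnogram(sample(c("NREM", "WAKE"), n_ep, TRUE))
    spec <- matrix(rexp(n_ep * 30), n_ep, 30)
    attr(spec, "bin_hz") <- c(seq(0.5, 5, 0.5), 6:25)
    # piecewise-constant delta: scale epochs by hour-of-day block
    hr <- ((seq_len(n_ep) - 1) %/% 900)
    spec <- spec * (1 + hr / 10)
    tc <- swa_timecourse(spec, hyp, interval_h = 4)
    ref_row <- tc[tc$interval_start_h == 8, ]
    expect_equal(ref_row$swa_pct, 100)

    # brute-force interval means over NREM delta
    labels <- attr(spec, "bin_hz")
    delta <- rowMeans(spec[, labels >= 1 & labels <= 4.5])
    zt <- (seq_len(n_ep) - 1) * 4 / 3600
    ref <- mean(delta[hyp$state == "NREM" & zt >= 8 & zt < 12])
    for (k in c(0, 3, 5)) {
      sel <- hyp$state == "NREM" & zt >= k * 4 & zt < (k + 1) * 4
      expect_equal(tc$swa_pct[tc$interval_start_h == k * 4],
                   100 * mean(delta[sel]) / ref, tolerance = 1e-10)
    }
  })
  # empty reference window errors
  hyp_w <- as_hypnogram(rep("WAKE", 21600))
  spec_w <- matrix(1, 21600, 30)
  attr(spec_w, "bin_hz") <- c(seq(0.5, 5, 0.5), 6:25)
  expect_error(swa_timecourse(spec_w, hyp_w), "ZT8-12")
})
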
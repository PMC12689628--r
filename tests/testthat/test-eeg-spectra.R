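make_rec <- function(x, fs = 128, emg = NULL) {
  recording(eeg = list(parietal = x),
            emg = if (is.null(emg)) numeric(length(x)) else emg, fs = fs)
}

test_that("preprocessing removes DC, decimates 512 to 128 Hz, and rejects bad rates", {
  n <- 512 * 60
  rec <- recording(eeg = list(parietal = rep(2, n)), emg = rep(2, n),
                   fs = 512)
  out <- preprocess(rec)
  expect_equal(out$fs, 128)
  expect_equal(length(out$eeg$parietal), n / 4)
  expect_lt(abs(mean(out$eeg$parietal)), 1e-6 * 2)

  expect_error(preprocess(rec, fs_out = 100), "divide")
  expect_error(preprocess(recording(eeg = list(p = rnorm(512)),
                                    emg = rnorm(512), fs = 64)), "Nyquist")
})

test_that("stop-band tones are attenuated at least as much as the designed filter response", {
  fs <- 512; t <- seq(0, 20, by = 1 / fs)[-1]
  s10 <- sin(2 * pi * 10 * t); s60 <- sin(2 * pi * 60 * t)
  # evaluate the cascade transfer function as the oracle
  H <- bandpass_response(c(10, 60), fs)
  expect_gt(H[1], 0.95)
  expect_lt(H[2], 0.2)
  out <- preprocess(recording(eeg = list(p = s10 + s60),
                              emg = numeric(length(t)), fs = fs))
  spec <- epoch_psd(out, channel = "p")
  f <- as.numeric(colnames(spec))
  p10 <- mean(spec[, which.min(abs(f - 10))])
  p60 <- mean(spec[, which.min(abs(f - 60))])
  # equal input amplitudes: the measured power ratio must respect the
  # theoretical squared response ratio (within leakage slack)
  expect_lt(p60 / p10, (H[2] / H[1])^2 * 2)
})

test_that("epoch PSD satisfies Parseval on white noise and is exact on tones", {
  # zero in, zero out
  z <- epoch_psd(make_rec(numeric(512 * 3)))
  expect_true(all(z == 0))

  with_test_seed(21, {
    x <- rnorm(512 * 1000)
    p <- epoch_psd(make_rec(x))
    tot <- mean(rowSums(p) * attr(p, "df"))
    expect_lt(abs(tot - 1), 0.05)
  })

  t <- seq_len(512 * 50) / 128
  tone <- sin(2 * pi * 4 * t)
  p <- epoch_psd(make_rec(tone))
  f <- as.numeric(colnames(p))
  frac <- sum(p[, f >= 3.75 & f <= 4.25]) / sum(p)
  expect_gt(frac, 0.95)

  expect_error(epoch_psd(make_rec(rnorm(1024), fs = 256)), "128")
})

test_that("rebin produces the hybrid 0.5/1 Hz scheme and averages quarter-bins", {
  with_test_seed(31, {
    raw <- epoch_psd(make_rec(rnorm(512 * 20)))
    b <- rebin(raw)
    labels <- attr(b, "bin_hz")
    expect_equal(labels, c(seq(0.5, 5, 0.5), 6:25))
    expect_equal(ncol(b), 30L)

    # brute-force grouping oracle on the quarter-bin frequencies
    qf <- as.numeric(colnames(raw))
    for (lb in c(0.5, 2.5, 5, 6, 17, 25)) {
      members <- if (lb <= 5) c(lb - 0.25, lb) else lb - c(0.75, 0.5, 0.25, 0)
      manual <- rowMeans(raw[, qf %in% members, drop = FALSE])
      expect_equal(unname(b[, as.character(lb)]), unname(manual))
    }

    # constant spectrum in, same constant out
    cst <- raw; cst[] <- 3.3; attr(cst, "df") <- 0.25
    expect_true(all(abs(rebin(cst) - 3.3) < 1e-12))
  })
})

test_that("rebin conserves mean power over covered ranges and rejects wrong input", {
  with_test_seed(32, {
    raw <- epoch_psd(make_rec(rnorm(512 * 5)))
    b <- rebin(raw)
    qf <- as.numeric(colnames(raw))
    # 0.25-5 Hz region: ten 0.5 Hz bins of 2 quarter-bins each
    expect_equal(rowMeans(b[, 1:10]), rowMeans(raw[, qf <= 5]))
    # 5.25-25 Hz region
    expect_equal(rowMeans(b[, 11:30]), rowMeans(raw[, qf > 5 & qf <= 25]))
  })
  bad <- matrix(1, 2, 100)
  expect_error(rebin(bad), "0.25")
})

test_that("band power selects inclusive label ranges and excludes TREM", {
  hyp <- as_hypnogram(rep(c("NREM", "TREM"), 10))
  with_test_seed(33, {
    spec <- rebin(epoch_psd(make_rec(rnorm(512 * 20))))
    labels <- attr(spec, "bin_hz")
    bp <- band_power(spec, hyp, band_def("sigma"), "NREM")
    ix <- which(labels %in% 10:15)   # sigma resolves to bins 10..15
    manual <- rowMeans(spec[hyp$state == "NREM", ix])
    expect_equal(unname(bp$epoch), unname(manual))
    expect_equal(length(bp$epoch), 10L)  # TREM epochs never included
    expect_error(band_power(spec, hyp, band_def("sigma"), "TREM"), "TREM")
    expect_error(band_power(spec, hyp,
                            band_def("custom", lo = 30, hi = 40), "NREM"),
                 "no bins")
  })
})
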
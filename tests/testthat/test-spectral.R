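# DPSS construction, multitaper spectrogram calibration, condition PSDs
# and dB band contrasts.

test_that("DPSS tapers are orthonormal, ordered and well concentrated", {
  ts <- compute_dpss(1000, 3, 5)
  V <- ts$tapers
  G <- V %*% t(V)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  lam <- ts$concentrations
  expect_true(all(diff(lam) < 0))
  expect_true(all(lam > 0 & lam < 1))
  expect_gt(lam[1], 0.99)
  # taper k has exactly k - 1 sign changes
  for (k in 1:5) {
    expect_equal(sum(diff(sign(V[k, ])) != 0), k - 1)
  }
})

test_that("the leading taper is symmetric and K is capped at 2NW", {
  ts <- compute_dpss(501, 2, 1)
  v <- ts$tapers[1, ]
  expect_equal(v, rev(v), tolerance = 1e-10)
  expect_error(compute_dpss(1000, 3, 7), "2\\*NW")
  expect_error(compute_dpss(4, 3, 5), "exceed")
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  fs <- 500
  set.seed(101)
  x <- rnorm(120 * fs)
  rec <- new_recording(rbind(x, deparse.level = 0), fs, "w")
  est <- multitaper_spectrogram(rec)
  df <- est$freqs[2] - est$freqs[1]
  mean_psd <- colMeans(est$power[1, , ])
  expect_equal(sum(mean_psd) * df, var(x), tolerance = 0.05)
  # partition additivity: band powers over a partition sum to the total
  edges <- c(0, 50, 120, 250.5)
  parts <- vapply(1:3, function(i) {
    sel <- est$freqs >= edges[i] & est$freqs < edges[i + 1]
    sum(mean_psd[sel]) * df
  }, numeric(1))
  expect_equal(sum(parts), sum(mean_psd) * df, tolerance = 1e-10)
})

test_that("a sinusoid's spectral mass stays within the half-bandwidth", {
  fs <- 500
  tt <- seq_len(60 * fs) / fs
  rec <- new_recording(rbind(sin(2 * pi * 10 * tt), deparse.level = 0), fs,
                       "s")
  est <- multitaper_spectrogram(rec)
  mean_psd <- colMeans(est$power[1, , ])
  inband <- sum(mean_psd[est$freqs >= 8.5 & est$freqs <= 11.5])
  expect_gt(inband / sum(mean_psd), 0.95)
  expect_equal(est$freqs[which.max(mean_psd)], 10)
  # analysis bandwidth identities for the default parameters
  expect_equal(2 * est$params$W, 3)            # 2 NW / T
  expect_equal(est$params$K, 2 * est$params$NW - 1)
})

test_that("window bookkeeping follows floor((dur - T)/step) + 1", {
  fs <- 100
  rec <- new_recording(matrix(rnorm(600 * fs), 1), fs, "a")
  est <- multitaper_spectrogram(rec)
  expect_equal(dim(est$power)[2], floor((600 - 2) / 1.5) + 1)  # 399
  expect_equal(est$times[1], 1)                # first window center T/2
  expect_equal(diff(est$times[1:2]), 1.5)
  expect_error(multitaper_spectrogram(new_recording(matrix(0, 1, 50), fs)),
               "shorter")
  expect_error(multitaper_spectrogram(rec, T = 1/3), "integer")
  # fractional overlap reading: 0.5 fraction of T = 1 s step
  est2 <- multitaper_spectrogram(rec, overlap = 0.5,
                                 overlap_unit = "fraction")
  expect_equal(diff(est2$times[1:2]), 1)
})

test_that("K = 1 boxcar reduces to the plain windowed periodogram", {
  fs <- 100
  N <- 2 * fs
  set.seed(102)
  x <- rnorm(20 * fs)
  rec <- new_recording(rbind(x, deparse.level = 0), fs, "x")
  est <- multitaper_spectrogram(rec, tapers = boxcar_taper(N))
  # oracle: rectangular periodogram of each window, one-sided density
  nf <- N %/% 2 + 1
  scale <- c(1, rep(2, nf - 2), 1)
  starts <- seq(0, 20 * fs - N, by = 1.5 * fs)
  for (w in c(1, 5, length(starts))) {
    seg <- x[(starts[w] + 1):(starts[w] + N)]
    P <- (Mod(stats::fft(seg / sqrt(N)))^2)[1:nf] * scale / fs
    expect_equal(est$power[1, w, ], P, tolerance = 1e-10)
  }
})

test_that("averaging K = 5 tapers cuts per-bin variance about fivefold", {
  fs <- 250
  set.seed(103)
  x <- rnorm(302 * fs)
  rec <- new_recording(rbind(x, deparse.level = 0), fs, "w")
  e5 <- multitaper_spectrogram(rec)                       # K = 5
  e1 <- multitaper_spectrogram(rec, K = 1)                # leading taper only
  sel_w <- 1:200
  sel_f <- e5$freqs > 10 & e5$freqs < 100
  v5 <- mean(apply(e5$power[1, sel_w, sel_f], 2, var))
  v1 <- mean(apply(e1$power[1, sel_w, sel_f], 2, var))
  expect_gt(v5 / v1, 0.15)
  expect_lt(v5 / v1, 0.3)
})

test_that("integer-step delays shift times but not window content", {
  fs <- 100
  set.seed(104)
  x <- rnorm(30 * fs)
  rec <- new_recording(rbind(x, deparse.level = 0), fs, "x")
  est <- multitaper_spectrogram(rec)
  shifted <- new_recording(rbind(x[-seq_len(1.5 * fs)], deparse.level = 0),
                           fs, "x")
  est2 <- multitaper_spectrogram(shifted)
  nw <- dim(est2$power)[2]
  expect_equal(est2$power[1, 1:nw, ], est$power[1, 2:(nw + 1), ],
               tolerance = 1e-12)
})

test_that("condition means use only windows fully inside each epoch", {
  fs <- 100
  set.seed(105)
  x <- rnorm(60 * fs)
  rec <- new_recording(rbind(x, deparse.level = 0), fs, "x")
  est <- multitaper_spectrogram(rec)
  # boundary at 30.5 s: window centered 30.25 (29.25-31.25) straddles it
  ep <- tibble::tibble(condition = c("a", "b"),
                       start_s = c(0, 30.5), end_s = c(30.5, 60))
  psd <- condition_mean_psd(est, ep)
  in_a <- sum(est$times - 1 >= 0 & est$times + 1 <= 30.5)
  in_b <- sum(est$times - 1 >= 30.5 & est$times + 1 <= 60)
  expect_equal(unname(psd$n_windows), c(in_a, in_b))
  expect_lt(in_a + in_b, dim(est$power)[2])    # at least one straddler out

  # stationary input: the two condition means agree within sampling error
  d <- psd$db[1, "a", ] - psd$db[1, "b", ]
  expect_lt(abs(mean(d)), 1)

  ep_bad <- tibble::tibble(condition = c("a", "b", "c"),
                           start_s = c(0, 28, 58.5), end_s = c(28, 58.5, 60))
  expect_error(condition_mean_psd(est, ep_bad), "min")
})

test_that("decibel conversion follows 10 log10 with a guarded floor", {
  expect_equal(to_decibels(c(1, 100, 1e-3)), c(0, 20, -30))
  expect_warning(z <- to_decibels(c(1, 0)), "floor")
  expect_equal(z, c(0, -300))
  expect_error(to_decibels(-1), "non-negative")
})

test_that("band contrasts aggregate per-bin dB differences as configured", {
  freqs <- seq(0, 25, by = 0.5)
  db <- array(0, c(2, 2, length(freqs)),
              dimnames = list(c("u", "v"), c("a", "b"), NULL))
  db[, "b", ] <- 10                            # flat 10 dB offset
  psd <- structure(list(db = db, freqs = freqs, conditions = c("a", "b"),
                        params = list()), class = "condition_psd")
  m <- band_power_change(psd, c(8, 15), "b", "a")
  expect_equal(m$value, c(10, 10))
  expect_equal(m$n_bins, c(14, 14))            # half-open [8, 15)
  s <- band_power_change(psd, c(8, 15), "b", "a", mode = "sum")
  expect_equal(s$value, c(140, 140))
  z <- band_power_change(psd, c(8, 15), "a", "a")
  expect_equal(z$value, c(0, 0))
  expect_error(band_power_change(psd, c(25.5, 26), "b", "a"), "no frequency")

  # adjacent bands never share a bin: 25 Hz belongs to gamma, not beta
  beta <- band_power_change(psd, c(15, 25), "b", "a")
  expect_equal(beta$n_bins[1], 20)
  bands <- ieeg_bands()
  expect_equal(nrow(bands), 9)
  expect_true(all(bands$f_lo < bands$f_hi))
})
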
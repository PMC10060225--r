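# Synthetic iEEG generator: background shaping, effect injection, epochs,
# determinism.

test_that("background has the requested spectral slope and statistics", {
  n <- 2^18
  x0 <- make_background(n, beta = 0, variance = 1, seed = 11)
  expect_equal(mean(x0), 0, tolerance = 1e-12)
  expect_equal(var(x0), 1, tolerance = 1e-10)
  expect_lt(abs(loglog_slope(x0, fs = 500)), 0.1)

  x1 <- make_background(n, beta = 1, variance = 2, seed = 12)
  s <- loglog_slope(x1, fs = 500)
  expect_gt(s, -1.15)
  expect_lt(s, -0.85)
  expect_equal(var(x1), 2, tolerance = 1e-10)

  expect_identical(make_background(4096, 1.5, seed = 3),
                   make_background(4096, 1.5, seed = 3))
  expect_error(make_background(4096, beta = -1), "beta")
  expect_error(make_background(1, beta = 1), "n_samples")
})

test_that("low-frequency knee flattens below the knee, leaves slope above", {
  n <- 2^18
  fs <- 500
  x <- make_background(n, beta = 2, variance = 1, seed = 13, fs = fs,
                       f_knee = 2)
  expect_lt(loglog_slope(x, fs, f_lo = 4, f_hi = 100), -1.7)
  expect_gt(loglog_slope(x, fs, f_lo = 0.15, f_hi = 1), -0.6)
  expect_error(make_background(n, 2, f_knee = 1), "fs")
})

test_that("band effect injection realizes the target power ratio", {
  fs <- 500
  set.seed(21)
  x <- make_background(120 * fs, beta = 2, variance = 100, fs = fs,
                       f_knee = 0.3)

  expect_identical(inject_band_effect(x, fs, c(8, 15), 0), x)

  y <- inject_band_effect(x, fs, c(3, 4), 20)
  ratio <- rect_band_power(y, fs, 3, 4) / rect_band_power(x, fs, 3, 4)
  expect_equal(ratio, 100, tolerance = 0.12)

  y2 <- inject_band_effect(x, fs, c(8, 15), -30)
  expect_lte(rect_band_power(y2, fs, 8, 15) / rect_band_power(x, fs, 8, 15),
             0.002)

  # out-of-band power further than one resolution bandwidth away unchanged
  for (band in list(c(1, 2.5), c(16, 25), c(30, 60))) {
    d_db <- 10 * log10(rect_band_power(y2, fs, band[1], band[2]) /
                         rect_band_power(x, fs, band[1], band[2]))
    expect_lt(abs(d_db), 0.5)
  }

  expect_error(inject_band_effect(x, fs, c(100, 300), 6), "Nyquist")
  expect_error(inject_band_effect(x, fs, c(8, 15), 6, interval = c(100, 200)),
               "interval")
})

test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- quick_cfg(dur = 10, seed = 99)
  a <- generate_subject(cfg, 1)
  b <- generate_subject(cfg, 1)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$channels, b$channels)
  # different subject counters give different data
  expect_false(identical(a$recording$data,
                         generate_subject(cfg, 2)$recording$data))
})

test_that("default config carries the study epoch structure", {
  cfg <- synth_config()
  expect_equal(unname(cfg$epoch_durations[c("baseline", "ketamine")]),
               c(300, 840))
  expect_equal(unname(cfg$epoch_durations["propofol"]), 235)
  expect_equal(cfg$fs_raw, 2000)
  expect_equal(nrow(cfg$shanks), 100)           # 10 shanks x 10 contacts
  sub <- generate_subject(quick_cfg(dur = 5), 1)
  expect_equal(sub$epochs$start_s, c(0, 5))
  expect_equal(sub$epochs$end_s, c(5, 10))      # half-open, contiguous
  expect_error(synth_config(epoch_durations = c(baseline = 1)), "epoch")
})

test_that("an injected effect is realized on the raw trace (Welch oracle)", {
  dur <- 150
  eff <- tibble::tibble(condition = "drug", roi = "lateraloccipital",
                        f_lo = 8, f_hi = 15, delta_db = 10)
  cfg <- quick_cfg(dur = dur, shanks = flat_plan(1, 2), effects = eff,
                   seed = 31)
  sub <- generate_subject(cfg, 1)
  got <- oracle_band_contrast(sub$recording$data[1, ], cfg$fs_raw, 8, 15,
                              int_b = c(dur, 2 * dur), int_a = c(0, dur))
  expect_equal(got, 10, tolerance = 0.1)        # +/-1 dB on a 10 dB effect
})

test_that("null generator shows no systematic condition difference", {
  cfg <- quick_cfg(dur = 24, fs = 250, shanks = flat_plan(25, 2), seed = 41)
  sub <- generate_subject(cfg, 1)
  pp <- preprocess(sub$recording, sub$channels, target_fs = 250)
  psd <- condition_mean_psd(multitaper_spectrogram(pp$recording), sub$epochs)
  bc <- band_power_change(psd, c(8, 15), "drug", "baseline")
  # 25 independent bipolar channels (2-contact shanks): mean contrast ~ 0
  expect_gt(stats::t.test(bc$value)$p.value, 0.01)
})

test_that("unmatched effect ROI warns and leaves data untouched", {
  eff <- tibble::tibble(condition = "drug", roi = "insula",
                        f_lo = 8, f_hi = 15, delta_db = 10)
  cfg <- quick_cfg(dur = 5, shanks = flat_plan(1, 2), effects = eff,
                   seed = 51)
  expect_warning(sub <- generate_subject(cfg, 1), "matches no contact")
  null_sub <- generate_subject(quick_cfg(dur = 5, shanks = flat_plan(1, 2),
                                         seed = 51), 1)
  expect_identical(sub$recording$data, null_sub$recording$data)
})

test_that("line-noise harmonics are the dominant narrowband peaks", {
  cfg <- quick_cfg(dur = 30, fs = 1000, shanks = flat_plan(1, 1),
                   line_noise = list(base = 60, n_harmonics = 3,
                                     amplitude = c(50, 40, 30)),
                   seed = 61)
  sub <- generate_subject(cfg, 1)
  p <- welch_psd(sub$recording$data[1, ], 1000, nseg = 4000)
  sel <- p$freq >= 20                          # skip the 1/f bulk
  ord <- order(p$psd[sel], decreasing = TRUE)
  peaks <- sort(unique(round(p$freq[sel][ord[1:12]] / 10) * 10))
  expect_true(all(c(60, 120, 180) %in% peaks))
})
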
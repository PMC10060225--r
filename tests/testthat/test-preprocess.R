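# Signal conditioning: notch, resample, detrend, exclusion, bipolar montage.

make_rec <- function(x, fs) new_recording(rbind(x, deparse.level = 0), fs,
                                          "c1")

test_that("notch removes line harmonics and spares the passband", {
  fs <- 2000
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(1)
  noise <- rnorm(length(tt))
  x <- sin(2 * pi * 60 * tt) + noise
  y <- notch_filter(make_rec(x, fs))$data[1, ]
  att60 <- 10 * log10(rect_band_power(y, fs, 59.5, 60.5) /
                        rect_band_power(x, fs, 59.5, 60.5))
  expect_lt(att60, -30)

  # 120 Hz harmonic also covered
  x2 <- sin(2 * pi * 120 * tt) + 0.01 * noise
  y2 <- notch_filter(make_rec(x2, fs))$data[1, ]
  att120 <- 10 * log10(rect_band_power(y2, fs, 119.5, 120.5) /
                         rect_band_power(x2, fs, 119.5, 120.5))
  expect_lt(att120, -30)

  # broadband neutrality: white-noise power away from every harmonic
  yn <- notch_filter(make_rec(noise, fs))$data[1, ]
  harm <- 60 * (1:16)
  tot_in <- 0; tot_out <- 0
  for (lo in seq(5, 950, by = 15)) {
    if (any(harm >= lo - 3 & harm <= lo + 13)) next
    tot_in <- tot_in + rect_band_power(noise, fs, lo, lo + 10)
    tot_out <- tot_out + rect_band_power(yn, fs, lo, lo + 10)
  }
  expect_lt(abs(tot_out / tot_in - 1), 0.01)

  expect_error(notch_filter(make_rec(x, 100), base = 60), "Nyquist")
})

test_that("fft and filtfilt notch realizations agree away from edges", {
  fs <- 500
  set.seed(2)
  x <- rnorm(20 * fs) + sin(2 * pi * 60 * seq_len(20 * fs) / fs)
  a <- notch_filter(make_rec(x, fs), method = "fft")$data[1, ]
  b <- notch_filter(make_rec(x, fs), method = "filtfilt")$data[1, ]
  core <- (2 * fs):(18 * fs)
  expect_lt(sd(a[core] - b[core]) / sd(x), 0.01)
})

test_that("resampling preserves band-limited content and rejects aliases", {
  fs <- 2000
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 10 * tt)
  y <- resample_to(make_rec(s, fs), 500)
  expect_equal(y$fs, 500)
  expect_equal(ncol(y$data), round(length(s) * 500 / 2000))
  expect_equal(sd(y$data[1, ]) * sqrt(2), 1, tolerance = 0.01)

  # deterministic multitone: per-tone amplitude preserved within 1% (<1 dB)
  tones <- c(5, 50, 150, 199)
  x <- rowSums(sapply(tones, function(f0) sin(2 * pi * f0 * tt)))
  yr <- resample_to(make_rec(x, fs), 500)$data[1, ]
  for (f0 in tones) {
    p <- rect_band_power(yr, 500, f0 - 0.4, f0 + 0.4)
    expect_equal(p, 0.5, tolerance = 0.02)
  }

  # content above the original 250 Hz has no image in the output
  set.seed(3)
  w <- rnorm(length(tt))
  yw <- resample_to(make_rec(w, fs), 500)$data[1, ]
  hi <- rect_band_power(yw, 500, 248, 250)
  mid <- rect_band_power(yw, 500, 100, 102)
  expect_lt(hi / mid, 0.05)                    # brick-wall stopband

  expect_error(resample_to(make_rec(s, fs), 2000), "below")
})

test_that("detrending removes exactly the per-channel linear trend", {
  fs <- 100
  t <- seq_len(10 * fs)
  line <- 2.5 + 0.03 * t
  out <- detrend_full(make_rec(line, fs))$data[1, ]
  expect_lt(max(abs(out)) / max(abs(line)), 1e-9)

  s <- sin(2 * pi * 7 * t / fs)
  rec <- detrend_full(make_rec(s + line, fs))$data[1, ]
  expect_gt(stats::cor(rec, s), 0.999)

  again <- detrend_full(make_rec(rec, fs))$data[1, ]
  expect_equal(again, rec, tolerance = 1e-12)
  expect_error(detrend_full(new_recording(matrix(1, 1, 1), 100)), "samples")
})

plan_rec <- function(plan, fs = 100, n = 500, fill = NULL, seed = 4) {
  set.seed(seed)
  ch <- plan |>
    dplyr::mutate(subject = "S01",
                  contact_id = sprintf("S01_%s%02d", shank_id, position),
                  excluded = FALSE) |>
    dplyr::select(subject, contact_id, shank_id, position, fine_label,
                  excluded)
  dat <- if (is.null(fill)) matrix(rnorm(nrow(ch) * n), nrow(ch), n)
         else matrix(fill, nrow(ch), n, byrow = TRUE)
  rownames(dat) <- ch$contact_id
  list(rec = new_recording(dat, fs), channels = ch)
}

test_that("exclusion removes exactly the flagged contacts, keeping order", {
  pr <- plan_rec(flat_plan(1, 10))
  out <- drop_excluded(pr$rec, pr$channels)
  expect_identical(out$recording$data, pr$rec$data)

  ch <- pr$channels
  ch$excluded[c(2, 5, 9)] <- TRUE
  out <- drop_excluded(pr$rec, ch)
  expect_equal(n_channels(out$recording), 7)
  expect_identical(channel_ids(out$recording),
                   ch$contact_id[!ch$excluded])

  bad <- ch
  bad$contact_id[1] <- "nonexistent"
  expect_error(drop_excluded(pr$rec, bad), "nonexistent")
})

test_that("bipolar montage derives adjacent same-shank pairs", {
  pr <- plan_rec(flat_plan(10, 10))
  out <- bipolar_montage(pr$rec, pr$channels)
  expect_equal(n_channels(out$recording), 90)   # 10 x (10 - 1)

  # derived trace = deeper minus shallower; label from the deeper contact
  expect_equal(out$recording$data[1, ],
               pr$rec$data[1, ] - pr$rec$data[2, ])
  expect_equal(out$channels$fine_label[1], pr$channels$fine_label[1])
  expect_match(out$channels$contact_id[1], ":1-2$")

  # identical adjacent traces cancel
  pr2 <- plan_rec(flat_plan(1, 2), fill = rep(sin(1:500), 2))
  out2 <- bipolar_montage(pr2$rec, pr2$channels)
  expect_equal(max(abs(out2$recording$data)), 0)
})

test_that("an excluded mid-shank contact breaks the pair chain", {
  pr <- plan_rec(flat_plan(1, 10))
  ch <- pr$channels
  ch$excluded[5] <- TRUE
  kept <- drop_excluded(pr$rec, ch)
  out <- bipolar_montage(kept$recording, kept$channels)
  # pairs 1-2..3-4 and 6-7..9-10: no bridging 4-6
  expect_equal(n_channels(out$recording), 7)
  expect_false(any(grepl(":4-6", out$channels$contact_id)))
})

test_that("shanks with fewer than two survivors yield zero pairs, warning", {
  pr <- plan_rec(flat_plan(2, 2))
  ch <- pr$channels
  ch$excluded[ch$shank_id == "SH01"] <- TRUE
  kept <- drop_excluded(pr$rec, ch)
  ch1 <- dplyr::bind_rows(kept$channels,
                          dplyr::mutate(pr$channels[1, ], excluded = FALSE))
  # a lone surviving contact on SH01
  lone <- plan_rec(flat_plan(2, 2))
  lch <- lone$channels
  lch$excluded[2] <- TRUE
  k2 <- drop_excluded(lone$rec, lch)
  expect_warning(out <- bipolar_montage(k2$recording, k2$channels),
                 "no bipolar pairs")
  expect_equal(n_channels(out$recording), 1)    # only SH02's pair remains
})

test_that("bipolar montage rejects common-mode signal across a shank", {
  pr <- plan_rec(flat_plan(1, 6))
  shared <- 10 * sin(2 * pi * 3 * seq_len(500) / 100)
  rec2 <- new_recording(sweep(pr$rec$data, 2, shared, "+"), pr$rec$fs)
  a <- bipolar_montage(pr$rec, pr$channels)
  b <- bipolar_montage(rec2, pr$channels)
  expect_equal(a$recording$data, b$recording$data, tolerance = 1e-12)
})

test_that("channel pair counts match the exhaustive enumeration oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n_sh <- sample(2:5, 1)
    sizes <- sample(2:8, n_sh, replace = TRUE)
    plan <- purrr::list_rbind(purrr::map(seq_len(n_sh), function(s) {
      tibble::tibble(shank_id = sprintf("SH%02d", s),
                     position = seq_len(sizes[s]), fine_label = "insula")
    }))
    pr <- plan_rec(plan)
    ch <- pr$channels
    ch$excluded <- stats::runif(nrow(ch)) < 0.3
    kept <- drop_excluded(pr$rec, ch)
    out <- suppressWarnings(bipolar_montage(kept$recording, kept$channels))
    # oracle: enumerate all surviving (p, p+1) pairs per shank
    oracle <- sum(purrr::map_int(split(ch, ch$shank_id), function(g) {
      surv <- sort(g$position[!g$excluded])
      sum(diff(surv) == 1L)
    }))
    expect_equal(n_channels(out$recording), oracle)
  }
})

test_that("conditioning stages are idempotent at the PSD level", {
  fs <- 500
  set.seed(8)
  x <- make_background(60 * fs, 1.5, 10, fs = fs, f_knee = 0.3) +
    sin(2 * pi * 60 * seq_len(60 * fs) / fs)
  once <- detrend_full(notch_filter(make_rec(x, fs)))
  twice <- detrend_full(notch_filter(once))
  p1 <- welch_psd(once$data[1, ], fs)
  p2 <- welch_psd(twice$data[1, ], fs)
  sel <- p1$freq >= 0.5 & p1$freq <= 200 &
    apply(abs(outer(p1$freq, 60 * (1:4), "-")) >= 3, 1, all)
  expect_lt(max(abs(10 * log10(p2$psd[sel] / p1$psd[sel]))), 1)
})
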
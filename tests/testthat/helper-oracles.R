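# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own estimation code paths.

# band-integrated power from a plain rectangular-window periodogram over the
# whole segment (bin width 1/duration); half-open [lo, hi)
rect_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / (n * fs)     # two-sided density
  f <- (0:(n - 1)) / n * fs
  sum(P[f >= lo & f < hi]) * fs / n * 2    # one-sided band integral
}

# Welch-averaged PSD with a Hann window; returns freq grid and one-sided
# density, independent of the package's multitaper code
welch_psd <- function(x, fs, nseg = 2048) {
  nw <- floor(length(x) / nseg)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)
  U <- sum(w^2)
  acc <- 0
  for (i in seq_len(nw)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  dens <- acc / (nw * U * fs)
  nf <- nseg %/% 2 + 1
  one <- dens[1:nf] * c(1, rep(2, nf - 2), 1)
  list(freq = (0:(nf - 1)) * fs / nseg, psd = one)
}

welch_band_power <- function(x, fs, lo, hi, nseg = 2048) {
  p <- welch_psd(x, fs, nseg)
  sel <- p$freq >= lo & p$freq < hi
  sum(p$psd[sel]) * fs / nseg
}

# dB contrast of band power between two half-open intervals of one trace,
# measured with the rectangular periodogram oracle
oracle_band_contrast <- function(x, fs, lo, hi, int_b, int_a) {
  seg <- function(iv) x[(floor(iv[1] * fs) + 1):floor(iv[2] * fs)]
  10 * log10(rect_band_power(seg(int_b), fs, lo, hi) /
               rect_band_power(seg(int_a), fs, lo, hi))
}

# single-label plan: n_shanks shanks of n_contacts contacts each
flat_plan <- function(n_shanks, n_contacts, label = "lateraloccipital") {
  tibble::tibble(
    shank_id = rep(sprintf("SH%02d", seq_len(n_shanks)), each = n_contacts),
    position = rep(seq_len(n_contacts), n_shanks),
    fine_label = label)
}

no_effects <- function() {
  tibble::tibble(condition = character(), roi = character(),
                 f_lo = numeric(), f_hi = numeric(), delta_db = numeric())
}

# small fast two-condition config used by several tests
quick_cfg <- function(dur = 30, fs = 500, shanks = flat_plan(2, 5),
                      effects = no_effects(), seed = 1, n_subjects = 1,
                      conditions = c("baseline", "drug"),
                      line_noise = list(base = 60, n_harmonics = 1,
                                        amplitude = 5), ...) {
  durs <- stats::setNames(rep(dur, length(conditions)), conditions)
  synth_config(fs_raw = fs, epoch_durations = durs, n_subjects = n_subjects,
               shanks = shanks, effects = effects, line_noise = line_noise,
               seed = seed, ...)
}

two_epochs <- function(dur = 30, conditions = c("baseline", "drug")) {
  tibble::tibble(condition = conditions,
                 start_s = (seq_along(conditions) - 1) * dur,
                 end_s = seq_along(conditions) * dur)
}

# least-squares slope of log10(psd) on log10(freq) over [f_lo, f_hi]
loglog_slope <- function(x, fs, f_lo = 1, f_hi = 100, nseg = 4096) {
  p <- welch_psd(x, fs, nseg)
  sel <- p$freq >= f_lo & p$freq <= f_hi & p$psd > 0
  stats::coef(stats::lm(log10(p$psd[sel]) ~ log10(p$freq[sel])))[[2]]
}
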
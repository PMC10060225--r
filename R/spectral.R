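# Multitaper spectrogram, condition-mean PSDs and dB band contrasts:
# the computational core of the pipeline.

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power spectral density. Each window of length
#' `T` seconds is tapered with the `K` leading DPSS sequences for
#' time-bandwidth product `NW`; per-taper periodograms are averaged with
#' uniform weights (no adaptive weighting) and scaled to a one-sided
#' density in signal units squared per Hz (interior bins doubled; DC and
#' Nyquist not), so the integral over `[0, fs/2]` recovers the signal
#' variance. Defaults follow common anesthesia-iEEG practice: `T = 2` s
#' windows with 0.5 s overlap (step 1.5 s), `NW = 3`, `K = 5`, giving a
#' 0.5 Hz frequency grid, half-bandwidth `W = NW/T = 1.5` Hz and full
#' analysis bandwidth `2 NW / T = 3` Hz.
#'
#' @param rec An [new_recording()] object; duration must be at least `T`
#'   and `fs * T` must be an integer number of samples.
#' @param T Window length in seconds.
#' @param overlap Window overlap; in seconds when `overlap_unit =
#'   "seconds"` (default), or as a fraction of `T` when `"fraction"`.
#' @param NW Time-bandwidth product.
#' @param K Number of tapers.
#' @param tapers Optional pre-computed [compute_dpss()] `taper_set`
#'   overriding `NW`/`K` (e.g. a boxcar for periodogram cross-checks).
#' @param overlap_unit How to read `overlap` (see above).
#' @return A `spectral_estimate`: list with `power` (channel x time x
#'   frequency array), `freqs` (Hz, spacing `1/T`), `times` (window centers
#'   in s), `channel_ids`, and `params`.
#' @export
multitaper_spectrogram <- function(rec, T = 2, overlap = 0.5, NW = 3, K = 5,
                                   tapers = NULL,
                                   overlap_unit = c("seconds", "fraction")) {
  stopifnot(inherits(rec, "ieeg_recording"))
  overlap_unit <- match.arg(overlap_unit)
  fs <- rec$fs
  N <- fs * T
  if (abs(N - round(N)) > 1e-9) {
    stop("fs * T must be an integer number of samples", call. = FALSE)
  }
  N <- as.integer(round(N))
  dur <- duration_s(rec)
  if (dur < T) stop("recording shorter than one window", call. = FALSE)
  ov_s <- if (overlap_unit == "seconds") overlap else overlap * T
  step_s <- T - ov_s
  if (step_s <= 0) stop("overlap must be smaller than T", call. = FALSE)
  step <- round(step_s * fs)
  if (is.null(tapers)) tapers <- compute_dpss(N, NW, K)
  stopifnot(inherits(tapers, "taper_set"), tapers$params$N == N)
  V <- tapers$tapers
  Kt <- nrow(V)
  n_win <- floor((ncol(rec$data) - N) / step) + 1L
  starts <- (seq_len(n_win) - 1L) * step
  nf <- N %/% 2 + 1L
  freqs <- (0:(N %/% 2)) / T
  scale <- c(1, rep(2, nf - 2), if (N %% 2 == 0) 1 else 2)
  pow <- array(0, dim = c(n_channels(rec), n_win, nf),
               dimnames = list(channel_ids(rec), NULL, NULL))
  seg_idx <- outer(seq_len(N), starts, "+")   # N x n_win index matrix
  for (ci in seq_len(n_channels(rec))) {
    segs <- matrix(rec$data[ci, ][seg_idx], N, n_win)
    acc <- matrix(0, nf, n_win)
    for (k in seq_len(Kt)) {
      X <- stats::mvfft(segs * V[k, ])
      acc <- acc + abs(X[seq_len(nf), , drop = FALSE])^2
    }
    pow[ci, , ] <- t(acc * (scale / (Kt * fs)))
  }
  structure(list(power = pow, freqs = freqs,
                 times = starts / fs + T / 2,
                 channel_ids = channel_ids(rec),
                 params = list(T = T, step = step_s, overlap = ov_s,
                               NW = tapers$params$NW, K = Kt, fs = fs,
                               W = if (is.na(tapers$params$NW)) NA_real_
                                   else tapers$params$NW / T)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<spectral_estimate> %d channels x %d windows x %d",
                     " freqs\n  T = %g s, step = %g s, NW = %s, K = %d,",
                     " fs = %g Hz, df = %g Hz\n"),
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              p$T, p$step, format(p$NW), p$K, p$fs, x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Condition-mean power spectral density in dB
#'
#' Averages the raw (not dB) spectrogram power over all windows lying
#' entirely inside each condition's `[start_s, end_s)` interval, then
#' converts to decibels. Windows straddling a condition boundary belong to
#' no condition.
#'
#' @param est A [multitaper_spectrogram()] result.
#' @param epochs Epoch table (see [validate_epoch_table()]).
#' @param floor_db dB value substituted for zero power (see
#'   [to_decibels()]).
#' @return A `condition_psd`: list with `db` (channel x condition x
#'   frequency array of dB values), `freqs`, `conditions`, `n_windows`
#'   (windows per condition) and `params`.
#' @export
condition_mean_psd <- function(est, epochs, floor_db = -300) {
  stopifnot(inherits(est, "spectral_estimate"))
  epochs <- validate_epoch_table(epochs, min_duration = est$params$T)
  half_T <- est$params$T / 2
  w_start <- est$times - half_T
  w_end <- est$times + half_T
  conds <- epochs$condition
  nf <- length(est$freqs)
  nc <- dim(est$power)[1]
  db <- array(NA_real_, dim = c(nc, length(conds), nf),
              dimnames = list(est$channel_ids, conds, NULL))
  n_windows <- integer(length(conds))
  tol <- 1e-9
  for (j in seq_along(conds)) {
    inside <- w_start >= epochs$start_s[j] - tol &
      w_end <= epochs$end_s[j] + tol
    n_windows[j] <- sum(inside)
    if (!any(inside)) {
      stop("condition '", conds[j], "' contains no complete analysis window",
           call. = FALSE)
    }
    mean_p <- apply(est$power[, inside, , drop = FALSE], c(1, 3), mean)
    db[, j, ] <- to_decibels(mean_p, floor_db = floor_db)
  }
  structure(list(db = db, freqs = est$freqs, conditions = conds,
                 n_windows = stats::setNames(n_windows, conds),
                 params = est$params),
            class = "condition_psd")
}

#' Convert power to decibels
#'
#' `10 * log10(power)`. Exact zeros map to `floor_db` with a warning;
#' negative input is an error.
#'
#' @param power Non-negative power values (vector, matrix or array).
#' @param floor_db Value substituted for zero power (default -300 dB).
#' @return dB values with the same shape as `power`.
#' @examples
#' to_decibels(c(1, 100, 1e-3))
#' @export
to_decibels <- function(power, floor_db = -300) {
  if (any(power < 0, na.rm = TRUE)) {
    stop("power must be non-negative", call. = FALSE)
  }
  zero <- !is.na(power) & power == 0
  if (any(zero)) {
    warning(sum(zero), " zero power value(s) mapped to the ", floor_db,
            " dB floor", call. = FALSE)
  }
  out <- 10 * log10(power)
  out[zero] <- floor_db
  out
}

#' Per-channel band power change between two conditions
#'
#' Subtracts the condition-mean PSDs in dB bin by bin (`cond_b - cond_a`)
#' and aggregates over the frequency bins falling in the half-open band
#' `[f_lo, f_hi)`, either as the mean per-bin dB difference (default) or
#' as the sum over bins.
#'
#' @param psd A [condition_mean_psd()] result.
#' @param band Either a row of [ieeg_bands()] (list/tibble with `band`,
#'   `f_lo`, `f_hi`) or a numeric `c(f_lo, f_hi)`.
#' @param cond_b,cond_a Condition names; the contrast is `cond_b - cond_a`.
#' @param mode `"mean"` or `"sum"` over band bins.
#' @return Tibble with columns `channel`, `band`, `contrast`, `value`
#'   (dB), `mode`, `n_bins`.
#' @export
band_power_change <- function(psd, band, cond_b, cond_a,
                              mode = c("mean", "sum")) {
  stopifnot(inherits(psd, "condition_psd"))
  mode <- match.arg(mode)
  if (is.numeric(band)) {
    edges <- band
    band <- tibble::tibble(band = sprintf("%g-%gHz", edges[1], edges[2]),
                           f_lo = edges[1], f_hi = edges[2])
  }
  band <- tibble::as_tibble(band)
  check_band(band$f_lo, band$f_hi)
  for (cc in c(cond_b, cond_a)) {
    if (!cc %in% psd$conditions) {
      stop("condition '", cc, "' not present in the PSD", call. = FALSE)
    }
  }
  sel <- psd$freqs >= band$f_lo & psd$freqs < band$f_hi
  if (!any(sel)) {
    stop("band [", band$f_lo, ", ", band$f_hi,
         ") contains no frequency bins", call. = FALSE)
  }
  d <- psd$db[, cond_b, sel, drop = FALSE] - psd$db[, cond_a, sel, drop = FALSE]
  agg <- apply(d, 1, if (mode == "mean") mean else sum)
  tibble::tibble(channel = dimnames(psd$db)[[1]], band = band$band,
                 contrast = paste0(cond_b, "-", cond_a),
                 value = unname(agg), mode = mode, n_bins = sum(sel))
}

#' All-band, all-contrast per-channel contrasts
#'
#' Convenience wrapper applying [band_power_change()] over a band table and
#' a list of condition contrasts.
#'
#' @param psd A [condition_mean_psd()] result.
#' @param bands Band table as from [ieeg_bands()].
#' @param contrasts List of `c(cond_b, cond_a)` pairs.
#' @param mode Aggregation mode passed through.
#' @return Tibble, one row per channel x band x contrast.
#' @export
band_contrasts <- function(psd, bands = ieeg_bands(),
                           contrasts = list(c("ketamine", "baseline"),
                                            c("propofol", "ketamine")),
                           mode = "mean") {
  purrr::list_rbind(purrr::map(contrasts, function(ct) {
    purrr::list_rbind(purrr::map(seq_len(nrow(bands)), function(i) {
      band_power_change(psd, bands[i, ], ct[1], ct[2], mode = mode)
    }))
  }))
}
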
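# broom-style tidiers for the pipeline's result objects.

#' Tidy a spectral estimate into a long tibble
#'
#' @param x A [multitaper_spectrogram()] result.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time`, `freq`, `power`.
#' @method tidy spectral_estimate
#' @export
tidy.spectral_estimate <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    channel = rep(x$channel_ids, times = d[2] * d[3]),
    time = rep(rep(x$times, each = d[1]), times = d[3]),
    freq = rep(x$freqs, each = d[1] * d[2]),
    power = as.vector(x$power))
}

#' @rdname tidy.spectral_estimate
#' @method glance spectral_estimate
#' @export
glance.spectral_estimate <- function(x, ...) {
  p <- x$params
  tibble::tibble(n_channels = dim(x$power)[1], n_windows = dim(x$power)[2],
                 n_freqs = dim(x$power)[3], T = p$T, step = p$step,
                 NW = p$NW, K = p$K, fs = p$fs, half_bandwidth = p$W)
}

#' Tidy a condition-mean PSD
#'
#' @param x A [condition_mean_psd()] result.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `condition`, `freq`, `db`.
#' @method tidy condition_psd
#' @export
tidy.condition_psd <- function(x, ...) {
  d <- dim(x$db)
  tibble::tibble(
    channel = rep(dimnames(x$db)[[1]], times = d[2] * d[3]),
    condition = rep(rep(x$conditions, each = d[1]), times = d[3]),
    freq = rep(x$freqs, each = d[1] * d[2]),
    db = as.vector(x$db))
}

#' Tidy / glance methods for ROI summaries
#'
#' `tidy()` returns the summary as a plain tibble; `glance()` reports the
#' run-level bootstrap metadata.
#'
#' @param x A [roi_summarize()] result.
#' @param ... Unused.
#' @method tidy roi_summary
#' @export
tidy.roi_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "roi_summary")
  tibble::as_tibble(out)
}

#' @rdname tidy.roi_summary
#' @method glance roi_summary
#' @export
glance.roi_summary <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x),
                 n_boot = x$n_boot[1],
                 aggregation_mode = (attr(x, "mode") %||% NA_character_)[1],
                 multiple_testing = attr(x, "multiple_testing") %||%
                   NA_character_)
}
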
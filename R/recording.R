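#' Multichannel recording container
#'
#' An `ieeg_recording` holds a channels-by-samples numeric matrix together
#' with its sampling rate. Channel ids are carried as matrix rownames and
#' must be unique. All preprocessing stages take and return this container.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Character vector of unique channel ids; defaults to
#'   existing rownames of `data`.
#' @return An object of class `ieeg_recording`.
#' @examples
#' rec <- new_recording(matrix(rnorm(2000), 2, 1000), fs = 500,
#'                      channel_ids = c("A1", "A2"))
#' n_samples(rec)
#' @export
new_recording <- function(data, fs, channel_ids = rownames(data)) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data)) {
    stop("`channel_ids` length must equal nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channel_ids)) {
    stop("channel ids must be unique", call. = FALSE)
  }
  rownames(data) <- channel_ids
  structure(list(data = data, fs = fs), class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @rdname new_recording
#' @param rec An `ieeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname new_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname new_recording
#' @export
channel_ids <- function(rec) rownames(rec$data)

#' @rdname new_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Validate a channel metadata table
#'
#' The channel table drives exclusion, bipolar montage derivation and
#' anatomical grouping. One row per contact with columns `subject`,
#' `contact_id`, `shank_id`, `position` (integer index along the shank,
#' 1 = deepest), `fine_label` (DKT-40 structure name) and `excluded`.
#' Positions must be unique and contiguous within each shank of a subject.
#'
#' @param channels A data frame with the columns above.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_channel_table <- function(channels) {
  req <- c("subject", "contact_id", "shank_id", "position", "fine_label", "excluded")
  miss <- setdiff(req, names(channels))
  if (length(miss)) {
    stop("channel table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  channels <- tibble::as_tibble(channels)
  if (anyDuplicated(channels$contact_id)) {
    stop("contact_id must be unique across the table", call. = FALSE)
  }
  bad <- channels |>
    dplyr::group_by(.data$subject, .data$shank_id) |>
    dplyr::summarise(
      ok = !anyDuplicated(.data$position) &&
        all(sort(.data$position) == seq_len(dplyr::n())),
      .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("positions must be unique and contiguous from 1 within each shank; ",
         "offending shank(s): ",
         paste(bad$subject, bad$shank_id, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  channels
}

#' Validate an epoch table
#'
#' Maps condition names to half-open `[start_s, end_s)` intervals on the
#' recording clock. Intervals must be non-overlapping and ordered.
#'
#' @param epochs Data frame with columns `condition`, `start_s`, `end_s`.
#' @param min_duration Minimum interval length in seconds (e.g. the spectral
#'   window length); intervals shorter than this are rejected.
#' @return The validated table as a tibble, ordered by `start_s`.
#' @export
validate_epoch_table <- function(epochs, min_duration = 0) {
  req <- c("condition", "start_s", "end_s")
  miss <- setdiff(req, names(epochs))
  if (length(miss)) {
    stop("epoch table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  epochs <- tibble::as_tibble(epochs) |> dplyr::arrange(.data$start_s)
  if (any(epochs$end_s <= epochs$start_s)) {
    stop("epoch intervals must have end_s > start_s", call. = FALSE)
  }
  if (any(epochs$end_s - epochs$start_s < min_duration)) {
    stop("epoch interval(s) shorter than the minimum duration of ",
         min_duration, " s", call. = FALSE)
  }
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    stop("epoch intervals must not overlap", call. = FALSE)
  }
  if (anyDuplicated(epochs$condition)) {
    stop("condition names must be unique", call. = FALSE)
  }
  epochs
}

# sample index of a time in seconds; half-open intervals, 0-based flooring
sample_index <- function(t_s, fs) floor(t_s * fs)
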
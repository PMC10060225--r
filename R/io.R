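# File interchange: EDF signals, TSV metadata tables, YAML configs and the
# persisted spectral container.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'",
                             call. = FALSE)
  formatC(x, width = -width)
}

num_field <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (nchar(s) <= width) return(pad_field(s, width))
  }
  stop("cannot format ", x, " into ", width, " characters", call. = FALSE)
}

#' Write a recording as a 16-bit EDF file
#'
#' Minimal European Data Format writer: one data record per `record_s`
#' seconds, each channel linearly scaled from its physical range onto the
#' full 16-bit digital range. Trailing samples that do not fill a whole
#' record are dropped with a warning.
#'
#' @param rec An [new_recording()] object; channel ids must fit the 16-byte
#'   EDF label field.
#' @param path Output file path.
#' @param record_s Data-record duration in seconds; `fs * record_s` must be
#'   an integer.
#' @param physical_dim Unit string stored per channel (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1, physical_dim = "uV") {
  stopifnot(inherits(rec, "ieeg_recording"))
  spr <- rec$fs * record_s
  if (abs(spr - round(spr)) > 1e-9) {
    stop("fs * record_s must be an integer", call. = FALSE)
  }
  spr <- as.integer(round(spr))
  ns <- n_channels(rec)
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  if (n_rec * spr < n_samples(rec)) {
    warning("dropping ", n_samples(rec) - n_rec * spr,
            " trailing sample(s) not filling a record", call. = FALSE)
  }
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("ieegpower export", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), num_field(record_s), pad_field(ns, 4))
  sig <- paste0(
    paste(vapply(channel_ids(rec), pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(physical_dim, 8), ns), collapse = ""),
    paste(vapply(pmin_, num_field, ""), collapse = ""),
    paste(vapply(pmax_, num_field, ""), collapse = ""),
    paste(rep(pad_field(-32768, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  dig <- matrix(0L, ns, n_rec * spr)
  for (i in seq_len(ns)) {
    x <- rec$data[i, seq_len(n_rec * spr)]
    dig[i, ] <- as.integer(round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                                   65535 - 32768))
  }
  for (r in seq_len(n_rec)) {
    block <- t(dig[, ((r - 1) * spr + 1):(r * spr), drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' Counterpart to [write_edf()]; all channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @return An [new_recording()] object in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd_str(8); rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  hdr_bytes <- as.integer(rd_str(8))
  rd_str(44)
  n_rec <- as.integer(rd_str(8))
  record_s <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  stopifnot(hdr_bytes == 256 * (ns + 1), n_rec >= 1, ns >= 1)
  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  rd_str(80 * ns); rd_str(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd_str(8), ""))
  rd_str(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd_str(8), ""))
  rd_str(32 * ns)
  if (length(unique(spr)) != 1) {
    stop("channels with differing sampling rates are not supported",
         call. = FALSE)
  }
  dat <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    block <- matrix(block, spr[1], ns)
    dat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  for (i in seq_len(ns)) {
    dat[i, ] <- (dat[i, ] - dmin_[i]) / (dmax_[i] - dmin_[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  new_recording(dat, spr[1] / record_s)
}

#' Read / write channel and epoch tables as TSV
#'
#' @param path TSV file path.
#' @return The validated table (readers) or `path` invisibly (writers).
#' @export
read_channel_table <- function(path) {
  ch <- readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(position = as.integer(.data$position),
                  excluded = as.logical(.data$excluded))
  validate_channel_table(ch)
}

#' @rdname read_channel_table
#' @param channels Channel table.
#' @export
write_channel_table <- function(channels, path) {
  readr::write_tsv(validate_channel_table(channels), path)
  invisible(path)
}

#' @rdname read_channel_table
#' @export
read_epoch_table <- function(path) {
  validate_epoch_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_channel_table
#' @param epochs Epoch table.
#' @export
write_epoch_table <- function(epochs, path) {
  readr::write_tsv(validate_epoch_table(epochs), path)
  invisible(path)
}

#' Read / write a synthetic study config as YAML
#'
#' @param path YAML file path.
#' @return A [synth_config()] (reader) or `path` invisibly (writer).
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_config(
    fs_raw = y$fs_raw %||% 2000,
    epoch_durations = unlist(y$epoch_durations %||%
                               list(baseline = 300, ketamine = 840,
                                    propofol = 235)),
    n_subjects = y$n_subjects %||% 10,
    shanks = if (is.null(y$shanks)) default_shank_plan()
             else dplyr::bind_rows(lapply(y$shanks, tibble::as_tibble)),
    background = y$background %||% list(beta = 2, variance = 100,
                                        f_knee = 0.3),
    line_noise = y$line_noise %||% list(base = 60, n_harmonics = 3,
                                        amplitude = c(5, 2, 1)),
    effects = if (is.null(y$effects)) default_effects()
              else dplyr::bind_rows(lapply(y$effects, tibble::as_tibble)),
    artifact_channels = y$artifact_channels %||% character(),
    ramp_s = y$ramp_s %||% 2,
    seed = y$seed %||% 1L)
}

#' @rdname read_synth_config
#' @param cfg A [synth_config()].
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  y <- list(fs_raw = cfg$fs_raw,
            epoch_durations = as.list(cfg$epoch_durations),
            n_subjects = cfg$n_subjects,
            shanks = lapply(seq_len(nrow(cfg$shanks)),
                            function(i) as.list(cfg$shanks[i, ])),
            background = cfg$background, line_noise = cfg$line_noise,
            effects = lapply(seq_len(nrow(cfg$effects)),
                             function(i) as.list(cfg$effects[i, ])),
            artifact_channels = cfg$artifact_channels,
            ramp_s = cfg$ramp_s, seed = cfg$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Persist / load a spectral estimate container
#'
#' Stores the full `spectral_estimate` (power array, frequency and time
#' grids, estimation parameters) as a single-file container.
#'
#' @param est A [multitaper_spectrogram()] result.
#' @param path File path (`.rds`).
#' @return `path` invisibly (writer) or the `spectral_estimate` (reader).
#' @export
write_spectral_estimate <- function(est, path) {
  stopifnot(inherits(est, "spectral_estimate"))
  saveRDS(est, path)
  invisible(path)
}

#' @rdname write_spectral_estimate
#' @export
read_spectral_estimate <- function(path) {
  est <- readRDS(path)
  stopifnot(inherits(est, "spectral_estimate"))
  est
}

#' Export a synthetic study to disk
#'
#' Writes one EDF per subject plus the pooled channel table, the epoch
#' table and the generating config (YAML) into a directory, in the same
#' schema accepted for recorded data.
#'
#' @param study A [generate_study()] result.
#' @param cfg The [synth_config()] that produced it.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_synth_study <- function(study, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edf <- character()
  for (s in names(study$recordings)) {
    p <- file.path(dir, paste0(s, ".edf"))
    write_edf(study$recordings[[s]], p)
    edf[s] <- p
  }
  ch <- file.path(dir, "channels.tsv")
  ep <- file.path(dir, "epochs.tsv")
  cf <- file.path(dir, "synth_config.yaml")
  write_channel_table(study$channels, ch)
  write_epoch_table(study$epochs, ep)
  write_synth_config(cfg, cf)
  invisible(list(edf = edf, channels = ch, epochs = ep, config = cf))
}
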
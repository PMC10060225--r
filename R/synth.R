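# Synthetic multi-subject iEEG with known injected condition-dependent band
# effects. Every downstream stage of the pipeline can therefore be checked
# against ground truth without patient data.

#' Configuration for the synthetic iEEG study generator
#'
#' Defaults emulate the recording context of a subanesthetic-ketamine /
#' propofol sEEG study: 2000 Hz sampling, three consecutive condition
#' epochs (baseline 300 s, ketamine 840 s, propofol 235 s), 10 depth shanks
#' of 10 contacts per subject, a 1/f background, 60 Hz line noise with
#' harmonics, and condition-dependent band-limited power effects assigned
#' by anatomical label.
#'
#' @param fs_raw Sampling rate in Hz (default 2000).
#' @param epoch_durations Named numeric vector of condition durations in
#'   seconds, in recording order.
#' @param n_subjects Number of synthetic subjects.
#' @param shanks Tibble with columns `shank_id`, `position`, `fine_label`
#'   describing one subject's electrode plan (1 = deepest contact). The same
#'   plan is used for every subject; see [default_shank_plan()].
#' @param background List with `beta` (log-log spectral slope magnitude of
#'   the 1/f background), `variance` (signal units squared) and optional
#'   `f_knee` (low-frequency knee in Hz, see [make_background()]).
#' @param line_noise List with `base` (Hz), `n_harmonics`, and `amplitude`
#'   (vector, one sinusoid amplitude per harmonic). Phases are shared across
#'   contacts of a subject with a per-contact amplitude jitter, so bipolar
#'   derivation removes most but not all of it, as in real recordings.
#' @param effects Tibble of injected effects with columns `condition`, `roi`
#'   (coarse group name or fine DKT label), `f_lo`, `f_hi`, `delta_db`
#'   (power change in dB **relative to baseline**). See [default_effects()].
#' @param artifact_channels Contact ids to corrupt with broadband noise and
#'   flag as excluded.
#' @param ramp_s Cosine on/off ramp applied to injected effects at epoch
#'   boundaries, seconds.
#' @param min_epoch_s Shortest admissible epoch (the spectral window length).
#' @param seed Master integer seed; per-subject seeds are derived as
#'   `seed + subject counter`.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(fs_raw = 2000,
                         epoch_durations = c(baseline = 300, ketamine = 840,
                                             propofol = 235),
                         n_subjects = 10,
                         shanks = default_shank_plan(),
                         background = list(beta = 2, variance = 100, f_knee = 0.3),
                         line_noise = list(base = 60, n_harmonics = 3,
                                           amplitude = c(5, 2, 1)),
                         effects = default_effects(),
                         artifact_channels = character(),
                         ramp_s = 2,
                         min_epoch_s = 2,
                         seed = 1L) {
  stopifnot(fs_raw > 0, n_subjects >= 1, ramp_s >= 0)
  if (is.null(names(epoch_durations)) || any(!nzchar(names(epoch_durations)))) {
    stop("`epoch_durations` must be a named vector of condition durations",
         call. = FALSE)
  }
  if (any(epoch_durations < min_epoch_s)) {
    stop("every epoch duration must be at least `min_epoch_s` (",
         min_epoch_s, " s)", call. = FALSE)
  }
  if (background$beta < 0) stop("background beta must be >= 0", call. = FALSE)
  shanks <- tibble::as_tibble(shanks)
  stopifnot(all(c("shank_id", "position", "fine_label") %in% names(shanks)))
  effects <- tibble::as_tibble(effects)
  if (nrow(effects)) {
    stopifnot(all(c("condition", "roi", "f_lo", "f_hi", "delta_db") %in%
                    names(effects)))
    for (i in seq_len(nrow(effects))) {
      check_band(effects$f_lo[i], effects$f_hi[i], nyquist = fs_raw / 2)
    }
    if (any(!is.finite(effects$delta_db))) {
      stop("effect delta_db must be finite", call. = FALSE)
    }
  }
  structure(list(fs_raw = fs_raw, epoch_durations = epoch_durations,
                 n_subjects = n_subjects, shanks = shanks,
                 background = background, line_noise = line_noise,
                 effects = effects, artifact_channels = artifact_channels,
                 ramp_s = ramp_s, min_epoch_s = min_epoch_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default 10-shank x 10-contact electrode plan
#'
#' A plausible bilateral sEEG implantation: deep contacts in mesial
#' structures (hippocampus, amygdala, striatum), superficial contacts in
#' cortex, covering all 15 coarse anatomical groups used by the ROI
#' analysis. Positions run 1 (deepest) to 10 per shank.
#'
#' @return Tibble with columns `shank_id`, `position`, `fine_label`.
#' @export
default_shank_plan <- function() {
  plan <- list(
    LA  = c(rep("amygdala", 3), rep("entorhinal", 2),
            rep("inferiortemporal", 2), rep("middletemporal", 3)),
    LH  = c(rep("hippocampus", 4), rep("parahippocampal", 2),
            rep("fusiform", 2), rep("inferiortemporal", 2)),
    LAC = c(rep("caudate", 2), rep("rostralanteriorcingulate", 3),
            rep("caudalanteriorcingulate", 2), rep("superiorfrontal", 3)),
    LMF = c(rep("putamen", 2), rep("caudalmiddlefrontal", 3),
            rep("rostralmiddlefrontal", 3), rep("superiorfrontal", 2)),
    LOF = c(rep("medialorbitofrontal", 3), rep("lateralorbitofrontal", 3),
            rep("parsorbitalis", 2), rep("parstriangularis", 2)),
    LPC = c(rep("posteriorcingulate", 3), rep("isthmuscingulate", 2),
            rep("precuneus", 3), rep("superiorparietal", 2)),
    LO  = c(rep("lingual", 2), rep("pericalcarine", 2),
            rep("lateraloccipital", 4), rep("cuneus", 2)),
    LT  = c(rep("insula", 3), rep("superiortemporal", 3),
            rep("supramarginal", 2), rep("inferiorparietal", 2)),
    RC  = c(rep("precentral", 3), rep("postcentral", 3),
            rep("paracentral", 2), rep("superiorfrontal", 2)),
    RO  = c(rep("hippocampus", 2), rep("lingual", 2),
            rep("lateraloccipital", 3), rep("cuneus", 3)))
  purrr::imap_dfr(plan, function(labels, id) {
    tibble::tibble(shank_id = id, position = seq_along(labels),
                   fine_label = labels)
  })
}

#' Default injected effect topography
#'
#' Encodes the qualitative drug-condition signature the pipeline is meant to
#' detect, with all changes expressed relative to baseline: under ketamine a
#' frontal gamma (25-55 Hz) increase, an occipital alpha (8-15 Hz) decrease
#' and a posteromedial 3-4 Hz increase; under propofol the frontal gamma
#' effect is absent (i.e. reversed relative to the ketamine period), the
#' occipital alpha decrease deepens, and the 3-4 Hz posteromedial rhythm
#' strengthens further (additive across the two drugs). Magnitudes are
#' moderate, physiologically plausible values; the source recordings carry
#' no published signal-level effect sizes.
#'
#' @return Tibble with columns `condition`, `roi`, `f_lo`, `f_hi`, `delta_db`.
#' @export
default_effects <- function() {
  frontal <- c("a & p cingul", "sup frontal", "mid frontal",
               "orb frontal", "inf frontal")
  dplyr::bind_rows(
    tibble::tibble(condition = "ketamine", roi = frontal,
                   f_lo = 25, f_hi = 55, delta_db = 6),
    tibble::tibble(condition = "ketamine", roi = "occipital",
                   f_lo = 8, f_hi = 15, delta_db = -8),
    tibble::tibble(condition = "ketamine",
                   roi = c("posteriorcingulate", "isthmuscingulate"),
                   f_lo = 3, f_hi = 4, delta_db = 3),
    tibble::tibble(condition = "propofol", roi = "occipital",
                   f_lo = 8, f_hi = 15, delta_db = -16),
    tibble::tibble(condition = "propofol",
                   roi = c("posteriorcingulate", "isthmuscingulate"),
                   f_lo = 3, f_hi = 4, delta_db = 9))
}

# evaluate code under a temporary RNG state seeded with `seed`;
# NULL seed means "use the current stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# zero-phase brick-wall band-pass via the full-length FFT; keeps bins with
# f_lo <= f < f_hi (half-open, matching the band convention)
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                     # fold to [0, fs/2]
  keep <- f >= f_lo & f < f_hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Generate a 1/f background trace
#'
#' Spectrally shaped Gaussian noise whose log power falls linearly with log
#' frequency at slope `-beta`, produced by scaling the DFT of white noise
#' by the square root of the target power shape (DC removed) and
#' inverting. An optional low-frequency knee `f_knee` flattens the
#' spectrum below that frequency (power ~ `(f^2 + f_knee^2)^(-beta/2)`),
#' matching the bounded infra-slow power of recorded field potentials
#' instead of letting a pure power law diverge; the log-log slope above
#' the knee is unaffected. Exactly zero mean, variance as requested.
#'
#' @param n_samples Length of the output vector (>= 2).
#' @param beta Spectral exponent (power ~ f^-beta); must be >= 0.
#' @param variance Target variance in signal units squared.
#' @param seed Optional integer seed; same seed gives an identical vector.
#' @param fs Sampling rate in Hz; only needed when `f_knee > 0`.
#' @param f_knee Knee frequency in Hz (0 = pure power law).
#' @return Numeric vector of length `n_samples`.
#' @examples
#' x <- make_background(2^12, beta = 1, variance = 1, seed = 7)
#' var(x)
#' @export
make_background <- function(n_samples, beta, variance = 1, seed = NULL,
                            fs = NULL, f_knee = 0) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (f_knee > 0 && is.null(fs)) {
    stop("`fs` is required when f_knee > 0", call. = FALSE)
  }
  with_seed(seed, {
    n <- n_samples
    w <- rnorm(n)
    k <- seq_len(n) - 1
    m <- pmin(k, n - k)                    # folded bin index
    knee_bins <- if (f_knee > 0) f_knee * n / fs else 0
    h <- (m^2 + knee_bins^2)^(-beta / 4)
    h[1] <- 0                              # kill DC
    y <- Re(fft(fft(w) * h, inverse = TRUE)) / n
    y <- y - mean(y)
    y * sqrt(variance) / sd(y)
  })
}

#' Inject a band-limited power change into an interval of a signal
#'
#' Changes the power of `x` inside the frequency band `band` over the time
#' `interval` by `delta_db` decibels while leaving out-of-band power
#' untouched. Increases add an independent band-limited Gaussian process
#' whose power is solved from the target ratio; decreases scale the
#' signal's own band content (extracted with a zero-phase brick-wall
#' filter) by the square root of the power ratio. A cosine ramp of
#' `ramp_s` seconds at the interval edges avoids spectral splatter.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param band Numeric `c(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param delta_db Target band power change in dB (`10*log10` ratio).
#' @param interval `c(start_s, end_s)` half-open interval in seconds;
#'   defaults to the whole signal.
#' @param ramp_s Edge ramp length in seconds (default 0).
#' @return The modified signal vector.
#' @export
inject_band_effect <- function(x, fs, band, delta_db,
                               interval = c(0, length(x) / fs), ramp_s = 0) {
  check_band(band[1], band[2], nyquist = fs / 2)
  if (band[1] <= 0) stop("band lower edge must be > 0 Hz", call. = FALSE)
  n <- length(x)
  i0 <- sample_index(interval[1], fs) + 1L
  i1 <- sample_index(interval[2], fs)
  if (i0 < 1 || i1 > n || i1 <= i0) {
    stop("interval must lie within the signal", call. = FALSE)
  }
  if (delta_db == 0) return(x)
  idx <- i0:i1
  nint <- length(idx)
  nr <- min(round(ramp_s * fs), floor(nint / 4))
  env <- rep(1, nint)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- ramp
    env[nint - seq_len(nr) + 1L] <- ramp
  }
  core <- if (nr > 0) idx[(nr + 1):(nint - nr)] else idx
  r <- 10^(delta_db / 10)
  b <- fft_bandpass(x, fs, band[1], band[2])
  p_band <- mean(b[core]^2)
  y <- x
  if (delta_db > 0) {
    if (p_band <= 0) {
      # no pre-existing band content to reference; use the trace's total
      # power as the reference level instead of silently doing nothing
      p_band <- mean(x[core]^2) / max(1, (fs / 2) / (band[2] - band[1]))
    }
    z <- fft_bandpass(rnorm(nint), fs, band[1], band[2])
    z <- z / sd(z) * sqrt((r - 1) * p_band)
    y[idx] <- x[idx] + env * z
  } else {
    g <- 1 - sqrt(r)
    y[idx] <- x[idx] - g * env * b[idx]
  }
  y
}

# map each contact's fine label to its coarse group for effect matching;
# an effect roi may name either level
effect_matches <- function(fine_label, roi, map) {
  coarse <- map$coarse_label[match(fine_label, map$fine_label)]
  fine_label == roi | (!is.na(coarse) & coarse == roi)
}

#' Generate one synthetic subject
#'
#' @param cfg A [synth_config()].
#' @param subject Integer subject counter (1-based); the subject RNG seed is
#'   `cfg$seed + subject`.
#' @return List with elements `recording` ([new_recording()]), `channels`
#'   (channel table) and `epochs` (epoch table).
#' @export
generate_subject <- function(cfg, subject = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_raw
  durs <- cfg$epoch_durations
  starts <- cumsum(c(0, unname(durs)))[seq_along(durs)]
  epochs <- tibble::tibble(condition = names(durs), start_s = starts,
                           end_s = starts + unname(durs))
  n <- sample_index(sum(durs), fs)
  subj_id <- sprintf("S%02d", subject)
  ch <- cfg$shanks |>
    dplyr::mutate(subject = subj_id,
                  contact_id = sprintf("%s_%s%02d", subj_id, .data$shank_id,
                                       .data$position),
                  excluded = .data$contact_id %in% cfg$artifact_channels |
                    sprintf("%s%02d", .data$shank_id, .data$position) %in%
                    cfg$artifact_channels) |>
    dplyr::select("subject", "contact_id", "shank_id", "position",
                  "fine_label", "excluded")
  ch <- validate_channel_table(ch)
  map <- dkt_label_map("ketamine15")

  with_seed(cfg$seed + subject, {
    ln <- cfg$line_noise
    harm_f <- ln$base * seq_len(ln$n_harmonics)
    harm_f <- harm_f[harm_f < fs / 2]
    phases <- stats::runif(length(harm_f), 0, 2 * pi)
    tt <- (seq_len(n) - 1) / fs
    dat <- matrix(0, nrow(ch), n, dimnames = list(ch$contact_id, NULL))
    for (i in seq_len(nrow(ch))) {
      x <- make_background(n, cfg$background$beta, cfg$background$variance,
                           fs = fs, f_knee = cfg$background$f_knee %||% 0)
      for (h in seq_along(harm_f)) {
        amp <- ln$amplitude[h] * stats::runif(1, 0.8, 1.2)
        x <- x + amp * sin(2 * pi * harm_f[h] * tt + phases[h])
      }
      if (ch$excluded[i]) {
        x <- x + rnorm(n, sd = 10 * sqrt(cfg$background$variance))
      }
      dat[i, ] <- x
    }
    if (nrow(cfg$effects)) {
      for (e in seq_len(nrow(cfg$effects))) {
        ef <- cfg$effects[e, ]
        if (!ef$condition %in% epochs$condition) {
          warning("effect condition '", ef$condition,
                  "' not in the epoch table; unrealized", call. = FALSE)
          next
        }
        hit <- which(effect_matches(ch$fine_label, ef$roi, map) & !ch$excluded)
        if (!length(hit)) {
          warning("effect roi '", ef$roi, "' matches no contact; unrealized",
                  call. = FALSE)
          next
        }
        iv <- epochs[epochs$condition == ef$condition, ]
        for (i in hit) {
          dat[i, ] <- inject_band_effect(dat[i, ], fs,
                                         c(ef$f_lo, ef$f_hi), ef$delta_db,
                                         interval = c(iv$start_s, iv$end_s),
                                         ramp_s = cfg$ramp_s)
        }
      }
    }
    list(recording = new_recording(dat, fs), channels = ch, epochs = epochs)
  })
}

#' Generate a full synthetic study
#'
#' Loops [generate_subject()] over `cfg$n_subjects` with per-subject derived
#' seeds so the whole study is reproducible from the master seed.
#'
#' @param cfg A [synth_config()].
#' @return List of class `ieeg_synth_study`: `recordings` (named list of
#'   [new_recording()] objects, one per subject), `channels` (pooled channel
#'   table), `epochs` (epoch table, shared across subjects).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  subs <- purrr::map(seq_len(cfg$n_subjects), ~generate_subject(cfg, .x))
  names(subs) <- purrr::map_chr(subs, ~.x$channels$subject[1])
  structure(
    list(recordings = purrr::map(subs, "recording"),
         channels = purrr::list_rbind(purrr::map(subs, "channels")),
         epochs = subs[[1]]$epochs),
    class = "ieeg_synth_study")
}
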
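# Anatomical grouping of contacts into coarse ROIs and channel-pooled
# percentile-bootstrap statistics per (ROI, band, contrast).

dkt_groups <- list(
  "a & p cingul"      = c("rostralanteriorcingulate", "caudalanteriorcingulate",
                          "posteriorcingulate"),
  "sup frontal"       = "superiorfrontal",
  "mid frontal"       = c("rostralmiddlefrontal", "caudalmiddlefrontal"),
  "orb frontal"       = c("lateralorbitofrontal", "medialorbitofrontal"),
  "inf frontal"       = c("parsopercularis", "parsorbitalis",
                          "parstriangularis"),
  "precentral"        = c("precentral", "paracentral"),
  "postcentral"       = "postcentral",
  "isth cingul"       = "isthmuscingulate",
  "pari, prec & sup"  = c("inferiorparietal", "superiorparietal",
                          "precuneus", "supramarginal"),
  "temp & fusi"       = c("superiortemporal", "middletemporal",
                          "inferiortemporal", "transversetemporal",
                          "fusiform", "entorhinal", "parahippocampal"),
  "ling & perical"    = c("lingual", "pericalcarine"),
  "occipital"         = c("lateraloccipital", "cuneus"),
  "hipp & amy"        = c("hippocampus", "amygdala"),
  "striatum"          = c("caudate", "putamen"),
  "insula"            = "insula")

#' Fine-to-coarse anatomical label maps
#'
#' Maps fine DKT-40 (Desikan-Killiany-Tourville) structure names, plus the
#' subcortical structures sampled by depth electrodes, onto the coarse
#' groups used for ROI pooling: a 15-group map for the ketamine analysis
#' and a 14-group map (identical minus striatum) for the propofol
#' analysis. The same tables ship as editable TSVs under
#' `inst/extdata/` (see [read_label_map()]).
#'
#' @param which `"ketamine15"` or `"propofol14"`.
#' @return Tibble with columns `fine_label`, `coarse_label`.
#' @examples
#' dkt_label_map()
#' @export
dkt_label_map <- function(which = c("ketamine15", "propofol14")) {
  which <- match.arg(which)
  groups <- dkt_groups
  if (which == "propofol14") groups <- groups[names(groups) != "striatum"]
  purrr::imap_dfr(groups, function(fine, coarse) {
    tibble::tibble(fine_label = fine, coarse_label = coarse)
  }) |> dplyr::select("fine_label", "coarse_label")
}

#' Read / write a label map TSV
#'
#' @param path TSV file with columns `fine_label`, `coarse_label`.
#' @return `read_label_map()`: the map tibble. `write_label_map()`: `path`,
#'   invisibly.
#' @export
read_label_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("fine_label", "coarse_label") %in% names(map)))
  if (anyDuplicated(map$fine_label)) {
    stop("label map assigns some fine label more than once", call. = FALSE)
  }
  map
}

#' @rdname read_label_map
#' @param map Label map tibble.
#' @export
write_label_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Annotate channels with coarse anatomical labels
#'
#' Joins the channel table with a label map on `fine_label`. Channels whose
#' fine label is absent from the map are dropped with a warning; the
#' dropped labels are attached as attribute `"unmapped"`.
#'
#' @param channels Channel table (typically bipolar-derived).
#' @param map Label map from [dkt_label_map()] or [read_label_map()].
#' @return The channel table with an added `coarse_label` column.
#' @export
map_to_coarse <- function(channels, map = dkt_label_map()) {
  channels <- tibble::as_tibble(channels)
  out <- dplyr::left_join(channels, map, by = "fine_label")
  unmapped <- sort(unique(out$fine_label[is.na(out$coarse_label)]))
  if (length(unmapped)) {
    warning("dropping ", sum(is.na(out$coarse_label)),
            " channel(s) with unmapped fine label(s): ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::filter(out, !is.na(.data$coarse_label))
  attr(out, "unmapped") <- unmapped
  out
}

#' Percentile-bootstrap confidence interval for a pooled mean
#'
#' Resamples values (channels pooled across subjects) with replacement
#' `n_boot` times and returns the sample mean together with the percentile
#' interval of the resampled means. Deterministic given `seed`.
#'
#' @param values Numeric vector of per-channel dB contrasts (length >= 1).
#' @param n_boot Number of bootstrap replicates (>= 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return One-row tibble: `mean`, `ci_lo`, `ci_hi`, `n`, `n_boot`,
#'   `level`, `seed`, `classification`.
#' @export
bootstrap_roi_ci <- function(values, n_boot = 10000, level = 0.95,
                             seed = NULL) {
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be at least 1000", call. = FALSE)
  n <- length(values)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(values[idx], n, n_boot))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha)))
  tibble::tibble(mean = mean(values), ci_lo = ci[1], ci_hi = ci[2],
                 n = n, n_boot = as.integer(n_boot), level = level,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 classification = classify_change(ci[1], ci[2]))
}

#' Classify a band-power change from its confidence interval
#'
#' `"increase"` if the whole interval is above zero, `"decrease"` if below,
#' otherwise `"no_change"` (interval overlaps zero).
#'
#' @param ci_lo,ci_hi Interval endpoints (vectorized).
#' @return Character vector of classifications.
#' @examples
#' classify_change(c(1.2, -3.4, -0.5), c(3.4, -1.2, 0.5))
#' @export
classify_change <- function(ci_lo, ci_hi) {
  dplyr::case_when(ci_lo > 0 ~ "increase",
                   ci_hi < 0 ~ "decrease",
                   TRUE ~ "no_change")
}

#' ROI-level bootstrap summary of band contrasts
#'
#' Joins per-channel band contrasts with coarse-labelled channels and
#' computes, for every (ROI, band, contrast), the channel-pooled mean dB
#' change, percentile-bootstrap CI, channel and subject counts, and the
#' overlap-zero classification. Channels are the resampling unit, pooled
#' across subjects; no multiple-comparison correction is applied (effect
#' sizes with CIs are reported instead), and this is recorded in the
#' attributes.
#'
#' @param contrasts Tibble from [band_contrasts()].
#' @param channels Coarse-labelled channel table from [map_to_coarse()].
#' @param n_boot,level Bootstrap parameters (see [bootstrap_roi_ci()]).
#' @param seed Integer master seed; each (ROI, band, contrast) cell uses a
#'   derived seed `seed + cell index` so results are reproducible and
#'   order-independent.
#' @return A `roi_summary` tibble: `roi`, `band`, `contrast`, `mean`,
#'   `ci_lo`, `ci_hi`, `n_channels`, `n_subjects`, `classification`,
#'   `n_boot`, `seed`.
#' @export
roi_summarize <- function(contrasts, channels, n_boot = 10000, level = 0.95,
                          seed = 1L) {
  joined <- dplyr::inner_join(
    contrasts,
    dplyr::select(channels, channel = "contact_id", "subject",
                  roi = "coarse_label"),
    by = "channel")
  cells <- joined |>
    dplyr::group_by(.data$roi, .data$band, .data$contrast) |>
    dplyr::group_split()
  out <- purrr::imap(cells, function(g, i) {
    ci <- bootstrap_roi_ci(g$value, n_boot = n_boot, level = level,
                           seed = seed + i)
    tibble::tibble(roi = g$roi[1], band = g$band[1], contrast = g$contrast[1],
                   mean = ci$mean, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                   n_channels = nrow(g),
                   n_subjects = dplyr::n_distinct(g$subject),
                   classification = ci$classification,
                   n_boot = ci$n_boot, seed = ci$seed)
  }) |> purrr::list_rbind()
  attr(out, "mode") <- unique(contrasts$mode)
  attr(out, "multiple_testing") <- "none (effect sizes with bootstrap CIs)"
  class(out) <- c("roi_summary", class(out))
  out
}

#' Per-frequency contrast spectrum for a set of regions
#'
#' For the channels whose fine or coarse label falls in `roi_set`, computes
#' at every frequency bin the channel-pooled mean dB difference
#' (`cond_b - cond_a`) with a percentile-bootstrap CI, resampling whole
#' channels (the same resample is used across bins, preserving spectral
#' smoothness of the replicates).
#'
#' @param psd A [condition_mean_psd()] result.
#' @param channels Coarse-labelled channel table from [map_to_coarse()].
#' @param roi_set Character vector of fine or coarse labels defining the
#'   region set (e.g. `c("posteriorcingulate", "isthmuscingulate")` for the
#'   posteromedial cortex).
#' @param cond_b,cond_a Conditions; the contrast is `cond_b - cond_a`.
#' @param n_boot,level,seed Bootstrap parameters.
#' @return Tibble: `freq`, `mean`, `ci_lo`, `ci_hi`, `n_channels`,
#'   `classification`.
#' @export
roi_spectrum <- function(psd, channels, roi_set, cond_b, cond_a,
                         n_boot = 10000, level = 0.95, seed = 1L) {
  stopifnot(inherits(psd, "condition_psd"))
  sel_ch <- channels$contact_id[channels$fine_label %in% roi_set |
                                  channels$coarse_label %in% roi_set]
  sel_ch <- intersect(dimnames(psd$db)[[1]], sel_ch)
  if (!length(sel_ch)) {
    stop("no channels fall in the requested ROI set", call. = FALSE)
  }
  d <- psd$db[sel_ch, cond_b, , drop = FALSE] -
    psd$db[sel_ch, cond_a, , drop = FALSE]
  d <- matrix(d, nrow = length(sel_ch))        # channels x freq
  n <- nrow(d)
  alpha <- (1 - level) / 2
  ci <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    reps <- apply(idx, 2, function(ii) colMeans(d[ii, , drop = FALSE]))
    apply(reps, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  })
  tibble::tibble(freq = psd$freqs, mean = colMeans(d),
                 ci_lo = ci[1, ], ci_hi = ci[2, ], n_channels = n,
                 classification = classify_change(ci[1, ], ci[2, ]))
}
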
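# Windowed PSD, band powers, relative powers, brain rate, aggregation.

#' Average PSD of a set of analysis windows
#'
#' Hamming-tapered FFT periodogram per window with the Welch normalization
#' (divide by `sampling_rate * sum(taper^2)`, one-sided with interior-bin
#' doubling), averaged over windows and restricted to the 1-40 Hz grid
#' (1-s windows give 1 Hz resolution; the 0 Hz bin falls in the high-pass
#' region and is excluded).
#'
#' @param w numeric matrix, samples x windows, one channel's windows in
#'   microvolts.
#' @param sampling_rate_hz sampling rate.
#' @param wspec the [window_spec()] used to cut the windows.
#' @param fmax top of the analyzed grid (Hz).
#' @return named numeric vector of PSD values (microvolt^2 per Hz) on the
#'   1 Hz grid `1..fmax`.
#' @export
psd_windows <- function(w, sampling_rate_hz, wspec = window_spec(),
                        fmax = 40) {
  if (is.vector(w)) w <- matrix(w, ncol = 1)
  n <- nrow(w)
  if (n != round(wspec$length_s * sampling_rate_hz))
    stop("window length ", n, " does not match length_s * rate = ",
         round(wspec$length_s * sampling_rate_hz), " samples")
  taper <- .hamming(n)
  X <- stats::mvfft(w * taper)
  scale <- sampling_rate_hz * sum(taper^2)
  P <- Mod(X)^2 / scale
  df <- sampling_rate_hz / n
  kmax <- round(fmax / df)
  stopifnot(kmax < n / 2)
  # one-sided: double interior bins (k and n-k fold together)
  p1 <- 2 * P[1 + seq_len(kmax), , drop = FALSE]
  avg <- rowMeans(p1)
  grid <- seq_len(kmax) * df
  keep <- grid >= 1 - 1e-9
  stats::setNames(avg[keep], format(grid[keep], trim = TRUE))
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Absolute and relative band powers from a PSD
#'
#' Per band: the mean PSD over the band's bins (`band_abs`, matching the
#' "mean absolute power" convention for absolute comparisons) and the band's
#' share of total summed bin power (`band_rel`, which guarantees the five
#' shares sum to 1 exactly despite unequal band widths). Bands own bins by
#' the half-open rule `low < f <= high`.
#'
#' @param psd named PSD vector from [psd_windows()] (names are bin
#'   frequencies in Hz).
#' @param bands a [band_specs()] table.
#' @return list with `band_abs` and `band_rel`, both named by band.
#' @export
band_powers <- function(psd, bands = band_specs()) {
  f <- as.numeric(names(psd))
  tot <- sum(psd)
  babs <- brel <- stats::setNames(numeric(nrow(bands)), bands$name)
  for (b in seq_len(nrow(bands))) {
    sel <- f > bands$low_hz[b] & f <= bands$high_hz[b] + 1e-9
    if (!any(sel)) stop("band ", bands$name[b], " contains no PSD bins")
    babs[b] <- mean(psd[sel])
    brel[b] <- sum(psd[sel]) / tot
  }
  if (tot == 0) brel[] <- NA_real_
  list(band_abs = babs, band_rel = brel)
}

#' Brain-rate summary frequency
#'
#' The relative-power-weighted mean of band center frequencies,
#' `f_BR = sum_b center_b * R_b`. Undefined (NA) when total power is zero.
#'
#' @param band_rel named relative band powers summing to 1.
#' @param bands a [band_specs()] table.
#' @return frequency in Hz, within the hull of band centers.
#' @export
brain_rate <- function(band_rel, bands = band_specs()) {
  if (anyNA(band_rel)) return(NA_real_)
  stopifnot(abs(sum(band_rel) - 1) < 1e-6)
  sum(bands$center_hz[match(names(band_rel), bands$name)] * band_rel)
}

#' Stimulus-level spectral features for a recording
#'
#' Cuts each stimulus into overlapping windows, computes the
#' window-averaged PSD per channel, and derives band powers, relative powers
#' and brain rate. One row per (stimulus, channel).
#'
#' @param rec an `eeg_recording` with events.
#' @param wspec a [window_spec()].
#' @param bands a [band_specs()] table.
#' @param fmax top of the analyzed grid (Hz).
#' @return data.frame with identifier columns, `n_windows`, `psd_<f>` bins,
#'   `abs_<band>`, `rel_<band>`, and `brain_rate_hz`.
#' @export
spectral_features <- function(rec, wspec = window_spec(),
                              bands = band_specs(), fmax = 40) {
  fs <- rec$sampling_rate_hz
  nwin_len <- round(wspec$length_s * fs)
  ch <- rec$montage$channel_names
  ev <- rec$events
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    nwin <- window_count(ev$duration_s[i], wspec$length_s, wspec$step_s)
    if (nwin == 0) next
    acc <- NULL
    for (k in seq_len(nwin)) {
      at <- round((ev$onset_s[i] + (k - 1) * wspec$step_s) * fs) + 1L
      seg <- t(rec$samples[, at:(at + nwin_len - 1), drop = FALSE])
      p <- .psd_multi(seg, fs, wspec, fmax)
      acc <- if (is.null(acc)) p else acc + p
    }
    p <- acc / nwin                       # channels in columns
    per_ch <- vector("list", length(ch))
    for (j in seq_along(ch)) {
      psd <- stats::setNames(p[, j], rownames(p))
      bp <- band_powers(psd, bands)
      per_ch[[j]] <- c(psd, stats::setNames(bp$band_abs,
                                            paste0("abs_", names(bp$band_abs))),
                       stats::setNames(bp$band_rel,
                                       paste0("rel_", names(bp$band_rel))),
                       brain_rate_hz = brain_rate(bp$band_rel, bands))
    }
    num <- do.call(rbind, per_ch)
    colnames(num)[seq_len(sum(!grepl("^(abs|rel|brain)", colnames(num))))] <-
      paste0("psd_", rownames(p))
    rows[[i]] <- data.frame(participant_id = rec$participant_id,
                            stimulus_id = ev$stimulus_id[i],
                            text_type = ev$text_type[i],
                            trial_index = ev$trial_index[i],
                            channel = ch, n_windows = nwin, num,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no stimulus long enough for a single window")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# window PSD for all channels at once (samples x channels in, bins x channels
# out, rownames = bin frequencies)
.psd_multi <- function(seg, fs, wspec, fmax) {
  n <- nrow(seg)
  taper <- .hamming(n)
  X <- stats::mvfft(seg * taper)
  P <- Mod(X)^2 / (fs * sum(taper^2))
  df <- fs / n
  kmax <- round(fmax / df)
  p1 <- 2 * P[1 + seq_len(kmax), , drop = FALSE]
  grid <- seq_len(kmax) * df
  keep <- grid >= 1 - 1e-9
  out <- p1[keep, , drop = FALSE]
  rownames(out) <- format(grid[keep], trim = TRUE)
  out
}

#' Aggregate spectral features
#'
#' For the absolute analysis (`level = "absolute"`), mean PSD per (channel,
#' frequency bin, cell), averaging first within participant and then across
#' participants, so participants with unequal stimulus counts carry equal
#' weight. For the relative analysis (`level = "relative"`), stimulus-level
#' rows are retained unaveraged and the band-share and brain-rate columns
#' are returned as-is.
#'
#' @param features output of [spectral_features()] (rows may span
#'   participants).
#' @param by grouping: `"text_type"` or a metadata variable name (requires a
#'   `metadata` table to map participants to levels).
#' @param level `"absolute"` or `"relative"`.
#' @param metadata [participant_metadata()] table, needed when `by` is a
#'   metadata variable.
#' @return For `"absolute"`: data.frame (channel, freq_hz, cell, mean, sd,
#'   n). For `"relative"`: the stimulus-level measure table with a `cell`
#'   column.
#' @export
aggregate_features <- function(features, by = "text_type",
                               level = c("absolute", "relative"),
                               metadata = NULL) {
  level <- match.arg(level)
  stopifnot(nrow(features) > 0)
  if (by == "text_type") {
    cell <- features$text_type
  } else {
    if (!by %in% names(metadata_levels()))
      stop("unknown grouping variable: ", by)
    if (is.null(metadata)) stop("metadata required for grouping by ", by)
    cell <- metadata[[by]][match(features$participant_id,
                                 metadata$participant_id)]
  }
  if (level == "relative") {
    keep <- c("participant_id", "stimulus_id", "text_type", "channel",
              grep("^rel_|^brain_rate", names(features), value = TRUE))
    out <- features[, keep]
    out$cell <- cell
    return(out)
  }
  psd_cols <- grep("^psd_", names(features), value = TRUE)
  long <- list()
  for (cl in unique(cell)) {
    sub <- features[cell == cl, , drop = FALSE]
    # within-participant means first
    pc <- lapply(split(sub, sub$participant_id), function(d) {
      m <- lapply(split(d, d$channel),
                  function(dc) colMeans(dc[, psd_cols, drop = FALSE]))
      do.call(rbind, m)
    })
    chs <- rownames(pc[[1]])
    arr <- simplify2array(pc)               # channel x bin x participant
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    mu <- apply(arr, c(1, 2), mean)
    sdv <- apply(arr, c(1, 2), stats::sd)
    long[[cl]] <- data.frame(
      channel = rep(chs, times = length(psd_cols)),
      freq_hz = rep(as.numeric(sub("^psd_", "", psd_cols)),
                    each = length(chs)),
      cell = cl, mean = as.numeric(mu), sd = as.numeric(sdv),
      n = dim(arr)[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, long)
  rownames(out) <- NULL
  out
}
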
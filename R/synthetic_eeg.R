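# Synthetic reading-study EEG with known-truth band structure.
#
# Each stimulus segment is a sum of band-limited Gaussian oscillations (one
# per frequency band, synthesized in the frequency domain and rescaled so the
# realized band variance equals its target power exactly), a 1/f^a pink
# background, white sensor noise, and Poisson-scheduled blink and muscle
# transients. Condition and group effects multiply band powers
# (absolute_scale) or shift band-power fractions (relative_shift), and the
# same bookkeeping yields an analytic truth table for recovery tests.

#' Frequency band definitions
#'
#' The five conventional QEEG bands partitioning the 0.5-40 Hz passband, as
#' half-open intervals (low, high]. Centers are midpoints and drive the
#' brain-rate summary.
#'
#' @param edges numeric vector of 6 increasing edges (Hz).
#' @return data.frame with columns `name`, `low_hz`, `high_hz`, `center_hz`.
#' @export
band_specs <- function(edges = c(0.5, 4, 8, 13, 30, 40)) {
  stopifnot(length(edges) == 6, all(diff(edges) > 0))
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = edges[1:5], high_hz = edges[2:6],
             center_hz = (edges[1:5] + edges[2:6]) / 2,
             stringsAsFactors = FALSE)
}

#' Noise model for the generator
#'
#' @param pink_exponent spectral exponent of the 1/f^a background.
#' @param pink_scale_uv RMS of the pink background per channel (microvolts).
#' @param blink_rate_hz expected blink rate (events per second).
#' @param blink_amplitude_uv peak blink amplitude at Fp1/Fp2.
#' @param muscle_burst_rate_hz expected muscle-burst rate.
#' @param muscle_band_hz two-vector, burst frequency band (Hz).
#' @param muscle_amplitude_uv RMS of a burst at the temporal channels.
#' @param sensor_white_uv white sensor-noise RMS.
#' @export
noise_spec <- function(pink_exponent = 1.0, pink_scale_uv = 4,
                       blink_rate_hz = 0.2, blink_amplitude_uv = 80,
                       muscle_burst_rate_hz = 0.05,
                       muscle_band_hz = c(25, 45), muscle_amplitude_uv = 15,
                       sensor_white_uv = 1.5) {
  stopifnot(pink_scale_uv >= 0, blink_rate_hz >= 0, blink_amplitude_uv >= 0,
            muscle_burst_rate_hz >= 0, sensor_white_uv >= 0,
            length(muscle_band_hz) == 2, all(muscle_band_hz > 0))
  structure(list(pink_exponent = pink_exponent,
                 pink_scale_uv = pink_scale_uv,
                 blink_rate_hz = blink_rate_hz,
                 blink_amplitude_uv = blink_amplitude_uv,
                 muscle_burst_rate_hz = muscle_burst_rate_hz,
                 muscle_band_hz = muscle_band_hz,
                 muscle_amplitude_uv = muscle_amplitude_uv,
                 sensor_white_uv = sensor_white_uv),
            class = "noise_spec")
}

#' Injectable condition or group effect
#'
#' An effect targets either a text type (`target = "text_type"`) or a level of
#' a metadata grouping variable (`target` = the variable name), and modifies
#' band power on a channel subset. `absolute_scale` multiplies the band's
#' power by `magnitude`; `relative_shift` adds `magnitude` to the band's
#' power fraction and renormalizes the other bands at constant total power.
#'
#' @param target `"text_type"` or one of `names(metadata_levels())`.
#' @param level the text type or group level the effect applies to.
#' @param band band name from [band_specs()].
#' @param mode `"absolute_scale"` or `"relative_shift"`.
#' @param magnitude power multiplier (> 0) or signed fraction shift.
#' @param channel_subset channel labels, or `"all"`.
#' @export
effect_spec <- function(target, level, band, mode, magnitude,
                        channel_subset = "all") {
  stopifnot(mode %in% c("absolute_scale", "relative_shift"))
  if (mode == "absolute_scale" && magnitude <= 0)
    stop("absolute_scale magnitude must be > 0")
  ok_targets <- c("text_type", names(metadata_levels()))
  if (!target %in% ok_targets)
    stop("unknown effect target: ", target)
  structure(list(target = target, level = level, band = band, mode = mode,
                 magnitude = magnitude, channel_subset = channel_subset),
            class = "effect_spec")
}

#' Study design specification for the generator
#'
#' Defaults emulate the reading study: 40 participants, 15 trials of the
#' 10-stimulus pattern (4 originals, 1 fanfiction, 4 originals, 1 badfiction),
#' hence 150 stimuli per participant (120/15/15), a 32-channel montage at
#' 500 Hz, and the reported group sizes for the five metadata variables.
#' Stimulus durations are drawn uniformly from `stimulus_duration_s` (a
#' plausible reading-time range for a 40-word text).
#'
#' @param n_participants,n_trials design size.
#' @param trial_pattern character vector of text types making up one trial.
#' @param stimulus_duration_s length-2 range (s), or a single fixed duration.
#' @param sampling_rate_hz sampling rate.
#' @param montage an [montage()].
#' @param bands a [band_specs()] table.
#' @param noise a [noise_spec()].
#' @param effects list of [effect_spec()] objects.
#' @param group_sizes named list; for each metadata variable a named vector of
#'   level counts (remainder of participants goes to `rest`).
#' @param participant_sd lognormal sd of per-participant band-amplitude
#'   factors (between-subject variability).
#' @param baseline_uv optional override of the baseline band RMS amplitudes
#'   (microvolts): a named vector over bands (applied to all channels) or a
#'   full bands x channels matrix. `NULL` selects the built-in
#'   posterior-alpha resting topography.
#' @param seed master seed; every stochastic step derives from it.
#' @export
design_spec <- function(n_participants = 40, n_trials = 15,
                        trial_pattern = c("original", "original", "original",
                                          "original", "fanfiction",
                                          "original", "original", "original",
                                          "original", "badfiction"),
                        stimulus_duration_s = c(8, 15),
                        sampling_rate_hz = 500,
                        montage = default_montage(),
                        bands = band_specs(),
                        noise = noise_spec(),
                        effects = list(),
                        group_sizes = list(
                          reading_frequency = c(frequent = 10,
                                                non_frequent = 10),
                          literary_familiarity = c(buff = 12, rookie = 14),
                          fantasy_reader = c(fantasy = 26, non_fantasy = 14),
                          hp_fan = c(fan = 17, non_fan = 23),
                          badfiction_attitude = c(positive = 9,
                                                  negative = 8)),
                        participant_sd = 0.08,
                        baseline_uv = NULL,
                        seed = 1L) {
  stopifnot(n_participants >= 1, n_trials >= 0,
            all(trial_pattern %in% text_types()))
  if (length(stimulus_duration_s) == 1)
    stimulus_duration_s <- rep(stimulus_duration_s, 2)
  for (v in names(group_sizes)) {
    if (!v %in% names(metadata_levels())) stop("unknown group variable: ", v)
    if (sum(group_sizes[[v]]) > n_participants)
      stop("group sizes for ", v, " exceed n_participants")
  }
  for (ef in effects) .validate_effect(ef, montage, bands)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 trial_pattern = trial_pattern,
                 stimulus_duration_s = stimulus_duration_s,
                 sampling_rate_hz = sampling_rate_hz, montage = montage,
                 bands = bands, noise = noise, effects = effects,
                 group_sizes = group_sizes,
                 participant_sd = participant_sd,
                 baseline_uv = baseline_uv,
                 seed = as.integer(seed)),
            class = "design_spec")
}

.validate_effect <- function(ef, montage, bands) {
  if (!ef$band %in% bands$name)
    stop("effect references unknown band: ", ef$band)
  if (!identical(ef$channel_subset, "all")) {
    miss <- setdiff(ef$channel_subset, montage$channel_names)
    if (length(miss)) stop("effect references unknown channel(s): ",
                           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

# run expr under a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# per-participant substreams so adding participants never perturbs earlier
# ones; kept below 2^31
derive_seed <- function(master, idx, stream = 0L) {
  as.integer((as.double(master) * 48271 + idx * 30269 +
              stream * 104729) %% 2147483629)
}

#' Generate the experimental design
#'
#' Assigns group labels by a seeded shuffle honoring the design's group
#' sizes, and lays out each participant's stimulus schedule: `n_trials`
#' repeats of the trial pattern with stimulus identities randomized within
#' text type and durations drawn from the design range.
#'
#' @param spec a [design_spec()].
#' @return list with `metadata` (a [participant_metadata()] table) and
#'   `schedules` (named list of per-participant data.frames with columns
#'   `slot`, `trial_index`, `text_type`, `stimulus_id`, `duration_s`).
#' @export
generate_design <- function(spec) {
  n <- spec$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  meta <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  lev <- metadata_levels()
  for (v in names(lev)) {
    lab <- rep("rest", n)
    sizes <- spec$group_sizes[[v]]
    if (is.null(sizes) && !"rest" %in% lev[[v]]) {
      # binary variable without stated sizes: split as evenly as possible
      sizes <- stats::setNames(c(floor(n / 2), n - floor(n / 2)),
                               lev[[v]][1:2])
    }
    if (!is.null(sizes)) {
      ord <- with_seed(derive_seed(spec$seed, 0L, match(v, names(lev))),
                       sample.int(n))
      pos <- 1L
      for (g in names(sizes)) {
        k <- sizes[[g]]
        if (k > 0) lab[ord[pos:(pos + k - 1)]] <- g
        pos <- pos + k
      }
    }
    meta[[v]] <- lab
  }
  meta <- participant_metadata(meta)

  pat <- spec$trial_pattern
  n_stim <- spec$n_trials * length(pat)
  type_seq <- rep(pat, times = spec$n_trials)
  n_per_type <- table(factor(type_seq, levels = text_types()))
  schedules <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    schedules[[i]] <- with_seed(derive_seed(spec$seed, i, 1L), {
      sid <- character(n_stim)
      for (tt in text_types()) {
        k <- n_per_type[[tt]]
        if (k > 0)
          sid[type_seq == tt] <- sprintf("%s_%03d", substr(tt, 1, 4),
                                         sample.int(k))
      }
      dur <- stats::runif(max(n_stim, 1), spec$stimulus_duration_s[1],
                          spec$stimulus_duration_s[2])[seq_len(n_stim)]
      data.frame(slot = seq_len(n_stim),
                 trial_index = rep(seq_len(spec$n_trials),
                                   each = length(pat)),
                 text_type = type_seq, stimulus_id = sid,
                 duration_s = dur, stringsAsFactors = FALSE)
    })
  }
  list(metadata = meta, schedules = schedules)
}

# baseline band RMS amplitudes (microvolts) per channel: posterior-dominant
# alpha, mild frontal delta/theta emphasis -- a generic resting topography
.baseline_amplitudes <- function(montage, bands, override = NULL) {
  ch <- montage$channel_names
  if (!is.null(override)) {
    if (is.matrix(override)) {
      stopifnot(nrow(override) == nrow(bands),
                ncol(override) == length(ch))
      dimnames(override) <- list(bands$name, ch)
      return(override)
    }
    stopifnot(all(bands$name %in% names(override)))
    return(matrix(override[bands$name], nrow(bands), length(ch),
                  dimnames = list(bands$name, ch)))
  }
  post <- grepl("^(P|O|CP|TP)", ch)
  front <- grepl("^(F|Fp|FC|FT)", ch)
  A <- matrix(0, nrow(bands), length(ch),
              dimnames = list(bands$name, ch))
  A["delta", ] <- 4.0 * ifelse(front, 1.2, 1.0)
  A["theta", ] <- 3.0 * ifelse(front, 1.1, 1.0)
  A["alpha", ] <- 5.0 * ifelse(post, 1.6, 1.0)
  A["beta", ]  <- 2.0
  A["gamma", ] <- 1.0
  A
}

# per-participant lognormal band factors, deterministic given (seed, idx)
.participant_band_factors <- function(spec, idx) {
  with_seed(derive_seed(spec$seed, idx, 2L),
            exp(stats::rnorm(nrow(spec$bands), 0, spec$participant_sd)))
}

# apply effects to a bands x channels power matrix for one stimulus context
.effective_band_power <- function(P, effects, tt, meta_row, montage) {
  for (ef in effects) {
    applies <- if (ef$target == "text_type") identical(tt, ef$level)
               else identical(meta_row[[ef$target]], ef$level)
    if (!applies) next
    cols <- if (identical(ef$channel_subset, "all"))
      seq_len(ncol(P)) else match(ef$channel_subset, colnames(P))
    if (ef$mode == "absolute_scale") {
      P[ef$band, cols] <- P[ef$band, cols] * ef$magnitude
    } else {
      for (j in cols) {
        tot <- sum(P[, j])
        rel <- P[, j] / tot
        s <- ef$magnitude
        new_b <- rel[ef$band] + s
        if (new_b <= 0 || new_b >= 1)
          stop("relative_shift pushes band fraction outside (0,1)")
        scale_others <- (1 - new_b) / (1 - rel[ef$band])
        rel <- rel * scale_others
        rel[ef$band] <- new_b
        P[, j] <- rel * tot
      }
    }
  }
  P
}

# band-limited unit-variance Gaussian noise, n x nch, exact per-column scaling
.rand_bandlimited <- function(n, nch, fs, low, high) {
  n2 <- floor(n / 2)
  freqs <- (1:(n2 - 1)) * fs / n
  sel <- which(freqs > low & freqs <= high)
  if (!length(sel)) sel <- which.min(abs(freqs - (low + high) / 2))
  S <- matrix(0 + 0i, n, nch)
  z <- matrix(stats::rnorm(length(sel) * nch), length(sel), nch) +
    1i * matrix(stats::rnorm(length(sel) * nch), length(sel), nch)
  S[sel + 1, ] <- z
  S[n - sel + 1, ] <- Conj(z)
  x <- Re(stats::mvfft(S, inverse = TRUE)) / n
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(x, 2, sdv, "/")
}

# pink 1/f^a noise, n x nch, unit variance columns
.rand_pink <- function(n, nch, fs, exponent) {
  n2 <- floor(n / 2)
  freqs <- (1:(n2 - 1)) * fs / n
  amp <- freqs^(-exponent / 2)
  S <- matrix(0 + 0i, n, nch)
  z <- (matrix(stats::rnorm((n2 - 1) * nch), n2 - 1, nch) +
        1i * matrix(stats::rnorm((n2 - 1) * nch), n2 - 1, nch)) * amp
  S[2:n2, ] <- z
  S[n - (1:(n2 - 1)) + 1, ] <- Conj(z)
  x <- Re(stats::mvfft(S, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

.blink_weights <- function(ch) {
  w <- rep(0.05, length(ch)); names(w) <- ch
  w[ch %in% c("Fp1", "Fp2")] <- 1
  w[ch %in% c("F7", "F8")] <- 0.6
  w[ch %in% c("F3", "F4", "Fz")] <- 0.5
  w[ch %in% c("FC1", "FC2", "FC5", "FC6")] <- 0.25
  w
}

.muscle_weights <- function(ch) {
  w <- rep(0.05, length(ch)); names(w) <- ch
  w[ch %in% c("T7", "T8")] <- 1
  w[ch %in% c("FT9", "FT10")] <- 0.8
  w[ch %in% c("TP9", "TP10")] <- 0.6
  w
}

#' Synthesize one participant's recording
#'
#' Concatenates one segment per scheduled stimulus. Within a segment, each
#' band contributes band-limited Gaussian noise whose variance equals the
#' participant's effective band power (baseline topography x participant
#' factor x all applicable effects); pink background, sensor noise, blinks
#' (frontal-dominant low-frequency transients) and muscle bursts
#' (temporal-dominant high-frequency) are added on top. Deterministic given
#' the design seed.
#'
#' @param meta_row single row of the design's metadata table.
#' @param schedule that participant's schedule from [generate_design()].
#' @param spec the [design_spec()].
#' @return An `eeg_recording` with one event per stimulus.
#' @export
synthesize_recording <- function(meta_row, schedule, spec) {
  stopifnot(nrow(meta_row) == 1)
  idx <- as.integer(sub("^P", "", meta_row$participant_id))
  fs <- spec$sampling_rate_hz
  ch <- spec$montage$channel_names
  nch <- length(ch)
  pf <- .participant_band_factors(spec, idx)
  A2base <- (.baseline_amplitudes(spec$montage, spec$bands, spec$baseline_uv) * pf)^2
  ns <- spec$noise
  segs <- vector("list", nrow(schedule))
  with_seed(derive_seed(spec$seed, idx, 3L), {
    for (s in seq_len(nrow(schedule))) {
      n <- round(schedule$duration_s[s] * fs)
      P <- .effective_band_power(A2base, spec$effects,
                                 schedule$text_type[s], meta_row,
                                 spec$montage)
      x <- matrix(0, n, nch)
      for (b in seq_len(nrow(spec$bands))) {
        xb <- .rand_bandlimited(n, nch, fs, spec$bands$low_hz[b],
                                spec$bands$high_hz[b])
        x <- x + sweep(xb, 2, sqrt(P[b, ]), "*")
      }
      if (ns$pink_scale_uv > 0)
        x <- x + .rand_pink(n, nch, fs, ns$pink_exponent) * ns$pink_scale_uv
      if (ns$sensor_white_uv > 0)
        x <- x + matrix(stats::rnorm(n * nch, 0, ns$sensor_white_uv), n, nch)
      if (ns$blink_rate_hz > 0 && ns$blink_amplitude_uv > 0) {
        nb <- stats::rpois(1, ns$blink_rate_hz * n / fs)
        if (nb > 0) {
          w <- .blink_weights(ch)
          len <- round(0.4 * fs)
          pulse <- ns$blink_amplitude_uv *
            sin(pi * seq_len(len) / (len + 1))^2
          for (k in seq_len(nb)) {
            at <- sample.int(max(n - len, 1), 1)
            ii <- at:min(at + len - 1, n)
            x[ii, ] <- x[ii, ] + outer(pulse[seq_along(ii)], w)
          }
        }
      }
      if (ns$muscle_burst_rate_hz > 0 && ns$muscle_amplitude_uv > 0) {
        nb <- stats::rpois(1, ns$muscle_burst_rate_hz * n / fs)
        if (nb > 0) {
          w <- .muscle_weights(ch)
          len <- round(0.5 * fs)
          taper <- sin(pi * seq_len(len) / (len + 1))^2
          for (k in seq_len(nb)) {
            burst <- .rand_bandlimited(len, 1, fs, ns$muscle_band_hz[1],
                                       min(ns$muscle_band_hz[2],
                                           fs / 2 - 1))[, 1] *
              taper * ns$muscle_amplitude_uv
            at <- sample.int(max(n - len, 1), 1)
            ii <- at:min(at + len - 1, n)
            x[ii, ] <- x[ii, ] + outer(burst[seq_along(ii)], w)
          }
        }
      }
      segs[[s]] <- x
    }
  })
  samples <- t(do.call(rbind, segs))
  onsets <- cumsum(c(0, vapply(segs, nrow, 0L)))[seq_len(nrow(schedule))] / fs
  ev <- stimulus_events(onset_s = onsets,
                        duration_s = vapply(segs, nrow, 0L) / fs,
                        stimulus_id = schedule$stimulus_id,
                        text_type = schedule$text_type,
                        trial_index = schedule$trial_index)
  recording(meta_row$participant_id, samples, spec$montage, fs, ev)
}

#' Analytic expected band powers (generator truth)
#'
#' The absolute and relative band powers implied by the baseline topography,
#' per-participant factors, and all effects -- before noise. Recovery tests
#' compare measured spectra against this table.
#'
#' @param spec a [design_spec()].
#' @param design optional output of [generate_design()] (regenerated from
#'   `spec` when omitted).
#' @return data.frame with one row per (participant, text_type, channel,
#'   band): `band_abs_uv2` (expected band power) and `band_rel`.
#' @export
truth_table <- function(spec, design = generate_design(spec)) {
  meta <- design$metadata
  ch <- spec$montage$channel_names
  out <- vector("list", nrow(meta) * length(text_types()))
  k <- 0L
  for (i in seq_len(nrow(meta))) {
    idx <- as.integer(sub("^P", "", meta$participant_id[i]))
    pf <- .participant_band_factors(spec, idx)
    A2 <- (.baseline_amplitudes(spec$montage, spec$bands, spec$baseline_uv) * pf)^2
    for (tt in text_types()) {
      P <- .effective_band_power(A2, spec$effects, tt, meta[i, ],
                                 spec$montage)
      R <- sweep(P, 2, colSums(P), "/")
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = meta$participant_id[i], text_type = tt,
        channel = rep(ch, each = nrow(spec$bands)),
        band = rep(spec$bands$name, times = length(ch)),
        band_abs_uv2 = as.numeric(P), band_rel = as.numeric(R),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
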
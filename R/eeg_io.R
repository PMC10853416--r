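# Recording data model and on-disk formats (native fixture, BrainVision, EDF,
# TSV feature tables). All potentials are microvolts; all times are seconds
# from recording start; stimulus intervals are half-open [onset, onset+dur).

#' The three text-type labels
#'
#' Reading conditions distinguished throughout the pipeline: excerpts from the
#' original novels, conventional fanfiction, and deliberately badly written
#' fanfiction ("badfiction").
#' @export
text_types <- function() c("original", "fanfiction", "badfiction")

.default_channels <- c(
  "Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
  "FT9", "FT10", "Cz", "C3", "C4", "T7", "T8", "CP1", "CP2", "CP5", "CP6",
  "TP9", "TP10", "Pz", "P3", "P4", "P7", "P8", "Oz", "O1", "O2")

#' Electrode montage
#'
#' An ordered set of 10/10-system electrode labels plus reference and ground.
#' The default is the 32-channel reading-study montage.
#'
#' @param channel_names character vector of unique electrode labels.
#' @param reference_label,ground_label single labels for the reference and
#'   ground electrodes (not part of `channel_names`).
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(channel_names = .default_channels,
                    reference_label = "FCz", ground_label = "Fpz") {
  stopifnot(is.character(channel_names), length(channel_names) >= 1)
  if (anyDuplicated(channel_names))
    stop("montage channel names must be unique")
  structure(list(channel_names = channel_names,
                 reference_label = reference_label,
                 ground_label = ground_label),
            class = "eeg_montage")
}

#' @rdname montage
#' @export
default_montage <- function() montage()

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_names), " channels; ref ",
      x$reference_label, ", gnd ", x$ground_label, "\n", sep = "")
  cat(" ", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

#' Stimulus event annotations
#'
#' Builds and validates the event table attached to a recording: one row per
#' stimulus presentation.
#'
#' @param onset_s onset in seconds from recording start (non-negative).
#' @param duration_s stimulus duration in seconds (positive).
#' @param stimulus_id stimulus identifier.
#' @param text_type one of `text_types()`.
#' @param trial_index 1-based trial number the stimulus belongs to.
#' @return A `data.frame` sorted by onset.
#' @export
stimulus_events <- function(onset_s = numeric(), duration_s = numeric(),
                            stimulus_id = character(), text_type = character(),
                            trial_index = integer()) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   stimulus_id = as.character(stimulus_id),
                   text_type = as.character(text_type),
                   trial_index = as.integer(trial_index),
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    stopifnot(all(ev$onset_s >= 0), all(ev$duration_s > 0))
    if (!all(ev$text_type %in% text_types()))
      stop("text_type must be one of: ", paste(text_types(), collapse = ", "))
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' EEG recording container
#'
#' One participant's continuous multichannel EEG: a channels-by-time matrix of
#' potentials in microvolts plus montage, sampling rate and stimulus events.
#'
#' @param participant_id participant identifier.
#' @param samples numeric matrix, channels x time, microvolts. Row order must
#'   match the montage channel order.
#' @param montage an [montage()] object.
#' @param sampling_rate_hz sampling rate in Hz (default 500).
#' @param events event table from [stimulus_events()].
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(participant_id, samples, montage = default_montage(),
                      sampling_rate_hz = 500,
                      events = stimulus_events()) {
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (nrow(samples) != length(montage$channel_names))
    stop("samples has ", nrow(samples), " rows but montage has ",
         length(montage$channel_names), " channels")
  stopifnot(sampling_rate_hz > 80)  # > 2 x highest analysis frequency (40 Hz)
  rownames(samples) <- montage$channel_names
  dur <- ncol(samples) / sampling_rate_hz
  events <- stimulus_events(events$onset_s, events$duration_s,
                            events$stimulus_id, events$text_type,
                            events$trial_index)
  if (nrow(events) && any(events$onset_s + events$duration_s > dur + 1e-9))
    stop("event extends past end of recording (duration ", dur, " s)")
  structure(list(participant_id = as.character(participant_id),
                 montage = montage,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 samples = samples, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> participant ", x$participant_id, ": ",
      nrow(x$samples), " ch x ", ncol(x$samples), " samples @ ",
      x$sampling_rate_hz, " Hz (", round(ncol(x$samples) /
      x$sampling_rate_hz, 1), " s), ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$sampling_rate_hz

#' Extract channel rows by montage label
#'
#' All downstream indexing into the sample matrix resolves through montage
#' labels, never raw row positions.
#' @param rec an `eeg_recording`.
#' @param labels channel labels to extract.
#' @return numeric matrix, `length(labels)` x time.
#' @export
channel_data <- function(rec, labels) {
  miss <- setdiff(labels, rec$montage$channel_names)
  if (length(miss)) stop("unknown channel label(s): ",
                         paste(miss, collapse = ", "))
  rec$samples[labels, , drop = FALSE]
}

#' Participant metadata table
#'
#' Validates per-participant grouping variables: reading frequency, literary
#' familiarity and badfiction attitude admit a `rest` level excluded from the
#' group analyses; fantasy readership and fandom are binary.
#'
#' @param df data.frame with columns `participant_id`, `reading_frequency`
#'   (frequent / non_frequent / rest), `literary_familiarity` (buff / rookie /
#'   rest), `fantasy_reader` (fantasy / non_fantasy), `hp_fan` (fan / non_fan),
#'   `badfiction_attitude` (positive / negative / rest).
#' @return The validated data.frame.
#' @export
participant_metadata <- function(df) {
  need <- c("participant_id", "reading_frequency", "literary_familiarity",
            "fantasy_reader", "hp_fan", "badfiction_attitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  lev <- metadata_levels()
  for (v in names(lev)) {
    bad <- setdiff(unique(df[[v]]), lev[[v]])
    if (length(bad)) stop("invalid level(s) for ", v, ": ",
                          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$participant_id)) stop("duplicate participant_id")
  df
}

#' Grouping variables and their levels
#'
#' The two analysis levels for each of the five grouping variables, in the
#' order (level_a, level_b) used for group comparisons; a third `rest` level,
#' where present, is excluded from analysis.
#' @export
metadata_levels <- function() {
  list(reading_frequency    = c("frequent", "non_frequent", "rest"),
       literary_familiarity = c("buff", "rookie", "rest"),
       fantasy_reader       = c("fantasy", "non_fantasy"),
       hp_fan               = c("fan", "non_fan"),
       badfiction_attitude  = c("positive", "negative", "rest"))
}

## ---------------------------------------------------------------- native ----

#' Write / read the native two-file recording fixture
#'
#' A JSON sidecar (`<prefix>.json`: montage, rate, events, participant) plus a
#' flat little-endian 32-bit float binary (`<prefix>.dat`, channel-major: all
#' samples of channel 1, then channel 2, ...).
#'
#' @param rec an `eeg_recording`.
#' @param prefix path prefix without extension.
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, prefix) {
  meta <- list(participant_id = rec$participant_id,
               sampling_rate_hz = rec$sampling_rate_hz,
               n_samples = ncol(rec$samples),
               channel_names = rec$montage$channel_names,
               reference_label = rec$montage$reference_label,
               ground_label = rec$montage$ground_label,
               events = rec$events)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  jpath <- paste0(prefix, ".json"); dpath <- paste0(prefix, ".dat")
  for (p in c(jpath, dpath))
    if (!file.exists(p)) stop("missing file: ", p)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  nch <- length(meta$channel_names); nt <- meta$n_samples
  con <- file(dpath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = nch * nt, size = 4, endian = "little")
  if (length(raw) != nch * nt)
    stop("truncated .dat file: expected ", nch * nt, " samples, got ",
         length(raw))
  samples <- matrix(raw, nrow = nch, byrow = TRUE)
  ev <- meta$events
  if (is.null(ev) || !length(ev)) ev <- stimulus_events()
  recording(meta$participant_id, samples,
            montage(meta$channel_names, meta$reference_label,
                    meta$ground_label),
            meta$sampling_rate_hz,
            stimulus_events(ev$onset_s, ev$duration_s, ev$stimulus_id,
                            ev$text_type, ev$trial_index))
}

## ------------------------------------------------------------ BrainVision ----

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the `.vmrk` marker file and the binary `.eeg`
#' data (IEEE float 32 or signed 16-bit int, multiplexed). Markers whose
#' description parses as `texttype/stimulus_id/trial` become stimulus events.
#' Values are scaled to microvolts using each channel's resolution field.
#'
#' @param header_path path to the `.vhdr` file.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("missing file: ", header_path)
  hdr <- readLines(header_path, warn = FALSE)
  kv <- .bv_keyvals(hdr)
  dir <- dirname(header_path)
  data_path <- file.path(dir, kv[["DataFile"]])
  mark_path <- file.path(dir, kv[["MarkerFile"]])
  if (!file.exists(data_path)) stop("missing file: ", data_path)
  if (!file.exists(mark_path)) stop("missing file: ", mark_path)
  if (toupper(kv[["DataFormat"]]) != "BINARY" ||
      toupper(kv[["DataOrientation"]]) != "MULTIPLEXED")
    stop("unsupported BrainVision data layout: ", kv[["DataFormat"]], "/",
         kv[["DataOrientation"]])
  fmt <- toupper(kv[["BinaryFormat"]])
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported BinaryFormat: ", fmt)
  nch <- as.integer(kv[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["SamplingInterval"]])  # interval is microseconds
  chlines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  chparts <- strsplit(sub("^Ch[0-9]+=", "", chlines), ",")
  labels <- vapply(chparts, `[`, "", 1)
  resol <- vapply(chparts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  stopifnot(length(labels) == nch)
  sz <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n <- file.size(data_path) / sz
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32")
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  else
    readBin(con, "integer", n = n, size = 2, signed = TRUE,
            endian = "little")
  samples <- matrix(raw, nrow = nch) * resol  # multiplexed: channels fastest
  mk <- readLines(mark_path, warn = FALSE)
  mklines <- grep("^Mk[0-9]+=", mk, value = TRUE)
  ev <- list()
  for (ln in mklines) {
    p <- strsplit(sub("^Mk[0-9]+=", "", ln), ",")[[1]]
    if (length(p) < 4 || p[1] != "Stimulus") next
    lab <- strsplit(p[2], "/", fixed = TRUE)[[1]]
    if (length(lab) != 3 || !lab[1] %in% text_types()) next
    ev[[length(ev) + 1]] <- data.frame(
      onset_s = (as.numeric(p[3]) - 1) / fs,
      duration_s = as.numeric(p[4]) / fs,
      stimulus_id = lab[2], text_type = lab[1],
      trial_index = as.integer(lab[3]), stringsAsFactors = FALSE)
  }
  ev <- if (length(ev)) do.call(rbind, ev) else stimulus_events()
  pid <- sub("\\.vhdr$", "", basename(header_path))
  recording(pid, samples, montage(labels), fs,
            stimulus_events(ev$onset_s, ev$duration_s, ev$stimulus_id,
                            ev$text_type, ev$trial_index))
}

.bv_keyvals <- function(lines) {
  lines <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^;", lines)]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

#' Write a BrainVision triplet for a recording
#'
#' Emits `<prefix>.vhdr`, `<prefix>.vmrk`, `<prefix>.eeg` (IEEE float 32,
#' multiplexed, resolution 1 microvolt) so that [read_brainvision()] inverts
#' the write.
#' @param rec an `eeg_recording`.
#' @param prefix path prefix without extension.
#' @export
write_brainvision <- function(rec, prefix) {
  base <- basename(prefix)
  fs <- rec$sampling_rate_hz
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$samples)),
           paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$samples)),
                   rec$montage$channel_names))
  writeLines(hdr, paste0(prefix, ".vhdr"))
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events)) {
    ev <- rec$events
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s/%s/%d,%d,%d,0",
                        seq_len(nrow(ev)) + 1L,
                        ev$text_type, ev$stimulus_id, ev$trial_index,
                        round(ev$onset_s * fs) + 1L,
                        round(ev$duration_s * fs)))
  }
  writeLines(mk, paste0(prefix, ".vmrk"))
  con <- file(paste0(prefix, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  invisible(prefix)
}

## -------------------------------------------------------------------- EDF ----

#' Write a recording as EDF+
#'
#' 16-bit EDF with one data record per second and an `EDF Annotations` signal
#' carrying stimulus events as `texttype/stimulus_id/trial` labels. The
#' recording is zero-padded to a whole number of records. The physical range
#' is set symmetrically from the data maximum, so quantization error is
#' bounded by `physmax / 32767`.
#'
#' @param rec an `eeg_recording`; sampling rate must be a whole number.
#' @param path output path.
#' @return The quantization step (microvolts per digital unit), invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate_hz
  stopifnot(fs == round(fs))
  nch <- nrow(rec$samples)
  nrec <- ceiling(ncol(rec$samples) / fs)
  x <- rec$samples
  if (ncol(x) < nrec * fs)
    x <- cbind(x, matrix(0, nch, nrec * fs - ncol(x)))
  physmax <- ceiling(max(1e-6, max(abs(x))) * 100) / 100  # as stored (2 dp)
  dig <- round(x / physmax * 32767)
  # annotation TALs, one batch per record holding its onsets; each TAL is
  # NUL-terminated at write time (NUL cannot live in an R string)
  tal_rec <- lapply(seq_len(nrec),
                    function(r) sprintf("+%d\x14\x14", r - 1L))
  if (nrow(rec$events)) {
    ev <- rec$events
    for (i in seq_len(nrow(ev))) {
      r <- min(nrec, floor(ev$onset_s[i]) + 1L)
      tal_rec[[r]] <- c(tal_rec[[r]],
        sprintf("+%.4f\x15%.4f\x14%s/%s/%d\x14",
                ev$onset_s[i], ev$duration_s[i], ev$text_type[i],
                ev$stimulus_id[i], ev$trial_index[i]))
    }
  }
  tal_raw <- lapply(tal_rec, function(tals)
    unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0)))))
  ann_n <- ceiling((max(lengths(tal_raw)) + 1) / 2)  # 2-byte samples
  pad8 <- function(v) formatC(v, width = 8, flag = "-")
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  ns <- nch + 1L
  hdr <- paste0(
    pad8("0"), pad(rec$participant_id, 80), pad("readspectra", 80),
    "01.01.26", "00.00.00", pad8(256 * (ns + 1)), pad(" ", 44),
    pad8(nrec), pad8(1), formatC(ns, width = 4, flag = "-"))
  labels <- c(substr(paste0("EEG ", rec$montage$channel_names), 1, 16),
              "EDF Annotations")
  sig <- paste0(
    paste0(vapply(labels, pad, "", w = 16), collapse = ""),
    paste0(rep(pad(" ", 80), ns), collapse = ""),
    paste0(vapply(c(rep("uV", nch), " "), pad8, ""), collapse = ""),
    paste0(vapply(c(rep(sprintf("%.2f", -physmax), nch), "-1"), pad8, ""),
           collapse = ""),
    paste0(vapply(c(rep(sprintf("%.2f", physmax), nch), "1"), pad8, ""),
           collapse = ""),
    paste0(vapply(c(rep("-32767", nch), "-32768"), pad8, ""), collapse = ""),
    paste0(vapply(c(rep("32767", nch), "32767"), pad8, ""), collapse = ""),
    paste0(rep(pad(" ", 80), ns), collapse = ""),
    paste0(vapply(c(rep(as.character(fs), nch), as.character(ann_n)),
                  pad8, ""), collapse = ""),
    paste0(rep(pad(" ", 32), ns), collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
    tal <- tal_raw[[r]]
    writeBin(c(tal, raw(2 * ann_n - length(tal))), con)
  }
  invisible(physmax / 32767)
}

#' Read an EDF/EDF+ recording
#'
#' Annotations whose label parses as `texttype/stimulus_id/trial` are mapped
#' to stimulus events; other annotations are ignored.
#' @param path path to the EDF file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (bad magic): ", path)
  pid <- trimws(rd(80)); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  physmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  is_ann <- labels == "EDF Annotations"
  gain <- (physmax - physmin) / (digmax - digmin)
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        sig[[i]][[r]] <- readBin(con, "raw", 2 * nsamp[i])
      } else {
        d <- readBin(con, "integer", nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
        if (length(d) < nsamp[i]) stop("truncated EDF file: ", path)
        sig[[i]][[r]] <- physmin[i] + gain[i] * (d - digmin[i])
      }
    }
  }
  eeg_idx <- which(!is_ann)
  fs <- nsamp[eeg_idx[1]] / recdur
  samples <- do.call(rbind, lapply(eeg_idx, function(i)
    unlist(sig[[i]], use.names = FALSE)))
  ev <- list()
  for (i in which(is_ann)) {
    txt <- rawToChar(unlist(sig[[i]], use.names = FALSE)[
      unlist(sig[[i]], use.names = FALSE) != as.raw(0)])
    # parse +onset \x15 duration \x14 label \x14 sequences
    m <- gregexpr("\\+[0-9.]+\x15[0-9.]+\x14[^\x14\x15+]+\x14", txt)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      s <- substr(txt, m[j], m[j] + attr(m, "match.length")[j] - 1)
      p <- strsplit(s, "[\x14\x15]")[[1]]
      lab <- strsplit(p[3], "/", fixed = TRUE)[[1]]
      if (length(lab) != 3 || !lab[1] %in% text_types()) next
      ev[[length(ev) + 1]] <- data.frame(
        onset_s = as.numeric(sub("+", "", p[1], fixed = TRUE)),
        duration_s = as.numeric(p[2]), stimulus_id = lab[2],
        text_type = lab[1], trial_index = as.integer(lab[3]),
        stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(ev)) do.call(rbind, ev) else stimulus_events()
  chn <- sub("^EEG ", "", labels[eeg_idx])
  recording(pid, samples, montage(chn), fs,
            stimulus_events(ev$onset_s, ev$duration_s, ev$stimulus_id,
                            ev$text_type, ev$trial_index))
}

## --------------------------------------------------------- feature tables ----

#' Write / read spectral feature tables
#'
#' Tab-separated, one row per (participant, stimulus, channel): identifier
#' columns, PSD bins, absolute and relative band powers and brain rate, as
#' produced by [spectral_features()]. All feature rows must share one
#' frequency grid (the `psd_*` columns).
#'
#' @param features feature data.frame.
#' @param path file path.
#' @export
write_features_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_table
#' @export
read_features_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
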
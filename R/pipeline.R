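# End-to-end orchestration: simulate -> preprocess -> features -> stats ->
# SOM -> report, from one config, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles the stage configurations. Simulation mode (the default) drives
#' everything from the [design_spec()]; real-data mode reads recordings from
#' `input_paths` (native-fixture prefixes, `.vhdr` or `.edf` files) plus a
#' metadata TSV.
#'
#' @param design a [design_spec()].
#' @param filter a [filter_spec()].
#' @param window a [window_spec()].
#' @param som a [som_config()].
#' @param stats list of statistical settings: `alpha_anova`, `n_perm`,
#'   `q_fdr`, `cascade_unit` ("stimulus" or "participant"), `bh_pool`
#'   ("pooled" or "per_variable").
#' @param reject_z channel-rejection threshold ([reject_channels()]).
#' @param ica list: `enabled`, `threshold` (artifact-probability ladder
#'   0.85 / 0.80 / 0.75; explicit config, never auto-selected), `seed`.
#' @param som_drop_channels channels excluded from the SOM feature vector.
#' @param input_paths,metadata_path real-data inputs; leaving both `NULL`
#'   selects simulation mode.
#' @export
pipeline_config <- function(design = design_spec(),
                            filter = filter_spec(),
                            window = window_spec(),
                            som = som_config(),
                            stats = list(alpha_anova = 0.05,
                                         n_perm = 39999, q_fdr = 0.05,
                                         cascade_unit = "stimulus",
                                         bh_pool = "pooled"),
                            reject_z = 5,
                            ica = list(enabled = FALSE, threshold = 0.85,
                                       seed = 1),
                            som_drop_channels = character(),
                            input_paths = NULL, metadata_path = NULL) {
  if (xor(is.null(input_paths), is.null(metadata_path)))
    stop("real-data mode needs both input_paths and metadata_path")
  structure(list(design = design, filter = filter, window = window,
                 som = som, stats = stats, reject_z = reject_z, ica = ica,
                 som_drop_channels = som_drop_channels,
                 input_paths = input_paths, metadata_path = metadata_path),
            class = "pipeline_config")
}

#' Run the pipeline
#'
#' Executes the enabled stages in order and writes each stage's artifact
#' under `out_dir`: the feature table (`features.tsv`), ANOVA grid
#' (`anova_grid.tsv`), cascade results (`cascade.tsv`), the classification
#' report (`som_report.json`) and a run manifest (`manifest.json`) with the
#' config hash, seeds, counts and per-artifact digests. A `stats`- or
#' `som`-only rerun reuses `features.tsv` from a previous run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "preprocess", "features", "stats", "som")`.
#' @return the manifest, invisibly; components also returned in
#'   `$results`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "features",
                                    "stats", "som")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...)
    message(sprintf("[%s] %s", stage, paste0(...)))
  manifest <- list(started = format(Sys.time(), tz = "UTC"),
                   stages = stages,
                   seed = config$design$seed, counts = list(), log = list())
  results <- list()

  features <- NULL
  if (any(c("simulate", "preprocess", "features") %in% stages)) {
    if (is.null(config$input_paths)) {
      design <- generate_design(config$design)
      meta <- design$metadata
      log_line("simulate", nrow(meta), " participants, ",
               sum(vapply(design$schedules, nrow, 0L)), " stimuli")
      recs <- NULL
      feat_list <- vector("list", nrow(meta))
      for (i in seq_len(nrow(meta))) {
        rec <- synthesize_recording(meta[i, ], design$schedules[[i]],
                                    config$design)
        if ("preprocess" %in% stages) {
          rec <- apply_bandlimit(rec, config$filter)
          rj <- reject_channels(rec, config$reject_z)
          if (length(rj$rejected))
            log_line("preprocess", rec$participant_id, ": rejected ",
                     paste(rj$rejected, collapse = ","))
          rec <- rj$recording
          if (isTRUE(config$ica$enabled)) {
            ica <- decompose_ica(rec, seed = config$ica$seed)
            sc <- score_components(ica, rec$sampling_rate_hz)
            rm <- remove_artifacts(rec, ica, sc, config$ica$threshold)
            if (length(rm$removed))
              log_line("preprocess", rec$participant_id, ": removed ",
                       length(rm$removed), " ICA component(s)")
            rec <- rm$recording
          }
        }
        feat_list[[i]] <- spectral_features(rec, config$window,
                                            config$design$bands)
      }
      features <- do.call(rbind, feat_list)
    } else {
      meta <- participant_metadata(utils::read.delim(config$metadata_path,
                                                     stringsAsFactors = FALSE))
      feat_list <- lapply(config$input_paths, function(p) {
        rec <- if (grepl("\\.vhdr$", p)) read_brainvision(p)
               else if (grepl("\\.edf$", p)) read_edf(p)
               else read_recording(p)
        if ("preprocess" %in% stages) {
          rec <- apply_bandlimit(rec, config$filter)
          rec <- reject_channels(rec, config$reject_z)$recording
        }
        spectral_features(rec, config$window, config$design$bands)
      })
      features <- do.call(rbind, feat_list)
    }
    write_features_table(features, file.path(out_dir, "features.tsv"))
    manifest$counts$participants <- length(unique(features$participant_id))
    manifest$counts$stimulus_rows <-
      nrow(unique(features[, c("participant_id", "stimulus_id")]))
    log_line("features", nrow(features), " feature rows")
  } else {
    fpath <- file.path(out_dir, "features.tsv")
    if (!file.exists(fpath)) stop("no cached features at ", fpath)
    features <- read_features_table(fpath)
    if (is.null(config$input_paths))
      meta <- generate_design(config$design)$metadata
    else
      meta <- participant_metadata(utils::read.delim(config$metadata_path,
                                                     stringsAsFactors = FALSE))
  }

  if ("stats" %in% stages) {
    st <- config$stats
    grid <- anova_grid(features, n_perm = st$n_perm,
                       alpha = st$alpha_anova, seed = config$design$seed)
    utils::write.table(grid, file.path(out_dir, "anova_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cascade <- run_cascade(features, meta, q = st$q_fdr,
                           unit = st$cascade_unit, bh_pool = st$bh_pool)
    utils::write.table(cascade, file.path(out_dir, "cascade.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$anova_grid <- grid
    results$cascade <- cascade
    manifest$counts$anova_cells <- nrow(grid)
    manifest$counts$cascade_tests <- nrow(cascade)
    log_line("stats", sum(grid$significant), " significant grid cells; ",
             sum(cascade$p_passes_fdr), " cascade cells pass FDR")
  }

  if ("som" %in% stages) {
    keep_ch <- setdiff(unique(features$channel), config$som_drop_channels)
    fm <- som_feature_matrix(features, channels = keep_ch)
    rows <- data.frame(participant_id = fm$participant_id,
                       stringsAsFactors = FALSE)
    sp <- split_participant_holdout(rows, 0.7, seed = config$som$seed)
    tr <- rows$participant_id %in% unique(sp$train$participant_id)
    model <- train_som(fm$x[tr, , drop = FALSE], fm$labels[tr],
                       config$som)
    pred <- predict(model, fm$x[!tr, , drop = FALSE])
    report <- evaluate_classification(fm$labels[!tr], pred)
    jsonlite::write_json(
      list(confusion = as.data.frame.matrix(report$confusion),
           f1 = as.list(report$f1), accuracy = report$accuracy,
           train_rows = sum(tr), test_rows = sum(!tr)),
      file.path(out_dir, "som_report.json"), auto_unbox = TRUE,
      digits = NA)
    results$som_model <- model
    results$som_report <- report
    manifest$counts$som_train_rows <- sum(tr)
    manifest$counts$som_test_rows <- sum(!tr)
    log_line("som", "test accuracy ", round(report$accuracy, 3))
  }

  cfg_json <- jsonlite::serializeJSON(config)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  arts <- list.files(out_dir, pattern = "\\.(tsv|json)$",
                     full.names = TRUE)
  arts <- setdiff(arts, file.path(out_dir, "manifest.json"))
  manifest$artifacts <- as.list(tools::md5sum(arts))
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$results <- results
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Prints the significant (channel, frequency) runs of the grid analysis,
#' the FDR-passing cascade cells in a site / p / d layout, and the SOM
#' confusion matrix with per-class F1.
#'
#' @param manifest value returned by [run_pipeline()] (with `$results`).
#' @return the summary lines, invisibly.
#' @export
pipeline_report <- function(manifest) {
  res <- manifest$results
  lines <- c("== run summary ==",
             paste0("participants: ", manifest$counts$participants,
                    "; stimulus rows: ", manifest$counts$stimulus_rows))
  if (!is.null(res$anova_grid)) {
    runs <- significant_runs(res$anova_grid)
    lines <- c(lines, "-- significant condition effects (channel, Hz) --")
    lines <- c(lines, if (nrow(runs))
      sprintf("  %-5s %g-%g Hz (%d bins)", runs$channel, runs$from_hz,
              runs$to_hz, runs$n_bins) else "  none")
  }
  if (!is.null(res$cascade)) {
    sig <- res$cascade[res$cascade$p_passes_fdr, ]
    lines <- c(lines, "-- group differences passing FDR --")
    lines <- c(lines, if (nrow(sig))
      sprintf("  %-5s %-10s %-20s p=%.2e |d|=%.2f", sig$site, sig$measure,
              paste0(sig$variable, ":", sig$group_a, ">", sig$group_b),
              sig$p_raw, abs(sig$cohens_d)) else "  none")
  }
  if (!is.null(res$som_report)) {
    r <- res$som_report
    lines <- c(lines, "-- SOM test-set confusion --",
               utils::capture.output(print(r$confusion)),
               paste0("F1: ", paste(names(r$f1), sprintf("%.3f", r$f1),
                                    collapse = ", ")),
               sprintf("accuracy: %.3f", r$accuracy))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
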
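# From-scratch Kohonen self-organizing map on a hexagonal grid, with the
# participant-level holdout split and confusion-matrix / F1 metrics.

#' SOM training configuration
#'
#' Defaults follow the common convention for small maps: a 6 x 6 hexagonal
#' grid, 10,000 iterations, learning rate decaying linearly 0.05 -> 0.01,
#' and a bubble neighborhood whose radius starts at the 2/3 quantile of
#' pairwise unit distances (the "default radius" convention) and decays
#' linearly to `radius_end`.
#'
#' @param grid_rows,grid_cols grid size.
#' @param topology `"hexagonal"`.
#' @param n_iterations training iterations (default 10000).
#' @param lr_start,lr_end learning-rate schedule endpoints.
#' @param radius_start neighborhood radius start; `NULL` means the 2/3
#'   quantile of pairwise unit grid distances.
#' @param radius_end radius end (default 0: only the winning unit late in
#'   training).
#' @param neighborhood `"bubble"` (all units within the radius updated
#'   equally) or `"gaussian"`.
#' @param seed RNG seed for initialization and sample order.
#' @export
som_config <- function(grid_rows = 6, grid_cols = 6,
                       topology = "hexagonal", n_iterations = 10000,
                       lr_start = 0.05, lr_end = 0.01, radius_start = NULL,
                       radius_end = 0,
                       neighborhood = c("bubble", "gaussian"), seed = 1) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(grid_rows >= 1, grid_cols >= 1, topology == "hexagonal",
            n_iterations >= 1, lr_start > lr_end, lr_end >= 0)
  if (!is.null(radius_start)) stopifnot(radius_start > 0)
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 topology = topology, n_iterations = n_iterations,
                 lr_start = lr_start, lr_end = lr_end,
                 radius_start = radius_start, radius_end = radius_end,
                 neighborhood = neighborhood, seed = seed),
            class = "som_config")
}

# hexagonal unit coordinates: odd rows offset by half a unit
.som_grid <- function(rows, cols) {
  ij <- expand.grid(col = seq_len(cols) - 1, row = seq_len(rows) - 1)
  x <- ij$col + 0.5 * (ij$row %% 2)
  y <- ij$row * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Participant-level 70/30 holdout split
#'
#' Assigns whole participants to train or test so no participant straddles
#' the split, targeting `round(train_fraction * nrow(rows))` training rows.
#' A subset-sum dynamic program over per-participant row counts (with the
#' participant order shuffled under the seed, which randomizes which
#' participants realize the chosen size) finds the assignment whose
#' train-row count is closest to the target among all assignments that keep
#' at least one participant on each side. Warns when the target cannot be
#' hit exactly.
#'
#' @param rows data.frame of stimulus-level rows with a `participant_id`
#'   column.
#' @param train_fraction fraction of rows for training (default 0.7).
#' @param seed RNG seed.
#' @return list: `train`, `test` (row subsets), `target_train`,
#'   `achieved_train`.
#' @export
split_participant_holdout <- function(rows, train_fraction = 0.7, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(rows$participant_id)
  ids <- names(counts)
  np <- length(ids)
  if (np < 2)
    stop("need >= 2 participants to hold out at participant level")
  target <- round(train_fraction * nrow(rows))
  ord <- with_seed(seed, sample.int(np))
  cnt <- as.integer(counts)[ord]
  total <- sum(cnt)
  # 0/1 subset-sum dp over achievable train sums, tracking subset size so
  # neither side ends up empty; backpointers allow reconstruction
  nr <- total + 1L
  reach <- matrix(FALSE, nr, np + 1)          # row = sum + 1, col = size + 1
  reach[1, 1] <- TRUE
  pick <- matrix(NA_integer_, nr, np + 1)
  prev_row <- matrix(NA_integer_, nr, np + 1)
  prev_col <- matrix(NA_integer_, nr, np + 1)
  for (i in seq_len(np)) {
    for (k in rev(seq_len(i))) {             # sizes descending: item used once
      src <- reach[, k]
      if (!any(src)) next
      shifted <- c(rep(FALSE, cnt[i]), src[seq_len(nr - cnt[i])])
      new <- shifted & !reach[, k + 1]
      if (any(new)) {
        idx <- which(new)
        reach[idx, k + 1] <- TRUE
        pick[idx, k + 1] <- i
        prev_row[idx, k + 1] <- idx - cnt[i]
        prev_col[idx, k + 1] <- k
      }
    }
  }
  ok <- which(reach[, 2:np, drop = FALSE], arr.ind = TRUE)
  sums <- ok[, 1] - 1L
  best <- which.min(abs(sums - target))
  achieved <- sums[best]
  # reconstruct the chosen subset
  sel <- logical(np)
  r <- ok[best, 1]
  k <- ok[best, 2] + 1L
  while (k > 1) {
    i <- pick[r, k]
    sel[i] <- TRUE
    r2 <- prev_row[r, k]
    k <- prev_col[r, k]
    r <- r2
  }
  if (achieved != target)
    warning("train-row target ", target, " not reachable; achieved ",
            achieved)
  train_ids <- ids[ord][sel]
  list(train = rows[rows$participant_id %in% train_ids, , drop = FALSE],
       test = rows[!rows$participant_id %in% train_ids, , drop = FALSE],
       target_train = target, achieved_train = achieved)
}

#' Select the SOM feature columns of a feature table
#'
#' Per stimulus, the feature vector concatenates per-channel absolute band
#' powers, relative band powers and brain rate over the retained channels:
#' one wide row per stimulus.
#'
#' @param features stimulus-level [spectral_features()] rows.
#' @param channels channels to keep (default all present).
#' @param feature_set any of `"abs"`, `"rel"`, `"brain_rate"`.
#' @return list: `x` (numeric matrix, stimuli x features), `labels` (text
#'   type per stimulus), `participant_id`, `stimulus_id`.
#' @export
som_feature_matrix <- function(features,
                               channels = NULL,
                               feature_set = c("abs", "rel", "brain_rate")) {
  if (is.null(channels)) channels <- unique(features$channel)
  pat <- paste0("^(", paste(c(
    if ("abs" %in% feature_set) "abs_",
    if ("rel" %in% feature_set) "rel_",
    if ("brain_rate" %in% feature_set) "brain_rate"), collapse = "|"), ")")
  fcols <- grep(pat, names(features), value = TRUE)
  sub <- features[features$channel %in% channels, ]
  key <- paste(sub$participant_id, sub$stimulus_id, sep = "\r")
  ukey <- unique(key)
  blocks <- lapply(channels, function(ch) {
    d <- sub[sub$channel == ch, ]
    m <- as.matrix(d[match(ukey, paste(d$participant_id, d$stimulus_id,
                                       sep = "\r")), fcols, drop = FALSE])
    colnames(m) <- paste(ch, fcols, sep = ".")
    m
  })
  x <- do.call(cbind, blocks)
  first <- sub[match(ukey, key), ]
  list(x = x, labels = first$text_type,
       participant_id = first$participant_id,
       stimulus_id = first$stimulus_id)
}

#' Train a Kohonen self-organizing map
#'
#' Features are standardized (centers/scales stored in the model;
#' zero-variance features dropped with a warning) and the codebook is
#' initialized from a seeded sample of training rows. Each iteration draws
#' a training row, finds the best-matching unit (BMU) by Euclidean
#' distance, and moves every unit within the current grid radius of the BMU
#' toward the row by the current learning rate (bubble neighborhood; a
#' Gaussian kernel is available). After training, units are labeled by
#' majority vote of the training rows they capture.
#'
#' @param x numeric matrix, rows x features.
#' @param labels optional class label per row, used for unit labeling.
#' @param config a [som_config()].
#' @param scale standardize features before training (default `TRUE`).
#'   With `scale = FALSE` data enter the map as-is (centers 0, scales 1).
#' @return An object of class `som_model`.
#' @export
train_som <- function(x, labels = NULL, config = som_config(),
                      scale = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  nunits <- config$grid_rows * config$grid_cols
  if (nrow(x) < nunits)
    warning("fewer training rows (", nrow(x), ") than units (", nunits, ")")
  if (scale) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    keep <- scl > 0
    if (!all(keep)) {
      warning(sum(!keep), " zero-variance feature(s) dropped")
      x <- x[, keep, drop = FALSE]
      ctr <- ctr[keep]; scl <- scl[keep]
    }
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    names(ctr) <- names(scl) <- colnames(x)
  }
  Z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pos <- .som_grid(config$grid_rows, config$grid_cols)
  udist <- as.matrix(stats::dist(pos))
  r0 <- config$radius_start
  if (is.null(r0))
    r0 <- stats::quantile(udist[upper.tri(udist)], 2 / 3, names = FALSE)
  nit <- config$n_iterations
  frac <- (seq_len(nit) - 1) / max(nit - 1, 1)
  alphas <- config$lr_start + frac * (config$lr_end - config$lr_start)
  radii <- r0 + frac * (config$radius_end - r0)
  cb <- with_seed(config$seed, {
    init <- Z[sample.int(nrow(Z), nunits, replace = nrow(Z) < nunits), ,
              drop = FALSE]
    draw <- sample.int(nrow(Z), nit, replace = TRUE)
    rs <- rowSums(init^2)
    for (t in seq_len(nit)) {
      v <- Z[draw[t], ]
      bmu <- which.min(rs - 2 * drop(init %*% v))
      if (config$neighborhood == "bubble") {
        nb <- which(udist[bmu, ] <= radii[t] + 1e-12)
        init[nb, ] <- init[nb, ] + alphas[t] *
          (matrix(v, length(nb), length(v), byrow = TRUE) -
             init[nb, , drop = FALSE])
        rs[nb] <- rowSums(init[nb, , drop = FALSE]^2)
      } else {
        h <- alphas[t] * exp(-udist[bmu, ]^2 /
                               (2 * max(radii[t], 0.5)^2))
        init <- init + h * (matrix(v, nunits, length(v), byrow = TRUE) -
                              init)
        rs <- rowSums(init^2)
      }
    }
    init
  })
  model <- structure(list(config = config, codebook = cb, unit_pos = pos,
                          unit_dist = udist, center = ctr, scale = scl,
                          features = colnames(x),
                          unit_labels = rep(NA_character_, nunits)),
                     class = "som_model")
  if (!is.null(labels)) {
    bmus <- .som_bmu(model, Z, scaled = TRUE)
    for (u in seq_len(nunits)) {
      lab <- labels[bmus == u]
      if (length(lab)) {
        tab <- sort(table(lab), decreasing = TRUE)
        model$unit_labels[u] <- names(tab)[1]
      }
    }
  }
  model
}

.som_bmu <- function(model, x, scaled = FALSE) {
  Z <- if (scaled) x
       else sweep(sweep(x[, model$features, drop = FALSE], 2,
                        model$center), 2, model$scale, "/")
  cb <- model$codebook
  d2 <- outer(rowSums(Z^2), rowSums(cb^2), "+") - 2 * Z %*% t(cb)
  max.col(-d2, ties.method = "first")
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$config$grid_rows, "x", x$config$grid_cols,
      " hexagonal, ", length(x$features), " features, ",
      sum(!is.na(x$unit_labels)), "/", nrow(x$codebook),
      " labeled units\n", sep = "")
  invisible(x)
}

#' Predict text type with a trained SOM
#'
#' Each row maps to its best-matching unit's label. Rows landing on an
#' unlabeled (dead) unit are classified by the nearest *labeled* unit in
#' codebook (feature) space — i.e. the nearest labeled prototype to the row
#' itself — which keeps predictions anchored to the data geometry when the
#' map holds interstitial units between clusters.
#'
#' @param object a `som_model` with unit labels.
#' @param newdata numeric matrix on the training feature space.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.som_model <- function(object, newdata, ...) {
  if (all(is.na(object$unit_labels)))
    stop("model has no labeled units; train with labels")
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features))
      stop("newdata has ", ncol(newdata), " features; model expects ",
           length(object$features))
    colnames(newdata) <- object$features
  }
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(miss[seq_len(min(3, length(miss)))],
                               collapse = ", "))
  bmus <- .som_bmu(object, newdata)
  labs <- object$unit_labels
  out <- labs[bmus]
  miss <- which(is.na(out))
  if (length(miss)) {
    labeled <- which(!is.na(labs))
    Z <- sweep(sweep(newdata[miss, object$features, drop = FALSE], 2,
                     object$center), 2, object$scale, "/")
    cb <- object$codebook[labeled, , drop = FALSE]
    d2 <- outer(rowSums(Z^2), rowSums(cb^2), "+") - 2 * Z %*% t(cb)
    out[miss] <- labs[labeled[max.col(-d2, ties.method = "first")]]
  }
  out
}

#' Classification report
#'
#' Confusion matrix (rows = true, columns = predicted) with per-class
#' precision, recall and F1, and overall accuracy. `classification_report`
#' computes the metrics from a counts matrix; `evaluate_classification`
#' counts first from label vectors.
#'
#' @param confusion square counts matrix with matching row/column names.
#' @return list of class `classification_report`: `confusion`, `precision`,
#'   `recall`, `f1`, `accuracy`.
#' @export
classification_report <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  precision <- tp / pmax(colSums(confusion), 1e-12)
  recall <- tp / pmax(rowSums(confusion), 1e-12)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = confusion,
                 precision = stats::setNames(precision,
                                             rownames(confusion)),
                 recall = stats::setNames(recall, rownames(confusion)),
                 f1 = stats::setNames(f1, rownames(confusion)),
                 accuracy = sum(tp) / sum(confusion)),
            class = "classification_report")
}

#' @rdname classification_report
#' @param truth,predicted label vectors of equal length.
#' @param levels class order for the matrix (default: sorted union, which
#'   for the three text types gives badfiction, fanfiction, original).
#' @export
evaluate_classification <- function(truth, predicted,
                                    levels = sort(unique(c(truth,
                                                           predicted)))) {
  if (!length(truth)) stop("empty input")
  stopifnot(length(truth) == length(predicted))
  confusion <- table(factor(truth, levels = levels),
                     factor(predicted, levels = levels))
  classification_report(unclass(as.matrix(confusion)))
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  cat("\nPer-class F1:", paste(names(x$f1),
                               sprintf("%.3f", x$f1), collapse = ", "),
      "\nAccuracy:", sprintf("%.3f", x$accuracy), "\n")
  invisible(x)
}
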
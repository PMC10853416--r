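# Permutation one-way ANOVA over the channel x frequency grid, and the
# cascaded two-group tests (Levene / Shapiro-Wilk gated t, Welch,
# Mann-Whitney) with Benjamini-Hochberg FDR and Cohen's d.

#' Permutation one-way ANOVA
#'
#' Observed F is the classical between/within mean-square ratio; the p-value
#' is estimated by uniformly permuting group labels with the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Total sum of squares is
#' permutation-invariant, so permuted F values are computed from group sums
#' alone. When within-group variance vanishes everywhere an infinite
#' observed F beats every finite permuted F.
#'
#' @param values numeric observations.
#' @param groups group labels (k >= 2 levels, each with n >= 2).
#' @param n_perm number of permutations (default 1999).
#' @param seed RNG seed.
#' @return list with `F_obs`, `p_perm`, `n_perm`.
#' @export
permutation_anova <- function(values, groups, n_perm = 1999, seed = 1) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(k >= 2, length(groups) == n, all(table(groups) >= 2))
  ng <- as.numeric(table(groups))
  Tsum <- sum(values)
  sst <- sum(values^2) - Tsum^2 / n
  fstat <- function(gsums) {
    ssb <- sum(gsums^2 / ng) - Tsum^2 / n
    ssw <- sst - ssb
    if (ssw <= sst * 1e-12)
      return(if (ssb <= sst * 1e-12) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  g_obs <- rowsum(values, groups)[, 1]
  F_obs <- fstat(g_obs)
  G <- t(sapply(levels(groups), function(l) as.numeric(groups == l)))
  F_perm <- with_seed(seed, {
    perm <- matrix(0L, n, n_perm)
    for (i in seq_len(n_perm)) perm[, i] <- sample.int(n)
    V <- matrix(values[perm], n, n_perm)      # permuted value columns
    S <- G %*% V                              # k x n_perm group sums
    ssb <- colSums(S^2 / ng) - Tsum^2 / n
    ssw <- pmax(sst - ssb, 0)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    f[ssw <= sst * 1e-12 & ssb > sst * 1e-12] <- Inf
    f[!is.finite(f) & !(ssw <= sst * 1e-12 & ssb > sst * 1e-12)] <- 0
    f
  })
  if (is.nan(F_obs)) F_obs <- 0
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  if (F_obs == 0 && sst <= 1e-12 * max(1, Tsum^2)) p <- 1
  list(F_obs = F_obs, p_perm = p, n_perm = n_perm)
}

#' Permutation ANOVA across the channel x frequency grid
#'
#' Within-participant PSD means per condition form the observations; one
#' permutation test per (channel, frequency-bin) cell, with a single label
#' permutation shared across cells per draw (so the grid sees a common
#' resampling of the design) and Bonferroni correction over all tested
#' cells. `permute` chooses full label permutation (default) or permutation
#' of condition labels within each participant.
#'
#' @param features stimulus-level features from [spectral_features()].
#' @param n_perm number of permutations. Note the Bonferroni threshold
#'   `alpha / n_cells` is only reachable when `n_perm + 1 >= n_cells /
#'   alpha`.
#' @param alpha family-wise error target (default 0.05).
#' @param seed RNG seed.
#' @param permute `"full"` or `"within_participant"`.
#' @return data.frame with one row per (channel, freq_bin_hz): `F_obs`,
#'   `p_perm`, `significant` (Bonferroni at `alpha`).
#' @export
anova_grid <- function(features, n_perm = 39999, alpha = 0.05, seed = 1,
                       permute = c("full", "within_participant")) {
  permute <- match.arg(permute)
  psd_cols <- grep("^psd_", names(features), value = TRUE)
  # participant x condition mean PSD per channel/bin
  key <- paste(features$participant_id, features$text_type,
               features$channel, sep = "\r")
  M <- rowsum(as.matrix(features[, psd_cols]), key)
  cnt <- as.numeric(table(key)[rownames(M)])
  M <- M / cnt
  kk <- do.call(rbind, strsplit(rownames(M), "\r", fixed = TRUE))
  pid <- kk[, 1]; cond <- kk[, 2]; chan <- kk[, 3]
  channels <- unique(features$channel)
  conds <- sort(unique(cond))
  k <- length(conds)
  if (k < 2) stop("need >= 2 conditions")
  # build obs x (channel*bin) matrix: rows are (participant, condition)
  ukey <- paste(pid, cond, sep = "\r")
  uobs <- unique(ukey)
  nobs <- length(uobs)
  ncell <- length(channels) * length(psd_cols)
  Y <- matrix(NA_real_, nobs, ncell)
  cellnames <- as.vector(outer(channels, sub("^psd_", "", psd_cols),
                               paste, sep = "\r"))
  colnames(Y) <- cellnames
  for (i in seq_len(nrow(M))) {
    r <- match(ukey[i], uobs)
    cidx <- match(paste(chan[i], sub("^psd_", "", psd_cols), sep = "\r"),
                  cellnames)
    Y[r, cidx] <- M[i, ]
  }
  if (anyNA(Y)) {
    drop_cells <- colSums(is.na(Y)) > 0
    message(sum(drop_cells), " cells with missing condition data skipped")
    Y <- Y[, !drop_cells, drop = FALSE]
  }
  obs_cond <- sub("^.*\r", "", uobs)
  obs_pid <- sub("\r.*$", "", uobs)
  G <- t(sapply(conds, function(cc) as.numeric(obs_cond == cc)))  # k x nobs
  ng <- rowSums(G)
  stopifnot(all(ng >= 2))
  n <- nobs
  Fgrid <- function(ord) {
    S <- (G[, ord, drop = FALSE] %*% Y)          # k x ncell group sums
    ssb <- colSums(S^2 / ng) - colSums(Y)^2 / n
    sst <- colSums(Y^2) - colSums(Y)^2 / n
    ssw <- pmax(sst - ssb, 0)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    f[ssw <= sst * 1e-12 & ssb > sst * 1e-12] <- Inf
    f[sst <= 1e-12] <- 0
    f
  }
  F_obs <- Fgrid(seq_len(n))
  counts <- numeric(length(F_obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ord <- if (permute == "full") sample.int(n)
             else .within_participant_perm(obs_pid)
      counts <- counts + (Fgrid(ord) >= F_obs)
    }
  })
  p <- (1 + counts) / (1 + n_perm)
  cn <- do.call(rbind, strsplit(colnames(Y), "\r", fixed = TRUE))
  data.frame(channel = cn[, 1], freq_bin_hz = as.numeric(cn[, 2]),
             F_obs = F_obs, p_perm = p,
             significant = p <= alpha / ncol(Y),
             stringsAsFactors = FALSE)
}

# permute observation order so condition labels shuffle within participant
.within_participant_perm <- function(obs_pid) {
  ord <- seq_along(obs_pid)
  for (p in unique(obs_pid)) {
    i <- which(obs_pid == p)
    ord[i] <- i[sample.int(length(i))]
  }
  ord
}

#' Contiguous significant frequency runs per channel
#'
#' Summarizes an [anova_grid()] result as runs of adjacent significant bins,
#' the tabular equivalent of the shaded areas in a grand-average spectrum
#' plot.
#' @param grid output of [anova_grid()].
#' @return data.frame (channel, from_hz, to_hz, n_bins).
#' @export
significant_runs <- function(grid) {
  out <- list()
  for (ch in unique(grid$channel)) {
    g <- grid[grid$channel == ch, ]
    g <- g[order(g$freq_bin_hz), ]
    sig <- g$significant
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        channel = ch, from_hz = g$freq_bin_hz[starts[j]],
        to_hz = g$freq_bin_hz[ends[j]], n_bins = r$lengths[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(channel = character(), from_hz = numeric(),
                      to_hz = numeric(), n_bins = integer()))
  do.call(rbind, out)
}

#' Choose the two-group test from assumption checks
#'
#' Levene's test (center = mean) for homogeneity of variances and a
#' Shapiro-Wilk test per group for normality, both at `alpha_assumption`.
#' Both normal and homogeneous: Student t. Both normal, heterogeneous:
#' Welch t. Any group non-normal (or a degenerate constant group):
#' Mann-Whitney U.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param alpha_assumption level for the assumption checks (default 0.05).
#' @return one of `"student_t"`, `"welch_t"`, `"mann_whitney_u"`.
#' @export
choose_test <- function(a, b, alpha_assumption = 0.05) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  normal_p <- function(x) {
    if (length(unique(x)) < 3) return(0)     # constant: treat as non-normal
    if (length(x) > 5000)
      x <- x[round(seq(1, length(x), length.out = 5000))]
    stats::shapiro.test(x)$p.value
  }
  both_normal <- normal_p(a) > alpha_assumption &&
    normal_p(b) > alpha_assumption
  if (!both_normal) return("mann_whitney_u")
  lev <- car::leveneTest(c(a, b),
                         factor(rep(c("a", "b"), c(length(a), length(b)))),
                         center = mean)
  homogeneous <- lev[["Pr(>F)"]][1] > alpha_assumption
  if (homogeneous) "student_t" else "welch_t"
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the usual (n-1)-weighted pooled
#' variance. NA when the pooled sd is zero.
#' @param a,b numeric samples (n >= 2 each).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts p ascending, finds the largest i with `p_(i) <= (i/m) q`; all
#' p-values up to `p_(i)` pass. The realized adjusted alpha is `p_(i)`
#' (0 when nothing passes).
#'
#' @param p p-values in \[0, 1\].
#' @param q FDR target (default 0.05).
#' @return list with `passes` (logical, in input order) and
#'   `adjusted_alpha`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(passes = logical(), adjusted_alpha = 0))
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) / m * q)
  if (!length(ok)) return(list(passes = rep(FALSE, m), adjusted_alpha = 0))
  thr <- p[o][max(ok)]
  list(passes = p <= thr, adjusted_alpha = thr)
}

#' Cascaded two-group comparisons over sites, measures and variables
#'
#' For every (site, measure, grouping variable) cell: form the two analysis
#' groups (dropping any `rest` participants), pick the test with
#' [choose_test()], run it, and record Cohen's d. P-values are pooled across
#' all cells for BH-FDR (`bh_pool = "pooled"`, default) or adjusted per
#' variable.
#'
#' @param features stimulus-level features (from [spectral_features()] or a
#'   relative [aggregate_features()] table) with `participant_id`, `channel`
#'   and the measure columns.
#' @param metadata [participant_metadata()] table.
#' @param sites channel labels to test (default: all in `features`).
#' @param measures measure column suffixes; default the five band shares and
#'   brain rate.
#' @param variables grouping variables (default all five).
#' @param q FDR target (default 0.05).
#' @param unit `"stimulus"` (stimulus-level rows, the extensive data set) or
#'   `"participant"` (per-participant means, avoiding pseudoreplication).
#' @param bh_pool `"pooled"` or `"per_variable"`.
#' @param alpha_assumption level for the Levene / Shapiro-Wilk gates.
#' @return data.frame of class `cascade_result`: one row per cell with
#'   `test_used`, `p_raw`, `p_passes_fdr`, `adjusted_alpha`, `cohens_d`
#'   (signed; tables conventionally print the magnitude), group means, sds
#'   and ns.
#' @export
run_cascade <- function(features, metadata, sites = NULL,
                        measures = c("delta", "theta", "alpha", "beta",
                                     "gamma", "brain_rate"),
                        variables = names(metadata_levels()),
                        q = 0.05, unit = c("stimulus", "participant"),
                        bh_pool = c("pooled", "per_variable"),
                        alpha_assumption = 0.05) {
  unit <- match.arg(unit)
  bh_pool <- match.arg(bh_pool)
  if (is.null(sites)) sites <- unique(features$channel)
  mcol <- function(m) if (m == "brain_rate") "brain_rate_hz"
                      else paste0("rel_", m)
  miss <- setdiff(vapply(measures, mcol, ""), names(features))
  if (length(miss)) stop("missing measure column(s): ",
                         paste(miss, collapse = ", "))
  lev <- metadata_levels()
  rows <- list()
  for (v in variables) {
    la <- lev[[v]][1]; lb <- lev[[v]][2]
    pa <- metadata$participant_id[metadata[[v]] == la]
    pb <- metadata$participant_id[metadata[[v]] == lb]
    if (!length(pa) || !length(pb)) {
      message("variable ", v, " skipped: empty analysis group")
      next
    }
    for (s in sites) {
      fs <- features[features$channel == s, ]
      for (m in measures) {
        va <- fs[fs$participant_id %in% pa, mcol(m)]
        vb <- fs[fs$participant_id %in% pb, mcol(m)]
        if (unit == "participant") {
          va <- tapply(va, fs$participant_id[fs$participant_id %in% pa],
                       mean)
          vb <- tapply(vb, fs$participant_id[fs$participant_id %in% pb],
                       mean)
          va <- as.numeric(va[!is.na(va)]); vb <- as.numeric(vb[!is.na(vb)])
        }
        test <- choose_test(va, vb, alpha_assumption)
        p <- switch(test,
          student_t = stats::t.test(va, vb, var.equal = TRUE)$p.value,
          welch_t = stats::t.test(va, vb)$p.value,
          mann_whitney_u = stats::wilcox.test(va, vb, exact = FALSE)$p.value)
        rows[[length(rows) + 1]] <- data.frame(
          site = s, measure = m, variable = v, group_a = la, group_b = lb,
          test_used = test, p_raw = p, cohens_d = cohens_d(va, vb),
          mean_a = mean(va), mean_b = mean(vb),
          sd_a = stats::sd(va), sd_b = stats::sd(vb),
          n_a = length(va), n_b = length(vb), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable (site, measure, variable) cells")
  out <- do.call(rbind, rows)
  if (bh_pool == "pooled") {
    fdr <- bh_fdr(out$p_raw, q)
    out$p_passes_fdr <- fdr$passes
    out$adjusted_alpha <- fdr$adjusted_alpha
  } else {
    out$p_passes_fdr <- FALSE
    out$adjusted_alpha <- NA_real_
    for (v in unique(out$variable)) {
      i <- out$variable == v
      fdr <- bh_fdr(out$p_raw[i], q)
      out$p_passes_fdr[i] <- fdr$passes
      out$adjusted_alpha[i] <- fdr$adjusted_alpha
    }
  }
  class(out) <- c("cascade_result", class(out))
  out
}
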
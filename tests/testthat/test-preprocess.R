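# Filtering, channel rejection, ICA artifact removal, windowing.

tone_recording <- function(freqs, fs = 500, dur = 20, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- do.call(rbind, lapply(freqs, function(f)
    if (f == 0) rep(amp, length(t)) else amp * sin(2 * pi * f * t)))
  recording("tone", x, montage(paste0("C", seq_along(freqs))), fs)
}

test_that("filter stopband and passband contracts hold", {
  # attenuation measured in the central half of a 20 s tone: the slow
  # high-pass poles make the first/last seconds a settling region, as in
  # any zero-phase IIR chain
  rec <- tone_recording(c(0, 10, 45, 0.3))
  out <- apply_bandlimit(rec)
  rms <- function(v) sqrt(mean(v^2))
  mid <- 2501:7500
  att_db <- function(i) 20 * log10(rms(out$samples[i, mid]) /
                                     rms(rec$samples[i, ]))
  expect_lt(max(abs(out$samples[1, ])), 0.01)       # DC removed outright
  expect_equal(rms(out$samples[2, mid]) / rms(rec$samples[2, ]), 1,
               tolerance = 0.05)                    # 10 Hz within 5 percent
  expect_lt(att_db(3), -40)                         # 45 Hz >= 40 dB down
  expect_lt(att_db(4), -40)                         # 0.3 Hz >= 40 dB down
  expect_error(apply_bandlimit(recording("n", matrix(NA_real_, 1, 500),
                                         montage("A"), 500)),
               "NaN")
})

test_that("filtering is linear and zero-phase", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 10 * t)
  b <- 0.5 * sin(2 * pi * 23 * t + 1)
  mk <- function(x) recording("p", matrix(x, 1), montage("A"), fs)
  fa <- apply_bandlimit(mk(a))$samples[1, ]
  fb <- apply_bandlimit(mk(b))$samples[1, ]
  fab <- apply_bandlimit(mk(a + b))$samples[1, ]
  expect_lt(max(abs(fab - (fa + fb))) / max(abs(fab)), 1e-6)
  # zero phase: cross-correlation of a 10 Hz tone peaks at lag 0
  cc <- stats::ccf(fa, a, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("robust variance z-score rejects the injected bad channel only", {
  spec <- small_spec(seed = 19)
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  bad <- rec
  bad$samples["T7", ] <- bad$samples["T7", ] * 100
  rj <- reject_channels(bad, 5)
  expect_identical(rj$rejected, "T7")
  expect_false("T7" %in% rj$recording$montage$channel_names)
  expect_identical(reject_channels(rec, 5)$rejected, character(0))
  expect_identical(reject_channels(bad, Inf)$rejected, character(0))
  expect_error(reject_channels(recording("p", matrix(rnorm(300), 3),
                                         montage(c("A", "B", "C")), 500)),
               "4")
})

test_that("FastICA separates super-Gaussian mixtures deterministically", {
  set.seed(3)
  n <- 20000
  s <- rbind(rexp(n) * sample(c(-1, 1), n, TRUE),
             rexp(n) * sample(c(-1, 1), n, TRUE))
  A <- matrix(c(1, 0.4, 0.3, 1), 2)
  rec <- recording("m", A %*% s, montage(c("A", "B")), 500)
  ica <- decompose_ica(rec, 2, seed = 5)
  cc <- abs(stats::cor(t(ica$sources), t(s)))
  expect_true(all(apply(cc, 2, max) >= 0.95))
  expect_lt(max(abs(ica$mixing %*% ica$unmixing - diag(2))), 1e-8)
  ica2 <- decompose_ica(rec, 2, seed = 5)
  expect_identical(ica$unmixing, ica2$unmixing)
  # identity mixing of already independent inputs: unmixing is a signed
  # permutation (one dominant entry per row)
  rec2 <- recording("i", s, montage(c("A", "B")), 500)
  u <- decompose_ica(rec2, 2, seed = 5)$unmixing
  dom <- abs(u) / sqrt(rowSums(u^2))
  expect_true(all(apply(dom, 1, max) > 0.99))
  expect_error(decompose_ica(rec, 2, seed = 1, max_iter = 200, tol = 1e-6),
               NA)
  short <- recording("s", matrix(rnorm(2 * 50), 2), montage(c("A", "B")),
                     500)
  expect_error(decompose_ica(short, 2), "too short")
})

test_that("component scoring flags blink and muscle components", {
  rec <- artifact_recording()
  ica <- decompose_ica(rec, seed = 2)
  sc <- score_components(ica, rec$sampling_rate_hz)
  expect_equal(nrow(sc), 32)
  expect_true(all(abs(rowSums(sc[, c("p_eye", "p_muscle", "p_brain",
                                     "p_other")]) - 1) < 1e-9))
  expect_gte(max(sc$p_eye), 0.85)
  expect_gte(max(sc$p_muscle), 0.85)
  # a flat-spectrum, uniform-topography component scores as brain/other
  flat <- list(mixing = matrix(1, 32, 1), unmixing = matrix(1 / 32, 1, 32),
               sources = matrix(rnorm(32 * 5000), 1),
               center = rep(0, 32),
               channel_names = default_montage()$channel_names)
  class(flat) <- "eeg_ica"
  fs <- score_components(flat, 500)
  expect_true(fs$artifact_class %in% c("brain", "other"))
})

test_that("artifact removal cleans frontal low frequencies, spares alpha", {
  rec <- artifact_recording()
  ica <- decompose_ica(rec, seed = 2)
  sc <- score_components(ica, rec$sampling_rate_hz)
  rm1 <- remove_artifacts(rec, ica, sc, 0.85)
  expect_gt(length(rm1$removed), 0)
  band_mean <- function(r, ch, cols) {
    f <- spectral_features(r)
    mean(rowSums(f[f$channel == ch, cols, drop = FALSE]))
  }
  low_cols <- paste0("psd_", 1:4)
  before <- band_mean(rec, "Fp1", low_cols)
  after <- band_mean(rm1$recording, "Fp1", low_cols)
  expect_gte(1 - after / before, 0.8)
  a0 <- band_mean(rec, "Pz", "abs_alpha")
  a1 <- band_mean(rm1$recording, "Pz", "abs_alpha")
  expect_lte(abs(a1 / a0 - 1), 0.1)
  # idempotent at fixed decomposition
  rm2 <- remove_artifacts(rm1$recording, ica, sc, 0.85)
  expect_equal(rm2$recording$samples, rm1$recording$samples,
               tolerance = 1e-10)
  # nothing above threshold leaves the data untouched
  none <- remove_artifacts(rec, ica, sc, 1)
  expect_identical(none$recording$samples, rec$samples)
  expect_error(remove_artifacts(rec, ica, sc, 0), "threshold")
})

test_that("window segmentation matches the count formula", {
  expect_equal(window_count(10, 1, 0.5), 19)
  expect_equal(window_count(1, 1, 0.5), 1)
  expect_equal(window_count(0.8, 1, 0.5), 0)
  expect_error(window_count(5, 1, 0), "step_s")
  expect_error(window_spec(step_s = -1), "step_s")
  # brute-force enumerator over a randomized grid
  brute <- function(dur, len, step) {
    k <- 0; start <- 0
    while (start + len <= dur + 1e-9) { k <- k + 1; start <- start + step }
    k
  }
  set.seed(8)
  for (i in 1:200) {
    dur <- runif(1, 0, 20); len <- runif(1, 0.2, 3)
    step <- runif(1, 0.05, len)
    expect_equal(window_count(dur, len, step), brute(dur, len, step),
                 info = sprintf("dur=%g len=%g step=%g", dur, len, step))
  }
})

test_that("segment_windows tags windows per stimulus", {
  x <- matrix(rnorm(2 * 5000), 2)
  ev <- stimulus_events(c(0, 4), c(3.2, 5.8), c("s1", "s2"),
                        c("original", "badfiction"), c(1L, 1L))
  rec <- recording("p", x, montage(c("A", "B")), 500, ev)
  w <- segment_windows(rec)
  expect_equal(sum(w$stimulus_id == "s1"), window_count(3.2, 1, 0.5))
  expect_equal(sum(w$stimulus_id == "s2"), window_count(5.8, 1, 0.5))
  expect_equal(w$text_type[w$stimulus_id == "s2"][1], "badfiction")
  expect_true(all(w$start_s + 1 <=
                    ev$onset_s[match(w$stimulus_id, ev$stimulus_id)] +
                    ev$duration_s[match(w$stimulus_id, ev$stimulus_id)] +
                    1e-9))
})
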
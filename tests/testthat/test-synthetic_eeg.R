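# Generator: design layout, determinism, known-truth band structure.

test_that("default design yields 150 stimuli per participant (120/15/15)", {
  d <- generate_design(design_spec(seed = 3))
  expect_equal(nrow(d$metadata), 40)
  for (sch in d$schedules[c(1, 40)]) {
    expect_equal(nrow(sch), 150)
    counts <- table(sch$text_type)
    expect_equal(counts[["original"]], 120)
    expect_equal(counts[["fanfiction"]], 15)
    expect_equal(counts[["badfiction"]], 15)
  }
})

test_that("trial arithmetic scales with n_trials", {
  expect_equal(nrow(generate_design(small_spec(n_trials = 0))$schedules[[1]]),
               0)
  sch <- generate_design(small_spec(n_trials = 2))$schedules[[1]]
  expect_equal(nrow(sch), 20)
  expect_equal(as.vector(table(sch$text_type)[text_types()]), c(16, 2, 2))
})

test_that("group sizes are honored and overruns rejected", {
  d <- generate_design(design_spec(seed = 5))
  md <- d$metadata
  expect_equal(sum(md$reading_frequency == "frequent"), 10)
  expect_equal(sum(md$reading_frequency == "non_frequent"), 10)
  expect_equal(sum(md$reading_frequency == "rest"), 20)
  expect_equal(sum(md$fantasy_reader == "fantasy"), 26)
  expect_equal(sum(md$hp_fan == "fan"), 17)
  expect_equal(sum(md$badfiction_attitude == "negative"), 8)
  expect_error(design_spec(n_participants = 5,
                           group_sizes = list(hp_fan = c(fan = 4,
                                                         non_fan = 4))),
               "exceed")
})

test_that("same spec and seed give bit-identical recordings", {
  spec <- small_spec(seed = 13)
  d <- generate_design(spec)
  r1 <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  r2 <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  expect_identical(r1$samples, r2$samples)
  # and per-participant streams: participant 2 unchanged by regenerating 1
  r3 <- synthesize_recording(d$metadata[2, ], d$schedules[[2]], spec)
  r4 <- synthesize_recording(d$metadata[2, ], d$schedules[[2]], spec)
  expect_identical(r3$samples, r4$samples)
  expect_false(identical(r1$samples[, 1:100], r3$samples[, 1:100]))
})

test_that("a noise-free pure 10 Hz tone lands almost fully in alpha", {
  # degenerate synthesis band (9.9, 10] produces a pure 10 Hz oscillator;
  # analysis uses the standard band partition
  spec <- small_spec(n_participants = 1, stimulus_duration_s = 4, seed = 2,
                     noise = silent_noise(), participant_sd = 0,
                     bands = band_specs(c(0.5, 4, 9.9, 10, 30, 40)),
                     baseline_uv = c(delta = 0, theta = 0, alpha = 1,
                                     beta = 0, gamma = 0))
  d <- generate_design(spec)
  rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
  f <- spectral_features(rec, bands = band_specs())
  expect_gt(min(f$rel_alpha), 0.99)
})

test_that("absolute_scale effect reproduces its power ratio", {
  eff <- effect_spec("text_type", "badfiction", "beta", "absolute_scale",
                     0.5)
  spec <- small_spec(n_participants = 1, n_trials = 6,
                     stimulus_duration_s = 4, seed = 17, effects = list(eff),
                     participant_sd = 0)
  f <- build_features(spec)
  # interior beta bins: band-edge bins pick up taper leakage from the
  # unscaled alpha/gamma neighbors, biasing the full-band ratio upward
  interior <- rowMeans(f[, paste0("psd_", 16:28)])
  ratio <- mean(interior[f$text_type == "badfiction"]) /
    mean(interior[f$text_type == "original"])
  expect_equal(ratio, 0.5, tolerance = 0.1)   # n = 6 vs 48 stimuli
  full <- mean(f$abs_beta[f$text_type == "badfiction"]) /
    mean(f$abs_beta[f$text_type == "original"])
  expect_equal(full, 0.5, tolerance = 0.25)
  # truth table agrees exactly
  tt <- truth_table(spec)
  tb <- tt[tt$band == "beta" & tt$channel == "Cz", ]
  expect_equal(tb$band_abs_uv2[tb$text_type == "badfiction"] /
                 tb$band_abs_uv2[tb$text_type == "original"], 0.5)
})

test_that("truth table conserves relative power and encodes shifts", {
  spec0 <- small_spec(n_participants = 2, seed = 23)
  tt0 <- truth_table(spec0)
  sums <- tapply(tt0$band_rel,
                 paste(tt0$participant_id, tt0$text_type, tt0$channel),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # no effects: identical across text types
  w <- reshape(tt0, idvar = c("participant_id", "channel", "band"),
               timevar = "text_type", direction = "wide")
  expect_equal(w$band_rel.original, w$band_rel.badfiction)
  # relative_shift raises the target band fraction by its magnitude
  spec1 <- small_spec(
    n_participants = 2, seed = 23,
    group_sizes = list(reading_frequency = c(frequent = 1,
                                             non_frequent = 1)),
    effects = list(effect_spec("reading_frequency", "non_frequent",
                               "delta", "relative_shift", 0.1)))
  d1 <- generate_design(spec1)
  tt1 <- truth_table(spec1, d1)
  md <- d1$metadata
  nf <- md$participant_id[md$reading_frequency == "non_frequent"]
  fr <- md$participant_id[md$reading_frequency == "frequent"]
  dl <- tt1[tt1$band == "delta" & tt1$channel == "Pz" &
              tt1$text_type == "original", ]
  base <- tt0[tt0$band == "delta" & tt0$channel == "Pz" &
                tt0$text_type == "original", ]
  gain <- dl$band_rel[dl$participant_id == nf] -
    base$band_rel[base$participant_id == nf]
  expect_equal(gain, 0.1, tolerance = 1e-9)
  expect_equal(dl$band_rel[dl$participant_id == fr],
               base$band_rel[base$participant_id == fr])
  # absolute scaling renormalizes the other bands consistently
  spec2 <- small_spec(n_participants = 1, seed = 23,
                      effects = list(effect_spec("text_type", "badfiction",
                                                 "beta", "absolute_scale",
                                                 2)))
  tt2 <- truth_table(spec2)
  bb <- tt2[tt2$channel == "Cz" & tt2$text_type == "badfiction", ]
  expect_equal(sum(bb$band_rel), 1, tolerance = 1e-12)
})

test_that("raising a band's absolute scale raises its measured power", {
  mk <- function(mag) {
    spec <- small_spec(n_participants = 1, n_trials = 2,
                       stimulus_duration_s = 2, seed = 29,
                       effects = if (mag != 1)
                         list(effect_spec("text_type", "original", "beta",
                                          "absolute_scale", mag)),
                       participant_sd = 0)
    f <- build_features(spec)
    mean(f$abs_beta[f$text_type == "original"])
  }
  p1 <- mk(1); p2 <- mk(1.5); p3 <- mk(2.5)
  expect_lt(p1, p2)
  expect_lt(p2, p3)
})

test_that("effects referencing unknown bands or channels are rejected", {
  expect_error(small_spec(effects = list(
    effect_spec("text_type", "badfiction", "sigma", "absolute_scale", 2))),
    "unknown band")
  expect_error(small_spec(effects = list(
    effect_spec("text_type", "badfiction", "beta", "absolute_scale", 2,
                channel_subset = "XX"))), "unknown channel")
  expect_error(effect_spec("text_type", "badfiction", "beta",
                           "absolute_scale", -1), "magnitude")
})
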
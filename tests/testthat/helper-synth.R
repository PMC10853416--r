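# Shared fixtures for the suite: small, quiet design specs and a memoized
# feature builder so expensive syntheses run once per session.

quiet_noise <- function() {
  noise_spec(pink_scale_uv = 1, blink_rate_hz = 0,
             muscle_burst_rate_hz = 0, sensor_white_uv = 0.5)
}

silent_noise <- function() {
  noise_spec(pink_scale_uv = 0, blink_rate_hz = 0,
             muscle_burst_rate_hz = 0, sensor_white_uv = 0)
}

small_spec <- function(n_participants = 2, n_trials = 1,
                       stimulus_duration_s = 3, seed = 7,
                       noise = quiet_noise(), group_sizes = list(), ...) {
  design_spec(n_participants = n_participants, n_trials = n_trials,
              stimulus_duration_s = stimulus_duration_s,
              noise = noise, group_sizes = group_sizes, seed = seed, ...)
}

# synthesize features for every participant of a design
build_features <- function(spec) {
  d <- generate_design(spec)
  do.call(rbind, lapply(seq_len(spec$n_participants), function(i)
    spectral_features(synthesize_recording(d$metadata[i, ],
                                           d$schedules[[i]], spec))))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

rel_cols <- function() paste0("rel_", c("delta", "theta", "alpha", "beta",
                                        "gamma"))

# one small shared recording with artifacts, used across preprocess tests
artifact_recording <- function() {
  cached("artifact_rec", {
    spec <- design_spec(
      n_participants = 1, n_trials = 2, stimulus_duration_s = 10,
      noise = noise_spec(pink_scale_uv = 1, blink_rate_hz = 0.4,
                         blink_amplitude_uv = 120,
                         muscle_burst_rate_hz = 0.2,
                         muscle_amplitude_uv = 30, sensor_white_uv = 0.5),
      group_sizes = list(), seed = 11)
    d <- generate_design(spec)
    rec <- synthesize_recording(d$metadata[1, ], d$schedules[[1]], spec)
    apply_bandlimit(rec)
  })
}
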
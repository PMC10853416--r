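Package: readspectra
Title: Spectral Band-Power Analysis and Self-Organizing-Map
    Classification of Reading EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for distinguishing brain responses to different
    classes of literary text from multichannel EEG: zero-phase IIR
    band-limiting, automated channel rejection, ICA-based blink and
    muscle artifact removal, windowed power-spectral-density extraction
    with absolute and relative band powers and the brain-rate summary
    frequency, permutation one-way ANOVA across the channel-by-frequency
    grid with Bonferroni correction, a cascaded two-group testing scheme
    (Levene / Shapiro-Wilk gated t, Welch or Mann-Whitney tests) with
    Benjamini-Hochberg false-discovery-rate control and Cohen's d, and a
    from-scratch Kohonen self-organizing map that classifies the text
    type being read from stimulus-level spectral features. A synthetic
    EEG generator emulating a 32-channel reading study with injectable
    condition and group effects provides a known-truth test bed, so the
    full pipeline runs without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
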
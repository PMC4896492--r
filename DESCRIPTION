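Package: gammasel
Title: Category Selectivity of Broadband Gamma Activity in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for grouped intracranial EEG
    (icEEG/ECoG) category-selectivity analysis. Extracts percent-change
    broadband gamma activity (BGA, 60-120 Hz) from trial-epoched voltage
    recordings via notch filtering, zero-phase elliptical band-pass
    filtering, Hilbert analytic amplitude and Savitzky-Golay smoothing;
    quantifies multi-category selectivity per electrode with the d-prime
    sensitivity index, label-permutation null distributions and
    Benjamini-Hochberg false discovery rate control within region by
    hemisphere families; detects selectivity onset latencies from
    sustained pointwise significance; and relates selectivity to cortical
    topology (Talairach electrode coordinates) with random-intercept
    linear mixed-effects models. Includes a synthetic icEEG generator
    with known ground truth, plain-text dataset serialization, and a
    reader for MATLAB (v5) electrode-level supplementary matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
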
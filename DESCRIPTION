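Package: larvamotor
Title: Locomotor Phenotyping of Larval Zebrafish from Tail Kinematics and
    Fictive Motor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying larval zebrafish locomotor phenotypes from
    tracked tail kinematics and extracellular motor-nerve recordings. Computes
    the three-point body angle from head/mid-trunk/tail coordinates, classifies
    tail movements into low-amplitude wags and large-angle movements (LAMs)
    with left/right direction, and summarizes event frequency and duration per
    recording window. Segments spike trains into bursts nested within episodes
    using inter-spike-interval rules and derives burst metrics (spikes per
    burst, burst duration, burst period, bursts per episode). Provides the
    statistical layer used for such studies: chi-square phenotype scoring,
    rank-sum tests with Bonferroni correction, Kruskal-Wallis comparisons, a
    Lilliefors-gated repeated-measures ANOVA/Friedman test, and LC50 estimation
    from dose-survival tables. A synthetic-data generator emulates control,
    manganese-treated and recovered phenotypes so the full pipeline runs and is
    tested without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
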
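Package: nwreflex
Title: Automated Nociceptive Withdrawal Reflex Threshold Measurement and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated determination of the nociceptive withdrawal reflex
    (NWR, RIII) threshold from stimulus-locked surface EMG. Implements the
    windowed Z-score response criterion (peak amplitude 90-150 ms post
    stimulus against a -60 to 0 ms baseline, response when Z >= 12), a
    multi-phase adaptive staircase (2 mA coarse ascent, 1 mA descent,
    0.5 mA fine steps, threshold = mean of three phase-terminating
    successes), a synthetic subject and EMG simulator for closed-loop
    validation, two-group cohort statistics (group summaries with t-based
    confidence intervals, pooled t-tests from raw data or summary moments,
    Mann-Whitney U, paired t and Wilcoxon signed-rank, Spearman correlation
    with Fisher-z intervals), and reproducible simulated experiment
    orchestration with session logging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
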
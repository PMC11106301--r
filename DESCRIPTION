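Package: mblfp
Title: Multi-Brain Local Field Potential Analysis for Group-Housed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous multi-animal local field
    potential (LFP) recordings. Reads hexadecimal space-delimited wireless
    telemetry traces and per-second behavioural annotations, computes
    per-second Welch band powers and the high-to-low-power ratio (HLR),
    models locomotive states, huddle episodes and immobility-defined sleep,
    and quantifies interbrain coupling via HLR cross-correlation against
    shuffled-pair permutation nulls, locomotion-residualised correlation,
    and lag-1 Granger causality directionality graphs. Includes a seeded
    synthetic cohort generator with planted state-dependent spectra,
    huddling-coupled behaviour, shared interbrain modulation and directed
    leader-follower influence for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest
Config/testthat/edition: 3
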
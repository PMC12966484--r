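Package: corticoflow
Title: Single-Trial Mapping of Directed Cortico-Limbic Signal Flow from
    Single-Pulse Intracranial Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping directed effective connectivity from repeated
    single-pulse intracortical stimulation in intracranial EEG. Evoked
    responses are detected trial-by-trial against surrogate null
    distributions built from non-stimulated baseline data, using a compound
    line-length and centroid-correlation score. Trial-level decisions are
    aggregated into signaling probability, a directionality index,
    connection classes, response magnitude, and a stimulation-response
    excitability index, with group-level models for distance, region-pair
    and vigilance-state (sleep/wake) effects. A bundled synthetic iEEG
    generator produces ground-truth directed networks, stimulation
    schedules and recordings so the whole pipeline can be exercised and
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
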
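Package: barcoweb
Title: Plant-Herbivore Interaction Networks from Field Observation and
    DNA Barcoding of Gut Contents
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and compares bipartite plant-herbivore interaction
    networks obtained by two routes: field co-occurrence (which tree a
    larva was collected from) and DNA barcoding of larval gut contents
    against a local plant reference library. Provides OTU delimitation of
    insect barcode sequences at a divergence threshold with
    family-consistency taxonomy rules, multi-marker diet identification
    and resolution scoring, network construction with node/link overlap
    tables, spatial attribution of diet mismatches to observation or
    molecular bias using mapped stem neighbourhoods, a bipartite
    network-metric suite (H2' specialization, interaction evenness,
    qualitative and quantitative generality and vulnerability, NODF and
    weighted NODF nestedness, Barber modularity maximized by weighted
    label propagation), size-matched randomized-subweb null comparison,
    logistic modelling of detection probability against observed
    co-occurrence counts, and a fully seeded synthetic-data generator so
    the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
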
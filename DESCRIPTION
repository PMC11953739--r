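Package: wormarena
Title: Analysis of Quadrant-Count Chemotaxis Assays for Freely Moving Nematodes
Version: 0.1.0
Authors@R:
    person("Arena", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing population chemotaxis assays in which
    nematodes are released at the centre of a rectangular four-quadrant
    arena and counted per quadrant after about one hour. Implements the
    entropy-based dispersal statistic, the response ratio, the chemotaxis
    index, Cohen's d effect sizes with unpaired t-tests, an
    opposing-orientation consistency check for laboratory-frame gradients,
    and a rule-based decision rubric that maps the three metrics to a
    behavioural verdict. A seeded agent-based biased-random-walk simulator
    generates synthetic assay data so the whole pipeline can be exercised
    and validated without laboratory input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
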
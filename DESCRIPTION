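Package: chosensor
Title: Soft-Sensor Models for Growth, Metabolite and Glycan Prediction in
    Fed-Batch CHO Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares three soft-sensor model families for
    galactose-fed CHO fed-batch cultures producing a monoclonal antibody: a
    mechanistic Michaelis-Menten/Monod kinetic model of growth, production,
    nucleotide-sugar-donor synthesis and N-glycan maturation (G0F/G1F/G2F); an
    orthogonal partial least squares (OPLS) soft sensor fitted by
    missing-data-tolerant NIPALS; and a small penalized tanh feed-forward
    network trained by BFGS with a penalty line search. Includes maximum
    likelihood parameter estimation with teacher forcing, a statistical
    comparison harness (one-way ANOVA, Tukey's HSD, specific consumption
    rates, galactosylation index), and a synthetic-data generator emulating
    the galactose-feed design of experiments so every stage is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
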
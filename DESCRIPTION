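Package: hyperoxr1
Title: Three-Compartment Modelling of Hyperoxia-Induced Changes in Tissue R1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the change in the longitudinal relaxation rate R1 of an
    imaging voxel induced by a hyperoxic gas challenge, as used in
    oxygen-enhanced MRI. A voxel is modelled as three compartments (arterial
    blood, venous blood, tissue): oxygen content and tension are propagated
    along a capillary from arterial inputs and the oxygen extraction fraction,
    tissue oxygenation is solved with a Krogh cylinder model with
    Michaelis-Menten consumption, blood R1 follows a two-compartment
    erythrocyte-plasma relaxometry model, and the compartment R1 changes are
    combined with blood-volume weights. Ships tissue-type presets (healthy
    brain, tumour vascular periphery, hypoxic, normally metabolising and
    necrotic tumour tissue), factorial parameter sweeps across field
    strengths, and a sex-stratified hematocrit comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
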
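Package: morbsim
Title: Dynamic Microsimulation of Multi-Morbidity in an Ageing Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time dynamic microsimulation of chronic disease,
    geriatric impairment and multi-morbidity in a closed population aged 35
    and over. Individuals evolve monthly under fitted binary, ordinal and
    generalised (multinomial) logistic transition models and an exogenous
    age-sex-year mortality schedule. The package fits transition models to
    two-wave panel data, converts interval probabilities to monthly
    probabilities under a constant-hazard assumption, allocates dementia
    probabilistically outside the simulation loop, and summarises annual
    snapshots as prevalence and count tables, Sullivan health expectancies
    (years lived with multi-morbidity from age 65) and a symmetric
    decomposition of change into mortality and prevalence components. A
    seeded synthetic-population generator emulating the England 2014
    population aged 35 and over supplies base populations and ground-truth
    panels for testing in place of restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
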
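Package: lumenvbe
Title: Virtual Bioequivalence of Gut-Targeted Controlled-Release Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates local (gut lumen and enterocyte) and systemic exposure
    of an orally dosed, pH-triggered controlled-release formulation with a
    segmented gastrointestinal absorption model, and runs replicated 2x2
    crossover virtual bioequivalence trials in healthy and Crohn's disease
    virtual populations. Provides Weibull dissolution modelling, the f2
    similarity factor (plain and bootstrap), noncompartmental analysis,
    closed-form crossover bioequivalence statistics, and classification of
    discordance between plasma and local gut bioequivalence decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
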
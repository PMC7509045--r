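Package: amubench
Title: Antimicrobial Usage Indicators and High-Usage Farm Benchmarking for Pig Herds
Version: 0.1.0
Authors@R: person("amubench", "maintainers", email = "maintainers@amubench.org", role = c("aut", "cre"))
Description: Quantifies farm-level antimicrobial usage from electronic
    treatment-journal records using two indicators: the Animal Treatment
    Index (ATI, treatments per animal per year) and the number of national
    Defined Daily Doses per animal per year (nDDDch/animal/year).
    Implements the journal validation and inclusion filters, percentile
    benchmarking of high-usage farms per age category, and agreement
    statistics between the indicators (percent agreement, Cohen's Kappa,
    Spearman's Rho, Bland-Altman limits of agreement), together with a
    seeded synthetic-data generator that emulates the farm, census and
    treatment structure of a national pig-herd monitoring programme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
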
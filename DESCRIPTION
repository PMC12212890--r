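Package: cinemort
Title: Film Versus Real-Life Mortality Representation Analysis
Version: 0.2.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying how on-screen deaths
    misrepresent real-world mortality. Parses crowd-sourced film-death
    entries from MediaWiki-style XML dumps (or CSV), classifies cause of
    death with a stem-based keyword lexicon against the 13 NVSS 2021
    leading-cause categories, infers gender from actor first names with a
    name dictionary and the mostly-male/mostly-female consolidation rule,
    and compares the classified corpus with the packaged NVSS 2021
    by-gender reference: per-cause representation ratios, per-cause gender
    proportions, and a one-sample goodness-of-fit chi-square battery with
    a small-count applicability rule. Includes a synthetic corpus
    generator with planted cause and gender structure for end-to-end
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    ggplot2,
    optparse,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
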
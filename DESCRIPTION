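Package: ubrisk
Title: Probabilistic Risk Assessment of Miners' Unsafe Behaviors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative risk assessment of unsafe worker
    behaviors in underground coal mining, built around gas-explosion
    causation. Accident records coded to working types and the 13
    unsafe-behavior classes of Chinese standard GB 6441-86 are tabulated
    into occurrence probabilities, corrected for organizational,
    human-machine and personal influencing factors elicited as triangular
    distributions, and combined with an expert-scored accident hazard
    index into per-behavior risk R = P * I. Uncertainty is propagated by
    seeded Monte Carlo simulation with distribution fitting and
    comonotonic or independent aggregation into per-working-type totals,
    and contribution-to-variance sensitivity analysis attributes output
    variance to the stochastic inputs via signed normalized squared
    Spearman rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
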
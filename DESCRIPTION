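Package: surrofrax
Title: Surrogate FRAX-Style Fracture Probability Models Under Competing Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct surrogate country models of 10-year fracture
    probability in the FRAX style: age- and sex-specific hip fracture incidence
    from a donor country is combined with the index country's own mortality,
    major osteoporotic fracture incidence is imputed from hip rates via
    age-specific ratio tables, and first-fracture probabilities are computed as
    cause-specific cumulative incidences under the competing risk of death with
    piecewise-constant yearly hazards. Includes a multiplicative clinical
    risk-factor and BMD layer, enumeration of risk-factor/T-score comparison
    grids, model-agreement summaries (Pearson, Spearman, least squares),
    national fracture-burden projection against population pyramids, synthetic
    Gompertz-style data generators, and a Monte-Carlo verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
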
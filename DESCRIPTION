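Package: diallelkit
Title: Diallel Analysis of Temperature-Mediated Trait Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temperature-mediated trait plasticity as the fold
    change of a phenotype between two growth temperatures in a full diallel
    crossing design, classifies each cross's mode of inheritance (additive,
    dominant, overdominant) against its mid-parent value with
    Benjamini-Hochberg false discovery rate control, and decomposes the
    plasticity variation via Griffing's Method I fixed-effects
    combining-ability analysis into general and specific combining abilities,
    reciprocal effects, Baker's ratio, additive/dominance/environmental
    variance components and heritabilities. Includes a father-offspring
    regression estimator of narrow-sense heritability, parent-versus-hybrid
    group comparisons, and a seeded simulator of diallel flower-diameter
    tables with known genetic architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    yaml
Config/testthat/edition: 3
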
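Package: acylid
Title: Systematic Identifiers and Balanced Reaction Templates for Fatty Acyl Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating fatty acyl metabolites in genome-scale metabolic
    models. Provides a bidirectional codec between Liebisch-style lipid shorthand
    (e.g. CoA(18:1(9Z))) and systematic, BiGG-compatible model identifiers
    (e.g. coa18_1_9z); elemental formula, charge and monoisotopic mass computation
    for fatty acids and their CoA, carnitine, acyl-carrier-protein and
    N-acylethanolamide conjugates; mass- and charge-balance checking of reactions;
    grading of metabolite annotation completeness with propagation of structural
    detail across the substrate-product pair network; and template-based generation
    of fully detailed, balanced fatty-acid biosynthesis, elongation, desaturation,
    beta-oxidation and carnitine-shuttle reaction sets with a lumping operator to
    recover net stoichiometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    ChemmineR,
    ChemmineOB
VignetteBuilder: knitr
Config/testthat/edition: 3
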
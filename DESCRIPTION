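Package: trophicweb
Title: Multitrophic Community-Web Inference from Ordination Congruence
    and Path Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed webs of community-composition relationships
    across trophic levels from plot-by-species abundance tables. Each
    organism group is summarised by the site scores of the first two
    principal-component axes of its relative-abundance matrix; pairwise
    congruence between groups is measured by symmetric Procrustes
    correlation with a permutation (protest) test; significant
    relationships seed a maximum-likelihood path model (structural
    equation model over observed variables) with environmental
    principal components as covariates, which is expanded via
    modification indices and pruned by stepwise AIC to a minimum
    adequate model. Competing bottom-up and top-down causal orientations
    are compared by AIC. Includes a synthetic multitrophic community
    generator with a known causal web for validation, and parallel
    analyses of species richness and Shannon diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: igraph, stats, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
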
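Package: volemicrobiome
Title: Paired Pre/Post Probiotic Microbiome Analysis for Small Cohorts
Version: 0.1.0
Authors@R: person("Vole", "Microbiome Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Statistical machinery for paired pre/post probiotic-treatment
    microbiome studies in small animal cohorts: median-of-ratios
    normalization, alpha diversity (Chao1, Shannon effective number of
    species, inverse Simpson), Bray-Curtis and UniFrac beta diversity with
    PERMANOVA and dispersion-homogeneity testing, a per-animal
    ("vole-by-vole") paired differential-representation procedure with
    supermajority criteria, delta-delta-Ct qPCR quantification, rank tests
    with the |Z|/sqrt(N) effect size, two-way ANOVA with
    Student-Newman-Keuls letters, and community-gated Spearman correlations
    between taxa and phenotypes. Includes a synthetic cohort generator so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
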
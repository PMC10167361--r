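Package: dishmap
Title: Fine-Mapping, Colocalization and Mendelian Randomization for
    Spinal Hyperostosis Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical-genetics toolkit for characterizing diffuse
    idiopathic skeletal hyperostosis (DISH) from GWAS summary statistics:
    variant quality control and locus definition, approximate
    conditional/joint analysis for distinct association signals,
    approximate-Bayes-factor fine-mapping with ranked credible sets,
    Bayesian colocalization with strong/suggestive classification rules,
    two-sample Mendelian randomization (Wald ratio, IVW, MR-Egger,
    weighted median, weighted mode), and a bin-based population
    prevalence projection from ordinal spine flow scores.  A synthetic
    data module generates LD-structured genotype panels, polygenic
    phenotypes, marginal summary statistics, trait pairs, MR scenarios
    and spine-score cohorts with known ground truth, so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
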
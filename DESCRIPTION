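Package: fgmhybrid
Title: Individual-Based Fisher's Geometric Model Simulations of Hybrid and
    Parental Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-in-time, individual-based Wright-Fisher simulations under
    Fisher's geometric model to compare the speed of adaptation of hybrid and
    parental populations after an environmental shift of the phenotypic
    optimum.  Supports diploid, haplodiploid (arrhenotokous), and
    autotetraploid genetic systems, a two-phase scenario design (allopatric
    parental adaptation, hybrid formation, joint adaptation to a novel
    optimum), intrinsic Bateson-Dobzhansky-Muller incompatibilities, simple
    demography with extinction, per-generation summary statistics (mean
    fitness by sex, the adaptation rate dW/(1-W), expected heterozygosity),
    parameter sweeps, and a small command-line interface with reproducibility
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
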
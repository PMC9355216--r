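Package: crisprout
Title: Stochastic Dynamics of Phage Outbreaks Against CRISPR-Cas Immunity
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the early dynamics of a virulent-phage outbreak in a
    bacterial population defending with a naive type I/II or type III
    CRISPR-Cas system. Provides the full stochastic reaction network (spacer
    acquisition, phage escape mutation, interference, autoimmune death), an
    exact Gillespie and an adaptive tau-leaping engine with a deterministic
    mean-field oracle, summary statistics (Simpson diversity, relative
    fitness, extinction predicates, outbreak size), replicated Monte-Carlo
    experiment runners (extinction-probability sweeps, threshold location,
    two-strain competitions, autoimmunity-propensity scans, type-versus-type
    grids) and a PAM-motif protospacer counter for phage genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo: Rcpp
Imports:
    Biostrings,
    Rcpp,
    deSolve,
    jsonlite,
    Matrix,
    methods,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
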
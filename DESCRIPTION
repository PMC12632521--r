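Package: serialcoal
Title: Pairwise Genealogies Under the Structured Serial Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytical propagators for pairwise genealogical quantities under the
    structured serial coalescent with piecewise-constant backward migration and
    coalescence rates on a deme graph: probability density functions of pairwise
    branch lengths, expected pairwise branch-length matrices, and survival
    functions of long pairwise shared coalescent (IBD) segment lengths, all built
    from matrix exponentials of the migration Laplacian and its Kronecker-sum
    two-lineage operator. Includes an exact two-lineage Gillespie simulator (used
    as a Monte-Carlo oracle and to generate grid stepping-stone demographies) and
    a sequential, time-stratified inference protocol that recovers per-epoch
    absolute backward migration rates (and optionally coalescence rates) from
    estimated expected pairwise branch-length matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
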
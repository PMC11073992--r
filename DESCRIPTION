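Package: akrsa
Title: Anna Karenina Models and Group-Consensus Representational Similarity
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether individuals who score high on a trait
    (canonically, loneliness) hold idiosyncratic multivariate representations
    of shared cultural targets. Implements pairwise representational
    similarity (Pearson, cosine, Jaccard), kernel-weighted group-consensus
    representations built from a stress-minimizing multidimensional scaling
    embedding and a Gaussian kernel density mode, dyadic "Anna Karenina"
    linear mixed-effects inference with doubled dyads, Satterthwaite degrees
    of freedom and degrees-of-freedom halving, reliability-based voxel
    selection for split-half imaging data, and a synthetic-data generator
    that plants the assumed statistical structure so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    lmerTest,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
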
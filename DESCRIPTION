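Package: miljifs
Title: Multiple-Instance Learning via Joint Instance and Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-instance learning for bag-structured binary-fingerprint
    data, as arises in drug-activity prediction where a molecule (bag) is
    represented by the pharmacophore fingerprints of its conformers
    (instances). Bags are embedded into an instance-based feature space by
    bag-to-concept similarity (minimum Hamming distance or a Gaussian kernel
    maximum), a sparsity-inducing 1-norm linear classifier is trained by
    linear programming, instances are classified by their contribution to
    the bag decision, top-ranked instances are used to re-fit the classifier
    in the original fingerprint space, and the loop iterates until no
    feature is eliminated, jointly selecting prototype instances and
    discriminative fingerprint bits. Includes a planted-concept synthetic
    data generator, cross-validated regularization selection, an optional
    backward-elimination finalization, and TSV/JSON readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
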
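Package: pgpcrm
Title: Pattern-Generating Potential for Cis-Regulatory Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cis-regulatory modules (CRMs) and infers TF-CRM
    regulatory networks from transcription-factor binding motifs, TF
    concentration profiles along the anterior-posterior embryo axis, and
    binary gene expression patterns. Implements probabilistic (HMM) window
    scoring of sequences with position weight matrices, phylogenetic
    averaging of orthologous motif scores under a Brownian-motion model,
    a logistic-regression model of CRM activity fitted by iteratively
    reweighted least squares, the Pattern-Generating Potential (PGP)
    similarity score with multi-domain subset selection, sliding-window CRM
    discovery with empirical p-values from background scans, and
    permutation-based regulatory edge inference with in-silico knockdowns.
    Includes seeded synthetic-data generators with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
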
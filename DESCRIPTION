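Package: pentascan
Title: Fragment-Based Structural Prediction of Transcription Factor Binding Motifs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based prediction of transcription factor (TF) binding
    motifs by threading DNA sequences onto a solved TF-DNA complex. The
    binding site is split into overlapping 5-bp fragments (pentamers); every
    5-bp sequence permutation is threaded onto each fragment and scored with
    a simplified integrative energy combining a residue-level knowledge-based
    multibody potential with a Coulomb electrostatic term restricted to
    hydrogen-bond and pi-interaction distance windows. Full-length motifs are
    reconstructed from the fragment score tables by Kmer-Sum or PWM stacking,
    with a direct full-length enumeration as a reference, and predicted
    position weight matrices are compared to references via information
    content, IC-weighted Pearson correlation, and averaged Kullback-Leibler
    divergence. Includes an idealized B-DNA fixture builder so the full
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
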
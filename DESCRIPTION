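Package: quatfit
Title: Fast Batched Superimposition of Protein Structure Models by
    Quaternion Gradient Descent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Superimposes large collections of protein structure models
    (molecular dynamics snapshots, docking poses, design ensembles) onto a
    common reference by optimizing one rotation quaternion per structure
    with two-phase gradient descent on a masked alpha-carbon RMSD loss.
    Residue deletions relative to the reference are handled through a
    binary masking matrix, insertions are ignored, and structures are
    processed in fixed-size batches so memory scales with the batch size
    rather than the collection size. The learned rigid transform is applied
    to all atoms and superimposed PDB files are written with non-coordinate
    columns preserved byte-for-byte. Includes a closed-form Kabsch SVD
    solver used as an exact oracle, a synthetic-fixture generator with
    known ground-truth transforms, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
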
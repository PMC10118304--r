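Package: panedit
Title: Sequence, Hydropathy and Structure Analysis of U-Insertion mRNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how uridine-insertion mRNA editing in
    kinetoplastid mitochondria reshapes coding sequences and the proteins
    they encode.  Provides cumulative nucleotide walks and codon-position
    composition tests, inference of inserted and deleted uridines from
    cryptogene/edited-mRNA pairs, cumulative Kyte-Doolittle hydropathy
    profiles, hydrophobic cluster analysis on a duplicated alpha-helical
    net, Shrake-Rupley solvent-accessible surface areas with exposure and
    interface classification, site-wise hydrophobicity comparisons between
    aligned homologs, and seeded generators of synthetic editing pairs,
    diverged sequence sets and toy multi-chain structures for testing the
    whole pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
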
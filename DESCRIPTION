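Package: cxvariants
Title: Domain Distribution and Evolutionary Coupling of Connexin Missense Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing disease-linked and population (gnomAD-style)
    missense variants of gap-junction connexins on a structure-referenced
    domain map. Parses protein-level HGVS variant labels, maps query connexins
    onto a reference cryo-EM segmentation by pairwise global alignment,
    tests per-domain enrichment with an exact two-sided Fisher test and
    length-normalised densities, computes per-position Kullback-Leibler
    conservation from identity-weighted alignments, and extracts co-evolving
    protein sectors from a conservation-weighted covariation matrix via
    spectral analysis against a column-permutation null and independent
    component analysis. Includes seeded synthetic generators for alignments
    with planted co-varying residue groups and for variant cohorts with
    controlled per-domain enrichment, so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralPrediction, VariantAnnotation, Alignment, Genetics
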
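Package: gapclade
Title: Canonical Isoform Selection from Gap-Distance Trees of Orthologous Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects consistent canonical protein isoforms across reference
    proteomes. For each orthogroup the package gathers canonical and isoform
    sequences, computes a gap-only pairwise distance from a multiple sequence
    alignment (amino-acid substitutions contribute nothing; only alignment
    columns where exactly one sequence is gapped count), builds a
    Neighbor-Joining tree on those distances, scans the tree for low-cost
    clades holding at most one sequence per proteome, ranks the clades, and
    reports confirmed canonicals and proposed canonical changes. Also
    provides gap-statistics diagnostics for pairwise proteome comparisons
    from BTOP-encoded best-hit search output, orthogroup extension by an
    identity/coverage rule, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
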
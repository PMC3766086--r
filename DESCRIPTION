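Package: hexaprimer
Title: Degenerate PCR Primer Design from Conserved Peptide Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering homologous genes of a protein family by
    degenerate PCR. Mines conserved hexa- and heptapeptides from sets of
    homologous protein sequences, reverse-translates them into
    inosine-containing degenerate primers using codon-family conventions
    (third-position four-fold degeneracy encoded as inosine, wobble bases
    trimmed from the 3' end, reverse primers complemented, constant 5'
    tails), and predicts amplicons by in-silico PCR of primer pairs against
    DNA templates. Includes seeded generators of synthetic protein families
    with planted conserved motifs and matched DNA templates, so the whole
    pipeline can be exercised and benchmarked without external sequence
    downloads. Developed around glycoside hydrolase (GH6/GH7/GH45) cellulase
    gene discovery, but applicable to any protein family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
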
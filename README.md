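# hexaprimer

Degenerate PCR primer design from conserved peptide motifs, with
in-silico validation.

## What this is for

Many interesting organisms — thermophilic fungi among them — have no
sequenced genome, yet their gene families can be cloned by degenerate
PCR: a short peptide conserved across known homologs is
reverse-translated into a mixture of oligonucleotides that anneals to
the unknown family member's coding sequence. `hexaprimer` implements
that workflow end to end for molecular biologists hunting new family
members (it was shaped around glycoside hydrolase cellulases, families
GH6/GH7/GH45, but is family-agnostic):

* **mine** the most conserved hexa-/heptapeptides from a protein FASTA
  (`mineConserved`),
* **design** inosine-containing degenerate primers from those peptides
  (`buildPrimer`), and
* **validate** primer pairs by in-silico PCR against DNA templates
  (`predictAmplicons`),

plus a seeded simulator of protein families with planted motifs and
matched templates (`generateFamily`, `generateTemplates`) so every
stage is testable offline.

## The method in brief

A peptide pattern `p = p1 p2 ... pk` (each `pi` a set of allowed
residues, e.g. `WR[FY][DN]WF`) is reverse-translated codon by codon
under the standard genetic code. Four-fold degenerate wobble positions
become inosine (I), which pairs with all four bases but is a single
physical nucleoside — so the mixture's *degeneracy* (I counts 1) stays
small while its *coverage fold* (I counts 4) stays large. Two- and
three-fold wobbles use IUPAC codes (Ile = ATH); the six-codon residues
use one codon box each (Leu CTI, Arg MGI, Ser TCI — Ser's missing AGY
box is flagged, never silent). Degenerate bases are then trimmed from
the 3' end of the sense encoding so the polymerase always extends from
a concretely paired terminus; reverse primers take the reverse
complement; and a constant 6-nt 5' tail (default `CTGGAC`) is prepended
to boost the performance of short primers.

Conservation is alignment-free: a peptide's support is the number of
distinct sequences containing a match, and near-identical k-mers can be
greedily merged into bracketed patterns. In-silico PCR scans both
template strands with the primer core only (tails are non-templated),
requiring a zero-mismatch 3'-terminal anchor (default 3 nt) on top of
the overall mismatch budget (default 0).

The package ships the published 20-row GH6/GH7/GH45 primer table as a
golden suite: `verifyTable2()` rebuilds every primer from its (peptide,
direction, tail) triple and reproduces 18 rows character-for-character;
the two remaining rows are flagged as documented 1- and 2-base
deviations (likely manual edits in the source table) and asserted as
such.

## Worked example

```r
library(hexaprimer)

# rebuild the published primer set
table(verifyTable2()$fidelity)
#> deviant   exact
#>       2      18

primerSequence(buildPrimer("LPDRDC", "forward", tail = "CAGGTC"))
#> [1] "CAGGTCCTICCIGAYMGIGAYTG"

buildPrimer("VVTQF", "reverse")
#> PrimerRecord VVTQF_R (reverse)
#>   peptide:  VVTQF
#>   sequence: CTGGACAAYTGIGTIACIAC (tail CTGGAC + core AAYTGIGTIACIAC)
#>   length 20 nt; degeneracy 2; coverage fold 128

# simulate a family with two planted motifs, mine them back, amplify
fam <- generateFamily(nSequences = 12, length = 150,
                      motifs = list(list(pattern = "YWDCCK", position = 30),
                                    list(pattern = "EFTFDVD", position = 100)),
                      substitutionRate = 0.3, seed = 11)
head(mineConserved(fam, k = 6, minSupportFraction = 1)[, 1:5])
#>   pattern k support support_fraction degeneracy
#> 1  FTFDVD 6      12                1          8
#> 2  EFTFDV 6      12                1         16
#> 3  YWDCCK 6      12                1         16

fwd <- buildPrimer("YWDCCK", "forward")
rev <- buildPrimer("EFTFDVD", "reverse")
gen <- generateTemplates(fam, "YWDCCK", "EFTFDVD", seed = 12)
hits <- predictAmplicons(fwd, rev, gen$templates)
nrow(hits); unique(hits$product_length)
#> [1] 12
#> [1] 237
```

Every template yields exactly one amplicon of 237 nt: the 17-nt forward
core, the 200-nt default inter-core spacer, and the 20-nt reverse core.
(All three unanimous hexapeptides above are real — two are windows of
the planted heptapeptide; mine with `k = 7` to recover `EFTFDVD`
whole.)

A command-line wrapper with the subcommands `mine`, `design`, `pcr`,
`simulate` and `table2` is installed at `inst/scripts/hexaprimer.R`:

```sh
Rscript inst/scripts/hexaprimer.R design --peptide LPDRDC \
    --direction forward --tail CAGGTC
```

See `vignettes/degenerate-primer-design.Rmd` for the full account of
the encoding rules, trimming, mining definitions, simulator assumptions
and limitations.

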
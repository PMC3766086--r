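---
title: "Degenerate primer design from conserved peptide motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate primer design from conserved peptide motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexaprimer)
```

## The problem

Cloning new members of a gene family from organisms without sequenced
genomes is classically done by degenerate PCR: protein regions conserved
across known homologs are reverse-translated into mixed-base
oligonucleotides that can anneal to the unknown gene's coding sequence.
`hexaprimer` implements this workflow for short conserved peptides
(hexa- and heptapeptides), the scale at which glycoside hydrolase
cellulase genes (families GH6, GH7 and GH45) have been discovered from
thermophilic fungi. The pipeline has four stages, each usable on its own:

1. **Motif mining** — find the most conserved k-peptides across a set of
   homologous protein sequences (`mineConserved()`).
2. **Reverse translation** — encode a peptide as a degenerate,
   inosine-containing sense-strand DNA core (`encodeSense()`).
3. **Primer construction** — trim, orient, and tail the core into a
   finished primer (`buildPrimer()`).
4. **In-silico PCR** — scan DNA templates with a primer pair and predict
   amplicons (`predictAmplicons()`).

A seeded simulator (`generateFamily()`, `generateTemplates()`) produces
protein families with planted motifs and matched DNA templates so the
whole chain can be validated without downloading any sequences.

## The degenerate alphabet

All primer arithmetic runs over the 15 IUPAC DNA codes plus inosine
(`I`). Inosine base-pairs with all four bases but is a single physical
nucleoside, which motivates the package's two complexity measures:

* `degeneracy()` — the number of distinct oligonucleotide species in the
  synthesized mixture (`I` counts 1). High degeneracy dilutes each
  species and hurts PCR yield.
* `coverageFold()` — the number of concrete template sequences the
  primer can pair with (`I` counts 4).

Complementation maps each IUPAC code to the code of the complemented
base set, and `I` to itself — an inosine keeps pairing with anything on
either strand. `revComp()` is an involution, exercised as a property
test over the full 16-symbol alphabet. Input is case-insensitive and
canonicalized to uppercase; `U` is rejected because this is a DNA-only
tool.

## Reverse translation rules

`codonFor()` maps a residue (or a set of alternative residues) to one
canonical degenerate codon:

* codon families sharing their first two bases encode the third position
  as the IUPAC code of the observed bases, or **inosine when all four
  occur** (four-fold boxes: Ala GCI, Gly GGI, Pro CCI, Thr ACI, Val GTI);
* Ile keeps its three-fold wobble as `ATH` rather than widening to `I`;
* the six-codon residues, split across two codon boxes, use a single
  convention each: Leu `CTI` (CTN family only), Arg `MGI` (CGN plus AGR —
  at the cost of also encoding AGY serine, which is reported in the
  codon's covered set), Ser `TCI` (TCN family only). Ser's codon misses
  the AGY box entirely, so it carries an explicit partial-coverage flag
  that propagates to the primer record. Ser never occurs in the
  published GH peptides; the TCN choice is by analogy with Leu, and the
  flag keeps the limitation visible rather than silent.
* multi-residue alternatives (e.g. `[FY]`, written `WR[FY][DN]WF` in
  pattern text) are merged by position-wise IUPAC union. Merging can
  widen coverage beyond the requested residues; the truly covered
  residue set is always computed by expanding the triplet and
  translating, never assumed.

A fully degenerate union at codon positions 1 or 2 becomes `N`, not
inosine: the inosine substitution is a wobble-position convention.

## Primer assembly

`buildPrimer()` applies, in order: reverse translation, a 3' wobble trim,
orientation, and 5' tailing.

The trim removes bases from the 3' end of the **sense-strand encoding**
while the terminal base is degenerate or inosine, so every primer ends
on a concretely pairing base — the polymerase extends from a matched 3'
terminus. Applying the trim to the sense encoding *before* reverse
complementation is what reproduces the published reverse primers, whose
missing wobble base sits next to the 5' tail rather than at their own 3'
end. For reverse primers the same trim is applied once more after
complementation: complementing can expose a degenerate base at the new
3' end (an Arg-initial peptide's MGI codon complements to a terminal K),
and the second pass — which removes nothing on any published row —
makes the concrete-terminus guarantee universal.

The tail is a constant non-templated 5' extension, 6 nt by default
(`CTGGAC`), added to improve the performance of short primers. The
published set mixes two tails (`CAGGTC` and `CTGGAC`) with no stated
rule, so the golden table stores each row's printed tail verbatim and
the tail is a per-primer parameter everywhere else.

`table2Suite()` ships the twenty published (peptide, direction, tail)
triples; `verifyTable2()` rebuilds each primer and compares it
character-for-character with the printed string. Eighteen rows
reproduce exactly. Two do not and are flagged `deviant` rather than
regenerated or excused: the GWLGWP primer is one base shorter than the
rule output, and the WR[FY][DN]WF primer differs at two internal bases —
most plausibly manual edits or typos in the published table; the intent
is not guessed. The verification asserts their documented deviation
sizes (1 and 2 bases), so a silent drift in either direction fails.

## Motif mining

`mineConserved()` defines "most conserved" as the largest number of
*distinct* sequences containing the peptide, not the total occurrence
count: a primer's value lies in how many species it can amplify, and a
repeat within one sequence adds nothing. No multiple alignment is
performed — conservation is alignment-free containment, which matches
how short catalytic-site peptides recur at varying offsets in unaligned
homologs.

With `maxVariablePositions > 0`, exact k-mers within that Hamming
distance of a seed (processed highest-support first; ties broken by
lower encoded-core degeneracy, then text, so ranking is fully
deterministic) are greedily merged into an ambiguous pattern whose
variable positions carry the union of observed residues — how a pattern
like `WR[FY][DN]WF` arises from `WRFDWF`/`WRYNWF` variants. Defaults:
`k = 6` (hexapeptides; 7 supported for heptapeptides such as EFTFDVD
and EMDIWEA), `minSupportFraction = 0.5` — a deliberate artifact choice,
surfaced in `runConfig()`, since no support threshold is stated for the
original mining.

## In-silico PCR

`findBindingSites()` scans both template strands with the primer *core*
only — tails are non-templated and never affect matching, an invariant
under test. A site must satisfy the total mismatch budget
(`maxMismatches`, default 0) *and* match with zero mismatches over the
3'-terminal `anchorLen` bases (default 3): polymerases do not extend
mismatched 3' termini, and the defaults favor specificity since no
in-silico matching was part of the original workflow. Template `N`
matches nothing at budget 0 (conservative). Coordinates are 0-based
half-open on the + strand; product length runs from the 5' end of the
forward binding site to the 5' end of the reverse binding site and
excludes tails (a gel band for a tailed pair runs a constant
2 × tail-length larger). Degenerate positions match by base-set
membership with no transition/transversion weighting, since nothing in
the source workflow justifies a weighting.

A known limitation: genomic templates of fungal genes contain introns,
so real amplicons from genomic DNA exceed coding-sequence predictions.
The simulator can insert `GT...AG` introns to quantify exactly this
shift, but the scanner itself is intron-unaware by design.

## The simulator, and what passing tests do not show

`generateFamily()` draws an ancestor uniformly over the 20 residues,
plants motifs at fixed positions, and derives homologs by i.i.d.
per-site substitution outside motif spans. Each motif is retained in
exactly `round(fraction * n)` sequences; in the others its span is
resampled until it no longer matches, so conservation fractions are
exact by construction. The benchmark conditions used throughout the
tests — 20 homologs, 300 residues, substitution rate 0.3, one fully
conserved hexapeptide — emulate a small, diverged GenBank family of the
size one would realistically assemble for a fungal GH subfamily; under
them the planted motif must rank first in at least 95 of 100 seeded
runs.

`generateTemplates()` back-translates each protein from its start
through the forward motif and from the reverse motif through its end,
drawing codons uniformly from each residue's **full** codon set, and
joins the two coding regions with a random non-coding stretch sized so
the distance between the two core binding sites equals the drawn spacer
(200 nt by default; the stretch is shortened by the 0–2 trimmed wobble
bases so the inter-core distance is exact). Drawing from the full codon
set means Leu/Arg/Ser wobble positions can fall outside a core's
coverage — intentionally, so the partial-coverage flags correspond to
real, observable binding failures. Zero-mismatch site uniqueness is
enforced by bounded resampling of the codon choices.

The simulator is deliberately simple: i.i.d. substitution with no
phylogenetic tree structure, no indels, no codon-usage bias, uniform
background composition. Passing its benchmarks shows the machinery is
correct and deterministic, not that mining thresholds or mismatch
budgets transfer to any particular real protein family.

All generators take explicit integer seeds, restore the caller's RNG
state, and are pure functions of their arguments; regenerated FASTA
output is byte-identical.

## Numerical and interface choices

* Expansion (`expandDegenerate()`) refuses to enumerate above an
  explicit limit rather than silently truncating.
* Degeneracies are returned as doubles: a long fully degenerate pattern
  overflows 32-bit integers.
* Tables are TSV (tab-separated, unquoted, UTF-8) with stable column
  order; FASTA wraps at 60 columns; inosine is written as plain
  uppercase `I`, a documented non-standard FASTA extension.
* `primerCli()` exposes the subcommands `mine`, `design`, `pcr`,
  `simulate` and `table2`; logging goes to standard error so result
  streams compose in pipelines. The same function backs the shipped
  `inst/scripts/hexaprimer.R` wrapper and the in-process tests.
* `PCRProfile` records the thermal metadata the primers are run with
  (default: 95 °C/5 min; 30–40 cycles of 95 °C/20 s, annealing 30 s,
  72 °C/60 s; 72 °C/5 min). The annealing temperature defaults to `NA`
  because it is optimized per primer set, not predicted — melting
  temperature prediction is out of scope.

## Worked example

```{r example}
suite <- verifyTable2()
table(suite$fidelity)

primerSequence(buildPrimer("LPDRDC", "forward", tail = "CAGGTC"))

fam <- generateFamily(nSequences = 12, length = 150,
                      motifs = list(list(pattern = "YWDCCK", position = 30),
                                    list(pattern = "EFTFDVD", position = 100)),
                      substitutionRate = 0.3, seed = 11)
head(mineConserved(fam, k = 6, minSupportFraction = 1)[, 1:5])

fwd <- buildPrimer("YWDCCK", "forward")
rev <- buildPrimer("EFTFDVD", "reverse")
gen <- generateTemplates(fam, "YWDCCK", "EFTFDVD", seed = 12)
hits <- predictAmplicons(fwd, rev, gen$templates)
nrow(hits)
unique(hits$product_length)
```
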
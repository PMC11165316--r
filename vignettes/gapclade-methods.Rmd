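---
title: "Gap-distance clades for canonical isoform selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-distance clades for canonical isoform selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapclade)
```

## The problem

Reference proteomes distribute one *canonical* protein per gene. For
unreviewed (TrEMBL) entries the canonical is typically the longest isoform
in the gene's Gene-Centric group, which produces biologically implausible
inconsistencies: orthologous proteins that are more than 90% identical in
sequence but differ in length by dozens or hundreds of residues, because
different species' genes had different isoforms picked. In pairwise
alignments these wrong picks show up as long alignment gaps — bacterial and
yeast proteomes, which effectively lack isoforms, almost never show gaps of
five or more residues between >90%-identical orthologs, while mammalian
proteome pairs show them in 10–30% of such alignments.

`gapclade` selects, for each orthogroup (a set of orthologous genes across
proteomes), a clade of isoforms — at most one per proteome — that align
essentially without gaps, and uses it to either confirm the current
canonicals or propose an isoform switch.

## The gap-only distance

Given a multiple sequence alignment of all canonical and isoform sequences
of an orthogroup, the distance between rows $a$ and $b$ is

$$ d(a,b) \;=\; \frac{\#\{\text{columns where exactly one of } a,b
\text{ is gapped}\}}{\#\{\text{columns where at least one of } a,b
\text{ has a residue}\}} $$

Substitutions contribute nothing: two gap-free rows are at distance zero no
matter how many residues differ, and a single 5-residue gap over an
effective length of 100 gives 0.05. Three choices deserve comment:

* **Columns gapped in both rows are excluded** from numerator and
  denominator. Such columns are some third sequence's insertion; keeping
  them would create phantom distance between two rows with identical gap
  structure.
* **Terminal gaps count exactly like internal gaps**, so clade members are
  forced to similar overall lengths, not merely similar internal exon
  structure.
* **The denominator is the pairwise effective length**, not the full MSA
  width. For a two-sequence alignment this reproduces "gap length /
  alignment length" exactly; in a many-row MSA it keeps a pair's distance
  invariant to unrelated rows' insertions. (For multi-row alignments the
  normalisation is genuinely ambiguous in the field's informal usage; this
  package fixes the pairwise convention.)

The implementation is a single matrix product on the gap-indicator matrix,
and is checked against a literal per-column counting oracle on a thousand
random alignments, including exact invariance under random residue
substitution.

## Trees and the clade search

A Neighbor-Joining tree is built from the gap-distance matrix. NJ is
implemented in the package rather than delegated, for one reason:
gap-distance matrices are full of *exact ties* (zero blocks are the normal
case), and reproducible output requires a defined tie-break. At each step,
among all pairs minimising the Saitou–Nei $Q$ criterion (within a relative
tolerance of $10^{-12}$), the pair whose sorted representative labels (each
cluster represented by its smallest descendant leaf label) is
lexicographically smallest is joined. Negative branch-length estimates —
possible in NJ — are clamped to zero, since downstream costs must be
non-negative; clamps are counted on the returned tree. On additive
matrices the tree reproduces all leaf-to-leaf path lengths to $10^{-9}$,
and its topology agrees with `ape::nj` (used purely as an independent
cross-check) on random matrices.

The **cost of a clade** is the *maximum* pairwise gap distance among its
members. The maximum, rather than a mean or a branch-length sum, is the
strictest reading of "low-cost": cost zero then means literally that every
pair of members aligns without one-sided gaps, and any single aberrant
member disqualifies a clade. A clade is accepted when it spans at least
`min_proteomes` (default 3) distinct proteomes and its cost is at most
`cost_threshold` (default 0.02, *inclusive* — observed clade costs
distribute between zero and the threshold, with about half exactly zero on
realistic data).

The search examines **every bipartition side of the unrooted tree**, not
only the descendant sets under the traversal root. The final NJ
agglomeration node is an arbitrary rooting artifact; a genuine low-cost
clade can sit "across" the root trifurcation, where a descendant-only scan
would never assemble it. Exhaustive bipartition scanning is cheap at
orthogroup scale (tens of sequences).

Within a tree clade, several isoforms of one proteome often co-cluster.
The clade then keeps, per proteome, the sequence with the smallest summed
gap distance to the clade members of *other* proteomes (so rival isoforms
do not influence each other's score), with ties resolved canonical-first,
then reviewed-first, then by accession. Candidates from nested nodes that
resolve to the same member set are reported once; a candidate strictly
contained in another is dropped in favour of the larger (largest proteome
coverage, then lowest cost). A consequence worth knowing: raising the cost
threshold can *replace* a reported clade by a larger one that absorbs it —
the correct monotonicity statement, which the tests assert, is that every
clade accepted under a stricter setting is contained in one accepted under
a laxer setting.

## Ranking, selection, and policy

Accepted clades of an orthogroup are ranked by strict lexicographic
priority: (i) lower cost; (ii) more proteomes; (iii) more canonical
members; (iv) more reviewed human/mouse members; (v) smaller relative
length deviation $|\mathrm{med}(L_{clade}) -
\mathrm{med}(L_{canon})|/\mathrm{med}(L_{canon})$; ties fall back to the
smallest member accession so the order is total. The criteria are widely
agreed on but their combination is not; order-as-priority is the only
parameter-free reading, and planted-truth validation is deliberately
designed so the winner dominates on criterion (i) and is insensitive to
this choice.

Selection is greedy over Gene-Centric gene sets: the best clade is always
selected, and further clades only if their member gene groups are disjoint
from everything already selected — one orthogroup can thus confirm one set
of genes while proposing changes for another ("both" in the run summary).

Every member of a selected clade yields one suggestion: `confirm` if it is
its gene group's current canonical; otherwise a switch to the member's
base accession, emitted as `propose_change` when the displaced canonical
is unreviewed, and as `flag_reviewed` when it is reviewed — **reviewed
(Swiss-Prot) canonicals are never changed automatically**; those rows are
for curators. The run summary counts both kinds under `proposed_changes`
(with `flagged_reviewed` tallied separately), and its group counts satisfy
the partition identity
`skipped + no_low_cost + confirmed + proposed + both + failed = total`
on every run; orthogroup failures are isolated, logged, and counted.

## Gap statistics from BTOP encodings

The diagnostic module decodes BTOP (BLAST trace-back operations) strings —
integer identity runs, residue-pair mismatches, `X-`/`-X` gap columns —
into event lists, merging adjacent same-side gap columns into single gap
events. Per alignment it reports BTOP-derived percent identity (printed
identities are only cross-checked, to 0.1), the number of gap events, and
the longest gap regardless of side. Best-hit filtering keeps, per query
strictly longer than 100 residues, the hit with the lowest E-value
(strictly below $10^{-6}$; ties by bit score, then subject accession).
Identity bins in the pair-statistics table are half-open $[lo, hi)$ of
width 1, with the last bin closed at 100; the ">90% identical" subset is
strict.

## Orthogroup extension

Proteomes without curated orthology are mapped by searching them against
the human proteome: a sequence inherits the orthogroup of its best
qualifying human hit, where qualifying means identity $\ge 50\%$ and
alignment coverage $> 75\%$ of the *human* sequence length. Coverage is
measured in human coordinates — alignment columns minus the columns gapped
on the human side, decoded from BTOP. The two boundary conventions are
configurable (`mapping_rule()`), since published usage varies between
"$\ge$" and "$>$" at both cutoffs; the defaults are inclusive identity,
strict coverage. The best hit is the highest-identity qualifying one (ties
by coverage, then accession), independent of input order.

## The synthetic-data generator

All validation runs on generated data with planted truth; nothing is
downloaded and no external aligner is invoked (the generator emits the
true alignment, since its exon blocks define the columns).

Each synthetic gene is 3–6 exon blocks of 25–60 residues. The *truth*
isoform — present in every proteome — is the concatenation of the core
blocks, diverged by i.i.d. amino-acid substitutions only (default rate
0.05 per residue per proteome branch), so the truth clade has gap cost
exactly 0 by construction. A *decoy* proteome's current canonical instead
carries an N-terminal extension, emulating the commonest real failure mode
(a longest-isoform canonical with an N-terminal extension relative to the
orthologous clade); the truth isoform is still present in its Gene-Centric
group as a separate unreviewed entry. Extension lengths are
proteome-specific and spaced 20 columns apart (40, 60, 80, …), which
guarantees — given the block-length ranges — that every decoy-containing
pair has gap distance well above the 0.02 threshold: the planted truth
clade is the unique admissible low-cost clade, and recovery can be
asserted at 100%, not merely "high". Optionally each proteome also gets a
cassette-skip isoform (one core block missing, a different block per
proteome) to exercise duplicate-proteome resolution.

Default study conditions: 6 proteomes, 30% of proteomes per orthogroup
decoyed, human and mouse canonicals reviewed, decoy canonicals unreviewed
(so planted changes are auto-applicable). The proteome-pair generator
plants exact fractions — by default 50% of alignments above 90% identity
and, within that subset, 20% carrying a gap of at least 5 residues
(sampled 5–120 columns) — recovered exactly by the statistics module.

What the generator does *not* emulate: alignment error (its alignments are
true by construction), codon-level or indel evolution inside shared exons,
paralogy, partial orthogroup membership, and the long tail of annotation
artifacts in real proteomes. Passing the planted-truth suite therefore
demonstrates correctness of the machinery under the stated model — clean
exon-block isoform structure — not performance on real UniProt releases.

## Problem sizes and numerical choices

The shipped validation uses 1000 random alignments for the distance
oracle, 200 additive and 200 random matrices for NJ, 200 small
orthogroups for brute-force clade-search equivalence, a 500-orthogroup /
6-proteome study for planted-truth recovery (re-run a second time after
applying the proposals, which must leave zero remaining proposals and
zero-cost clades), and a 400-alignment proteome pair for the gap
statistics; `scripts/acceptance.R` re-runs the study and diagnostics from
scratch for any seed. Ties in $Q$ are compared within $10^{-12}$
relative tolerance; additive recovery is asserted at $10^{-9}$; all
planted-truth assertions are exact (`==`), never approximate, because the
generator makes them exact by construction. Degenerate inputs are
contracts, not silent fallbacks: an all-gap column pair is an error, a
singleton clade costs 0 with a warning, an empty canonical-length set
yields penalty 0 with a warning.
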
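---
title: "Comparative mitogenomics with mitocomp: models, conventions and design choices"
author: "mitocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope

`mitocomp` analyses small circular mitochondrial genomes of the
standard animal type: 37 genes (13 protein-coding genes, 22 tRNAs, two
rRNAs) plus an A+T-rich control region (CR) that harbours replication
and transcription signals, and frequently a short stem-loop-forming
light-strand replication origin (OL). The package grew out of
comparative spider mitogenomics, where genomes are unusually compact,
tRNAs are heavily truncated (neighbouring genes overlap), and the gene
order has diverged from the ancestral arthropod arrangement retained
by the horseshoe crab *Limulus polyphemus*.

The pipeline has four layers: annotation arithmetic, sequence
statistics (composition, codon usage, substitution metrics,
control-region structure), gene-order analysis (boundaries, blocks,
synapomorphies), and rearrangement-event inference with tree-based
reconstruction. Each layer is usable on its own.

## Coordinates and annotation arithmetic

Coordinates are 1-based inclusive on the majority strand throughout;
conversion to 0-based half-open happens only inside sequence slicing.
Genomes are circular by default and genes may span the origin
(`stop < start`); sizes are always recomputed on the circle
(`size = ((stop − start) mod L) + 1`), and a `size` column that
disagrees with its own coordinates is overridden with a warning. The
parser rejects non-positive coordinates and unknown gene tokens
(listing the canonical vocabulary), since silent guessing is how
annotation errors propagate.

Spacers between consecutive genes use the convention
`IGN = start(i+1) − stop(i) − 1`, negative values meaning overlap;
strand is ignored because both strands share one coordinate system.
`pairwiseOverlap()` intersects position *sets* on the circle, so it is
symmetric, handles origin-spanning genes, and `overlap(a, a)` equals
the gene's size. `exclusiveResidues()` counts positions covered by no
other locus; it is clamped at zero by construction, which matters for
extremely truncated tRNAs that are fully covered by their neighbours.

GenBank flat files are read and written by a minimal single-record
parser (plain and `complement(a..b)` locations; `/gene`, `/product`
and `/anticodon` qualifiers; the ORIGIN block). Feature names map onto
canonical tokens through an editable synonym table; tRNA-Leu/Ser
without an anticodon qualifier is an error rather than a guess,
because the L1/L2 and S1/S2 distinction is exactly what downstream
gene-order analysis depends on.

## Composition, codon usage and substitution statistics

Skews are computed as `(A − T)/(A + T)` and `(G − C)/(G + C)` on the
deposited majority strand; per-class partitions (PCG/tRNA/rRNA/CR)
concatenate transcription-direction sequences, because that is how
gene-class AT content is conventionally reported. Whether published
per-class values used deposited-strand or transcription-direction
sequence is usually unstated; we chose transcription direction and
document it here. Ambiguity codes are excluded from numerators and
denominators alike and reported separately. Percentages are kept at
full precision; rounding is a display concern.

The genetic code defaults to the invertebrate mitochondrial code
(NCBI translation table 5) and is configurable everywhere. RSCU uses
the standard definition (count scaled by uniform-usage expectation
within the synonymous family); families with zero usage are reported
missing rather than zero. "High-frequency" codons are those with
RSCU > 1, excluding single-codon families.

ENc is Wright's homozygosity estimator. For each family with
`n ≥ 2` sampled codons, `F̂ = (n Σ p̂ᵢ² − 1)/(n − 1)`; class means
`F̄_k` combine into `ENc = Σ_k N_k / F̄_k` over the degeneracy classes
of the genetic code in use. For the standard code this reduces to
Wright's `2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`; table 5 has classes
{2, 4, 6, 8}, and the value is capped at 61 so the familiar
20–61 range holds for every code. A class with no usable family
borrows the mean `F̂` of all usable families — a documented
generalisation of the usual missing-class rule. Published ENc values
computed by other tools can differ by a few tenths depending on the
variant, so cross-tool comparisons should carry a tolerance of about
±0.5.

Ka/Ks is Nei–Gojobori (1986): per-codon synonymous site fractions
averaged over the two sequences, difference counts averaged over all
shortest substitution pathways (pathways through stop codons excluded
whenever a stop-free pathway exists), Jukes–Cantor correction
`d = −(3/4)ln(1 − 4p/3)` applied to both proportions, `NA` when
`p ≥ 3/4` (saturated). Mutations to stop codons count as
nonsynonymous for site fractions. Other common methods
(Li 93/Pamilo–Bianchi, ML codon models) give systematically different
values; comparisons against numbers produced by other software should
allow ±0.02 or more. Transition/transversion curves use raw counts
with the K2P distance; pairs whose logarithm argument collapses are
flagged saturated rather than silently dropped.

The saturation index is the entropy ratio `Iss = H_obs / H_fss`:
mean per-site Shannon entropy across taxa over the *expected*
per-site entropy under full saturation, computed exactly by
enumerating base compositions of the taxon count under a multinomial
with the observed base frequencies. Using the exact finite-sample
expectation (rather than `−Σ f log f`) is what makes the fully
saturated simulation converge to 1 at small panel sizes. Critical
values for the index are topology-dependent simulation quantities and
are out of scope; the report prints the index itself.

## Control-region structure

Tandem repeats are exact, maximal, primitive arrays: the unit is not
itself periodic, the array extends in neither direction, and a partial
trailing copy is reported separately
(`copies × unit + partial = span`). Overlapping arrays with different
units are all reported, ordered by start then unit length. Mismatch-
tolerant repeat detection is deliberately out of scope — published
mitochondrial CR repeats are exact motifs. Motif scans count
non-overlapping occurrences left-to-right by default with an
`overlapping = TRUE` option; for the motifs that matter here the two
conventions coincide.

Stem-loops are found per pairing diagonal (positions `i` and `j` with
`i + j` constant), reporting maximal complementary windows; defaults
are `minStem = 5` bp, `minLoop = 3` nt, no mismatches, Watson–Crick
pairs only (G–T wobble off). The best hit is the longest stem, ties
broken by smaller loop then leftmost position.

## Gene orders, boundaries and synapomorphies

A `GeneOrder` is a signed circular permutation, canonically rotated to
start at *cox1*; two orders are equal iff one is a rotation of the
other. The CR is excluded from orders by default but can be carried as
a 38th locus (`includeCR = TRUE`); OL is never a locus.

A boundary is the adjacency of two consecutive signed genes read in
canonical direction; an order over *n* loci yields exactly *n*
boundaries. Under signed matching, the same physical junction read
from the other strand, `(−b, −a)` versus `(a, b)`, is normalised to
one key; an inverted gene therefore breaks both flanking boundaries.
Sign-insensitive matching (`signed = FALSE`) treats the unordered gene
pair as the identity. Both conventions are exposed because published
boundary tallies are not always computable under a single consistent
rule: a sign-sensitive reading is needed for an in-place inversion to
create "new" boundaries, while a sign-insensitive reading is needed
for a boundary to be shared across taxa that differ only in a gene's
strand. The package default is signed; the packaged panel analyses use
`signed = FALSE, includeCR = TRUE`, the combination under which the
largest subset of the published narrative statements is
simultaneously true.

Classification against an ancestor labels each boundary plesiomorphic
(key present in the ancestor) or derived; cross-taxon tallies report
unique boundaries (one taxon), shared-derived types with repeat
counts, and the exact identity
`Σ per-taxon derived = unique + Σ repeats`, which is asserted in the
tests on every panel. Conserved blocks are maximal runs of consecutive
ancestral genes whose internal boundaries are retained by every taxon
in a caller-chosen scope; block labels follow ancestral reading order.
Note that a formal maximal-run definition can extend a block past a
boundary that a published figure happened to stop at; the per-block
`retained_in` column is the robust quantity.

A derived boundary type is synapomorphic for the smallest clade
containing all its possessors, provided every tip of that clade
possesses it and the clade has at least two tips (strict,
homoplasy-free criterion); single-tip types are autapomorphic, the
rest homoplastic. The reference topology is an input, never inferred
here.

## Event inference and reconstruction

`inferEvents()` explains one order by another with a deterministic
greedy heuristic, in this priority: (1) any contiguous window of
displaced genes (≥ 3) that a single tandem-duplication–random-loss
step turns into its target arrangement — same strands, contiguous in
both orders, two-increasing-subsequence partition test, not
achievable by relocating one gene, and strictly reducing the
breakpoint distance — becomes one TDRL; (2) otherwise single genes
are peeled in order of how much their removal shrinks the adjacency
mismatch, each relocation classified as transposition (moved),
inversion (flipped in place) or inverse transposition (both), and
accepted only if it strictly reduces the breakpoint distance; (3) as
a fallback, short contiguous blocks (2–3 genes) that the target keeps
intact or reversed-and-flipped are moved as units. If no rule makes
progress the scenario is returned with an unresolved residue — a
legal outcome, flagged, never silently patched. Every resolved
scenario replays exactly; this is asserted on all outputs including
fuzzed pairs.

Two conventions deserve emphasis. First, when both orders carry the
CR it is pinned as an immovable landmark: it is not a gene, and
rearrangements are conventionally described relative to it. This is
what lets a tRNA pair that hops across the CR be reported as tRNA
moves rather than a CR move. Second, an adjacent swap has two equally
valid single-gene descriptions ("X moved past Y" / "Y moved past X");
the event records the partner (`swappedWith`) so reports can name
either gene, instead of pretending the choice is informative. The
TDRL test is the two-subsequence partition in its interleaving form,
which also covers patterns that pedantically require a duplication
plus one transposition; this matches how tree-rearrangement tools in
this field report single TDRL events and is documented as a
relaxation. TDRL inference runs source-to-target only, as the event
is asymmetric.

`reconstructAncestors()` performs parsimony over the set of distinct
arrangements observed at the tips: directed event costs between
states come from `inferEvents()`, a postorder pass scores each state
at each node, and a preorder pass fixes each node to the state
minimising parent-branch plus subtree cost (ties prefer the parent's
state, then the lexicographically smallest token string). Nodes are
labelled `consistent` (unique minimiser), `one_consistent` (tie) or
`fallback` (a branch scenario with unresolved residue), mirroring the
green/yellow/red node-colouring convention of tree-based
rearrangement analyses; the labels are analogous to, but not
algorithmically identical with, the consistency levels of the
established tool, so published consistent-node counts are not a
binding target. Restricting candidate states to observed tip
arrangements keeps the search exact-within-its-space and fast; truly
novel ancestral arrangements are outside that space, a documented
limitation.

`geneOrderTree()` is neighbour joining on the breakpoint-distance
matrix — a distance stand-in with the same input/output contract as
likelihood gene-order inference (orders in, tree out), stated
prominently because the estimator differs. Taxa with identical orders
are collapsed before NJ and re-attached as zero-length ladders with
name-sorted determinism, which resolves what would otherwise be
polytomies.

## Synthetic data: what it emulates and what it does not

The generators define the package's study conditions and are not
tuning knobs.

* `evolveOrders()` starts at the ancestral arthropod order and draws
  per-branch events (default one expected event per branch; kind
  weights 0.5/0.2/0.15/0.15 for transposition/inversion/inverse
  transposition/TDRL, short blocks, TDRL blocks of 3–6 genes with
  duplication–loss semantics). Every event is logged and the truth
  log replays bit-exactly; identical seeds give identical output.
* `simulateCdsPanel()` evolves codons on a star phylogeny under a
  mutation–selection scheme: third-position GC target 0.2 (matching
  the strong AT bias at synonymous sites of spider mitogenomes),
  transition weight κ = 2, nonsynonymous acceptance ω, branch length
  0.1 expected mutation attempts per site. There is no rate
  heterogeneity, no indels, no CpG effects; it is a calibration
  instrument for the estimators, not a biological model. Recovery
  gates used in the tests: ω within ±0.1 at 5,000 codons, GC3 within
  ±0.03, and ω-ordering recovery.
* `buildGenome()` lays an order on a circle with a configurable
  spacer/overlap pattern and an optional origin rotation, writes
  in-frame PCGs (ATG…TAA, no internal stops), and builds a CR of 365
  nt at 68% AT with planted `ATTTTTATTC ×2` and `CATATA ×6` arrays
  and a planted 7 bp stem / 13 nt loop element — the published
  control-region features of the tarantula genome. Non-pairing
  separators stop planted arrays from extending into the flanks, so
  planted truth is recovered exactly.

Passing tests on these data show the estimators and the event
machinery are correct under the stated conditions; they do not show
robustness to alignment error, indels, rate heterogeneity or
annotation noise in real data.

## Fixtures and their provenance

Four fixtures ship under `inst/extdata/`: (i) the tarantula
(*Lyrognathus crotalus*, MN072398) annotation table; (ii) the
ancestral arthropod (Limulus) 37-gene order with the CR as a 38th
locus; (iii) a 17-taxon spider gene-order panel; (iv) the reference
topology used for synapomorphy mapping. The annotation table was
transcribed from the published table and verified row-by-row against
its own spacer column; where the publication disagrees with itself
(total genome length printed two ways; a printed CR length of 356 bp
versus coordinates spanning 365; a printed tRNA total of 1,329 bp
versus column entries summing to 1,402), the fixture keeps the
coordinate-consistent reading and the discrepancy is surfaced, not
resolved. The panel's non-tarantula rows are reconstructions from the
published narrative (identical-arrangement groups, per-branch events,
block retention, synapomorphy statements); the original supplementary
listing was unavailable, so family-private relocation destinations
are explicit reconstruction choices flagged in the file's provenance
column, and whole-panel tallies computed from the reconstruction are
approximate at that level. Tests that depend on those tallies are
marked accordingly.

## Numerical and degenerate-input conventions

All tie-breaks are lexicographic (genes, states, taxa); nothing
outside the simulators draws random numbers. Percent-scale
comparisons in the tests use absolute tolerances; regression slopes
on noise-free input are exact to 1e-9. Degenerate inputs are defined,
not rejected: a single-gene genome yields one circular self-spacer; a
constant alignment has saturation index 0; identical orders give an
empty, resolved scenario; an empty family set makes ENc an error
(there is nothing to estimate). Events that would wrap the canonical
anchor are never generated; the anchor gene (*cox1*) is stable by
construction.

## Known limitations

* The event heuristic is not a minimum-event sorter (that problem is
  NP-hard for TDRL mixtures); its guarantee is replay-exactness and a
  sane event-count envelope, checked by fuzzing.
* Ancestral reconstruction searches only arrangements observed at the
  tips.
* The GenBank parser handles single-record files with the common
  feature types; it is not a general-purpose flat-file library.
* Iss critical values, thermodynamic folding of the CR, de novo
  annotation and sequence-based phylogenetics are out of scope.
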
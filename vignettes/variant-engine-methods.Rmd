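---
title: "Methods: the strainforge variant-calling and genome-engineering engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the strainforge variant-calling and genome-engineering engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(strainforge)
```

This vignette documents the models, parameters, and design choices behind
the package — what each stage assumes, which knobs matter, and what the
simulation-based tests do and do not establish about real data.

## Scope and data model

The engine targets clonal haploid microbial resequencing: many clones, one
(possibly multi-replicon) reference, short paired-end reads. All internal
coordinates are 0-based half-open; conversion to the 1-based conventions
of GenBank and VCF happens only in the readers/writers. The common
currencies are tibbles — alignment records, variant rows, per-sample
calls, the melted evidence table — plus two light S3 containers:
`ref_genome` (sequences + feature tibble + version lineage) and
`placement_graph` (contig/reference-fragment nodes, alignment edges).

## Read alignment

The internal aligner is a seed-and-extend mapper, not a BWA-class
general-purpose tool, and is sized for the data this package is meant for
(tens of kilobases to a few megabases, Illumina-length reads, low
substitution error):

* exact 21-mer seeds at five positions per read, hashed against the
  reference; seeds vote for diagonals;
* per-diagonal vectorised comparison; a read matching end-to-end with at
  most `max_mm = 5` mismatches is reported as a full match;
* otherwise the matching block around the seed is extended base by base —
  an isolated mismatch is absorbed when followed by four matching bases,
  anything denser stops the extension — and the remainder is soft-clipped.
  This mimics the local-alignment behaviour that matters downstream:
  sequencing errors inside a read are tolerated, but the foreign tail of a
  junction-spanning read is clipped rather than forced;
* clipped tails of at least `min_split = 25` bases are re-seeded
  independently and emitted as supplementary records with `SA` tags
  (split reads);
* equal-scoring placements (identical repeat copies) are broken by a
  deterministic per-read hash so coverage spreads across copies instead of
  piling onto one — the classical cause of phantom coverage dropouts over
  repeats — and such reads get `MAPQ 0`;
* proper-pair calling uses the *median* and *MAD* of the fragment-size
  distribution (window: 3 scaled MADs). A robust scale matters:
  SV-spanning pairs are exactly the outliers that would otherwise widen a
  mean/SD window until deletion-spanning pairs looked proper.

There is no gapped extension: indels inside reads surface as
clips/splits, which is precisely the signal the SV machinery consumes.
Indels are therefore *not* called by the pileup genotyper (see below) —
mirroring the separation between an SNV caller and the assembly/coverage
SV callers.

## Pileup genotyping and the GT_TYPE trichotomy

SNVs are called from a pileup of primary alignments (supplementary records
excluded). Each site with non-reference evidence and depth ≥ `d_min = 5`
is genotyped under a symmetric binomial mixture over diploid allele
fractions {0, ½, 1} with a flat prior; per-read error probabilities come
from base qualities. The maximum-posterior class maps to
`GT_TYPE` 0 / 1 / 2. Running a *diploid* model on haploid clones is
deliberate: the heterozygous class absorbs sites where only a fraction of
reads support the variant — regional duplication, non-unique mapping, or a
non-clonal culture — so marginal evidence is surfaced rather than
silently rounded to a hard call. The genotype quality is the phred-scaled
complement of the winning posterior, capped at 99.

With Q30 bases the decision boundary between "wild type with coincident
errors" and "marginal" sits near 3 alternate reads out of ~30, so at the
30× design coverage coincident sequencing errors essentially never reach a
call; at materially lower coverage occasional `GT_TYPE 1` artifacts are
expected and are exactly what the marginal class is for.

## Candidate reads, assembly, and the placement graph

Reads classified `unmapped`, `clipped` (≥ `s_min = 10` clipped bases),
`split`, or `discordant_pair`, plus their mates, are the assembly input.
The assembler is a compact de Bruijn implementation in the Velvet mould:
k = 31, k-mer coverage cutoff 3 (counting both strands, i.e. two physical
observations), dead-end tips up to 2k nodes clipped, maximal
non-branching paths emitted, contigs reported in canonical orientation
and dropped under `l_min = 200` bp.

Contigs are aligned back by exact 21-mer anchors merged per diagonal and
extended base-by-base, both orientations, all replicons. Edges nested on
the contig are dropped, equal-span placements over identical repeat
copies are collapsed to one flagged (`multi`) representative, and
overlapping chain edges are trimmed so edges abut on the contig. Edges
mostly ( ≥ 80 %) inside an annotated `mobile_element` feature inherit the
element's label. Reference fragments are created by splitting each
replicon at every junction point observed across edges, so the node set is
data-driven.

Traversal calls, per consecutive edge pair on a contig:

* **deletion** — colinear edges, no contig gap, reference gap ≥ 50 bp;
* **novel insertion** — no reference gap (or a small *negative* one, see
  below), contig gap ≥ 20 bp; the unaligned interior is the insert;
* **mobile-element insertion** — a flank edge meeting an element edge is a
  junction signature; a left and a right signature for the same element at
  the same site (± 20 bp) are paired into one call citing 4 edges.

Two subtleties dominate breakpoint exactness. First, flank alignments
over-extend by chance into an insert whose first bases happen to match the
reference; the resulting negative reference gap is reconciled exactly
(the mutant locally equals `ref[..q1) + interior + ref[q2..)`, which is an
insertion of `interior ++ ref[q2,q1)` at `q1`). Second, all indel calls —
and the simulator's truth table — are **left-normalized** (the standard
VCF convention), so "exact breakpoint" comparisons are between canonical
representatives of the homology equivalence class rather than arbitrary
members of it.

Element-interior reads of a *new* element copy align cleanly to the donor
copy and enter the candidate set only through their discordant mates, so
assembly normally produces two junction contigs (2 + 2 = 4 edges) rather
than one element-spanning contig; with the default element length
(1,340 bp) and fragment size (300 ± 30) this topology is stable. When
identical donor copies make the source ambiguous, the insertion *site* is
still reported authoritatively and the call is flagged `multiplacement` —
the site, not the donor, is what downstream analysis needs.

The coverage-based deletion caller is independent: maximal runs of at
least `r_min = 100` bases with depth ≤ `eps = 0.1` × replicon median.
Assembly and coverage calls at the same locus are *both* emitted with
distinct `METHOD` values (and distinct ids); deduplication is left to the
query layer, because collapsing them would hide exactly the disagreement a
reviewer wants to see.

## Effect annotation

A feature-based annotator intersects variants with CDS features and
translates through the standard genetic code (the bacterial table differs
only in start-codon policy, which this annotator does not use),
strand-aware. Impact classes follow the four-level convention: nonsense /
frameshift / element-insertion-upstream → HIGH, missense /
in-frame-indel → MODERATE, synonymous → LOW, upstream / intergenic →
MODIFIER. The upstream window is `u_up = 200` bp — generous for bacterial
promoters, chosen so regulatory disruption by an upstream IS insertion is
never silently MODIFIER. Overlapping genes: the most severe effect is
reported, the rest listed in `eff_others`.

## Evidence table, query language, variant sets

`build_evidence_table()` melts variants × samples into one row per pair;
samples without a call at a site appear explicitly with `GT_TYPE 0`,
`DP 0`. Uppercase column keys double as query keys; `INFO_`-prefixed keys
map to VCF INFO fields; a `replicon:start-end` locus string per row serves
external genome browsers. A content hash records the inputs, making
rebuild idempotence checkable.

The query language is a recursive-descent parser over comparisons
(`= != < <= > >=`) with `&` binding tighter than `|` and parentheses
overriding — the precedence is our choice, made explicit since mixed
expressions are otherwise ambiguous. Keys are case-insensitive, values
case-sensitive; ordering operators on non-numeric columns are an error,
unknown keys name the valid ones, syntax errors carry a column number.
The cast view uses ANY-sample semantics (a variant appears if *any*
sample row matches) — the natural reading for triage ("show variants that
are HIGH-impact in at least one clone").

Default triage sets use `alpha = 0.3` (insufficient coverage),
`beta = 2.5` (excess coverage, e.g. duplications), `M_min = 20` (poor
mapping) against per-sample median depth — conventional round numbers, all
exposed as arguments.

## Genome versioning and convergence

`apply_variant_set()` rejects overlapping variants (listing the pairs) and
mismatched REF alleles, applies right-to-left per replicon so coordinates
never shift under earlier applications, and returns a block lift map.
Features are shifted, truncated at deletion edges (flagged
`truncated by versioning` — truncation rather than dropping keeps partial
genes visible in the next round's annotation), or dropped when fully
deleted; applied element insertions add a `mobile_element` feature at the
new site. GenBank output records lineage in the COMMENT field.

`iterate_to_convergence()` applies the high-confidence set (SNVs with
`GT_TYPE 2` and assembly-method SVs — coverage-method calls are excluded
because their breakpoints are run boundaries, not base-exact junctions),
realigns, and stops at zero calls. On clean simulations this converges in
one round and reproduces the mutant genome string exactly; the round
counter and an unconverged flag guard the pathological cases.

## MAGE oligo design

Oligos are `l_oligo = 90`-mers with the edit centered
(`offset = floor((l_oligo − edit_len)/2)`, our fixed tie-break for
even-length windows) and at least `f_min = 20` bp flanks, taken from the
post-edit genome: the applied variant for `introduce`, the unedited
reference for `revert`. The strand is chosen to anneal to the
lagging-strand template: replichore 1 (clockwise ori → ter, increasing
coordinates) uses the reverse complement of the + strand window,
replichore 2 the + strand window — stated as the package's convention;
flipping the replichore reverse-complements the oligo, which is the
testable invariant. Variants at ori/ter are rejected as ambiguous.
Secondary-structure (ΔG) screening is out of scope.

## The simulator: what it emulates, and what it does not

`sim_genome()` builds a uniform-random background with non-overlapping
valid ORFs and identical IS-element copies; `sim_mutate()` plants
non-overlapping events with a 500 bp safety margin, away from donor
element copies, recording left-normalized truth coordinates;
`sim_reads()` samples fragments uniformly (normal size 300 ± 30 bp),
substitutes bases independently at `error_rate` (default 10⁻³), and
assigns constant Q30 qualities matching that error scale.

Default study conditions: 50 kb genome, 30× coverage, 100 bp paired
reads, Q30, one planted event per SV class (2 kb deletion, 500 bp novel
insertion, one IS-element move) and five SNVs — small enough to run on one
CPU in minutes, large enough that every junction topology (including
repeat-induced multi-placement) actually occurs. Test problem sizes
elsewhere range from 8–20 kb.

What passing these tests does *not* show: robustness to indel sequencing
errors, platform-specific quality decay, GC-coverage bias, true tandem
repeats longer than the read length, non-uniform library preparation, or
contamination. Real data adds all of these; the marginal-call class and
the default triage sets are the designed landing zones for such artifacts,
not a substitute for inspecting them.

## Numerical and degenerate-input choices

* Tie-breaks: equal-scoring read placements — deterministic per-read
  hash; equal-span contig placements — smallest reference start kept,
  flagged `multi`; genotype posterior ties — lower class wins
  (conservative).
* Degenerate inputs: empty read sets, empty alignment sets, empty variant
  tables, and empty graphs all produce typed empty outputs, not errors; a
  replicon with median depth 0 produces a warning and no coverage calls
  (failed sample).
* Left-normalization is applied at exactly two places — simulator truth
  and SV emission — so equality tests compare canonical forms.
* All simulation entry points take an integer seed and are byte-stable
  for a given seed; derived seeds stay below 2³¹.

## Known limitations

Inversions, tandem duplications, and inter-replicon translocations other
than element moves are out of scope. The aligner is not BWA: it assumes
substitution-dominated error and will soft-clip rather than gap-align a
read containing a true short indel. The assembler has no bubble-popping
beyond the coverage cutoff, so high error rates fragment contigs. The
evidence store is an in-process tibble with single-writer semantics, not a
database.
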
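# strainforge

Multiplex microbial resequencing, structural-variant discovery, and
iterative genome engineering — as a headless R package.

## The problem

Laboratory evolution and multiplex genome-engineering experiments (MAGE,
CAGE, biocontainment selections) produce dozens to hundreds of clonal
bacterial genomes that must each be compared against a reference: which
designed edits took, which off-target mutations accumulated, which
structural events (IS-element hops, large deletions, novel insertions)
explain a phenotype. Going from reads to a cross-sample, queryable mutation
table — and then back to the bench with a corrected reference genome and a
new pool of repair oligos — normally requires stitching together half a
dozen tools. `strainforge` implements that whole loop as composable R
functions over tibbles.

## What is in the box

* **Alignment & genotyping** — an internal seed-and-extend short-read
  aligner (exact k-mer seeds, diagonal voting, soft-clipping, split-read
  rescue with SA tags) and a diploid-mode pileup genotyper. Although the
  organisms are haploid, genotyping against allele fractions
  {0, ½, 1} deliberately exposes a three-level evidence class:

  `GT_TYPE = 0` (clean wild type), `1` (marginal — duplication, mapping
  artifact, or non-clonality), `2` (clean mutant).

  For a site with `n_ref` reference and `n_alt` alternate reads with
  per-read error probability `e` (from base qualities), the genotype is the
  maximum-posterior class under a flat prior on the symmetric binomial
  mixture: `L(0) = e^n_alt (1-e)^n_ref`, `L(½) = ½^(n_ref+n_alt)`,
  `L(1) = e^n_ref (1-e)^n_alt`.

* **Structural variants by local assembly** — candidate reads (unmapped,
  clipped, split, discordant, and their mates) are assembled with a de
  Bruijn assembler (k = 31, tip clipping, k-mer coverage cutoff), contigs
  are aligned back by exact-anchor chaining, and a **placement graph**
  (nodes: contigs and reference fragments; edges: local alignments) is
  traversed: two colinear edges with a reference gap → deletion; two edges
  with a contig gap → novel insertion (2 supporting edges); paired junction
  signatures into an annotated `mobile_element` feature → IS translocation
  (4 supporting edges, labelled with the element name). A coverage-based
  caller flags long low-depth runs as deletions independently.

* **Evidence table & query language** — all variant-sample evidence is
  melted into one denormalized tibble and filtered with Boolean key-value
  queries, e.g.

  ```
  GT_TYPE = 2 & (INFO_EFF_IMPACT = HIGH | INFO_EFF_IMPACT = MODERATE)
  ```

  in *melted* (one row per variant-sample) or *cast* (one row per variant,
  samples aggregated) views. Default triage sets (`no_coverage`,
  `insufficient_coverage`, `high_coverage`, `poor_mapping`) are assigned
  automatically.

* **Genome versioning & oligo design** — a variant set can be applied to
  the reference to produce a new annotated genome version (features lifted,
  truncated, or dropped; lineage recorded), iterated until zero variants
  are called against the new reference; and MAGE oligos (90-mers targeting
  the lagging strand of the appropriate replichore) are designed to
  introduce or revert each variant.

* **A seeded simulator** — annotated genomes with real ORFs and identical
  IS-element copies, mutant derivatives with a recorded truth table, and
  error-bearing paired-end reads, so the entire pipeline is testable
  end-to-end without downloads.

## Worked example

```r
library(strainforge)

ref <- sim_genome(20000, n_genes = 8, n_elements = 2, seed = 7)
mut <- sim_mutate(ref, events = list(snv = 3, deletion = 1000,
                                     novel_insertion = 400,
                                     element_move = 1), seed = 7)
rd  <- sim_reads(mut$genome, depth = 30, seed = 7)
res <- call_sample_variants(ref, reads = rd$reads)

res$snvs[, c("variant_id", "gt_type", "dp", "af")]
#> 1 chr:3842:SNV:C        2    29 1
#> 2 chr:13702:SNV:A       2    30 0.967
#> 3 chr:14275:SNV:T       2    29 1

res$svs[, c("variant_id", "type", "pos", "length", "element_label", "n_edges")]
#> 1 chr:1396:INS   novel_insertion           1396    400  NA     2
#> 2 chr:8273:DEL   deletion                  8273   1000  NA     2
#> 3 chr:11558:MEI  mobile_element_insertion 11558   1340  IS186  4
```

All three planted SNVs come back as clean mutants (`gt_type = 2`); the
three structural events are recovered with exact breakpoints, the novel
insertion with its full 400 bp sequence, and the IS hop labelled `IS186`
with the 4-edge junction topology. Iterating the versioning loop
reconstructs the mutant genome string exactly:

```r
conv <- iterate_to_convergence(ref, rd$reads)
conv$rounds                                            #> 1
identical(conv$genome$sequence[[1]],
          mut$genome$sequence[[1]])                    #> TRUE
```

A whole project (many samples, manifest CSV, YAML config) runs through
`run_project()`, or from a shell via the thin wrapper in
`inst/cli/strainforge` (`run`, `query`, `sets`, `version-genome`,
`design-oligos`, `simulate` subcommands).

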
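tiling_reads <- function(seq, step = 3, read_len = 50) {
  starts <- unique(c(seq(1, nchar(seq) - read_len + 1, by = step),
                     nchar(seq) - read_len + 1))
  tibble::tibble(name = paste0("t", seq_along(starts)),
                 seq = substring(seq, starts, starts + read_len - 1),
                 qual = strrep("?", read_len))
}

test_that("error-free tiling reads assemble into the original sequence", {
  set.seed(8)
  region <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  ## error-free input: no coverage cutoff needed, recovery is exact
  ctg <- assemble_contigs(tiling_reads(region), k = 31,
                          min_count = 1, l_min = 200)
  expect_equal(nrow(ctg), 1)
  expect_identical(ctg$sequence, pmin(region, revcomp(region)))
})

test_that("reads from two disjoint regions give two matching contigs", {
  set.seed(9)
  r1 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  r2 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  reads <- dplyr::bind_rows(tiling_reads(r1), tiling_reads(r2))
  reads$name <- paste0(reads$name, seq_len(nrow(reads)))
  ctg <- assemble_contigs(reads, k = 31, min_count = 1, l_min = 200)
  expect_equal(nrow(ctg), 2)
  canon <- function(s) pmin(s, revcomp(s))
  expect_setequal(canon(ctg$sequence), canon(c(r1, r2)))
})

test_that("reads shorter than k assemble to nothing", {
  reads <- tibble::tibble(name = "a", seq = strrep("ACGT", 5),
                          qual = strrep("?", 20))
  expect_equal(nrow(assemble_contigs(reads, k = 31)), 0)
})

test_that("assembly is strand-symmetric", {
  res <- fix_result()
  cand <- res$candidates
  flipped <- dplyr::mutate(cand, seq = revcomp(seq))
  c1 <- assemble_contigs(cand)
  c2 <- assemble_contigs(flipped)
  expect_identical(c1$sequence, c2$sequence)
})

test_that("contig alignment produces identity edges with exact coordinates", {
  g <- fix_genome()
  seq <- g$sequence[[1]]
  ## a contig equal to reference[1000:1400) -> one full-length edge
  ctg <- tibble::tibble(contig_id = "c1",
                        sequence = substring(seq, 1001, 1400),
                        length = 400L, read_support = 10)
  gr <- align_contigs(ctg, g)
  expect_equal(nrow(gr$edges), 1)
  expect_equal(gr$edges$r_start, 1000L)
  expect_equal(gr$edges$r_end, 1400L)
  expect_equal(gr$edges$c_start, 0L)
  expect_equal(gr$edges$c_end, 400L)
  ## the reverse complement aligns with strand "-" over the same locus
  ctg_rc <- dplyr::mutate(ctg, sequence = revcomp(sequence))
  gr2 <- align_contigs(ctg_rc, g)
  expect_equal(gr2$edges$strand, "-")
  expect_equal(gr2$edges$r_start, 1000L)
  expect_equal(gr2$edges$r_end, 1400L)
})

test_that("a contig with a novel interior yields two flanking edges", {
  set.seed(10)
  g <- fix_genome()
  seq <- g$sequence[[1]]
  novel <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
  ctg <- tibble::tibble(
    contig_id = "c1",
    sequence = paste0(substring(seq, 2001, 2400), novel,
                      substring(seq, 2401, 2800)),
    length = 1300L, read_support = 10)
  gr <- align_contigs(ctg, g)
  expect_equal(nrow(gr$edges), 2)
  e <- dplyr::arrange(gr$edges, c_start)
  ## flank edges may legitimately extend a few chance-matching bases into
  ## the insert; they must stay on their diagonals and flank the interior
  expect_equal(e$r_end[1] - e$c_end[1], 2000)
  expect_equal(e$r_start[2] - (e$c_start[2] - 900L), 2400)
  expect_lte(abs(e$c_end[1] - 400L), 5)
  expect_lte(abs(e$c_start[2] - 900L), 5)
  ## the graph traversal reconstructs the inserted sequence exactly
  sv <- call_structural_variants(gr, g)
  expect_equal(nrow(sv), 1)
  expect_equal(sv$type, "novel_insertion")
  nrm <- strainforge:::normalize_insertion(seq, 2400L, novel)
  expect_equal(sv$pos, nrm$pos)
  expect_identical(sv$inserted_sequence, nrm$ins)
})

test_that("the anchor aligner agrees with a Smith-Waterman oracle on placement", {
  set.seed(12)
  g <- fix_genome()
  seq <- g$sequence[[1]]
  for (trial in 1:5) {
    start <- sample(1000:9000, 1)
    len <- sample(300:1500, 1)
    ctg_seq <- substring(seq, start + 1, start + len)
    ## plant a couple of mismatches away from the ends
    mpos <- sample(50:(len - 50), 2)
    for (p in mpos) {
      substr(ctg_seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(ctg_seq, p, p)), 1)
    }
    ctg <- tibble::tibble(contig_id = "c1", sequence = ctg_seq,
                          length = nchar(ctg_seq), read_support = 5)
    gr <- align_contigs(ctg, g)
    expect_gte(nrow(gr$edges), 1)
    span <- range(c(gr$edges$r_start, gr$edges$r_end))
    ## independent oracle: local alignment against the same window
    window <- substring(seq, max(1, start - 200), start + len + 200)
    sw <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ctg_seq), Biostrings::DNAString(window),
      type = "local", gapOpening = 6, gapExtension = 1)
    sw_start <- max(1, start - 200) - 1 +
      Biostrings::start(Biostrings::subject(sw)) - 1
    sw_end <- sw_start + Biostrings::nchar(Biostrings::subject(sw))
    expect_lte(abs(span[1] - sw_start), 5)
    expect_lte(abs(span[2] - sw_end), 5)
  }
})

test_that("graph nodes include contigs and data-driven reference fragments", {
  res <- fix_result()
  gr <- res$graph
  expect_setequal(unique(gr$nodes$kind), c("contig", "ref_fragment"))
  frag <- gr$nodes[gr$nodes$kind == "ref_fragment", ]
  ## fragments tile the replicon
  frag <- dplyr::arrange(frag, start)
  expect_equal(frag$start[1], 0L)
  expect_equal(dplyr::last(frag$end), nchar(fix_genome()$sequence[[1]]))
  expect_true(all(frag$start[-1] == head(frag$end, -1)))
  ## tidy/glance accessors
  expect_identical(generics::tidy(gr), gr$edges)
  expect_equal(generics::glance(gr)$n_contigs, nrow(gr$contigs))
})
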
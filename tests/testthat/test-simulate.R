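test_that("genome simulation is deterministic per seed and structurally sound", {
  g1 <- sim_genome(20000, n_genes = 10, n_elements = 2, seed = 7)
  g2 <- sim_genome(20000, n_genes = 10, n_elements = 2, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  expect_equal(sum(g1$features$kind == "CDS"), 10)
  expect_equal(sum(g1$features$kind == "mobile_element"), 2)
  ## element copies are identical sequences
  els <- g1$features[g1$features$kind == "mobile_element", ]
  seqs <- substring(g1$sequence[[1]], els$start + 1, els$end)
  expect_equal(length(unique(seqs)), 1)
  ## CDS are valid ORFs on their own strand
  cds <- g1$features[g1$features$kind == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    s <- substring(g1$sequence[[1]], cds$start[i] + 1, cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in%
                  c("TAA", "TAG", "TGA"))
    codons <- substring(s, seq(1, nchar(s) - 3, 3),
                        seq(3, nchar(s) - 3 + 2, 3))
    expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("a genome with no genes carries only element features", {
  g <- sim_genome(8000, n_genes = 0, n_elements = 2, seed = 3)
  expect_true(all(g$features$kind == "mobile_element"))
})

test_that("infeasible packing raises a capacity error", {
  expect_error(sim_genome(3000, n_genes = 20, n_elements = 2, seed = 1),
               class = "strainforge_capacity_error")
})

test_that("mutation spec counts are honoured exactly", {
  g <- fix_genome()
  m <- sim_mutate(g, events = list(snv = 5), seed = 5)
  s1 <- strsplit(g$sequence[[1]], "")[[1]]
  s2 <- strsplit(m$genome$sequence[[1]], "")[[1]]
  expect_equal(nchar(m$genome$sequence[[1]]), nchar(g$sequence[[1]]))
  expect_equal(sum(s1 != s2), 5)
  el_len <- 1340L
  m2 <- sim_mutate(g, events = list(element_move = 1), seed = 6)
  expect_equal(nchar(m2$genome$sequence[[1]]),
               nchar(g$sequence[[1]]) + el_len)
  m3 <- sim_mutate(g, events = list(), seed = 7)
  expect_identical(m3$genome$sequence, g$sequence)
  expect_equal(nrow(m3$truth), 0)
})

test_that("planted truth events reproduce the mutant via apply_variant_set", {
  mut <- fix_mut()
  re <- apply_variant_set(fix_genome(), mut$truth)
  expect_identical(re$genome$sequence, mut$genome$sequence)
})

test_that("read simulation follows the coverage arithmetic and error model", {
  g <- sim_genome(10000, n_genes = 2, n_elements = 0, seed = 2)
  rd <- sim_reads(g, depth = 30, read_len = 100, seed = 2)
  expect_equal(nrow(rd$reads), round(30 * 10000 / (2 * 100)))
  ## same seed -> byte-identical output
  rd2 <- sim_reads(g, depth = 30, read_len = 100, seed = 2)
  expect_identical(rd$reads, rd2$reads)
  fq <- withr::local_tempfile()
  fq2 <- withr::local_tempfile()
  write_fastq_pairs(rd$reads, fq)
  write_fastq_pairs(rd2$reads, fq2)
  expect_identical(readLines(paste0(fq, "_1.fastq")),
                   readLines(paste0(fq2, "_1.fastq")))
  ## error-free reads are exact substrings (or reverse complements)
  rd0 <- sim_reads(g, depth = 2, error_rate = 0, seed = 3)
  seq <- g$sequence[[1]]
  for (i in seq_len(min(40, nrow(rd0$reads)))) {
    expect_true(grepl(rd0$reads$seq1[i], seq, fixed = TRUE))
    expect_true(grepl(revcomp(rd0$reads$seq2[i]), seq, fixed = TRUE))
  }
  ## qualities are constant Q30
  expect_true(all(rd0$reads$qual1 == strrep("?", 100)))
})
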
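test_that("read classification assigns one category with the documented precedence", {
  aln <- tibble::tibble(
    qname = c("a", "a", "b", "b", "c", "c"),
    flag = c(77L, 141L, 99L, 147L, 97L, 145L),
    replicon = c("*", "*", "chr", "chr", "chr", "chr"),
    pos = c(-1L, -1L, 100L, 300L, 100L, 5000L),
    mapq = 60L,
    cigar = c("*", "*", "30S70M", "100M", "100M", "100M"),
    mrnm = "*", mpos = -1L, tlen = 0L,
    seq = strrep("A", 100), qual = strrep("?", 100), sa = NA_character_,
    is_unmapped = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_reverse = FALSE, is_supplementary = FALSE,
    is_proper_flag = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    read_ord = c(1L, 2L, 1L, 2L, 1L, 2L))
  cls <- classify_reads(aln, s_min = 10)
  expect_equal(cls$category,
               c("unmapped", "unmapped", "clipped", "proper",
                 "discordant_pair", "discordant_pair"))
  ## the proper mate of a clipped read is flagged
  expect_true(cls$mate_of_candidate[4])
  expect_false(cls$mate_of_candidate[3])
})

test_that("a clean 30x simulation yields few candidates; junction reads all qualify", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 21)
  rd <- sim_reads(g, depth = 30, seed = 21)
  aln <- align_reads(rd$reads, g)
  cand <- extract_candidates(aln)
  expect_lt(nrow(cand), 0.05 * 2 * nrow(rd$reads))
  ## insertion junctions: every straddling read appears among candidates
  mut <- fix_mut()
  res <- fix_result()
  st <- reads_over_junctions(fix_reads()$meta, mut$junctions, 100,
                             min_overlap = 15)
  keys <- paste0(st$name, "/", st$mate)
  expect_true(all(keys %in% res$candidates$name))
  ## empty input -> empty candidate set
  expect_equal(nrow(extract_candidates(strainforge:::empty_alignments())),
               0)
})

test_that("coverage counts aligned bases only and matches simulation depth", {
  g <- ref_genome("r", c(chr = strrep("ACGT", 250)))
  one <- tibble::tibble(
    qname = "r1", flag = 0L, replicon = "chr", pos = 0L, mapq = 60L,
    cigar = "100M", mrnm = "*", mpos = -1L, tlen = 0L,
    seq = substr(g$sequence[[1]], 1, 100), qual = strrep("?", 100),
    sa = NA_character_, is_unmapped = FALSE, is_reverse = FALSE,
    is_supplementary = FALSE, is_proper_flag = TRUE, read_ord = 1L)
  cov <- coverage_profile(one, g)
  expect_equal(cov$depth[1:100], rep(1L, 100))
  expect_true(all(cov$depth[101:1000] == 0L))
  ## deleted reference bases get no depth from a 50M100D50M record
  spanning <- dplyr::mutate(one, cigar = "50M100D50M",
                            seq = strrep("A", 100))
  cov2 <- coverage_profile(spanning, g)
  expect_equal(sum(cov2$depth[1:50]), 50)
  expect_equal(sum(cov2$depth[51:150]), 0)
  expect_equal(sum(cov2$depth[151:200]), 50)
  ## 30x simulation: mean depth within 10% of target
  res <- fix_result()
  expect_lt(abs(mean(res$coverage$depth) - 30) / 30, 0.1)
})

test_that("the diploid pileup genotyper reproduces the GT_TYPE trichotomy", {
  gt <- strainforge:::genotype_from_counts(0, 30, 0.001)
  expect_equal(gt$gt, "1/1")
  expect_equal(gt$gt_type, 2L)
  gt <- strainforge:::genotype_from_counts(15, 15, 0.001)
  expect_equal(gt$gt, "0/1")
  expect_equal(gt$gt_type, 1L)
  gt <- strainforge:::genotype_from_counts(30, 0, 0.001)
  expect_equal(gt$gt, "0/0")
  expect_equal(gt$gt_type, 0L)
})

test_that("call_snvs recovers planted SNVs exactly with no false calls", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 31)
  mut <- sim_mutate(g, events = list(snv = 6), seed = 31)
  rd <- sim_reads(mut$genome, depth = 30, error_rate = 0, seed = 31)
  aln <- align_reads(rd$reads, g)
  calls <- call_snvs(aln, g)
  truth <- mut$truth
  expect_setequal(calls$variant_id, truth$variant_id)
  expect_true(all(calls$gt_type == 2L))
  ## permutation invariance: shuffled records give the same calls
  set.seed(1)
  calls2 <- call_snvs(aln[sample.int(nrow(aln)), ], g)
  expect_equal(dplyr::arrange(calls2, variant_id),
               dplyr::arrange(calls, variant_id))
})

test_that("a 50:50 mix of wild-type and mutant reads yields marginal calls", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 33)
  mut <- sim_mutate(g, events = list(snv = 4), seed = 33)
  rd_wt <- sim_reads(g, depth = 15, error_rate = 0, seed = 34)
  rd_mut <- sim_reads(mut$genome, depth = 15, error_rate = 0, seed = 35)
  mixed <- dplyr::bind_rows(
    dplyr::mutate(rd_wt$reads, name = paste0("wt_", name)),
    dplyr::mutate(rd_mut$reads, name = paste0("mu_", name)))
  aln <- align_reads(mixed, g)
  calls <- call_snvs(aln, g)
  hit <- calls[calls$variant_id %in% mut$truth$variant_id, ]
  expect_equal(nrow(hit), nrow(mut$truth))
  expect_true(all(hit$gt_type == 1L))
  expect_true(all(abs(hit$af - 0.5) < 0.25))
})

test_that("genotype_sites reports wild-type and no-coverage evidence", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 36)
  rd <- sim_reads(g, depth = 20, error_rate = 0, seed = 36)
  aln <- align_reads(rd$reads, g)
  sites <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = c(5000L, 9999L), type = "snv",
    ref = substring(g$sequence[[1]], c(5001, 10000), c(5001, 10000)),
    alt = "N", length = 1L))
  calls <- genotype_sites(aln, g, sites)
  expect_equal(calls$gt_type[1], 0L)
  expect_gt(calls$dp[1], 5)
  ## empty alignments: all sites reported with DP 0
  none <- genotype_sites(strainforge:::empty_alignments(), g, sites)
  expect_equal(none$dp, c(0L, 0L))
  expect_equal(none$gt, c("./.", "./."))
})
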
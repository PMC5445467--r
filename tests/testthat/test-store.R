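mini_table_inputs <- function() {
  vars <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = c(10L, 20L, 30L), type = "snv",
    ref = c("A", "C", "G"), alt = c("T", "G", "A"), length = 1L))
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            phenotype = c("a", "a", "b", "b"))
  calls <- tidyr::crossing(variant_id = vars$variant_id,
                           sample_id = samples$sample_id) |>
    dplyr::mutate(gt = "1/1", gt_type = 2L, gq = 60, dp = 30L, af = 1,
                  mean_mapq = 60)
  list(vars = vars, samples = samples, calls = calls)
}

test_that("the melted table is the variant-by-sample cross product", {
  x <- mini_table_inputs()
  tb <- build_evidence_table(x$vars, x$calls, x$samples)
  expect_equal(nrow(tb), 12)
  expect_true(all(c("UID", "CHROM", "POSITION", "GT_TYPE", "DP", "LOCUS",
                    "PHENOTYPE") %in% names(tb)))
  ## a sample without a call gets GT_TYPE 0, DP 0
  partial <- x$calls[x$calls$sample_id != "s4", ]
  tb2 <- build_evidence_table(x$vars, partial, x$samples)
  expect_equal(nrow(tb2), 12)
  s4 <- tb2[tb2$SAMPLE_ID == "s4", ]
  expect_true(all(s4$GT_TYPE == 0L))
  expect_true(all(s4$DP == 0L))
  ## zero variants: empty table, full header
  tb0 <- build_evidence_table(strainforge:::empty_variants(),
                              x$calls[0, ], x$samples)
  expect_equal(nrow(tb0), 0)
  expect_true(all(c("UID", "GT_TYPE", "DP") %in% names(tb0)))
})

test_that("orphan calls are rejected", {
  x <- mini_table_inputs()
  bad <- dplyr::mutate(x$calls[1, ], variant_id = "chr:999:SNV:T")
  expect_error(build_evidence_table(x$vars, bad, x$samples),
               class = "strainforge_consistency_error")
})

test_that("rebuilds are idempotent and hashed", {
  x <- mini_table_inputs()
  t1 <- build_evidence_table(x$vars, x$calls, x$samples)
  t2 <- build_evidence_table(x$vars, x$calls, x$samples)
  expect_identical(t1, t2)
  expect_identical(attr(t1, "content_hash"), attr(t2, "content_hash"))
  t3 <- build_evidence_table(x$vars, x$calls[-1, ], x$samples)
  expect_false(identical(attr(t1, "content_hash"),
                         attr(t3, "content_hash")))
})

test_that("CSV export round-trips the table", {
  x <- mini_table_inputs()
  tb <- build_evidence_table(x$vars, x$calls, x$samples)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_evidence_csv(tb, csv)
  expect_equal(length(readLines(csv)), nrow(tb) + 1)
  back <- read_evidence_csv(csv)
  expect_equal(nrow(back), nrow(tb))
  expect_equal(back$UID, tb$UID)
  expect_equal(back$GT_TYPE, tb$GT_TYPE)
  expect_equal(back$AF, tb$AF)
  ## empty table -> header-only CSV
  csv0 <- withr::local_tempfile(fileext = ".csv")
  export_evidence_csv(tb[0, ], csv0)
  expect_equal(length(readLines(csv0)), 1)
})

test_that("default triage sets follow the threshold definitions", {
  x <- mini_table_inputs()
  calls <- x$calls
  ## s1 at v1: no coverage; s2 at v1: thin; s3 at v1: amplified; s4: poor
  v1 <- x$vars$variant_id[1]
  calls$dp[calls$variant_id == v1 & calls$sample_id == "s1"] <- 0L
  calls$dp[calls$variant_id == v1 & calls$sample_id == "s2"] <- 5L
  calls$dp[calls$variant_id == v1 & calls$sample_id == "s3"] <- 90L
  calls$mean_mapq[calls$variant_id == v1 & calls$sample_id == "s4"] <- 5
  tb <- build_evidence_table(x$vars, calls, x$samples)
  cs <- tibble::tibble(sample_id = paste0("s", 1:4), median_depth = 30)
  sets <- assign_default_sets(tb, cs)
  member <- function(nm, sid) {
    any(sets$name == nm & sets$variant_id == v1 & sets$sample_id == sid)
  }
  expect_true(member("no_coverage", "s1"))
  expect_true(member("insufficient_coverage", "s2"))
  expect_true(member("high_coverage", "s3"))
  expect_true(member("poor_mapping", "s4"))
  ## a clean 30x site with MAPQ 60 joins no default set
  v2 <- x$vars$variant_id[2]
  expect_false(any(sets$variant_id == v2))
})

test_that("user sets are created from queries", {
  x <- mini_table_inputs()
  tb <- build_evidence_table(x$vars, x$calls, x$samples)
  vs <- create_variant_set(tb, "GT_TYPE = 2", "all_mutants")
  expect_equal(nrow(vs), 12)
  expect_true(all(vs$provenance == "user"))
})
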
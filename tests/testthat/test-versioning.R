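test_that("SNV application substitutes in place", {
  g <- fix_genome()
  seq <- g$sequence[[1]]
  refb <- substr(seq, 100, 100)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 99L, type = "snv", ref = refb, alt = altb,
    length = 1L))
  out <- apply_variant_set(g, v)
  new <- out$genome$sequence[[1]]
  expect_equal(nchar(new), nchar(seq))
  expect_equal(substr(new, 100, 100), altb)
  expect_identical(paste0(substr(new, 1, 99), refb,
                          substr(new, 101, nchar(new))), seq)
  expect_equal(out$genome$version_parent, g$name)
  expect_equal(out$genome$applied_variants, v$variant_id)
  ## SNV-only lift map is the identity
  expect_true(all(out$liftmap$offset == 0L))
  expect_false(any(out$liftmap$deleted))
  ## applying twice trips the REF check (idempotence guard)
  expect_error(apply_variant_set(out$genome, v),
               class = "strainforge_consistency_error")
})

test_that("deletions shift downstream features by the offset arithmetic", {
  seq <- strrep("ACGT", 500)
  feats <- tibble::tibble(replicon = "chr", start = 500L, end = 800L,
                          strand = "+", kind = "CDS", gene = "x",
                          product = "p")
  g <- ref_genome("r", c(chr = seq), feats)
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 200L, type = "deletion", length = 10L))
  out <- apply_variant_set(g, v)
  expect_equal(nchar(out$genome$sequence[[1]]), 1990)
  ft <- out$genome$features
  expect_equal(ft$start, 490L)
  expect_equal(ft$end, 790L)
  expect_equal(lift_position(out$liftmap, "chr", c(100L, 500L)),
               c(100L, 490L))
})

test_that("features overlapping a deletion are truncated and flagged", {
  seq <- strrep("ACGT", 500)
  feats <- tibble::tibble(replicon = "chr", start = 100L, end = 400L,
                          strand = "+", kind = "CDS", gene = "x",
                          product = "p")
  g <- ref_genome("r", c(chr = seq), feats)
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 300L, type = "deletion", length = 500L))
  out <- apply_variant_set(g, v)
  ft <- out$genome$features
  expect_equal(nrow(ft), 1)
  expect_equal(ft$end, 300L)
  expect_equal(ft$note, "truncated by versioning")
  ## fully deleted features are dropped
  v2 <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 50L, type = "deletion", length = 400L))
  out2 <- apply_variant_set(g, v2)
  expect_equal(nrow(out2$genome$features), 0)
})

test_that("an element insertion adds sequence and a mobile_element feature", {
  g <- fix_genome()
  el <- g$features[g$features$kind == "mobile_element", ][1, ]
  eseq <- substring(g$sequence[[1]], el$start + 1, el$end)
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 5000L, type = "mobile_element_insertion",
    length = nchar(eseq), inserted_sequence = eseq,
    element_label = "IS186"))
  out <- apply_variant_set(g, v)
  new <- out$genome$sequence[[1]]
  expect_equal(nchar(new), nchar(g$sequence[[1]]) + nchar(eseq))
  ## direct splice oracle
  expect_identical(new, paste0(substr(g$sequence[[1]], 1, 5000), eseq,
                               substr(g$sequence[[1]], 5001,
                                      nchar(g$sequence[[1]]))))
  added <- out$genome$features[out$genome$features$start == 5000L &
                                 out$genome$features$kind ==
                                   "mobile_element", ]
  expect_equal(nrow(added), 1)
  expect_equal(added$end, 5000L + nchar(eseq))
  expect_equal(added$gene, "IS186")
})

test_that("length accounting is exact over random variant sets", {
  g <- fix_genome()
  set.seed(17)
  for (trial in 1:5) {
    pos <- sort(sample(seq(100, 11000, by = 700), 6))
    types <- sample(c("snv", "deletion", "novel_insertion"), 6,
                    replace = TRUE)
    lens <- sample(10:200, 6)
    vars <- tibble::tibble(
      replicon = "chr", pos = as.integer(pos), type = types,
      ref = ifelse(types == "snv",
                   substring(g$sequence[[1]], pos + 1, pos + 1), NA),
      alt = ifelse(types == "snv", "A", NA),
      length = ifelse(types == "snv", 1L, as.integer(lens)),
      inserted_sequence = ifelse(
        types == "novel_insertion",
        vapply(lens, function(n) paste(sample(c("A", "C", "G", "T"), n,
                                              replace = TRUE),
                                       collapse = ""), character(1)),
        NA))
    vars$alt[types == "snv"] <- vapply(
      which(types == "snv"),
      function(i) sample(setdiff(c("A", "C", "G", "T"), vars$ref[i]), 1),
      character(1))
    vars <- strainforge:::complete_variants(vars)
    out <- apply_variant_set(g, vars)
    expected <- nchar(g$sequence[[1]]) +
      sum(vars$length[vars$type == "novel_insertion"]) -
      sum(vars$length[vars$type == "deletion"])
    expect_equal(nchar(out$genome$sequence[[1]]), expected)
  }
})

test_that("overlapping variants are rejected with the conflicting pair named", {
  g <- fix_genome()
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = c(1000L, 1050L), type = "deletion",
    length = c(100L, 100L)))
  err <- expect_error(apply_variant_set(g, v),
                      class = "strainforge_conflict_error")
  expect_match(conditionMessage(err), v$variant_id[1], fixed = TRUE)
  expect_match(conditionMessage(err), v$variant_id[2], fixed = TRUE)
})

test_that("versioned GenBank output records lineage and re-reads", {
  g <- fix_genome()
  v <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 99L, type = "snv",
    ref = substr(g$sequence[[1]], 100, 100),
    alt = setdiff(c("A", "C", "G", "T"),
                  substr(g$sequence[[1]], 100, 100))[1],
    length = 1L))
  out <- apply_variant_set(g, v)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_reference(out$genome, gb, "genbank")
  txt <- readLines(gb)
  expect_true(any(grepl(paste0("derived from ", g$name), txt)))
  g2 <- read_reference(gb, "genbank")
  expect_identical(unname(g2$sequence), unname(out$genome$sequence))
  expect_equal(g2$version_parent, g$name)
})

test_that("a sample identical to the reference converges in zero rounds", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 51)
  rd <- sim_reads(g, depth = 25, error_rate = 0, seed = 51)
  conv <- iterate_to_convergence(g, rd$reads, max_rounds = 2)
  expect_true(conv$converged)
  expect_equal(conv$rounds, 0L)
  expect_identical(conv$genome$sequence, g$sequence)
})

test_that("SNV-carrying samples converge in one round to the mutant string", {
  g <- sim_genome(10000, n_genes = 3, n_elements = 0, seed = 52)
  mut <- sim_mutate(g, events = list(snv = 5), seed = 52)
  rd <- sim_reads(mut$genome, depth = 30, error_rate = 0, seed = 52)
  conv <- iterate_to_convergence(g, rd$reads, max_rounds = 3)
  expect_true(conv$converged)
  expect_equal(conv$rounds, 1L)
  expect_identical(conv$genome$sequence[[1]], mut$genome$sequence[[1]])
})
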
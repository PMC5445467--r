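oligo_fixture <- function() {
  g <- fix_genome()
  seq <- g$sequence[[1]]
  refb <- substr(seq, 5001, 5001)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  snv <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 5000L, type = "snv", ref = refb, alt = altb,
    length = 1L))
  list(g = g, snv = snv, ori = 0L, ter = 6000L)
}

test_that("replichore-1 SNV oligos center the edit on the lagging-anneal strand", {
  x <- oligo_fixture()
  ol <- design_oligos(x$g, x$snv, "introduce", ori = x$ori, ter = x$ter,
                      l_oligo = 90)
  expect_equal(nchar(ol$sequence), 90)
  expect_equal(ol$replichore, 1L)
  expect_equal(ol$target_strand, "-")
  ## 1 bp edit in a 90-mer: offset floor((90-1)/2) = 44 from the + strand
  ## 5' end; on the reported - strand that is 90 - 44 - 1 = 45
  expect_equal(ol$offset_of_edit, 45L)
  ## the oligo is the reverse complement of the post-edit + strand window
  post <- apply_variant_set(x$g, x$snv)$genome$sequence[[1]]
  win <- substr(post, 5001 - 44, 5001 - 44 + 89)
  expect_identical(ol$sequence, revcomp(win))
  ## edited base sits at the stated offset
  expect_identical(substr(ol$sequence, ol$offset_of_edit + 1,
                          ol$offset_of_edit + 1),
                   revcomp(x$snv$alt))
})

test_that("the opposite replichore gives the reverse-complement oligo", {
  x <- oligo_fixture()
  o1 <- design_oligos(x$g, x$snv, "introduce", ori = x$ori, ter = x$ter)
  ## moving ter before the site flips the variant onto replichore 2
  o2 <- design_oligos(x$g, x$snv, "introduce", ori = x$ori, ter = 2000L)
  expect_equal(o2$replichore, 2L)
  expect_equal(o2$target_strand, "+")
  expect_identical(o2$sequence, revcomp(o1$sequence))
})

test_that("oligos match the post-edit genome exactly and differ only at the edit", {
  x <- oligo_fixture()
  g <- x$g
  seq <- g$sequence[[1]]
  ins3 <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 5200L, type = "novel_insertion", length = 3L,
    inserted_sequence = "TTG"))
  del6 <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 5500L, type = "deletion", length = 6L))
  for (v in list(x$snv, ins3, del6)) {
    for (dir in c("introduce", "revert")) {
      ol <- design_oligos(g, v, dir, ori = x$ori, ter = x$ter)
      post <- if (dir == "introduce") {
        apply_variant_set(g, v)$genome$sequence[[1]]
      } else {
        seq
      }
      pre <- if (dir == "introduce") seq else
        apply_variant_set(g, v)$genome$sequence[[1]]
      probe <- revcomp(ol$sequence)  # replichore 1 -> + strand window
      ## mismatch-free hit on the post-edit genome
      expect_equal(length(gregexpr(probe, post, fixed = TRUE)[[1]]) >= 1 &&
                     gregexpr(probe, post, fixed = TRUE)[[1]][1] != -1,
                   TRUE, info = paste(v$type, dir))
      ## no exact hit on the pre-edit genome (the edit is present)
      expect_equal(gregexpr(probe, pre, fixed = TRUE)[[1]][1], -1,
                   info = paste(v$type, dir))
      ## flanks on both sides of the edit still anchor to the pre-edit
      ## genome (the difference is only the edit itself)
      expect_true(grepl(substr(probe, 1, 20), pre, fixed = TRUE))
      expect_true(grepl(substr(probe, nchar(probe) - 19, nchar(probe)),
                        pre, fixed = TRUE))
    }
  }
})

test_that("introduce and revert form reverse-image pairs around an SNV", {
  x <- oligo_fixture()
  oi <- design_oligos(x$g, x$snv, "introduce", ori = x$ori, ter = x$ter)
  or <- design_oligos(x$g, x$snv, "revert", ori = x$ori, ter = x$ter)
  d <- which(strsplit(oi$sequence, "")[[1]] != strsplit(or$sequence,
                                                        "")[[1]])
  expect_equal(d, oi$offset_of_edit + 1L)
})

test_that("oversized edits and ori/ter-spanning variants are rejected", {
  x <- oligo_fixture()
  big <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = 5000L, type = "novel_insertion",
    length = 60L, inserted_sequence = strrep("ACGT", 15)))
  expect_error(design_oligos(x$g, big, "introduce", ori = x$ori,
                             ter = x$ter),
               class = "strainforge_size_error")
  at_ori <- dplyr::mutate(x$snv, pos = 0L,
                          ref = substr(x$g$sequence[[1]], 1, 1))
  expect_error(design_oligos(x$g, at_ori, "introduce", ori = x$ori,
                             ter = x$ter),
               class = "strainforge_ambiguity_error")
})

test_that("oligo output files round-trip", {
  x <- oligo_fixture()
  ol <- design_oligos(x$g, x$snv, "introduce", ori = x$ori, ter = x$ter)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_oligos(ol, fa, tsv)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_identical(unname(as.character(ss)), ol$sequence)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$sequence, ol$sequence)
  expect_equal(back$replichore, ol$replichore)
})
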
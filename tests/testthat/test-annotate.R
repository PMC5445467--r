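mk_var <- function(pos, type = "snv", ref = NA, alt = NA, length = 1L,
                   ins = NA_character_) {
  strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = as.integer(pos), type = type,
    ref = as.character(ref), alt = as.character(alt),
    length = as.integer(length), inserted_sequence = ins))
}

test_that("coding SNVs translate to the expected effect classes", {
  g <- annot_genome()
  ## + strand CDS starts at 300: ATG GCT ... ; codon 2 GCT(A) -> GTT(V)
  v <- mk_var(304, ref = "C", alt = "T")
  a <- annotate_variants(v, g)
  expect_equal(a$eff_effect, "missense")
  expect_equal(a$eff_impact, "MODERATE")
  expect_equal(a$eff_aa, "A2V")
  expect_equal(a$eff_gene, "plusA")
  ## synonymous: GCT -> GCC (codon 2, third base)
  a2 <- annotate_variants(mk_var(305, ref = "T", alt = "C"), g)
  expect_equal(a2$eff_effect, "synonymous")
  expect_equal(a2$eff_impact, "LOW")
  ## nonsense: CAA (codon 4) -> TAA via first base
  a3 <- annotate_variants(mk_var(309, ref = "C", alt = "T"), g)
  expect_equal(a3$eff_effect, "nonsense")
  expect_equal(a3$eff_impact, "HIGH")
})

test_that("minus-strand CDS effects mirror the plus strand", {
  g <- annot_genome()
  ## CDS [600,630) on -: genomic base at 625 is complement of coding
  ## position 5 (codon 2, second base GCT -> GTT)
  a <- annotate_variants(mk_var(625, ref = "G", alt = "A"), g)
  expect_equal(a$eff_effect, "missense")
  expect_equal(a$eff_aa, "A2V")
  expect_equal(a$eff_gene, "minusB")
})

test_that("indels in CDS are frameshift or in-frame by length mod 3", {
  g <- annot_genome()
  a <- annotate_variants(mk_var(310, type = "deletion", length = 1L), g)
  expect_equal(a$eff_effect, "frameshift")
  expect_equal(a$eff_impact, "HIGH")
  a2 <- annotate_variants(mk_var(310, type = "deletion", length = 3L), g)
  expect_equal(a2$eff_effect, "disruptive_inframe")
  expect_equal(a2$eff_impact, "MODERATE")
  a3 <- annotate_variants(mk_var(310, type = "novel_insertion",
                                 length = 4L, ins = "ACGT"), g)
  expect_equal(a3$eff_effect, "frameshift")
})

test_that("upstream window and element insertions upstream are classified", {
  g <- annot_genome()
  a <- annotate_variants(mk_var(180, ref = "A", alt = "C"), g)
  expect_equal(a$eff_effect, "upstream")
  expect_equal(a$eff_impact, "MODIFIER")
  expect_equal(a$eff_gene, "plusA")
  ## for the - strand gene, upstream is to the right of its end
  a2 <- annotate_variants(mk_var(700, ref = "A", alt = "C"), g)
  expect_equal(a2$eff_effect, "upstream")
  expect_equal(a2$eff_gene, "minusB")
  mei <- mk_var(200, type = "mobile_element_insertion", length = 1340L,
                ins = strrep("ACGT", 335))
  a3 <- annotate_variants(mei, g)
  expect_equal(a3$eff_effect, "element_insertion_upstream")
  expect_equal(a3$eff_impact, "HIGH")
  ## far from everything -> intergenic MODIFIER
  a4 <- annotate_variants(mk_var(1500, ref = "A", alt = "C"), g)
  expect_equal(a4$eff_effect, "intergenic")
  expect_equal(a4$eff_impact, "MODIFIER")
})

test_that("annotation is strand-symmetric under genome mirroring", {
  g <- annot_genome()
  L <- nchar(g$sequence[[1]])
  mirrored <- ref_genome(
    "mirror", c(chr = revcomp(g$sequence[[1]])),
    dplyr::mutate(g$features, start2 = L - end, end2 = L - start,
                  start = start2, end = end2,
                  strand = ifelse(strand == "+", "-", "+"),
                  start2 = NULL, end2 = NULL))
  set.seed(4)
  cds <- g$features[1, ]
  for (p in seq(cds$start, cds$end - 1)) {
    refb <- substr(g$sequence[[1]], p + 1, p + 1)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    a1 <- annotate_variants(mk_var(p, ref = refb, alt = altb), g)
    a2 <- annotate_variants(mk_var(L - 1 - p, ref = revcomp(refb),
                                   alt = revcomp(altb)), mirrored)
    expect_equal(a1$eff_effect, a2$eff_effect, info = p)
    expect_equal(a1$eff_aa, a2$eff_aa, info = p)
  }
})

test_that("impact is always one of the four classes and never empty in CDS", {
  g <- annot_genome()
  set.seed(6)
  pos <- sample(0:1999, 120)
  refb <- substring(g$sequence[[1]], pos + 1, pos + 1)
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  vars <- strainforge:::complete_variants(tibble::tibble(
    replicon = "chr", pos = as.integer(pos), type = "snv", ref = refb,
    alt = altb, length = 1L))
  a <- annotate_variants(vars, g)
  expect_true(all(a$eff_impact %in% c("HIGH", "MODERATE", "LOW",
                                      "MODIFIER")))
  in_cds <- a$pos >= 300 & a$pos < 330 | a$pos >= 600 & a$pos < 630
  expect_true(all(!is.na(a$eff_impact[in_cds]) &
                    nzchar(a$eff_impact[in_cds])))
})

test_that("variants on unknown replicons raise a consistency error", {
  v <- mk_var(10, ref = "A", alt = "C")
  v$replicon <- "plasmid9"
  expect_error(annotate_variants(v, annot_genome()),
               class = "strainforge_consistency_error")
})
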
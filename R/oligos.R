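#' Design MAGE oligonucleotides for a variant set
#'
#' For each variant, designs a single-stranded oligo of length `l_oligo`
#' whose sequence matches the post-edit genome in a window centered on the
#' edit (`offset = floor((l_oligo - edit_len) / 2)` flanking bases 5' of the
#' edit on the + strand), taken from the strand that anneals to the
#' lagging-strand template of the replication fork. Replichore 1 runs
#' clockwise from the origin `ori` to the terminus `ter` (coordinates
#' increasing, wrapping); its lagging-strand template is the + strand, so
#' the oligo is the reverse complement of the + strand window. Replichore 2
#' uses the + strand window directly. With `direction = "introduce"` the
#' post-edit genome carries the variant; with `"revert"` the post-edit
#' genome is the unedited reference (oligos to convert a mutant strain
#' back).
#'
#' @param reference the [ref_genome] the variants are expressed against.
#' @param variants variant tibble (the set to target).
#' @param direction `"introduce"` or `"revert"`.
#' @param ori,ter 0-based replication origin and terminus positions.
#' @param l_oligo oligo length in nt.
#' @param f_min minimum flank on each side of the edit.
#' @return tibble: `variant_id`, `direction`, `replichore`, `target_strand`,
#'   `offset_of_edit`, `sequence`.
#' @export
design_oligos <- function(reference, variants, direction = c("introduce",
                                                             "revert"),
                          ori, ter, l_oligo = 90, f_min = 20) {
  direction <- match.arg(direction)
  variants <- complete_variants(as_tibble(variants))
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    rep_ch <- replichore_of(v$pos, ori, ter,
                            nchar(reference$sequence[[v$replicon]]))
    edit_len_post <- switch(v$type, snv = 1L, deletion = 0L,
                            nchar(v$inserted_sequence))
    if (edit_len_post > l_oligo - 2L * f_min) {
      abort(sprintf(
        "variant %s: edit of %d bp exceeds oligo capacity (%d - 2*%d)",
        v$variant_id, edit_len_post, l_oligo, f_min),
        class = "strainforge_size_error")
    }
    ## post-edit genome and the edit's location on it
    if (direction == "introduce") {
      ap <- apply_variant_set(reference, v, name = "post_edit")
      post <- ap$genome$sequence[[v$replicon]]
      edit_start <- lift_position(ap$liftmap, v$replicon, v$pos)
      if (v$type == "deletion") edit_start <- edit_start
    } else {
      ## reverting: the post-edit genome is the reference itself; the edit
      ## region is the reference allele at the variant locus
      post <- reference$sequence[[v$replicon]]
      edit_start <- v$pos
      edit_len_post <- switch(v$type, snv = 1L, deletion = v$length, 0L)
      if (edit_len_post > l_oligo - 2L * f_min) {
        abort(sprintf(
          "variant %s: edit of %d bp exceeds oligo capacity",
          v$variant_id, edit_len_post),
          class = "strainforge_size_error")
      }
    }
    offset <- as.integer(floor((l_oligo - edit_len_post) / 2))
    win_start <- edit_start - offset
    win_end <- win_start + l_oligo
    L <- nchar(post)
    if (win_start < 0L || win_end > L) {
      abort(sprintf("variant %s: oligo window [%d,%d) outside replicon",
                    v$variant_id, win_start, win_end),
            class = "strainforge_size_error")
    }
    window <- subseq0(post, win_start, win_end)
    if (rep_ch == 1L) {
      sequence <- revcomp(window)
      target_strand <- "-"
      offset_of_edit <- l_oligo - offset - edit_len_post
    } else {
      sequence <- window
      target_strand <- "+"
      offset_of_edit <- offset
    }
    out[[length(out) + 1L]] <- tibble(
      variant_id = v$variant_id, direction = direction,
      replichore = rep_ch, target_strand = target_strand,
      offset_of_edit = as.integer(offset_of_edit), sequence = sequence)
  }
  if (length(out) == 0) {
    return(tibble(variant_id = character(0), direction = character(0),
                  replichore = integer(0), target_strand = character(0),
                  offset_of_edit = integer(0), sequence = character(0)))
  }
  bind_rows(out)
}

## replichore 1: clockwise ori -> ter (increasing coordinates, wrapping);
## a variant exactly at ori or ter is ambiguous.
replichore_of <- function(pos, ori, ter, len) {
  if (pos == ori || pos == ter) {
    abort(sprintf("position %d coincides with ori/ter; replichore ambiguous",
                  pos),
          class = "strainforge_ambiguity_error")
  }
  if (ori < ter) {
    if (pos > ori && pos < ter) 1L else 2L
  } else {
    if (pos > ori || pos < ter) 1L else 2L
  }
}

#' Write designed oligos as FASTA and TSV
#'
#' @param oligos tibble from [design_oligos()].
#' @param fasta_path,tsv_path output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_oligos <- function(oligos, fasta_path, tsv_path) {
  ids <- sprintf("%s|%s|R%d", oligos$variant_id, oligos$direction,
                 oligos$replichore)
  ss <- Biostrings::DNAStringSet(setNames(as.character(oligos$sequence),
                                          ids))
  Biostrings::writeXStringSet(ss, fasta_path, width = 100)
  readr::write_tsv(oligos, tsv_path)
  invisible(tsv_path)
}
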
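#' Simulate an annotated bacterial reference genome
#'
#' Generates a random genome carrying non-overlapping protein-coding ORFs
#' (ATG start, stop codon, no internal stops on the coding strand) and a set
#' of identical insertion-sequence (IS) element copies annotated as
#' `mobile_element` features. Deterministic for a given seed.
#'
#' @param length total replicon length in bp.
#' @param n_genes number of CDS features to place.
#' @param n_elements number of identical IS-element copies.
#' @param seed integer RNG seed.
#' @param gene_len CDS length in bp (multiple of 3).
#' @param element_len IS element length in bp.
#' @param element_label label shared by all element copies.
#' @param replicon replicon name.
#' @param name genome name.
#' @return a [ref_genome].
#' @export
sim_genome <- function(length, n_genes = 20, n_elements = 2, seed = 1,
                       gene_len = 300, element_len = 1340,
                       element_label = "IS186", replicon = "chr",
                       name = "sim_ref") {
  stopifnot(gene_len %% 3 == 0)
  margin <- 60L
  need <- n_genes * (gene_len + 2L * margin) +
    n_elements * (element_len + 2L * margin)
  if (need > length) {
    abort(sprintf(
      "cannot place %d genes and %d elements in %d bp (need >= %d)",
      n_genes, n_elements, length, need),
      class = "strainforge_capacity_error")
  }
  set.seed(seed)
  seq <- random_dna(length)
  placed <- tibble(start = integer(0), end = integer(0))
  place <- function(len) {
    for (try in 1:500) {
      s <- sample.int(length - len - 2L * margin, 1L) + margin
      if (!any(placed$start < s + len + margin &
               placed$end > s - margin)) {
        placed <<- bind_rows(placed, tibble(start = s, end = s + len))
        return(s)
      }
    }
    abort("could not place features without overlap; genome too dense",
          class = "strainforge_capacity_error")
  }
  feats <- list()
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  sense_codons <- setdiff(codons, stops)
  for (i in seq_len(n_genes)) {
    orf <- paste0("ATG",
                  paste(sample(sense_codons, gene_len / 3 - 2,
                               replace = TRUE), collapse = ""),
                  "TAA")
    s <- place(gene_len)
    strand <- sample(c("+", "-"), 1L)
    seq <- splice0(seq, s, s + gene_len,
                   if (strand == "+") orf else revcomp(orf))
    feats[[length(feats) + 1L]] <- tibble(
      replicon = replicon, start = s, end = s + gene_len, strand = strand,
      kind = "CDS", gene = sprintf("gene%02d", i),
      product = "hypothetical protein")
  }
  if (n_elements > 0) {
    element_seq <- random_dna(element_len)
    for (i in seq_len(n_elements)) {
      s <- place(element_len)
      seq <- splice0(seq, s, s + element_len, element_seq)
      feats[[length(feats) + 1L]] <- tibble(
        replicon = replicon, start = s, end = s + element_len, strand = "+",
        kind = "mobile_element", gene = element_label,
        product = "insertion sequence")
    }
  }
  ref_genome(name = name, sequence = setNames(seq, replicon),
             features = if (length(feats)) arrange(bind_rows(feats),
                                                   .data$start)
                        else empty_features())
}

#' Derive a mutant genome with a recorded truth table
#'
#' Plants the requested events (SNVs, deletions, novel-sequence insertions,
#' and mobile-element moves, i.e. copy of an annotated IS element to a new
#' locus) at random non-overlapping positions, keeping a safety margin from
#' each other, from replicon ends, and from existing element copies. Indel
#' breakpoints in the truth table are left-normalized, the same canonical
#' representation the SV caller reports. Events are applied through
#' [apply_variant_set()], so the mutant genome's features are lifted
#' consistently.
#'
#' @param genome parent [ref_genome].
#' @param events list with any of: `snv` (count), `deletion` (vector of
#'   lengths), `novel_insertion` (vector of lengths), `element_move`
#'   (count).
#' @param seed integer RNG seed.
#' @param margin minimum distance in bp between planted events and other
#'   features of interest.
#' @return list with `genome` (mutant [ref_genome]), `truth` (variant tibble
#'   with parent-genome coordinates, `method = "truth"`), `liftmap`, and
#'   `junctions` (mutant-coordinate SV breakpoints).
#' @export
sim_mutate <- function(genome, events = list(), seed = 1, margin = 500) {
  set.seed(derive_seed(seed, 2L))
  replicon <- names(genome$sequence)[1]
  seq <- genome$sequence[[replicon]]
  L <- nchar(seq)
  elements <- genome$features[genome$features$kind == "mobile_element" &
                                genome$features$replicon == replicon, ]
  ## keep-out zones: element copies (donors must stay intact) and ends
  zones <- tibble(start = elements$start - margin,
                  end = elements$end + margin)
  zones <- bind_rows(zones, tibble(start = c(-1L, L - margin),
                                   end = c(margin, L + 1L)))
  place <- function(width) {
    for (try in 1:1000) {
      s <- sample.int(L - width - 2L, 1L)
      if (!any(zones$start < s + width + margin & zones$end > s - margin)) {
        zones <<- bind_rows(zones, tibble(start = s, end = s + width))
        return(s)
      }
    }
    abort("could not place simulated events without overlap",
          class = "strainforge_placement_error")
  }
  truth <- list()
  for (len in (events$deletion %||% integer(0))) {
    s <- normalize_deletion(seq, place(len), len)
    truth[[length(truth) + 1L]] <- tibble(
      replicon = replicon, pos = s, type = "deletion", ref = NA_character_,
      alt = NA_character_, length = as.integer(len),
      inserted_sequence = NA_character_, element_label = NA_character_,
      method = "truth", multiplacement = FALSE)
  }
  for (len in (events$novel_insertion %||% integer(0))) {
    ins <- random_dna(len)
    nrm <- normalize_insertion(seq, place(0L), ins)
    truth[[length(truth) + 1L]] <- tibble(
      replicon = replicon, pos = nrm$pos, type = "novel_insertion",
      ref = NA_character_, alt = NA_character_, length = as.integer(len),
      inserted_sequence = nrm$ins, element_label = NA_character_,
      method = "truth", multiplacement = FALSE)
  }
  n_moves <- events$element_move %||% 0L
  if (n_moves > 0 && nrow(elements) == 0) {
    abort("element_move requested but genome has no mobile_element features",
          class = "strainforge_placement_error")
  }
  for (i in seq_len(n_moves)) {
    donor <- elements[sample.int(nrow(elements), 1L), ]
    eseq <- subseq0(seq, donor$start, donor$end)
    nrm <- normalize_insertion(seq, place(0L), eseq)
    truth[[length(truth) + 1L]] <- tibble(
      replicon = replicon, pos = nrm$pos, type = "mobile_element_insertion",
      ref = NA_character_, alt = NA_character_,
      length = as.integer(nchar(eseq)), inserted_sequence = nrm$ins,
      element_label = donor$gene, method = "truth", multiplacement = FALSE)
  }
  n_snv <- events$snv %||% 0L
  for (i in seq_len(n_snv)) {
    s <- place(1L)
    refb <- subseq0(seq, s, s + 1L)
    altb <- sample(setdiff(DNA_BASES, refb), 1L)
    truth[[length(truth) + 1L]] <- tibble(
      replicon = replicon, pos = s, type = "snv", ref = refb, alt = altb,
      length = 1L, inserted_sequence = NA_character_,
      element_label = NA_character_, method = "truth",
      multiplacement = FALSE)
  }
  truth <- complete_variants(if (length(truth)) bind_rows(truth)
                             else empty_variants())
  truth <- arrange(truth, .data$replicon, .data$pos)
  applied <- apply_variant_set(genome, truth,
                               name = paste0(genome$name, "_mut"))
  ## SV breakpoints in mutant coordinates
  sv <- truth[truth$type != "snv", , drop = FALSE]
  junctions <- tibble(replicon = character(0), pos = integer(0))
  if (nrow(sv)) {
    jl <- list()
    for (i in seq_len(nrow(sv))) {
      ## lift the base just before the breakpoint so insertions get their
      ## own left junction, not the post-insertion offset
      j <- lift_position(applied$liftmap, sv$replicon[i],
                         sv$pos[i] - 1L) + 1L
      ps <- if (sv$type[i] == "deletion") j else c(j, j + sv$length[i])
      jl[[i]] <- tibble(replicon = sv$replicon[i], pos = as.integer(ps))
    }
    junctions <- distinct(bind_rows(jl))
  }
  list(genome = applied$genome, truth = truth, liftmap = applied$liftmap,
       junctions = junctions)
}

#' Simulate error-bearing paired-end reads
#'
#' Fragments are sampled uniformly along each replicon (length-proportional
#' across replicons), fragment sizes are normal with the given mean/SD, and
#' each base is substituted independently at `error_rate`. Base qualities
#' are constant Q30, matching the error model's scale. Deterministic for a
#' given seed.
#'
#' @param genome [ref_genome] to sequence.
#' @param depth target mean coverage.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-size distribution.
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return list with `reads` (tibble: `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `meta` (truth-only fragment coordinates: `name`,
#'   `replicon`, `frag_start`, `frag_end`).
#' @export
sim_reads <- function(genome, depth = 30, read_len = 100, insert_mean = 300,
                      insert_sd = 30, error_rate = 0.001, seed = 1) {
  stopifnot(read_len < insert_mean)
  set.seed(derive_seed(seed, 3L))
  all_reads <- list(); all_meta <- list()
  qual <- strrep("?", read_len)  # Phred+33 Q30
  for (r in names(genome$sequence)) {
    seq <- genome$sequence[[r]]
    L <- nchar(seq)
    n_pairs <- round(depth * L / (2 * read_len))
    if (n_pairs == 0) next
    frag_len <- pmax(read_len + 10L,
                     pmin(L, as.integer(round(rnorm(n_pairs, insert_mean,
                                                    insert_sd)))))
    frag_start <- vapply(frag_len, function(fl)
      sample.int(L - fl + 1L, 1L) - 1L, integer(1))
    r1 <- substring(seq, frag_start + 1L, frag_start + read_len)
    r2 <- revcomp(substring(seq, frag_start + frag_len - read_len + 1L,
                            frag_start + frag_len))
    if (error_rate > 0) {
      r1 <- add_read_errors(r1, error_rate)
      r2 <- add_read_errors(r2, error_rate)
    }
    names_ <- sprintf("rd_%s_%06d", r, seq_len(n_pairs))
    all_reads[[r]] <- tibble(name = names_, seq1 = r1, qual1 = qual,
                             seq2 = r2, qual2 = qual)
    all_meta[[r]] <- tibble(name = names_, replicon = r,
                            frag_start = frag_start,
                            frag_end = frag_start + frag_len)
  }
  list(reads = bind_rows(all_reads), meta = bind_rows(all_meta))
}

add_read_errors <- function(seqs, error_rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write simulated read pairs as FASTQ
#'
#' @param reads tibble from [sim_reads()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  write_fastq(tibble(name = paste0(reads$name, "/1"), seq = reads$seq1,
                     qual = reads$qual1), p1)
  write_fastq(tibble(name = paste0(reads$name, "/2"), seq = reads$seq2,
                     qual = reads$qual2), p2)
  invisible(c(p1, p2))
}

#' Read names of simulated reads straddling given junctions
#'
#' Truth-table helper: returns the reads whose aligned span covers a
#' junction with at least `min_overlap` bases on both sides.
#'
#' @param meta fragment metadata from [sim_reads()].
#' @param junctions tibble with `replicon`, `pos` (mutant coordinates).
#' @param read_len read length used in simulation.
#' @param min_overlap minimum bases on each side of the junction.
#' @return tibble with `name` and `mate` (1 or 2).
#' @export
reads_over_junctions <- function(meta, junctions, read_len,
                                 min_overlap = 10) {
  out <- list()
  for (j in seq_len(nrow(junctions))) {
    jm <- meta[meta$replicon == junctions$replicon[j], ]
    p <- junctions$pos[j]
    r1s <- jm$frag_start; r1e <- jm$frag_start + read_len
    r2s <- jm$frag_end - read_len; r2e <- jm$frag_end
    hit1 <- r1s + min_overlap <= p & p <= r1e - min_overlap
    hit2 <- r2s + min_overlap <= p & p <= r2e - min_overlap
    out[[length(out) + 1L]] <- bind_rows(
      tibble(name = jm$name[hit1], mate = 1L),
      tibble(name = jm$name[hit2], mate = 2L))
  }
  distinct(bind_rows(out))
}
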
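## SAM flag bits
FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L
FLAG_SECOND <- 128L
FLAG_SUPPLEMENTARY <- 2048L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

empty_alignments <- function() {
  tibble(qname = character(0), flag = integer(0), replicon = character(0),
         pos = integer(0), mapq = integer(0), cigar = character(0),
         mrnm = character(0), mpos = integer(0), tlen = integer(0),
         seq = character(0), qual = character(0), sa = character(0),
         is_unmapped = logical(0), is_reverse = logical(0),
         is_supplementary = logical(0), is_proper_flag = logical(0),
         read_ord = integer(0))
}

#' Read alignments from a SAM file
#'
#' Parses a plain-text SAM file into a tibble of alignment records with the
#' leftmost position converted to 0-based coordinates, flag bits expanded into
#' logical columns, and the `SA` tag (supplementary/split alignments) captured
#' when present. When `reference` is supplied, records naming a replicon
#' absent from the reference raise a consistency error.
#'
#' @param path SAM file path.
#' @param reference optional [ref_genome] to validate replicon names against.
#' @return a tibble, one row per alignment record.
#' @export
read_alignments <- function(path, reference = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("SAM file not found: %s", path),
          class = "strainforge_io_error")
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) return(empty_alignments())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    abort(sprintf("malformed SAM record at line %d (%d fields)",
                  which(!startsWith(lines, "@"))[which(nf < 11)[1]],
                  min(nf)),
          class = "strainforge_parse_error")
  }
  sa <- vapply(fields, function(f) {
    tag <- grep("^SA:Z:", f[-(1:11)], value = TRUE)
    if (length(tag)) sub("^SA:Z:", "", tag[1]) else NA_character_
  }, character(1))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  aln <- tibble(
    qname = get(1), flag = flag, replicon = get(3),
    pos = as.integer(get(4)) - 1L,      # SAM 1-based -> 0-based
    mapq = as.integer(get(5)), cigar = get(6),
    mrnm = get(7), mpos = as.integer(get(8)) - 1L,
    tlen = as.integer(get(9)), seq = get(10), qual = get(11), sa = sa,
    is_unmapped = has_flag(flag, FLAG_UNMAPPED),
    is_reverse = has_flag(flag, FLAG_REVERSE),
    is_supplementary = has_flag(flag, FLAG_SUPPLEMENTARY),
    is_proper_flag = has_flag(flag, FLAG_PROPER),
    read_ord = ifelse(has_flag(flag, FLAG_SECOND), 2L, 1L)
  )
  if (!is.null(reference)) {
    known <- names(reference$sequence)
    bad <- setdiff(unique(aln$replicon[!aln$is_unmapped]), c(known, "*"))
    if (length(bad)) {
      abort(sprintf("SAM references replicon(s) absent from the reference: %s",
                    paste(bad, collapse = ", ")),
            class = "strainforge_consistency_error")
    }
  }
  aln
}

#' Write alignments to a SAM file
#'
#' @param alignments tibble as produced by [align_reads()] or
#'   [read_alignments()].
#' @param reference a [ref_genome]; used for the `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$sequence),
                   nchar(reference$sequence)))
  body <- character(0)
  if (nrow(alignments)) {
    opt <- ifelse(is.na(alignments$sa), "",
                  paste0("\tSA:Z:", alignments$sa))
    body <- paste0(
      alignments$qname, "\t", alignments$flag, "\t", alignments$replicon,
      "\t", alignments$pos + 1L, "\t", alignments$mapq, "\t",
      alignments$cigar, "\t", alignments$mrnm, "\t", alignments$mpos + 1L,
      "\t", alignments$tlen, "\t", alignments$seq, "\t", alignments$qual,
      opt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- CIGAR helpers -------------------------------------------------------

cigar_ops <- function(cigar) {
  if (cigar == "*") return(tibble(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  tibble(len = lens, op = ops)
}

cigar_clipped_length <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("S", "H")])
}

cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

## (ref_start, ref_end, read_start, read_end) blocks of aligned (M/=/X) bases,
## all 0-based half-open; read coordinates are in SAM orientation.
cigar_match_blocks <- function(cigar, pos) {
  ops <- cigar_ops(cigar)
  rs <- integer(0); re <- integer(0); qs <- integer(0); qe <- integer(0)
  rp <- pos; qp <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      rs <- c(rs, rp); re <- c(re, rp + len)
      qs <- c(qs, qp); qe <- c(qe, qp + len)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    }
  }
  tibble(ref_start = rs, ref_end = re, read_start = qs, read_end = qe)
}

## ---- FASTQ ---------------------------------------------------------------

#' Read a FASTQ file
#'
#' @param path FASTQ path (Phred+33).
#' @return tibble with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  tibble(name = sub("\\s.*$", "", names(ss)),
         seq = unname(as.character(ss)),
         qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' Write a FASTQ file
#'
#' @param reads tibble with columns `name`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$name, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}
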
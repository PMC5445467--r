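#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n row_number distinct across rename count
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised over a character vector of sequences (alphabet ACGTN).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast scalar reverse complement (avoids XStringSet overhead in hot loops)
revcomp1 <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

## substring of a replicon sequence in 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

## splice `insert` into `seq` replacing 0-based half-open [start, end)
splice0 <- function(seq, start, end, insert) {
  paste0(substr(seq, 1L, start), insert, substr(seq, end + 1L, nchar(seq)))
}

phred_to_error <- function(q) 10^(-q / 10)

qual_string_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

phred_to_qual_string <- function(q) {
  intToUtf8(q + 33L)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-DNA characters (allowed: A,C,G,T,N)", what),
          class = "strainforge_validation_error")
  }
  invisible(x)
}

## Left-normalize a deletion of `len` bases at 0-based `pos`:
## shift left while the base before the deletion equals its last base.
normalize_deletion <- function(seq, pos, len) {
  while (pos > 0L &&
         substr(seq, pos, pos) == substr(seq, pos + len, pos + len)) {
    pos <- pos - 1L
  }
  pos
}

## Left-normalize an insertion of `ins` before 0-based `pos`: rotate the
## inserted string left while its last base equals the reference base at pos-1.
normalize_insertion <- function(seq, pos, ins) {
  n <- nchar(ins)
  while (pos > 0L && substr(seq, pos, pos) == substr(ins, n, n)) {
    ins <- paste0(substr(ins, n, n), substr(ins, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ins = ins)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 7919L + as.integer(salt) * 104729L) %% 2000000011L %% 2147483647L
}
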
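## Internal seed-and-extend short-read aligner.
##
## Exact k-mer seeds on a hashed reference index vote for diagonals; each
## candidate diagonal is scored by vectorised base comparison. Reads that do
## not match end-to-end are soft-clipped around the best matching block
## (single isolated mismatches are tolerated inside a block), and clipped
## tails long enough to re-seed are aligned independently and emitted as
## supplementary records with SA tags (split reads). There is no gapped
## extension: indels inside reads surface as clips/splits, which is what the
## downstream candidate-read classifier consumes.

#' Build a k-mer index over a reference genome
#'
#' @param reference a [ref_genome].
#' @param k seed length.
#' @return an opaque index object for [align_reads()].
#' @export
seq_index <- function(reference, k = 21) {
  reps <- lapply(names(reference$sequence), function(r) {
    seq <- reference$sequence[[r]]
    L <- nchar(seq)
    env <- new.env(hash = TRUE, size = max(64L, L))
    if (L >= k) {
      kmers <- substring(seq, 1:(L - k + 1L), k:L)
      pos_by_kmer <- split(0:(L - k), kmers)
      list2env(pos_by_kmer, envir = env)
    }
    list(name = r, raw = charToRaw(seq), len = L, env = env)
  })
  names(reps) <- names(reference$sequence)
  structure(list(k = k, replicons = reps), class = "sf_seq_index")
}

## Extend a matching block around seed read-offsets [s0, s1] (1-based, in
## read coordinates) given mismatch vector m. Isolated mismatches followed by
## >= 4 matches are absorbed. Returns c(block_start, block_end) 1-based
## inclusive.
extend_block <- function(m, s0, s1) {
  len <- length(m)
  i <- s1
  while (i < len) {
    if (!m[i + 1L]) { i <- i + 1L; next }
    if (i + 5L <= len && !any(m[(i + 2L):(i + 5L)])) { i <- i + 2L; next }
    break
  }
  j <- s0
  while (j > 1L) {
    if (!m[j - 1L]) { j <- j - 1L; next }
    if (j - 5L >= 1L && !any(m[(j - 5L):(j - 2L)])) { j <- j - 2L; next }
    break
  }
  c(j, i)
}

## Align one read string (one orientation) against one replicon index.
## `salt` deterministically breaks ties among equal-scoring placements
## (repeat copies) so coverage spreads over identical repeats instead of
## piling onto one copy; tied reads get MAPQ 0.
## Returns list(pos, qstart, qend, mm, score, tie) or NULL.
align_orientation <- function(seq, rawseq, rep, k, max_mm, seed_offsets,
                              salt = 0L) {
  len <- length(rawseq)
  hits <- integer(0); offs <- integer(0)
  for (o in seed_offsets) {
    p <- get0(substr(seq, o + 1L, o + k), envir = rep$env,
              inherits = FALSE)
    if (!is.null(p)) {
      hits <- c(hits, p); offs <- c(offs, rep.int(o, length(p)))
    }
  }
  if (length(hits) == 0) return(NULL)
  diags <- hits - offs
  tab <- table(diags)
  dvals <- as.integer(names(tab))
  jitter <- ((dvals %% 9973L) * ((salt %% 97L) + 3L)) %% 8191L
  ord <- order(-as.integer(tab), jitter)
  cand <- dvals[ord][seq_len(min(4L, length(dvals)))]
  best <- NULL
  for (d in cand) {
    lo <- max(1L, 1L - d)          # read positions with a valid ref base
    hi <- min(len, rep$len - d)
    if (hi - lo + 1L < k) next
    m <- rep.int(TRUE, len)
    m[lo:hi] <- rep$raw[(d + lo):(d + hi)] != rawseq[lo:hi]
    tot <- sum(m)
    if (tot == 0L) {
      res <- list(pos = d + lo - 1L, qstart = lo, qend = hi, mm = 0L,
                  score = hi - lo + 1L)
    } else {
      so <- offs[diags == d][1]
      ## seed may itself contain no mismatch; extend around it, absorbing
      ## isolated internal mismatches, trimming mismatching tails
      blk <- extend_block(m, so + 1L, so + k)
      mm_in <- sum(m[blk[1]:blk[2]])
      if (mm_in > max_mm) next
      res <- list(pos = d + blk[1] - 1L, qstart = blk[1], qend = blk[2],
                  mm = mm_in,
                  score = (blk[2] - blk[1] + 1L) - 5L * mm_in)
    }
    if (is.null(best) || res$score > best$score) {
      res$tie <- FALSE
      best <- res
    } else if (res$score == best$score && res$pos != best$pos) {
      best$tie <- TRUE
    }
  }
  best
}

align_read_string <- function(seq, idx, max_mm = 5L, min_block = 30L,
                              rc = NULL, salt = 0L) {
  k <- idx$k
  len <- nchar(seq)
  if (len < k) return(NULL)
  seed_offsets <- unique(pmax(0L, pmin(
    as.integer(c(0, floor(len * 0.25), floor(len * 0.5),
                 floor(len * 0.75), len - k)), len - k)))
  rc <- rc %||% revcomp1(seq)
  best <- NULL
  for (rep_ in idx$replicons) {
    for (ori in c("+", "-")) {
      s <- if (ori == "+") seq else rc
      a <- align_orientation(s, charToRaw(s), rep_, k, max_mm,
                             seed_offsets, salt = salt)
      if (!is.null(a) && (a$qend - a$qstart + 1L) >= min_block) {
        a$strand <- ori; a$replicon <- rep_$name
        if (is.null(best) || a$score > best$score) best <- a
        else if (a$score == best$score) best$tie <- TRUE
      }
    }
  }
  best
}

make_cigar <- function(len, qstart, qend) {
  paste0(if (qstart > 1L) paste0(qstart - 1L, "S") else "",
         qend - qstart + 1L, "M",
         if (qend < len) paste0(len - qend, "S") else "")
}

#' Align paired-end reads to a reference genome
#'
#' Runs the package's internal seed-and-extend aligner over a tibble of read
#' pairs (as produced by [sim_reads()] or loaded from FASTQ with
#' [read_fastq()]), producing SAM-convention alignment records: 0-based
#' leftmost positions, soft-clip CIGARs, SA tags for split reads, proper-pair
#' flags derived from the empirical fragment-size distribution (FR
#' orientation within `sd_mult` SDs of the mean), and MAPQ 60 for unique
#' placements / 0 for ties.
#'
#' @param reads tibble with columns `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param reference a [ref_genome].
#' @param index optional prebuilt [seq_index()]; rebuilt if `NULL`.
#' @param max_mm maximum mismatches for an end-to-end alignment.
#' @param min_split minimum soft-clipped tail length to attempt a
#'   supplementary (split) alignment.
#' @param sd_mult proper-pair window half-width in fragment-size SDs.
#' @return alignment tibble (see [read_alignments()] for columns).
#' @export
align_reads <- function(reads, reference, index = NULL, max_mm = 5L,
                        min_split = 25L, sd_mult = 3) {
  idx <- index %||% seq_index(reference)
  n <- nrow(reads)
  if (n == 0) return(empty_alignments())
  qn <- rep(reads$name, each = 2L)
  sq <- as.vector(rbind(reads$seq1, reads$seq2))
  ql <- as.vector(rbind(reads$qual1, reads$qual2))
  N <- 2L * n
  repl <- rep("*", N); pos <- rep(-1L, N); mapq <- rep(0L, N)
  cig <- rep("*", N); strand <- rep("+", N)
  qs <- integer(N); qe <- integer(N); mapped <- logical(N)
  osqv <- sq  # read in the primary alignment's reference-forward orientation
  rc_all <- revcomp(sq)
  supp <- vector("list", N)
  for (i in seq_len(N)) {
    a <- align_read_string(sq[i], idx, max_mm = max_mm, rc = rc_all[i],
                           salt = i)
    if (is.null(a)) next
    mapped[i] <- TRUE
    repl[i] <- a$replicon; pos[i] <- a$pos; strand[i] <- a$strand
    len <- nchar(sq[i])
    ## qstart/qend are already in aligned orientation (the oriented string
    ## that matched forward); keep pos/CIGAR/seq consistent in that frame
    if (a$strand == "-") osqv[i] <- rc_all[i]
    qs[i] <- a$qstart; qe[i] <- a$qend
    cig[i] <- make_cigar(len, a$qstart, a$qend)
    mapq[i] <- if (isTRUE(a$tie)) 0L else 60L
    ## split-read rescue on long clipped tails
    lclip <- a$qstart - 1L; rclip <- len - a$qend
    for (side in c("L", "R")) {
      cl <- if (side == "L") lclip else rclip
      if (cl < min_split) next
      sub <- if (side == "L") substr(osqv[i], 1L, lclip)
             else substr(osqv[i], a$qend + 1L, len)
      s2 <- align_read_string(sub, idx, max_mm = max_mm, salt = i)
      if (is.null(s2)) next
      supp[[i]] <- list(sub_off = if (side == "L") 0L else a$qend,
                        a = s2, sub_len = nchar(sub))
      break
    }
  }
  ## fragment-size stats from uniquely mapped FR pairs
  i1 <- seq(1L, N, by = 2L); i2 <- i1 + 1L
  pairable <- mapped[i1] & mapped[i2] & repl[i1] == repl[i2] &
    strand[i1] != strand[i2]
  span1 <- pos + (qe - qs)  # rightmost aligned ref pos (approx end)
  frag <- ifelse(strand[i1] == "+",
                 (pos[i2] + (qe[i2] - qs[i2]) + 1L) - pos[i1],
                 (pos[i1] + (qe[i1] - qs[i1]) + 1L) - pos[i2])
  ok <- pairable & frag > 0
  ## robust location/scale: SV-induced outlier fragments must not widen
  ## the proper-pair window
  mu <- if (any(ok)) stats::median(frag[ok]) else 0
  sdv <- if (sum(ok) > 1) stats::mad(frag[ok]) else 1
  proper_pair_v <- pairable & frag > 0 &
    abs(frag - mu) <= sd_mult * max(sdv, 1)
  n_supp <- sum(!vapply(supp, is.null, logical(1)))
  M <- N + n_supp
  o_qname <- character(M); o_flag <- integer(M); o_repl <- character(M)
  o_pos <- integer(M); o_mapq <- integer(M); o_cig <- character(M)
  o_mrnm <- character(M); o_mpos <- integer(M); o_tlen <- integer(M)
  o_seq <- character(M); o_qual <- character(M); o_sa <- rep(NA_character_, M)
  o_unm <- logical(M); o_rev <- logical(M); o_sup <- logical(M)
  o_prop <- logical(M); o_ord <- integer(M)
  rn <- 0L
  for (p in seq_len(n)) {
    prop <- proper_pair_v[p]
    for (side in 1:2) {
      me <- if (side == 1) i1[p] else i2[p]
      mt <- if (side == 1) i2[p] else i1[p]
      flag <- FLAG_PAIRED +
        (if (side == 1) FLAG_FIRST else FLAG_SECOND) +
        (if (prop) FLAG_PROPER else 0L) +
        (if (!mapped[me]) FLAG_UNMAPPED else 0L) +
        (if (!mapped[mt]) FLAG_MATE_UNMAPPED else 0L) +
        (if (mapped[me] && strand[me] == "-") FLAG_REVERSE else 0L) +
        (if (mapped[mt] && strand[mt] == "-") FLAG_MATE_REVERSE else 0L)
      oqual <- ql[me]
      if (mapped[me] && strand[me] == "-") {
        oqual <- paste(rev(strsplit(oqual, "")[[1]]), collapse = "")
      }
      tl <- 0L
      if (mapped[me] && mapped[mt] && repl[me] == repl[mt]) {
        left <- min(pos[me], pos[mt])
        right <- max(pos[me] + (qe[me] - qs[me]) + 1L,
                     pos[mt] + (qe[mt] - qs[mt]) + 1L)
        tl <- if (pos[me] <= pos[mt]) right - left else -(right - left)
      }
      sp <- supp[[me]]
      len <- nchar(sq[me])
      sa_main <- NA_character_
      sub_cig <- NULL
      if (!is.null(sp)) {
        s2 <- sp$a
        if (s2$strand == "+") {
          gs <- sp$sub_off + s2$qstart; ge <- sp$sub_off + s2$qend
        } else {
          base <- len - sp$sub_off - sp$sub_len
          gs <- base + s2$qstart; ge <- base + s2$qend
        }
        sub_cig <- make_cigar(len, gs, ge)
        sa_main <- sprintf("%s,%d,%s,%s,60,0;", s2$replicon, s2$pos + 1L,
                           s2$strand, sub_cig)
      }
      rn <- rn + 1L
      o_qname[rn] <- qn[me]; o_flag[rn] <- flag
      o_repl[rn] <- if (mapped[me]) repl[me] else "*"
      o_pos[rn] <- if (mapped[me]) pos[me] else -1L
      o_mapq[rn] <- mapq[me]; o_cig[rn] <- cig[me]
      o_mrnm[rn] <- if (mapped[mt]) repl[mt] else "*"
      o_mpos[rn] <- if (mapped[mt]) pos[mt] else -1L
      o_tlen[rn] <- tl
      o_seq[rn] <- osqv[me]; o_qual[rn] <- oqual; o_sa[rn] <- sa_main
      o_unm[rn] <- !mapped[me]
      o_rev[rn] <- mapped[me] && strand[me] == "-"
      o_sup[rn] <- FALSE; o_prop[rn] <- prop; o_ord[rn] <- side
      if (!is.null(sp)) {
        s2 <- sp$a
        supp_rev <- xor(strand[me] == "-", s2$strand == "-")
        sflag <- FLAG_PAIRED + FLAG_SUPPLEMENTARY +
          (if (side == 1) FLAG_FIRST else FLAG_SECOND) +
          (if (prop) FLAG_PROPER else 0L) +
          (if (supp_rev) FLAG_REVERSE else 0L) +
          (if (mapped[mt] && strand[mt] == "-") FLAG_MATE_REVERSE else 0L)
        rn <- rn + 1L
        o_qname[rn] <- qn[me]; o_flag[rn] <- sflag
        o_repl[rn] <- s2$replicon; o_pos[rn] <- s2$pos
        o_mapq[rn] <- if (isTRUE(s2$tie)) 0L else 60L
        o_cig[rn] <- sub_cig
        o_mrnm[rn] <- if (mapped[mt]) repl[mt] else "*"
        o_mpos[rn] <- if (mapped[mt]) pos[mt] else -1L
        o_tlen[rn] <- 0L
        o_seq[rn] <- if (s2$strand == "+") osqv[me] else revcomp1(osqv[me])
        o_qual[rn] <- oqual
        o_sa[rn] <- sprintf("%s,%d,%s,%s,%d,0;", repl[me], pos[me] + 1L,
                            strand[me], cig[me], mapq[me])
        o_unm[rn] <- FALSE; o_rev[rn] <- supp_rev
        o_sup[rn] <- TRUE; o_prop[rn] <- prop; o_ord[rn] <- side
      }
    }
  }
  tibble(qname = o_qname, flag = as.integer(o_flag), replicon = o_repl,
         pos = as.integer(o_pos), mapq = as.integer(o_mapq),
         cigar = o_cig, mrnm = o_mrnm, mpos = as.integer(o_mpos),
         tlen = as.integer(o_tlen), seq = o_seq, qual = o_qual, sa = o_sa,
         is_unmapped = o_unm, is_reverse = o_rev, is_supplementary = o_sup,
         is_proper_flag = o_prop, read_ord = o_ord)
}
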
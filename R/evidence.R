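## Read classification, candidate extraction, coverage, and the pileup
## SNV genotyper with the diploid-mode wild-type / marginal / mutant
## trichotomy.

clip_lengths <- function(cigar) {
  lead <- as.integer(stringr::str_match(cigar, "^(\\d+)S")[, 2])
  trail <- as.integer(stringr::str_match(cigar, "(\\d+)S$")[, 2])
  lead[is.na(lead)] <- 0L
  trail[is.na(trail)] <- 0L
  cbind(lead = lead, trail = trail)
}

#' Classify alignment records for structural-variant candidacy
#'
#' Assigns each record exactly one category — `unmapped`, `split` (has a
#' supplementary alignment), `clipped` (at least `s_min` soft-clipped
#' bases), `discordant_pair` (pair not in proper FR orientation within the
#' fragment-size window), or `proper` — with that precedence, and flags
#' records whose mate is a candidate.
#'
#' @param alignments alignment tibble.
#' @param s_min minimum clipped bases for the `clipped` category.
#' @return the tibble with `category` and `mate_of_candidate` columns added.
#' @export
classify_reads <- function(alignments, s_min = 10) {
  if (nrow(alignments) == 0) {
    return(mutate(alignments, category = character(0),
                  mate_of_candidate = logical(0)))
  }
  cl <- clip_lengths(alignments$cigar)
  nclip <- cl[, "lead"] + cl[, "trail"]
  category <- dplyr::case_when(
    alignments$is_unmapped ~ "unmapped",
    alignments$is_supplementary | !is.na(alignments$sa) ~ "split",
    nclip >= s_min ~ "clipped",
    !alignments$is_proper_flag ~ "discordant_pair",
    TRUE ~ "proper")
  out <- mutate(alignments, category = category)
  cand <- out$category != "proper" & !out$is_supplementary
  key <- paste0(out$qname, "/", out$read_ord)
  mate_key <- paste0(out$qname, "/", 3L - out$read_ord)
  cand_keys <- unique(key[cand])
  mutate(out, mate_of_candidate = mate_key %in% cand_keys)
}

#' Extract candidate reads for local de novo assembly
#'
#' Returns the union of non-proper reads (unmapped, clipped, split,
#' discordant) and their mates as FASTQ-like records, with sequences
#' reverse-complemented back to sequencing orientation.
#'
#' @param alignments alignment tibble; classified with [classify_reads()]
#'   first if the `category` column is absent.
#' @param s_min passed to [classify_reads()] when classification is needed.
#' @return tibble with `name`, `seq`, `qual`.
#' @export
extract_candidates <- function(alignments, s_min = 10) {
  if (!"category" %in% names(alignments)) {
    alignments <- classify_reads(alignments, s_min = s_min)
  }
  prim <- alignments[!alignments$is_supplementary, , drop = FALSE]
  take <- prim$category != "proper" | prim$mate_of_candidate
  sel <- prim[take, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(tibble(name = character(0), seq = character(0),
                  qual = character(0)))
  }
  cand_keys <- unique(paste0(prim$qname, "/", prim$read_ord)[
    prim$category != "proper"])
  missing_mates <- setdiff(
    paste0(sub("/.*$", "", cand_keys), "/",
           3L - as.integer(sub("^.*/", "", cand_keys))),
    paste0(prim$qname, "/", prim$read_ord))
  if (length(missing_mates)) {
    warn(sprintf("%d candidate read(s) have no mate record",
                 length(missing_mates)))
  }
  seq <- ifelse(sel$is_reverse, revcomp(sel$seq), sel$seq)
  qual <- ifelse(sel$is_reverse,
                 vapply(strsplit(sel$qual, ""),
                        function(x) paste(rev(x), collapse = ""),
                        character(1)),
                 sel$qual)
  distinct(tibble(name = paste0(sel$qname, "/", sel$read_ord),
                  seq = seq, qual = qual),
           .data$name, .keep_all = TRUE)
}

#' Per-base coverage profile
#'
#' Depth counts aligned (`M`/`=`/`X`) bases of primary alignments only;
#' deleted (`D`) and clipped reference bases get no depth.
#'
#' @param alignments alignment tibble.
#' @param reference a [ref_genome].
#' @return tibble with `replicon`, `pos` (0-based), `depth`; one row per
#'   reference base.
#' @export
coverage_profile <- function(alignments, reference) {
  prim <- alignments[!alignments$is_unmapped &
                       !alignments$is_supplementary, , drop = FALSE]
  out <- list()
  for (r in names(reference$sequence)) {
    L <- nchar(reference$sequence[[r]])
    delta <- integer(L + 1L)
    rec <- prim[prim$replicon == r, , drop = FALSE]
    if (nrow(rec)) {
      simple <- !grepl("[DIN]", rec$cigar)
      if (any(simple)) {
        rs <- rec[simple, ]
        cl <- clip_lengths(rs$cigar)
        mlen <- nchar(rs$seq) - cl[, "lead"] - cl[, "trail"]
        starts <- pmax(0L, rs$pos)
        ends <- pmin(L, rs$pos + mlen)
        keep <- ends > starts
        for (i in which(keep)) {
          delta[starts[i] + 1L] <- delta[starts[i] + 1L] + 1L
          delta[ends[i] + 1L] <- delta[ends[i] + 1L] - 1L
        }
      }
      for (i in which(!simple)) {
        bl <- cigar_match_blocks(rec$cigar[i], rec$pos[i])
        for (j in seq_len(nrow(bl))) {
          s <- max(0L, bl$ref_start[j]); e <- min(L, bl$ref_end[j])
          if (e > s) {
            delta[s + 1L] <- delta[s + 1L] + 1L
            delta[e + 1L] <- delta[e + 1L] - 1L
          }
        }
      }
    }
    out[[r]] <- tibble(replicon = r, pos = 0:(L - 1L),
                       depth = cumsum(delta[seq_len(L)]))
  }
  bind_rows(out)
}

## Pileup of aligned bases: one row per (record, aligned base).
build_pileup <- function(alignments) {
  prim <- alignments[!alignments$is_unmapped &
                       !alignments$is_supplementary, , drop = FALSE]
  if (nrow(prim) == 0) {
    return(tibble(replicon = character(0), pos = integer(0),
                  base = character(0), qual = integer(0), mapq = integer(0)))
  }
  cl <- clip_lengths(prim$cigar)
  complex_ <- grepl("[DIN]", prim$cigar)
  reps <- list()
  ## simple xS yM zS records, fully vectorised
  if (any(!complex_)) {
    ps <- prim[!complex_, , drop = FALSE]
    lead <- cl[!complex_, "lead"]; trail <- cl[!complex_, "trail"]
    mlen <- nchar(ps$seq) - lead - trail
    keep <- mlen > 0
    ps <- ps[keep, , drop = FALSE]
    lead <- lead[keep]; mlen <- mlen[keep]
    offs <- sequence(mlen) - 1L
    refpos <- rep(ps$pos, mlen) + offs
    sub <- substr(ps$seq, lead + 1L, lead + mlen)
    qsub <- substr(ps$qual, lead + 1L, lead + mlen)
    reps[[1]] <- tibble(
      replicon = rep(ps$replicon, mlen), pos = refpos,
      base = unlist(strsplit(sub, ""), use.names = FALSE),
      qual = unlist(lapply(qsub, qual_string_to_phred), use.names = FALSE),
      mapq = rep(ps$mapq, mlen))
  }
  if (any(complex_)) {
    pc <- prim[complex_, , drop = FALSE]
    for (i in seq_len(nrow(pc))) {
      bl <- cigar_match_blocks(pc$cigar[i], pc$pos[i])
      for (j in seq_len(nrow(bl))) {
        rs <- bl$read_start[j]; re <- bl$read_end[j]
        reps[[length(reps) + 1L]] <- tibble(
          replicon = pc$replicon[i],
          pos = bl$ref_start[j]:(bl$ref_end[j] - 1L),
          base = strsplit(substr(pc$seq[i], rs + 1L, re), "")[[1]],
          qual = qual_string_to_phred(substr(pc$qual[i], rs + 1L, re)),
          mapq = pc$mapq[i])
      }
    }
  }
  bind_rows(reps)
}

## Diploid genotype from ref/alt counts under a symmetric binomial mixture
## with allele fractions {0, 1/2, 1}, flat prior. `err` is the per-read
## error probability. Returns gt, gt_type, gq (phred of 1 - posterior).
genotype_from_counts <- function(n_ref, n_alt, err) {
  err <- pmin(pmax(err, 1e-6), 0.5)
  l0 <- n_alt * log(err) + n_ref * log1p(-err)
  l1 <- (n_ref + n_alt) * log(0.5)
  l2 <- n_ref * log(err) + n_alt * log1p(-err)
  ll <- cbind(l0, l1, l2)
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  gt_type <- max.col(post, ties.method = "first") - 1L
  pmax_ <- post[cbind(seq_len(nrow(post)), gt_type + 1L)]
  gq <- pmin(99, round(-10 * log10(pmax(1 - pmax_, 1e-10))))
  tibble(gt = c("0/0", "0/1", "1/1")[gt_type + 1L],
         gt_type = gt_type, gq = gq)
}

#' Call SNVs from a pileup with the diploid-mode trichotomy
#'
#' For every site with non-reference evidence and depth at least `d_min`,
#' fits a symmetric binomial mixture over diploid allele fractions
#' `{0, 1/2, 1}` with per-read error probabilities derived from base
#' qualities (flat prior, maximum a posteriori call). `GT_TYPE` maps
#' `0/0 -> 0` (wild type), `0/1 -> 1` (marginal), `1/1 -> 2` (mutant); only
#' sites with `GT_TYPE > 0` are emitted. Indels are not called here — they
#' are the assembly/coverage SV callers' job.
#'
#' @param alignments alignment tibble for one sample.
#' @param reference a [ref_genome].
#' @param d_min minimum depth to emit a call.
#' @return tibble of variant rows (see [empty_variants()]) joined with call
#'   columns `gt`, `gt_type`, `gq`, `dp`, `af`, `mean_mapq`.
#' @export
call_snvs <- function(alignments, reference, d_min = 5) {
  pu <- build_pileup(alignments)
  if (nrow(pu) == 0) return(snv_call_schema())
  counts <- pu |>
    group_by(.data$replicon, .data$pos, .data$base) |>
    summarise(n = dplyr::n(), err = mean(phred_to_error(.data$qual)),
              mapq = mean(.data$mapq), .groups = "drop")
  refchars <- lapply(reference$sequence, function(s) strsplit(s, "")[[1]])
  counts$ref_base <- vapply(seq_len(nrow(counts)), function(i)
    refchars[[counts$replicon[i]]][counts$pos[i] + 1L], character(1))
  ## only sites with any non-reference evidence need genotyping
  alt_sites <- distinct(counts[counts$base != counts$ref_base, ,
                               drop = FALSE],
                        .data$replicon, .data$pos)
  counts <- dplyr::semi_join(counts, alt_sites,
                             by = c("replicon", "pos"))
  if (nrow(counts) == 0) return(snv_call_schema())
  site <- counts |>
    group_by(.data$replicon, .data$pos, .data$ref_base) |>
    summarise(
      dp = sum(.data$n),
      n_ref = sum(.data$n[.data$base == .data$ref_base[1]]),
      alt = {
        nonref <- .data$base != .data$ref_base[1]
        if (any(nonref)) .data$base[nonref][which.max(.data$n[nonref])]
        else NA_character_
      },
      n_alt = if (any(.data$base != .data$ref_base[1]))
        max(.data$n[.data$base != .data$ref_base[1]]) else 0L,
      err = mean(.data$err), mean_mapq = sum(.data$n * .data$mapq) /
        sum(.data$n),
      .groups = "drop") |>
    filter(!is.na(.data$alt), .data$dp >= d_min)
  if (nrow(site) == 0) return(snv_call_schema())
  g <- genotype_from_counts(site$n_ref, site$n_alt, site$err)
  out <- bind_cols(site, g) |>
    filter(.data$gt_type > 0L) |>
    mutate(type = "snv", ref = .data$ref_base, length = 1L,
           method = "pileup", af = .data$n_alt / (.data$n_ref + .data$n_alt),
           variant_id = variant_id_of(.data$replicon, .data$pos, "snv",
                                      .data$alt)) |>
    select("variant_id", "replicon", "pos", "type", "ref", "alt",
           "length", "method", "gt", "gt_type", "gq", "dp", "af",
           "mean_mapq")
  out
}

snv_call_schema <- function() {
  tibble(variant_id = character(0), replicon = character(0),
         pos = integer(0), type = character(0), ref = character(0),
         alt = character(0), length = integer(0), method = character(0),
         gt = character(0), gt_type = integer(0), gq = numeric(0),
         dp = integer(0), af = numeric(0), mean_mapq = numeric(0))
}

#' Genotype a sample at a fixed list of SNV sites
#'
#' Used to fill in evidence (including clean wild-type `GT_TYPE = 0` rows)
#' at the union of variant sites discovered across samples. Sites without
#' coverage are reported with `gt = "./."`, `gt_type = 0`, `dp = 0`.
#'
#' @param alignments alignment tibble for one sample.
#' @param reference a [ref_genome].
#' @param sites variant tibble of SNV sites (`replicon`, `pos`, `ref`,
#'   `alt`, `variant_id`).
#' @return call tibble, one row per site.
#' @export
genotype_sites <- function(alignments, reference, sites) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0) return(snv_call_schema())
  pu <- build_pileup(alignments)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    here <- pu[pu$replicon == sites$replicon[i] &
                 pu$pos == sites$pos[i], , drop = FALSE]
    dp <- nrow(here)
    if (dp == 0) {
      out[[i]] <- tibble(variant_id = sites$variant_id[i], gt = "./.",
                         gt_type = 0L, gq = 0, dp = 0L, af = 0,
                         mean_mapq = NA_real_)
      next
    }
    n_ref <- sum(here$base == sites$ref[i])
    n_alt <- sum(here$base == sites$alt[i])
    g <- genotype_from_counts(n_ref, n_alt,
                              mean(phred_to_error(here$qual)))
    out[[i]] <- tibble(variant_id = sites$variant_id[i], gt = g$gt,
                       gt_type = g$gt_type, gq = g$gq, dp = dp,
                       af = if (n_ref + n_alt > 0)
                         n_alt / (n_ref + n_alt) else 0,
                       mean_mapq = mean(here$mapq))
  }
  bind_rows(out)
}
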
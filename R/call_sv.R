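#' Call structural variants by placement-graph traversal
#'
#' Walks each contig's chain of reference alignments and emits:
#' \describe{
#'   \item{deletion}{two colinear edges with a reference gap and no contig
#'     gap (2 supporting edges);}
#'   \item{novel_insertion}{two edges with a contig gap and no reference
#'     gap; the unaligned contig interior is the inserted sequence
#'     (2 supporting edges);}
#'   \item{mobile_element_insertion}{two junction signatures — an outer
#'     (flank) edge meeting an inner edge that maps inside an annotated
#'     `mobile_element` feature — paired across contigs at the same site
#'     (4 supporting edges), labelled with the element's name.}
#' }
#' Indel breakpoints are left-normalized against the reference. When the
#' inner edges align equally to several identical element copies the
#' insertion site is still reported authoritatively and the call is flagged
#' `multiplacement`.
#'
#' @param graph a `placement_graph` from [align_contigs()].
#' @param reference the [ref_genome] the graph was built against (supplies
#'   sequence for normalization and the feature table for element labels).
#' @param min_sv_len minimum deletion length to call.
#' @param min_ins_len minimum novel-insertion length to call.
#' @param tol maximum residual gap (bp) treated as "no gap".
#' @param site_tol maximum distance (bp) between left and right
#'   mobile-element junction signatures at one site.
#' @return variant tibble with a `supporting_edges` list-column and
#'   `n_edges` count.
#' @export
call_structural_variants <- function(graph, reference, min_sv_len = 50,
                                     min_ins_len = 20, tol = 5,
                                     site_tol = 20) {
  features <- reference$features
  contigs <- graph$contigs
  calls <- list()
  signatures <- list()
  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[ci]
    len <- contigs$length[ci]
    e <- graph$edges[graph$edges$contig_id == cid, , drop = FALSE]
    if (nrow(e) < 2) next
    cseq <- contigs$sequence[ci]
    ## canonical traversal orientation: flank (non-element) edges forward
    ref_strand <- e$strand[is.na(e$element)]
    if (length(ref_strand) == 0) ref_strand <- e$strand
    if (mean(ref_strand == "-") > 0.5) {
      e <- mutate(e,
                  new_start = len - .data$c_end,
                  new_end = len - .data$c_start,
                  strand = ifelse(.data$strand == "+", "-", "+"))
      e$c_start <- e$new_start; e$c_end <- e$new_end
      e$new_start <- NULL; e$new_end <- NULL
      cseq <- revcomp(cseq)
    }
    e <- arrange(e, .data$c_start)
    for (i in seq_len(nrow(e) - 1L)) {
      e1 <- e[i, ]; e2 <- e[i + 1L, ]
      g_c <- e2$c_start - e1$c_end
      el1 <- !is.na(e1$element); el2 <- !is.na(e2$element)
      if (!el1 && !el2 && e1$replicon == e2$replicon &&
          e1$strand == "+" && e2$strand == "+") {
        g_r <- e2$r_start - e1$r_end
        if (g_c <= tol && g_c >= -tol && g_r >= min_sv_len) {
          seq <- reference$sequence[[e1$replicon]]
          pos <- normalize_deletion(seq, e1$r_end, g_r)
          calls[[length(calls) + 1L]] <- tibble(
            replicon = e1$replicon, pos = as.integer(pos),
            type = "deletion", length = as.integer(g_r),
            inserted_sequence = NA_character_,
            element_label = NA_character_, method = "assembly",
            multiplacement = FALSE,
            supporting_edges = list(c(e1$edge_id, e2$edge_id)))
        } else if (g_r <= 0 && -g_r <= 4 * tol && g_c >= min_ins_len) {
          ## flank alignments over-extend into an insert whose ends happen
          ## to match the reference; the edges then overlap by -g_r on the
          ## reference. The mutant locally equals
          ## ref[..r_end1) + interior + ref[r_start2..), i.e. an insertion
          ## of interior ++ ref[r_start2, r_end1) at r_end1.
          seq <- reference$sequence[[e1$replicon]]
          ins <- paste0(subseq0(cseq, e1$c_end, e2$c_start),
                        subseq0(seq, e2$r_start, e1$r_end))
          nrm <- normalize_insertion(seq, e1$r_end, ins)
          calls[[length(calls) + 1L]] <- tibble(
            replicon = e1$replicon, pos = as.integer(nrm$pos),
            type = "novel_insertion", length = nchar(ins),
            inserted_sequence = nrm$ins, element_label = NA_character_,
            method = "assembly", multiplacement = FALSE,
            supporting_edges = list(c(e1$edge_id, e2$edge_id)))
        }
      } else if (xor(el1, el2) && abs(g_c) <= tol) {
        outer <- if (el1) e2 else e1
        inner <- if (el1) e1 else e2
        if (outer$strand != "+") next
        side <- if (el2) "L" else "R"   # element follows flank => left flank
        site <- if (side == "L") outer$r_end else outer$r_start
        signatures[[length(signatures) + 1L]] <- tibble(
          contig_id = cid, side = side, replicon = outer$replicon,
          site = as.integer(site), element = inner$element,
          element_strand = inner$strand,
          inner_replicon = inner$replicon,
          inner_start = inner$r_start, inner_end = inner$r_end,
          outer_edge = outer$edge_id, inner_edge = inner$edge_id,
          multi = isTRUE(inner$multi))
      }
    }
  }
  ## pair left and right element-junction signatures at a common site
  if (length(signatures)) {
    sig <- bind_rows(signatures)
    Ls <- sig[sig$side == "L", , drop = FALSE]
    Rs <- sig[sig$side == "R", , drop = FALSE]
    used_r <- logical(nrow(Rs))
    for (i in seq_len(nrow(Ls))) {
      j <- which(!used_r & Rs$replicon == Ls$replicon[i] &
                   Rs$element == Ls$element[i] &
                   abs(Rs$site - Ls$site[i]) <= site_tol)
      if (length(j) == 0) next
      j <- j[which.min(abs(Rs$site[j] - Ls$site[i]))]
      used_r[j] <- TRUE
      elfeat <- features[features$kind == "mobile_element" &
                           !is.na(features$gene) &
                           features$gene == Ls$element[i], , drop = FALSE]
      if (nrow(elfeat) == 0) next
      donor <- elfeat[1, ]
      eseq <- subseq0(reference$sequence[[donor$replicon]], donor$start,
                      donor$end)
      ori <- Ls$element_strand[i]
      if (ori == "-") eseq <- revcomp(eseq)
      seq <- reference$sequence[[Ls$replicon[i]]]
      ## reconcile over-extended flank edges: the left junction sits at
      ## p + a and the right at p - b when the element's ends match the
      ## reference around the true site p; recover p by matching the
      ## element prefix/suffix against the reference between the two
      ## junction estimates
      q1 <- Ls$site[i]; q2 <- Rs$site[j]
      if (q2 >= q1) {
        ## junction estimates bracket the site from the left; inserting E
        ## at the right estimate reproduces the mutant exactly
        p <- q2
      } else {
        ## flank edges over-extended into the element on both sides; find
        ## the split where the element prefix/suffix match the reference
        ## between the two junction estimates
        p <- q1
        n_el <- nchar(eseq)
        for (t in (q1 - q2):0) {
          pref_ok <- t == 0 ||
            subseq0(seq, q1 - t, q1) == substr(eseq, 1L, t)
          suf_len <- (q1 - q2) - t
          suf_ok <- suf_len == 0 ||
            subseq0(seq, q2, q1 - t) ==
              substr(eseq, n_el - suf_len + 1L, n_el)
          if (pref_ok && suf_ok) { p <- q1 - t; break }
        }
      }
      nrm <- normalize_insertion(seq, p, eseq)
      calls[[length(calls) + 1L]] <- tibble(
        replicon = Ls$replicon[i], pos = as.integer(nrm$pos),
        type = "mobile_element_insertion", length = nchar(eseq),
        inserted_sequence = nrm$ins, element_label = Ls$element[i],
        method = "assembly",
        multiplacement = Ls$multi[i] || Rs$multi[j] || nrow(elfeat) > 1,
        supporting_edges = list(c(Ls$outer_edge[i], Ls$inner_edge[i],
                                  Rs$inner_edge[j], Rs$outer_edge[j])))
    }
  }
  if (length(calls) == 0) {
    out <- empty_variants()
    out$supporting_edges <- list()
    out$n_edges <- integer(0)
    return(out)
  }
  out <- bind_rows(calls) |>
    mutate(ref = NA_character_, alt = NA_character_,
           n_edges = lengths(.data$supporting_edges)) |>
    distinct(.data$replicon, .data$pos, .data$type, .data$length,
             .keep_all = TRUE)
  out$variant_id <- variant_id_of(out$replicon, out$pos, out$type)
  out <- out[!duplicated(out$variant_id), , drop = FALSE]
  sup <- out$supporting_edges; ne <- out$n_edges
  out <- complete_variants(out)
  out$supporting_edges <- sup
  out$n_edges <- ne
  arrange(out, .data$replicon, .data$pos)
}

#' Call deletions from coverage dropouts
#'
#' Maximal runs of at least `r_min` bases where depth is at most
#' `eps * median(replicon depth)` become deletion calls with
#' `method = "coverage"`; breakpoint uncertainty equals the run boundaries.
#' A replicon whose median depth is 0 yields no calls and a warning (failed
#' sample).
#'
#' @param coverage coverage tibble from [coverage_profile()].
#' @param reference a [ref_genome].
#' @param eps depth threshold as a fraction of the replicon median.
#' @param r_min minimum run length in bp.
#' @return variant tibble of coverage deletions.
#' @export
call_coverage_deletions <- function(coverage, reference, eps = 0.1,
                                    r_min = 100) {
  calls <- list()
  for (r in unique(coverage$replicon)) {
    depth <- coverage$depth[coverage$replicon == r]
    med <- median(depth)
    if (med == 0) {
      warn(sprintf("replicon %s has median depth 0; no coverage calls", r))
      next
    }
    low <- depth <= eps * med
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= r_min)
    for (h in hit) {
      calls[[length(calls) + 1L]] <- tibble(
        replicon = r, pos = starts[h] - 1L, type = "deletion",
        length = rl$lengths[h], method = "coverage",
        multiplacement = FALSE)
    }
  }
  if (length(calls) == 0) return(empty_variants())
  out <- complete_variants(bind_rows(calls))
  ## keep coverage calls distinct from assembly calls at the same locus;
  ## deduplication is deliberately left to the query layer (METHOD key)
  out$variant_id <- paste0(out$variant_id, ":cov")
  out
}

#' Export contigs and their reference junctions
#'
#' Writes the contig sequences as FASTA and a tab-separated junction table
#' (contig id, contig interval, reference locus, strand, element label).
#'
#' @param graph a `placement_graph`.
#' @param fasta_path output FASTA path.
#' @param junctions_path output TSV path.
#' @return tibble of junction rows, invisibly.
#' @export
export_contigs <- function(graph, fasta_path, junctions_path) {
  ctg <- graph$contigs
  ss <- Biostrings::DNAStringSet(setNames(as.character(ctg$sequence),
                                          ctg$contig_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70)
  jt <- graph$edges |>
    mutate(locus = sprintf("%s:%d-%d", .data$replicon, .data$r_start,
                           .data$r_end)) |>
    select("contig_id", "c_start", "c_end", "locus", "strand", "element")
  readr::write_tsv(jt, junctions_path, na = "")
  invisible(jt)
}
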
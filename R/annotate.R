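#' Predict variant effects from genome annotations
#'
#' A feature-based effect annotator: each variant is intersected with the
#' reference's CDS features and translated through the standard (bacterial)
#' genetic code, strand-aware. Effects and impact classes follow the usual
#' four-level convention:
#' \itemize{
#'   \item `nonsense`, `frameshift`, `element_insertion_upstream` — HIGH
#'   \item `missense`, `disruptive_inframe` — MODERATE
#'   \item `synonymous` — LOW
#'   \item `upstream`, `intergenic` — MODIFIER
#' }
#' A variant within `u_up` bp upstream of a CDS start is `upstream`; a
#' mobile-element insertion there is `element_insertion_upstream` (HIGH).
#' When several genes are hit, the most severe effect is reported and the
#' rest are listed in `eff_others`.
#'
#' @param variants variant tibble.
#' @param reference a [ref_genome] with features.
#' @param u_up upstream window in bp.
#' @return the variant tibble with `eff_gene`, `eff_effect`, `eff_impact`,
#'   `eff_aa`, `eff_others` columns added.
#' @export
annotate_variants <- function(variants, reference, u_up = 200) {
  variants <- as_tibble(variants)
  n <- nrow(variants)
  eff <- tibble(eff_gene = rep(NA_character_, n),
                eff_effect = rep("intergenic", n),
                eff_impact = rep("MODIFIER", n),
                eff_aa = rep(NA_character_, n),
                eff_others = rep(NA_character_, n))
  if (n == 0) return(bind_cols(variants, eff))
  cds <- reference$features[reference$features$kind == "CDS", , drop = FALSE]
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (!v$replicon %in% names(reference$sequence)) {
      abort(sprintf("variant %s is on unknown replicon %s", v$variant_id,
                    v$replicon),
            class = "strainforge_consistency_error")
    }
    w <- switch(v$type, snv = 1L, deletion = v$length, 0L)
    hits <- list()
    for (j in seq_len(nrow(cds))) {
      ft <- cds[j, ]
      if (ft$replicon != v$replicon) next
      inside <- if (w > 0L) ft$start < v$pos + w && v$pos < ft$end
                else ft$start < v$pos && v$pos < ft$end
      upstream <- if (ft$strand == "+") {
        v$pos + max(w, 1L) > ft$start - u_up && v$pos + w <= ft$start
      } else {
        v$pos >= ft$end && v$pos < ft$end + u_up
      }
      if (inside) {
        hits[[length(hits) + 1L]] <- cds_effect(v, ft, reference)
      } else if (upstream) {
        hits[[length(hits) + 1L]] <- tibble(
          gene = ft$gene,
          effect = if (v$type == "mobile_element_insertion")
            "element_insertion_upstream" else "upstream",
          aa = NA_character_)
      }
    }
    if (length(hits)) {
      h <- bind_rows(hits)
      h$impact <- effect_impact(h$effect)
      sev <- match(h$impact, c("HIGH", "MODERATE", "LOW", "MODIFIER"))
      h <- h[order(sev), , drop = FALSE]
      eff$eff_gene[i] <- h$gene[1]
      eff$eff_effect[i] <- h$effect[1]
      eff$eff_impact[i] <- h$impact[1]
      eff$eff_aa[i] <- h$aa[1]
      if (nrow(h) > 1) {
        eff$eff_others[i] <- paste(sprintf("%s:%s", h$gene[-1],
                                           h$effect[-1]), collapse = ";")
      }
    }
  }
  bind_cols(variants, eff)
}

effect_impact <- function(effect) {
  dplyr::case_when(
    effect %in% c("nonsense", "frameshift",
                  "element_insertion_upstream") ~ "HIGH",
    effect %in% c("missense", "disruptive_inframe") ~ "MODERATE",
    effect == "synonymous" ~ "LOW",
    TRUE ~ "MODIFIER")
}

cds_effect <- function(v, ft, reference) {
  if (v$type == "snv") {
    seq <- reference$sequence[[v$replicon]]
    cds_seq <- subseq0(seq, ft$start, ft$end)
    if (ft$strand == "-") cds_seq <- revcomp(cds_seq)
    pos_in <- if (ft$strand == "+") v$pos - ft$start
              else ft$end - 1L - v$pos
    alt_in <- if (ft$strand == "+") v$alt else revcomp(v$alt)
    ci <- pos_in %/% 3L
    within <- pos_in %% 3L
    codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_in
    aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
    aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
    if (is.na(aa_ref) || is.na(aa_alt)) {
      return(tibble(gene = ft$gene, effect = "missense",
                    aa = NA_character_))
    }
    effect <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"
    tibble(gene = ft$gene, effect = effect,
           aa = sprintf("%s%d%s", aa_ref, ci + 1L, aa_alt))
  } else {
    delta <- if (v$type == "deletion") {
      min(v$pos + v$length, ft$end) - max(v$pos, ft$start)
    } else {
      v$length
    }
    effect <- if (delta %% 3L == 0L) "disruptive_inframe" else "frameshift"
    tibble(gene = ft$gene, effect = effect, aa = NA_character_)
  }
}
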
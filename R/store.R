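#' Build the denormalized variant-by-sample evidence table
#'
#' The melted evidence model: one row per (variant, sample) pair, carrying
#' the variant's site and annotation columns (uppercase query keys, VCF INFO
#' keys under an `INFO_` prefix), the sample's genotype evidence (`GT_TYPE`,
#' `GQ`, `DP`, `AF`, `MAPQ`), sample metadata columns, and a
#' `replicon:start-end` locus string for external genome browsers. Samples
#' lacking a call at a variant get `GT_TYPE = 0` with `DP = 0`. The table
#' carries a content hash attribute so rebuilds on unchanged inputs are
#' byte-identical and detectable.
#'
#' @param variants variant tibble (annotated or not).
#' @param calls per-sample call tibble (`variant_id`, `sample_id`, `gt`,
#'   `gt_type`, `gq`, `dp`, `af`, optionally `mean_mapq`).
#' @param samples sample manifest tibble with `sample_id` and optional
#'   metadata columns.
#' @return evidence tibble, one row per variant-sample pair.
#' @export
build_evidence_table <- function(variants, calls, samples) {
  variants <- as_tibble(variants)
  calls <- as_tibble(calls)
  samples <- as_tibble(samples)
  stopifnot("sample_id" %in% names(samples))
  if (nrow(calls)) {
    orphan_v <- setdiff(unique(calls$variant_id), variants$variant_id)
    orphan_s <- setdiff(unique(calls$sample_id), samples$sample_id)
    if (length(orphan_v) || length(orphan_s)) {
      abort(sprintf(
        "calls reference unknown variants (%s) or samples (%s)",
        paste(orphan_v, collapse = ","), paste(orphan_s, collapse = ",")),
        class = "strainforge_consistency_error")
    }
  }
  vcols <- tibble(
    UID = variants$variant_id,
    CHROM = variants$replicon,
    POSITION = variants$pos + 1L,   # displayed 1-based, like VCF
    REF = variants$ref,
    ALT = ifelse(variants$type == "snv", variants$alt,
                 toupper(sub("_", "", paste0("<", c(
                   deletion = "DEL", novel_insertion = "INS",
                   mobile_element_insertion = "MEI",
                   snv = "SNV")[variants$type], ">")))),
    INFO_SVTYPE = ifelse(variants$type == "snv", NA_character_,
                         c(deletion = "DEL", novel_insertion = "INS",
                           mobile_element_insertion = "MEI")[variants$type]),
    INFO_SVLEN = ifelse(variants$type == "snv", NA_integer_,
                        ifelse(variants$type == "deletion",
                               -variants$length, variants$length)),
    INFO_METHOD = variants$method,
    INFO_ELEMENT = variants$element_label,
    LOCUS = sprintf("%s:%d-%d", variants$replicon, variants$pos,
                    variants$pos + pmax(variants$length, 1L)))
  for (k in c("eff_gene", "eff_effect", "eff_impact", "eff_aa")) {
    vcols[[paste0("INFO_", toupper(k))]] <-
      if (k %in% names(variants)) variants[[k]] else NA_character_
  }
  if (nrow(vcols) == 0) {
    out <- bind_cols(vcols,
                     tibble(SAMPLE_ID = character(0), GT = character(0),
                            GT_TYPE = integer(0), GQ = numeric(0),
                            DP = integer(0), AF = numeric(0),
                            MAPQ = numeric(0)))
    meta <- samples[0, setdiff(names(samples), "sample_id"), drop = FALSE]
    names(meta) <- toupper(names(meta))
    out <- bind_cols(out, meta)
    attr(out, "content_hash") <- rlang::hash(list(variants, calls, samples))
    return(out)
  }
  grid <- tidyr::crossing(UID = vcols$UID, SAMPLE_ID = samples$sample_id)
  if (!"mean_mapq" %in% names(calls)) calls$mean_mapq <- NA_real_
  ev <- calls |>
    select(UID = "variant_id", SAMPLE_ID = "sample_id", GT = "gt",
           GT_TYPE = "gt_type", GQ = "gq", DP = "dp", AF = "af",
           MAPQ = "mean_mapq")
  out <- grid |>
    left_join(vcols, by = "UID") |>
    left_join(ev, by = c("UID", "SAMPLE_ID")) |>
    mutate(GT = dplyr::coalesce(.data$GT, "./."),
           GT_TYPE = dplyr::coalesce(.data$GT_TYPE, 0L),
           DP = dplyr::coalesce(.data$DP, 0L))
  meta <- samples
  names(meta) <- toupper(names(meta))
  out <- left_join(out, meta, by = "SAMPLE_ID")
  out <- arrange(out, .data$CHROM, .data$POSITION, .data$SAMPLE_ID)
  col_order <- c("UID", "CHROM", "POSITION", "REF", "ALT", "SAMPLE_ID",
                 "GT", "GT_TYPE", "GQ", "DP", "AF", "MAPQ")
  out <- out[, c(col_order, setdiff(names(out), col_order)), drop = FALSE]
  attr(out, "content_hash") <- rlang::hash(list(variants, calls, samples))
  out
}

#' Export an evidence table (or query result) to CSV
#'
#' @param rows evidence tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_evidence_csv <- function(rows, path) {
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' Read an evidence CSV back
#'
#' @param path CSV path written by [export_evidence_csv()].
#' @return evidence tibble.
#' @export
read_evidence_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "",
                  progress = FALSE)
}

#' Assign the default triage variant sets
#'
#' Reproduces the standard per-sample triage sets: `no_coverage`
#' (`DP = 0`), `insufficient_coverage` (`DP < alpha *` sample median depth),
#' `high_coverage` (`DP > beta *` sample median depth, e.g. duplicated
#' regions), and `poor_mapping` (mean `MAPQ < m_min`, e.g. non-unique
#' regions).
#'
#' @param table evidence tibble from [build_evidence_table()].
#' @param coverage_stats tibble with `sample_id`, `median_depth`.
#' @param alpha,beta,m_min thresholds.
#' @return tibble of set memberships: `name`, `variant_id`, `sample_id`,
#'   `provenance`.
#' @export
assign_default_sets <- function(table, coverage_stats, alpha = 0.3,
                                beta = 2.5, m_min = 20) {
  cs <- coverage_stats
  names(cs) <- tolower(names(cs))
  t2 <- left_join(table, rename(cs, SAMPLE_ID = "sample_id"),
                  by = "SAMPLE_ID")
  mk <- function(mask, nm) {
    rows <- t2[which(mask), , drop = FALSE]
    tibble(name = nm, variant_id = rows$UID, sample_id = rows$SAMPLE_ID,
           provenance = "default")
  }
  bind_rows(
    mk(t2$DP == 0L, "no_coverage"),
    mk(t2$DP > 0L & t2$DP < alpha * t2$median_depth,
       "insufficient_coverage"),
    mk(t2$DP > beta * t2$median_depth, "high_coverage"),
    mk(!is.na(t2$MAPQ) & t2$MAPQ < m_min, "poor_mapping"))
}

#' Create a named variant set from a query
#'
#' @param table evidence tibble.
#' @param query query text (see [parse_query()]).
#' @param name set name.
#' @return set-membership tibble (`name`, `variant_id`, `sample_id`,
#'   `provenance = "user"`).
#' @export
create_variant_set <- function(table, query, name) {
  rows <- evaluate_query(table, query, view = "melted")
  tibble(name = name, variant_id = rows$UID, sample_id = rows$SAMPLE_ID,
         provenance = "user")
}
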
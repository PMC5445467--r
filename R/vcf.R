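#' Empty variant table
#'
#' The variant tibble is the package's common currency: one row per variant
#' site, 0-based `pos`, `type` in
#' `{snv, deletion, novel_insertion, mobile_element_insertion}`. For SVs,
#' `length` is the affected span and `inserted_sequence` / `element_label`
#' are populated where applicable; `method` records the calling route
#' (`pileup`, `assembly`, `coverage`, `truth`).
#'
#' @return zero-row tibble with the variant schema.
#' @export
empty_variants <- function() {
  tibble(variant_id = character(0), replicon = character(0),
         pos = integer(0), type = character(0),
         ref = character(0), alt = character(0), length = integer(0),
         inserted_sequence = character(0), element_label = character(0),
         method = character(0), multiplacement = logical(0))
}

variant_id_of <- function(replicon, pos, type, alt = NULL) {
  short <- c(snv = "SNV", deletion = "DEL", novel_insertion = "INS",
             mobile_element_insertion = "MEI")[type]
  id <- paste0(replicon, ":", pos, ":", short)
  if (!is.null(alt)) {
    is_snv <- rep_len(type == "snv", length(id))
    altv <- rep_len(alt, length(id))
    id[is_snv] <- paste0(id[is_snv], ":", altv[is_snv])
  }
  id
}

complete_variants <- function(v) {
  defaults <- empty_variants()
  for (col in names(defaults)) {
    if (!col %in% names(v)) {
      v[[col]] <- if (nrow(v)) rep(defaults[[col]][NA_integer_][1], nrow(v)) else defaults[[col]]
    }
  }
  if (nrow(v) && any(is.na(v$variant_id))) {
    idx <- is.na(v$variant_id)
    v$variant_id[idx] <- variant_id_of(v$replicon[idx], v$pos[idx],
                                       v$type[idx], v$alt[idx])
  }
  v[names(defaults)]
}

## VCF alleles (1-based POS, anchor-base convention for indels)
vcf_alleles <- function(v, reference) {
  seq <- reference$sequence[[v$replicon]]
  if (v$type == "snv") {
    list(pos1 = v$pos + 1L, ref = v$ref, alt = v$alt)
  } else if (v$type == "deletion") {
    if (v$pos > 0L) {
      anchor <- subseq0(seq, v$pos - 1L, v$pos)
      list(pos1 = v$pos,
           ref = paste0(anchor, subseq0(seq, v$pos, v$pos + v$length)),
           alt = anchor)
    } else {
      anchor <- subseq0(seq, v$length, v$length + 1L)
      list(pos1 = 1L,
           ref = paste0(subseq0(seq, 0L, v$length), anchor), alt = anchor)
    }
  } else { # insertions (novel or mobile element) before 0-based pos
    anchor <- if (v$pos > 0L) subseq0(seq, v$pos - 1L, v$pos)
              else subseq0(seq, 0L, 1L)
    ins <- v$inserted_sequence %||% ""
    if (v$pos > 0L) {
      list(pos1 = v$pos, ref = anchor, alt = paste0(anchor, ins))
    } else {
      list(pos1 = 1L, ref = anchor, alt = paste0(ins, anchor))
    }
  }
}

vcf_info_string <- function(v) {
  kv <- character(0)
  if (v$type != "snv") {
    svtype <- c(deletion = "DEL", novel_insertion = "INS",
                mobile_element_insertion = "MEI")[v$type]
    svlen <- if (v$type == "deletion") -v$length else v$length
    kv <- c(kv, paste0("SVTYPE=", svtype), paste0("SVLEN=", svlen))
  }
  if (!is.na(v$method %||% NA)) kv <- c(kv, paste0("METHOD=", v$method))
  if (!is.na(v$element_label %||% NA))
    kv <- c(kv, paste0("ELEMENT=", v$element_label))
  for (k in c("EFF_GENE", "EFF_EFFECT", "EFF_IMPACT", "EFF_AA")) {
    col <- tolower(k)
    if (!is.null(v[[col]]) && !is.na(v[[col]]) && nzchar(v[[col]]))
      kv <- c(kv, paste0(k, "=", v[[col]]))
  }
  if (length(kv) == 0) "." else paste(kv, collapse = ";")
}

#' Write variants and per-sample evidence to VCF 4.2
#'
#' One record per variant site (multiallelic sites are split upstream).
#' Indels use the standard left-anchor-base convention; per-sample columns
#' carry `GT`, `GT_TYPE` (0 wild-type / 1 marginal / 2 mutant), `GQ`, `DP`
#' and `AF`. The REF allele is checked against the reference sequence.
#'
#' @param variants variant tibble (see [empty_variants()]).
#' @param evidence per-sample call tibble with columns `variant_id`,
#'   `sample_id`, `gt`, `gt_type`, `gq`, `dp`, `af`; may be empty.
#' @param path output path.
#' @param reference the [ref_genome] the variants were called against.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, evidence, path, reference) {
  variants <- complete_variants(as_tibble(variants))
  evidence <- as_tibble(evidence)
  samples <- if ("sample_id" %in% names(evidence)) {
    sort(unique(evidence$sample_id))
  } else {
    character(0)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", reference$name),
    sprintf("##contig=<ID=%s,length=%d>", names(reference$sequence),
            nchar(reference$sequence)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed SV length">',
    '##INFO=<ID=METHOD,Number=1,Type=String,Description="Calling method">',
    '##INFO=<ID=ELEMENT,Number=1,Type=String,Description="Mobile element label">',
    '##INFO=<ID=EFF_GENE,Number=1,Type=String,Description="Affected gene">',
    '##INFO=<ID=EFF_EFFECT,Number=1,Type=String,Description="Predicted effect">',
    '##INFO=<ID=EFF_IMPACT,Number=1,Type=String,Description="Predicted impact">',
    '##INFO=<ID=EFF_AA,Number=1,Type=String,Description="Amino acid change">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GT_TYPE,Number=1,Type=Integer,Description="0 wild-type, 1 marginal, 2 mutant">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  rows <- character(0)
  if (nrow(variants)) {
    variants <- arrange(variants, .data$replicon, .data$pos)
    for (i in seq_len(nrow(variants))) {
      v <- as.list(variants[i, ])
      al <- vcf_alleles(v, reference)
      ref_here <- subseq0(reference$sequence[[v$replicon]],
                          al$pos1 - 1L, al$pos1 - 1L + nchar(al$ref))
      if (!identical(ref_here, al$ref)) {
        abort(sprintf(
          "variant %s: REF allele '%s' does not match reference ('%s') at POS %d",
          v$variant_id, al$ref, ref_here, al$pos1),
          class = "strainforge_consistency_error")
      }
      fields <- c(v$replicon, al$pos1, v$variant_id, al$ref, al$alt, ".",
                  "PASS", vcf_info_string(v))
      if (length(samples)) {
        ev <- evidence[evidence$variant_id == v$variant_id, , drop = FALSE]
        cols <- vapply(samples, function(s) {
          e <- ev[ev$sample_id == s, , drop = FALSE]
          if (nrow(e) == 0) return("./.:.:.:0:.")
          sprintf("%s:%d:%d:%d:%.4f", e$gt[1], e$gt_type[1],
                  as.integer(round(e$gq[1])), e$dp[1], e$af[1])
        }, character(1))
        fields <- c(fields, "GT:GT_TYPE:GQ:DP:AF", cols)
      }
      rows <- c(rows, paste(fields, collapse = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF written by this package
#'
#' Reconstructs the variant tibble (0-based positions, SV types from
#' `SVTYPE`) and the per-sample evidence tibble from `GT`, `GT_TYPE`, `GQ`,
#' `DP`, `AF` columns.
#'
#' @param path VCF path.
#' @return list with elements `variants` and `evidence`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  chrom_line <- grep("^#CHROM", lines)
  if (length(chrom_line) == 0) {
    abort("no #CHROM header line found", class = "strainforge_parse_error")
  }
  hdr <- strsplit(lines[chrom_line], "\t")[[1]]
  samples <- if (length(hdr) > 9) hdr[-(1:9)] else character(0)
  body <- lines[-seq_len(chrom_line)]
  body <- body[nzchar(body)]
  vars <- list(); evs <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    info <- strsplit(f[8], ";")[[1]]
    ival <- function(k) {
      hit <- grep(paste0("^", k, "="), info, value = TRUE)
      if (length(hit)) sub(paste0("^", k, "="), "", hit[1]) else NA_character_
    }
    pos1 <- as.integer(f[2]); ref <- f[4]; alt <- f[5]
    svtype <- ival("SVTYPE")
    if (is.na(svtype)) {
      type <- "snv"; pos <- pos1 - 1L; length_ <- 1L
      vref <- ref; valt <- alt; ins <- NA_character_
    } else if (svtype == "DEL") {
      type <- "deletion"; pos <- pos1; length_ <- abs(as.integer(ival("SVLEN")))
      vref <- NA_character_; valt <- NA_character_; ins <- NA_character_
    } else {
      type <- if (svtype == "MEI") "mobile_element_insertion" else "novel_insertion"
      pos <- pos1; length_ <- as.integer(ival("SVLEN"))
      vref <- NA_character_; valt <- NA_character_
      ins <- substr(alt, 2L, nchar(alt))
    }
    vars[[length(vars) + 1L]] <- tibble(
      variant_id = f[3], replicon = f[1], pos = pos, type = type,
      ref = vref, alt = valt, length = length_,
      inserted_sequence = ins, element_label = ival("ELEMENT"),
      method = ival("METHOD"), multiplacement = NA,
      eff_gene = ival("EFF_GENE"), eff_effect = ival("EFF_EFFECT"),
      eff_impact = ival("EFF_IMPACT"), eff_aa = ival("EFF_AA"))
    if (length(samples)) {
      for (si in seq_along(samples)) {
        sf <- strsplit(f[9 + si], ":")[[1]]
        if (sf[1] == "./.") next
        evs[[length(evs) + 1L]] <- tibble(
          variant_id = f[3], sample_id = samples[si], gt = sf[1],
          gt_type = as.integer(sf[2]), gq = as.numeric(sf[3]),
          dp = as.integer(sf[4]), af = as.numeric(sf[5]))
      }
    }
  }
  list(variants = bind_rows(vars) %||% empty_variants(),
       evidence = bind_rows(evs))
}
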
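#' Apply a variant set to a reference genome
#'
#' Produces a new versioned [ref_genome] in which every variant in the set is
#' the reference allele: SNVs substituted, deletions removed, insertions
#' (novel sequence or mobile element) added. Variants are applied
#' right-to-left per replicon so earlier applications never shift later
#' coordinates. Features are lifted through the edit: shifted by the
#' cumulative indel offset, truncated at deletion edges (flagged with a
#' `note`), or dropped when fully deleted; an applied mobile-element
#' insertion adds a new `mobile_element` feature at the insertion site. The
#' returned lift map records, per replicon, the ordered `(old interval,
#' offset)` blocks tiling the old genome.
#'
#' @param reference a [ref_genome].
#' @param variants variant tibble (rows with `type`, `pos`, and `ref`/`alt`
#'   or `length`/`inserted_sequence` as appropriate).
#' @param name name for the new genome version; default bumps a `_v<k>`
#'   suffix on the parent's name.
#' @return list with elements `genome` (the new [ref_genome]) and `liftmap`
#'   (a tibble of blocks with columns `replicon`, `old_start`, `old_end`,
#'   `offset`, `deleted`).
#' @export
apply_variant_set <- function(reference, variants, name = NULL) {
  variants <- complete_variants(as_tibble(variants))
  name <- name %||% bump_version_name(reference$name)
  if (nrow(variants) == 0) {
    g <- reference
    g$name <- name
    g$version_parent <- reference$name
    g$applied_variants <- character(0)
    return(list(genome = g, liftmap = identity_liftmap(reference)))
  }
  bad_rep <- setdiff(unique(variants$replicon), names(reference$sequence))
  if (length(bad_rep)) {
    abort(sprintf("variants name unknown replicon(s): %s",
                  paste(bad_rep, collapse = ", ")),
          class = "strainforge_consistency_error")
  }
  variants$.w <- ifelse(variants$type == "snv", 1L,
                        ifelse(variants$type == "deletion",
                               variants$length, 0L))
  ## overlap check per replicon
  conflicts <- character(0)
  for (r in unique(variants$replicon)) {
    vr <- arrange(variants[variants$replicon == r, ], .data$pos)
    if (nrow(vr) > 1) {
      for (i in seq_len(nrow(vr) - 1L)) {
        overl <- vr$pos[i + 1L] < vr$pos[i] + vr$.w[i] ||
          (vr$pos[i + 1L] == vr$pos[i] && vr$.w[i] == 0L && vr$.w[i + 1L] == 0L)
        if (overl) {
          conflicts <- c(conflicts, sprintf("(%s, %s)", vr$variant_id[i],
                                            vr$variant_id[i + 1L]))
        }
      }
    }
  }
  if (length(conflicts)) {
    abort(paste0("overlapping variants cannot be applied together: ",
                 paste(conflicts, collapse = "; ")),
          class = "strainforge_conflict_error")
  }
  seqs <- reference$sequence
  lift_blocks <- list()
  new_feats <- list()
  for (r in names(seqs)) {
    vr <- arrange(variants[variants$replicon == r, ], .data$pos)
    seq <- seqs[[r]]
    L <- nchar(seq)
    if (nrow(vr) && (min(vr$pos) < 0L || max(vr$pos + vr$.w) > L)) {
      abort(sprintf("variant position outside replicon %s", r),
            class = "strainforge_consistency_error")
    }
    ## REF checks before any modification
    for (i in seq_len(nrow(vr))) {
      if (vr$type[i] == "snv") {
        here <- subseq0(seq, vr$pos[i], vr$pos[i] + 1L)
        if (!is.na(vr$ref[i]) && here != vr$ref[i]) {
          abort(sprintf("variant %s: REF '%s' does not match reference '%s'",
                        vr$variant_id[i], vr$ref[i], here),
                class = "strainforge_consistency_error")
        }
      }
    }
    ## apply right-to-left
    if (nrow(vr)) {
      for (i in rev(seq_len(nrow(vr)))) {
        p <- vr$pos[i]
        seq <- switch(vr$type[i],
          snv = splice0(seq, p, p + 1L, vr$alt[i]),
          deletion = splice0(seq, p, p + vr$length[i], ""),
          splice0(seq, p, p, vr$inserted_sequence[i]))
      }
    }
    seqs[[r]] <- seq
    ## lift map blocks, ascending
    cur <- 0L; off <- 0L
    add_block <- function(s, e, o, del) {
      if (e > s) lift_blocks[[length(lift_blocks) + 1L]] <<-
          tibble(replicon = r, old_start = s, old_end = e,
                 offset = o, deleted = del)
    }
    for (i in seq_len(nrow(vr))) {
      p <- vr$pos[i]
      if (vr$type[i] == "deletion") {
        add_block(cur, p, off, FALSE)
        add_block(p, p + vr$length[i], NA_integer_, TRUE)
        cur <- p + vr$length[i]
        off <- off - vr$length[i]
      } else if (vr$type[i] %in% c("novel_insertion",
                                   "mobile_element_insertion")) {
        add_block(cur, p, off, FALSE)
        cur <- p
        off <- off + nchar(vr$inserted_sequence[i])
        if (vr$type[i] == "mobile_element_insertion") {
          ins_len <- nchar(vr$inserted_sequence[i])
          new_feats[[length(new_feats) + 1L]] <- tibble(
            replicon = r, start = as.integer(p + off - ins_len),
            end = as.integer(p + off), strand = "+",
            kind = "mobile_element", gene = vr$element_label[i],
            product = "insertion sequence")
        }
      }
    }
    add_block(cur, L, off, FALSE)
  }
  liftmap <- bind_rows(lift_blocks)
  if (nrow(liftmap) == 0) liftmap <- identity_liftmap(reference)
  ## lift features
  lifted <- lift_features(reference$features, liftmap)
  feats <- bind_rows(lifted, bind_rows(new_feats))
  g <- ref_genome(name = name, sequence = seqs, features = feats,
                  version_parent = reference$name,
                  applied_variants = variants$variant_id)
  list(genome = g, liftmap = liftmap)
}

identity_liftmap <- function(reference) {
  tibble(replicon = names(reference$sequence), old_start = 0L,
         old_end = nchar(reference$sequence), offset = 0L, deleted = FALSE)
}

bump_version_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)_v(\\d+)$", name))[[1]]
  if (length(m) == 3) {
    sprintf("%s_v%d", m[2], as.integer(m[3]) + 1L)
  } else {
    paste0(name, "_v2")
  }
}

#' Lift a position through a lift map
#'
#' @param liftmap lift map tibble from [apply_variant_set()].
#' @param replicon replicon name.
#' @param pos 0-based position(s) on the old genome.
#' @return integer vector of new 0-based positions; positions falling in a
#'   deleted interval map to the deletion point on the new genome.
#' @export
lift_position <- function(liftmap, replicon, pos) {
  lm <- liftmap[liftmap$replicon == replicon, , drop = FALSE]
  vapply(pos, function(p) {
    b <- which(lm$old_start <= p & p < lm$old_end)
    if (length(b) == 0) {
      b_end <- which(lm$old_end == p)
      if (length(b_end)) {
        bb <- b_end[!lm$deleted[b_end]]
        if (length(bb)) return(p + lm$offset[bb[1]])
      }
      return(NA_integer_)
    }
    b <- b[1]
    if (lm$deleted[b]) {
      ## collapse onto the deletion point
      after <- which(lm$old_start >= lm$old_end[b] & !lm$deleted)
      if (length(after)) lm$old_end[b] + lm$offset[after[1]] else NA_integer_
    } else {
      p + lm$offset[b]
    }
  }, integer(1))
}

lift_features <- function(features, liftmap) {
  if (nrow(features) == 0) return(features)
  out <- list()
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    lm <- liftmap[liftmap$replicon == ft$replicon, , drop = FALSE]
    ov <- lm[lm$old_end > ft$start & lm$old_start < ft$end, , drop = FALSE]
    keep <- ov[!ov$deleted, , drop = FALSE]
    if (nrow(keep) == 0) next  # fully deleted -> dropped
    ns <- min(pmax(keep$old_start, ft$start) + keep$offset)
    ne <- max(pmin(keep$old_end, ft$end) + keep$offset)
    truncated <- any(ov$deleted)
    ft$start <- as.integer(ns)
    ft$end <- as.integer(ne)
    if (truncated) ft$note <- "truncated by versioning"
    out[[length(out) + 1L]] <- ft
  }
  bind_rows(out)
}

#' Write a lift map as TSV
#'
#' @param liftmap lift map tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_liftmap <- function(liftmap, path) {
  readr::write_tsv(liftmap, path)
  invisible(path)
}
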
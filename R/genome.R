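#' Reference genome objects
#'
#' A `ref_genome` bundles the replicon sequences of a (typically bacterial)
#' reference genome with its feature annotations and, for versioned genomes,
#' its derivation lineage. All coordinates inside the object are 0-based
#' half-open; conversion to the 1-based conventions of GenBank and VCF happens
#' only at the file boundary.
#'
#' @param name genome name (used as the version identifier).
#' @param sequence named character vector, one uppercase DNA string per
#'   replicon.
#' @param features tibble of features (see [empty_features()]), or `NULL`.
#' @param version_parent name of the genome this one was derived from, or
#'   `NA`.
#' @param applied_variants character vector of variant ids applied during
#'   derivation.
#' @return an object of class `ref_genome`.
#' @export
ref_genome <- function(name, sequence, features = NULL,
                       version_parent = NA_character_,
                       applied_variants = character(0)) {
  stopifnot(is.character(sequence), !is.null(names(sequence)))
  sequence <- toupper(sequence)
  assert_dna(sequence, "replicon sequence")
  features <- features %||% empty_features()
  features <- as_tibble(features)
  validate_features(features, sequence)
  structure(
    list(name = name, sequence = sequence, features = features,
         version_parent = version_parent,
         applied_variants = applied_variants),
    class = "ref_genome"
  )
}

#' Empty feature table
#'
#' Features use 0-based half-open `start`/`end`, `strand` in `{+,-}` and
#' `kind` in `{CDS, gene, mobile_element, other}`; `gene` and `product` carry
#' the corresponding GenBank qualifiers.
#'
#' @return a zero-row tibble with the feature schema.
#' @export
empty_features <- function() {
  tibble(replicon = character(0), start = integer(0), end = integer(0),
         strand = character(0), kind = character(0),
         gene = character(0), product = character(0))
}

validate_features <- function(features, sequence) {
  if (nrow(features) == 0) return(invisible(features))
  stopifnot(all(c("replicon", "start", "end", "strand", "kind") %in%
                  names(features)))
  lens <- nchar(sequence)[features$replicon]
  bad <- is.na(lens) | features$start < 0L | features$end > lens |
    features$start >= features$end
  if (any(bad)) {
    abort(sprintf("%d feature interval(s) fall outside their replicon",
                  sum(bad)),
          class = "strainforge_validation_error")
  }
  invisible(features)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s\n", x$name))
  for (r in names(x$sequence)) {
    cat(sprintf("  replicon %-12s %8d bp, %d feature(s)\n", r,
                nchar(x$sequence[[r]]),
                sum(x$features$replicon == r)))
  }
  if (!is.na(x$version_parent)) {
    cat(sprintf("  derived from %s via %d applied variant(s)\n",
                x$version_parent, length(x$applied_variants)))
  }
  invisible(x)
}

#' @export
tidy.ref_genome <- function(x, ...) x$features

#' @export
glance.ref_genome <- function(x, ...) {
  tibble(name = x$name, n_replicons = length(x$sequence),
         total_bp = sum(nchar(x$sequence)), n_features = nrow(x$features),
         version_parent = x$version_parent,
         n_applied_variants = length(x$applied_variants))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Read a reference genome from FASTA or GenBank
#'
#' FASTA carries no annotations, so the feature table is empty; GenBank
#' features are converted from 1-based inclusive to 0-based half-open
#' coordinates. Features with key `mobile_element`, or `repeat_region` whose
#' qualifiers mention "IS" or "insertion sequence", are classified
#' `kind = mobile_element`; `CDS` and `gene` keep their key; everything else
#' becomes `other`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return a [ref_genome].
#' @export
read_reference <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("reference file not found: %s", path),
          class = "strainforge_io_error")
  }
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) {
                     abort(sprintf("cannot parse FASTA %s: %s", path,
                                   conditionMessage(e)),
                           class = "strainforge_parse_error")
                   })
    seqs <- setNames(toupper(as.character(ss)),
                     sub("\\s.*$", "", names(ss)))
    assert_dna(seqs, "FASTA sequence")
    ref_genome(name = tools::file_path_sans_ext(basename(path)),
               sequence = seqs)
  } else {
    read_genbank(path)
  }
}

#' Write a reference genome
#'
#' @param genome a [ref_genome].
#' @param path output path.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(genome$sequence)
    Biostrings::writeXStringSet(ss, path, width = 70)
  } else {
    write_genbank(genome, path)
  }
  invisible(path)
}

## ---- GenBank flat file dialect -------------------------------------------
## Minimal reader/writer for the subset of the format this package emits:
## LOCUS / DEFINITION / COMMENT headers, a flat FEATURES table with
## `loc` or `complement(loc)` locations and quoted qualifiers, and ORIGIN
## sequence blocks. Multi-record files hold one replicon per record.

classify_feature_kind <- function(key, qualifiers) {
  if (key == "mobile_element") return("mobile_element")
  if (key == "repeat_region" &&
      grepl("\\bIS|insertion sequence", qualifiers, ignore.case = TRUE)) {
    return("mobile_element")
  }
  if (key %in% c("CDS", "gene")) return(key)
  "other"
}

read_genbank <- function(path) {
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) {
    abort(sprintf("no LOCUS record found in %s (line 1)", path),
          class = "strainforge_parse_error")
  }
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  seqs <- character(0)
  feats <- list()
  comment <- NA_character_
  for (ri in seq_along(rec_starts)) {
    rl <- lines[rec_starts[ri]:rec_ends[ri]]
    locus <- strsplit(trimws(rl[1]), "\\s+")[[1]]
    if (length(locus) < 2) {
      abort(sprintf("malformed LOCUS line at line %d", rec_starts[ri]),
            class = "strainforge_parse_error")
    }
    replicon <- locus[2]
    cm <- grep("^COMMENT", rl)
    if (length(cm)) comment <- trimws(sub("^COMMENT", "", rl[cm[1]]))
    fstart <- grep("^FEATURES", rl)
    ostart <- grep("^ORIGIN", rl)
    if (length(ostart) == 0) {
      abort(sprintf("record %s has no ORIGIN section (line %d)",
                    replicon, rec_starts[ri]),
            class = "strainforge_parse_error")
    }
    ## sequence
    seq_lines <- rl[(ostart[1] + 1L):length(rl)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    assert_dna(seq, sprintf("GenBank sequence for %s", replicon))
    seqs[replicon] <- seq
    ## features
    if (length(fstart)) {
      fl <- rl[(fstart[1] + 1L):(ostart[1] - 1L)]
      key_idx <- grep("^ {5}\\S", fl)
      for (j in seq_along(key_idx)) {
        block <- fl[key_idx[j]:(if (j < length(key_idx))
          key_idx[j + 1] - 1L else length(fl))]
        hdr <- strsplit(trimws(block[1]), "\\s+")[[1]]
        key <- hdr[1]
        loc <- hdr[2]
        if (key == "source") next
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        m <- regmatches(loc, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", loc))[[1]]
        if (length(m) != 3) {
          abort(sprintf("unsupported feature location '%s' near line %d",
                        loc, rec_starts[ri] + fstart[1] + key_idx[j] - 1L),
                class = "strainforge_parse_error")
        }
        quals <- paste(trimws(block[-1]), collapse = " ")
        qget <- function(q) {
          mm <- regmatches(quals,
                           regexec(sprintf('/%s="([^"]*)"', q), quals))[[1]]
          if (length(mm) == 2) mm[2] else NA_character_
        }
        feats[[length(feats) + 1L]] <- tibble(
          replicon = replicon,
          start = as.integer(m[2]) - 1L,   # 1-based inclusive -> 0-based
          end = as.integer(m[3]),
          strand = strand,
          kind = classify_feature_kind(key, quals),
          gene = qget("gene") %||% NA_character_,
          product = qget("product") %||% qget("mobile_element") %||%
            qget("note") %||% NA_character_
        )
      }
    }
  }
  g <- ref_genome(name = tools::file_path_sans_ext(basename(path)),
                  sequence = seqs, features = bind_rows(feats))
  if (!is.na(comment)) {
    pm <- regmatches(comment, regexec("derived from (\\S+)", comment))[[1]]
    if (length(pm) == 2) g$version_parent <- pm[2]
  }
  g
}

genbank_feature_key <- function(kind) {
  switch(kind, mobile_element = "mobile_element", CDS = "CDS",
         gene = "gene", "misc_feature")
}

write_genbank <- function(genome, path) {
  out <- character(0)
  for (r in names(genome$sequence)) {
    seq <- genome$sequence[[r]]
    out <- c(out, sprintf(
      "LOCUS       %s %d bp    DNA     linear   UNA %s",
      r, nchar(seq), format(Sys.Date(), "%d-%b-%Y")))
    out <- c(out, sprintf("DEFINITION  %s", genome$name))
    if (!is.na(genome$version_parent)) {
      out <- c(out, sprintf("COMMENT     derived from %s applying %d variant(s): %s",
                            genome$version_parent,
                            length(genome$applied_variants),
                            paste(genome$applied_variants, collapse = ",")))
    }
    out <- c(out, "FEATURES             Location/Qualifiers")
    out <- c(out, sprintf("     source          1..%d", nchar(seq)))
    fts <- genome$features[genome$features$replicon == r, , drop = FALSE]
    if (nrow(fts)) {
      for (i in seq_len(nrow(fts))) {
        loc <- sprintf("%d..%d", fts$start[i] + 1L, fts$end[i])
        if (fts$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        out <- c(out, sprintf("     %-16s%s", genbank_feature_key(fts$kind[i]), loc))
        if (!is.na(fts$gene[i]))
          out <- c(out, sprintf('                     /gene="%s"', fts$gene[i]))
        if (!is.na(fts$product[i])) {
          qk <- if (fts$kind[i] == "mobile_element") "mobile_element" else "product"
          out <- c(out, sprintf('                     /%s="%s"', qk, fts$product[i]))
        }
      }
    }
    out <- c(out, "ORIGIN")
    n <- nchar(seq)
    starts <- seq(1L, n, by = 60L)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59L, n))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", s, paste(tolower(blocks), collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}
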
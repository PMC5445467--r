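## Shared fixtures, computed once per test run and cached. All fixtures are
## generated in code from seeded simulations; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## 12 kb annotated genome with two identical IS copies
fix_genome <- function() {
  fixture("genome", sim_genome(12000, n_genes = 5, n_elements = 2,
                               seed = 42))
}

## mutant carrying one of each event class + reads at 30x
fix_mut <- function() {
  fixture("mut", sim_mutate(fix_genome(),
                            events = list(snv = 3, deletion = 800,
                                          novel_insertion = 300,
                                          element_move = 1),
                            seed = 42))
}

fix_reads <- function() {
  fixture("reads", sim_reads(fix_mut()$genome, depth = 30, seed = 42))
}

fix_result <- function() {
  fixture("result",
          call_sample_variants(fix_genome(), reads = fix_reads()$reads))
}

## tiny genome with a single known + and - strand CDS for annotation tests
annot_genome <- function() {
  fixture("annot_genome", {
    set.seed(9)
    bases <- c("A", "C", "G", "T")
    bg <- paste(sample(bases, 2000, replace = TRUE), collapse = "")
    ## + strand CDS at [300, 330): ATG GCT TGT CAA GAG AAA TGG CAT TAC TAA
    orf <- "ATGGCTTGTCAAGAGAAATGGCATTACTAA"
    seq <- paste0(substr(bg, 1, 300), orf, substr(bg, 331, 1200))
    ## - strand CDS at [600, 630): same ORF on the minus strand
    seq <- paste0(substr(seq, 1, 600), revcomp(orf),
                  substr(seq, 631, nchar(seq)))
    feats <- tibble::tibble(
      replicon = "chr",
      start = c(300L, 600L), end = c(330L, 630L),
      strand = c("+", "-"), kind = "CDS",
      gene = c("plusA", "minusB"), product = "test protein")
    ref_genome("annot_ref", c(chr = seq), feats)
  })
}

## random evidence table for query-language property tests
random_evidence_table <- function(n_var = 20, n_sample = 4, seed = 1) {
  set.seed(seed)
  tidyr::crossing(UID = sprintf("v%02d", seq_len(n_var)),
                  SAMPLE_ID = sprintf("s%d", seq_len(n_sample))) |>
    dplyr::mutate(
      CHROM = "chr",
      POSITION = as.integer(match(UID, sort(unique(UID))) * 37L),
      REF = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE),
      ALT = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE),
      GT_TYPE = sample(0:2, dplyr::n(), replace = TRUE),
      GQ = round(stats::runif(dplyr::n(), 0, 99)),
      DP = sample(0:60, dplyr::n(), replace = TRUE),
      AF = round(stats::runif(dplyr::n()), 3),
      INFO_EFF_IMPACT = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                               dplyr::n(), replace = TRUE))
}

## reference evaluator for the query language: scalar recursion over rows,
## structurally independent of the vectorised implementation
brute_force_filter <- function(table, ast) {
  eval_row <- function(node, row) {
    if (node$node == "and") {
      return(eval_row(node$left, row) && eval_row(node$right, row))
    }
    if (node$node == "or") {
      return(eval_row(node$left, row) || eval_row(node$right, row))
    }
    cname <- names(row)[match(toupper(node$key), toupper(names(row)))]
    x <- row[[cname]]
    if (is.numeric(x)) {
      v <- as.numeric(node$value)
      ok <- switch(node$op, "=" = x == v, "!=" = x != v, "<" = x < v,
                   "<=" = x <= v, ">" = x > v, ">=" = x >= v)
    } else {
      ok <- switch(node$op, "=" = x == node$value,
                   "!=" = x != node$value)
    }
    isTRUE(ok)
  }
  keep <- vapply(seq_len(nrow(table)),
                 function(i) eval_row(ast, as.list(table[i, ])),
                 logical(1))
  table[keep, , drop = FALSE]
}

## random query generator over a table's columns
random_query_text <- function(table) {
  num_keys <- c("GT_TYPE", "DP", "GQ", "AF", "POSITION")
  str_keys <- c("REF", "ALT", "INFO_EFF_IMPACT", "SAMPLE_ID")
  rand_cmp <- function() {
    if (stats::runif(1) < 0.6) {
      k <- sample(num_keys, 1)
      op <- sample(c("=", "!=", "<", "<=", ">", ">="), 1)
      v <- switch(k, GT_TYPE = sample(0:2, 1), DP = sample(0:60, 1),
                  GQ = sample(0:99, 1), AF = round(stats::runif(1), 2),
                  POSITION = sample(1:800, 1))
      sprintf("%s %s %s", k, op, v)
    } else {
      k <- sample(str_keys, 1)
      op <- sample(c("=", "!="), 1)
      v <- switch(k, REF = sample(c("A", "C", "G", "T"), 1),
                  ALT = sample(c("A", "C", "G", "T"), 1),
                  INFO_EFF_IMPACT = sample(c("HIGH", "MODERATE", "LOW",
                                             "MODIFIER"), 1),
                  SAMPLE_ID = sprintf("s%d", sample(1:4, 1)))
      sprintf("%s %s %s", k, op, v)
    }
  }
  build <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.4) return(rand_cmp())
    a <- build(depth - 1); b <- build(depth - 1)
    op <- sample(c("&", "|"), 1)
    if (stats::runif(1) < 0.5) sprintf("(%s %s %s)", a, op, b)
    else sprintf("%s %s %s", a, op, b)
  }
  build(sample(0:2, 1))
}
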
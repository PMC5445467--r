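#' Assemble candidate reads into contigs (de Bruijn graph)
#'
#' A compact de Bruijn assembler in the Velvet mould: k-mers from the reads
#' and their reverse complements are counted, low-coverage k-mers (sequencing
#' errors) removed, short dead-end tips clipped, and maximal non-branching
#' paths emitted as contigs. Contigs are reported in canonical orientation
#' (lexicographic minimum of the sequence and its reverse complement), so
#' the output is invariant to the strandedness of the input reads.
#'
#' @param reads tibble with `name`, `seq` (from [extract_candidates()]).
#' @param k odd k-mer size.
#' @param min_count minimum k-mer multiplicity (counting both strands).
#' @param l_min minimum contig length in bp.
#' @param tip_len maximum tip length, in nodes, to clip (default `2 * k`).
#' @return tibble with `contig_id`, `sequence`, `length`, `read_support`.
#' @export
assemble_contigs <- function(reads, k = 31, min_count = 3, l_min = 200,
                             tip_len = 2 * k) {
  stopifnot(k %% 2 == 1)
  empty <- tibble(contig_id = character(0), sequence = character(0),
                  length = integer(0), read_support = numeric(0))
  seqs <- reads$seq[nchar(reads$seq) >= k & !grepl("N", reads$seq)]
  if (length(seqs) == 0) return(empty)
  seqs <- c(seqs, revcomp(seqs))
  km <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    substring(s, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
  cnt <- table(km)
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0) return(empty)
  K <- names(cnt)
  counts <- as.integer(cnt)
  for (round in 1:2) {
    keep <- debruijn_clip_tips(K, k, tip_len)
    if (all(keep)) break
    K <- K[keep]; counts <- counts[keep]
    if (length(K) == 0) return(empty)
  }
  paths <- debruijn_unitigs(K, k)
  if (length(paths) == 0) return(empty)
  cnt_env <- new.env(hash = TRUE, size = length(K))
  for (i in seq_along(K)) assign(K[i], counts[i], envir = cnt_env)
  ctg <- tibble(
    sequence = vapply(paths, function(idx) {
      paste0(K[idx[1]], paste(substr(K[idx[-1]], k, k), collapse = ""))
    }, character(1)),
    read_support = vapply(paths, function(idx)
      mean(counts[idx]) / 2, numeric(1)))
  ctg <- ctg |>
    mutate(canon = pmin(.data$sequence, revcomp(.data$sequence))) |>
    group_by(.data$canon) |>
    summarise(sequence = .data$canon[1],
              read_support = max(.data$read_support), .groups = "drop") |>
    select(-"canon") |>
    mutate(length = nchar(.data$sequence)) |>
    filter(.data$length >= l_min, .data$read_support >= 2) |>
    arrange(dplyr::desc(.data$length), .data$sequence) |>
    mutate(contig_id = sprintf("ctg%03d", row_number())) |>
    select("contig_id", "sequence", "length", "read_support")
  ctg
}

debruijn_neighbors <- function(K, k) {
  pref <- substr(K, 1L, k - 1L)
  suf <- substr(K, 2L, k)
  pref_env <- list2env(split(seq_along(K), pref),
                       envir = new.env(hash = TRUE, size = length(K)))
  suf_env <- list2env(split(seq_along(K), suf),
                      envir = new.env(hash = TRUE, size = length(K)))
  succ <- function(i) get0(suf[i], envir = pref_env, inherits = FALSE)
  pred <- function(i) get0(pref[i], envir = suf_env, inherits = FALSE)
  list(succ = succ, pred = pred)
}

## returns logical keep-vector with short dead-end tips removed
debruijn_clip_tips <- function(K, k, tip_len) {
  nb <- debruijn_neighbors(K, k)
  n <- length(K)
  out_deg <- vapply(seq_len(n), function(i) length(nb$succ(i)), integer(1))
  in_deg <- vapply(seq_len(n), function(i) length(nb$pred(i)), integer(1))
  drop <- logical(n)
  walk_tip <- function(i, fwd) {
    chain <- i
    cur <- i
    repeat {
      nxt <- if (fwd) nb$succ(cur) else nb$pred(cur)
      if (length(nxt) != 1L) return(NULL)
      nxt_other <- if (fwd) in_deg[nxt] else out_deg[nxt]
      if (nxt_other > 1L) return(chain)  # reattaches at a branch: a tip
      chain <- c(chain, nxt)
      if (length(chain) > tip_len) return(NULL)
      cur <- nxt
    }
  }
  for (i in seq_len(n)) {
    if (in_deg[i] == 0L && out_deg[i] <= 1L) {
      ch <- walk_tip(i, fwd = TRUE)
      if (!is.null(ch) && length(ch) <= tip_len) drop[ch] <- TRUE
    } else if (out_deg[i] == 0L && in_deg[i] <= 1L) {
      ch <- walk_tip(i, fwd = FALSE)
      if (!is.null(ch) && length(ch) <= tip_len) drop[ch] <- TRUE
    }
  }
  !drop
}

## maximal non-branching paths as lists of node indices
debruijn_unitigs <- function(K, k) {
  nb <- debruijn_neighbors(K, k)
  n <- length(K)
  out_deg <- vapply(seq_len(n), function(i) length(nb$succ(i)), integer(1))
  in_deg <- vapply(seq_len(n), function(i) length(nb$pred(i)), integer(1))
  visited <- logical(n)
  paths <- list()
  is_start <- vapply(seq_len(n), function(i) {
    if (in_deg[i] != 1L) return(TRUE)
    p <- nb$pred(i)
    out_deg[p[1]] != 1L
  }, logical(1))
  for (i in which(is_start)) {
    if (visited[i]) next
    path <- i; visited[i] <- TRUE
    cur <- i
    repeat {
      nxt <- nb$succ(cur)
      if (length(nxt) != 1L) break
      nxt <- nxt[1]
      if (in_deg[nxt] != 1L || visited[nxt]) break
      path <- c(path, nxt); visited[nxt] <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- path
  }
  ## isolated cycles
  for (i in which(!visited)) {
    if (visited[i]) next
    path <- i; visited[i] <- TRUE
    cur <- i
    repeat {
      nxt <- nb$succ(cur)
      if (length(nxt) != 1L || visited[nxt[1]]) break
      path <- c(path, nxt[1]); visited[nxt[1]] <- TRUE
      cur <- nxt[1]
    }
    paths[[length(paths) + 1L]] <- path
  }
  paths
}
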
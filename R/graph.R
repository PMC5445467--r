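#' Align contigs to the reference and build the placement graph
#'
#' Each contig is aligned locally by exact k-mer anchoring: anchors shared
#' with the reference index vote for diagonals, anchors on one diagonal are
#' merged into a block, and block ends are extended base-by-base. Both
#' contig orientations are searched. The resulting placement graph has
#' contigs and reference fragments (replicons split at every junction point
#' observed across edges) as nodes and the local alignments as edges.
#' Edges falling inside an annotated `mobile_element` feature are labelled
#' with the element's name; a contig interval that aligns equally to several
#' identical element copies keeps one placement (smallest reference start)
#' and is flagged `multi`.
#'
#' @param contigs tibble from [assemble_contigs()].
#' @param reference a [ref_genome].
#' @param index optional prebuilt [seq_index()].
#' @param anchor_stride spacing of anchor k-mers along the contig.
#' @param min_edge minimum aligned block length to keep as an edge.
#' @return a `placement_graph` object.
#' @export
align_contigs <- function(contigs, reference, index = NULL,
                          anchor_stride = 10, min_edge = 30) {
  idx <- index %||% seq_index(reference)
  k <- idx$k
  edges <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$sequence[ci]
    len <- nchar(cseq)
    for (ori in c("+", "-")) {
      s <- if (ori == "+") cseq else revcomp(cseq)
      raw <- charToRaw(s)
      offs <- unique(c(seq(0L, len - k, by = anchor_stride), len - k))
      kmers <- substring(s, offs + 1L, offs + k)
      for (rep_ in idx$replicons) {
        hits <- lapply(seq_along(offs), function(j) {
          p <- get0(kmers[j], envir = rep_$env, inherits = FALSE)
          if (is.null(p)) NULL else cbind(pos = p, off = offs[j])
        })
        hits <- do.call(rbind, hits)
        if (is.null(hits)) next
        diag <- hits[, "pos"] - hits[, "off"]
        for (d in unique(diag)) {
          sel <- hits[diag == d, , drop = FALSE]
          q0 <- min(sel[, "off"])            # 0-based on oriented contig
          q1 <- max(sel[, "off"]) + k        # half-open end
          ## extend ends exactly
          while (q0 > 0L && d + q0 > 0L &&
                 raw[q0] == rep_$raw[d + q0]) q0 <- q0 - 1L
          while (q1 < len && d + q1 < rep_$len &&
                 raw[q1 + 1L] == rep_$raw[d + q1 + 1L]) q1 <- q1 + 1L
          if (q1 - q0 < min_edge) next
          ## convert oriented coords back to canonical contig forward
          if (ori == "+") {
            c_start <- q0; c_end <- q1
          } else {
            c_start <- len - q1; c_end <- len - q0
          }
          edges[[length(edges) + 1L]] <- tibble(
            contig_id = contigs$contig_id[ci], c_start = as.integer(c_start),
            c_end = as.integer(c_end), strand = ori,
            replicon = rep_$name, r_start = as.integer(d + q0),
            r_end = as.integer(d + q1), identity = 1.0)
        }
      }
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(contig_id = character(0), c_start = integer(0),
           c_end = integer(0), strand = character(0),
           replicon = character(0), r_start = integer(0),
           r_end = integer(0), identity = numeric(0))
  edges <- prune_edges(edges)
  edges <- label_element_edges(edges, reference$features)
  edges$edge_id <- seq_len(nrow(edges))
  nodes <- graph_nodes(edges, contigs, reference)
  structure(list(edges = edges, nodes = nodes, contigs = contigs,
                 reference_name = reference$name),
            class = "placement_graph")
}

## Per contig: drop strictly nested edges, collapse equal-span multi-
## placements to one flagged representative, and trim chain overlaps so
## edges abut on the contig.
prune_edges <- function(edges) {
  if (nrow(edges) == 0) {
    edges$multi <- logical(0)
    edges$n_placements <- integer(0)
    return(edges)
  }
  out <- list()
  for (cid in unique(edges$contig_id)) {
    e <- edges[edges$contig_id == cid, , drop = FALSE]
    ## collapse identical contig spans (multi-placement over repeats)
    e <- e |>
      group_by(.data$c_start, .data$c_end) |>
      arrange(.data$replicon, .data$r_start, .by_group = TRUE) |>
      mutate(n_placements = n()) |>
      dplyr::slice(1) |>
      ungroup() |>
      mutate(multi = .data$n_placements > 1L)
    ## drop strictly nested spans
    keep <- rep(TRUE, nrow(e))
    for (i in seq_len(nrow(e))) {
      for (j in seq_len(nrow(e))) {
        if (i != j && keep[i] &&
            e$c_start[j] <= e$c_start[i] && e$c_end[i] <= e$c_end[j] &&
            (e$c_end[j] - e$c_start[j]) > (e$c_end[i] - e$c_start[i])) {
          keep[i] <- FALSE
        }
      }
    }
    e <- e[keep, , drop = FALSE]
    e <- arrange(e, .data$c_start)
    ## trim chain overlaps
    if (nrow(e) > 1) {
      for (i in 2:nrow(e)) {
        v <- e$c_end[i - 1L] - e$c_start[i]
        if (v > 0) {
          e$c_start[i] <- e$c_start[i] + v
          if (e$strand[i] == "+") e$r_start[i] <- e$r_start[i] + v
          else e$r_end[i] <- e$r_end[i] - v
        }
      }
      e <- e[e$c_end > e$c_start, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- e
  }
  bind_rows(out)
}

label_element_edges <- function(edges, features, min_frac = 0.8) {
  edges$element <- NA_character_
  els <- features[features$kind == "mobile_element", , drop = FALSE]
  if (nrow(els) == 0 || nrow(edges) == 0) return(edges)
  for (i in seq_len(nrow(edges))) {
    ov <- els[els$replicon == edges$replicon[i] &
                els$start < edges$r_end[i] &
                els$end > edges$r_start[i], , drop = FALSE]
    if (nrow(ov)) {
      inter <- pmin(ov$end, edges$r_end[i]) - pmax(ov$start, edges$r_start[i])
      j <- which.max(inter)
      if (inter[j] >= min_frac * (edges$r_end[i] - edges$r_start[i])) {
        edges$element[i] <- ov$gene[j] %||% ov$product[j]
      }
    }
  }
  edges
}

graph_nodes <- function(edges, contigs, reference) {
  nodes <- list()
  if (nrow(contigs)) {
    nodes[[1]] <- tibble(node_id = contigs$contig_id, kind = "contig",
                         replicon = NA_character_, start = NA_integer_,
                         end = NA_integer_, length = contigs$length)
  }
  for (r in names(reference$sequence)) {
    L <- nchar(reference$sequence[[r]])
    cuts <- sort(unique(c(0L, L,
                          edges$r_start[edges$replicon == r],
                          edges$r_end[edges$replicon == r])))
    cuts <- cuts[cuts >= 0L & cuts <= L]
    if (length(cuts) >= 2) {
      frag <- tibble(replicon = r, start = head(cuts, -1L),
                     end = tail(cuts, -1L))
      frag <- frag[frag$end > frag$start, , drop = FALSE]
      nodes[[length(nodes) + 1L]] <- tibble(
        node_id = sprintf("%s:%d-%d", frag$replicon, frag$start, frag$end),
        kind = "ref_fragment", replicon = frag$replicon,
        start = frag$start, end = frag$end,
        length = frag$end - frag$start)
    }
  }
  bind_rows(nodes)
}

#' @export
print.placement_graph <- function(x, ...) {
  cat(sprintf("<placement_graph> vs %s: %d contig(s), %d edge(s), %d node(s)\n",
              x$reference_name, nrow(x$contigs), nrow(x$edges),
              nrow(x$nodes)))
  invisible(x)
}

#' @export
tidy.placement_graph <- function(x, ...) x$edges

#' @export
glance.placement_graph <- function(x, ...) {
  tibble(n_contigs = nrow(x$contigs), n_edges = nrow(x$edges),
         n_nodes = nrow(x$nodes),
         n_element_edges = sum(!is.na(x$edges$element)),
         reference = x$reference_name)
}
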
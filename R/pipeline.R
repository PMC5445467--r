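#' Default pipeline parameters
#'
#' Central knobs for the analysis engine, with the conventional defaults
#' used throughout: candidate-read clip threshold `s_min`, pileup depth
#' floor `d_min`, assembler `k` / k-mer coverage cutoff / contig size
#' threshold `l_min`, coverage-deletion thresholds `eps` and `r_min`, and
#' default-set thresholds `alpha`, `beta`, `m_min`.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(s_min = 10, d_min = 5, k = 31, min_count = 3, l_min = 200,
            eps = 0.1, r_min = 100, alpha = 0.3, beta = 2.5, m_min = 20,
            min_sv_len = 50, max_mm = 5, min_split = 25, sd_mult = 3)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Run the variant-calling pipeline for one sample
#'
#' Alignment (or pre-aligned SAM), read classification, pileup SNV calling,
#' candidate extraction, local de novo assembly, placement-graph SV calling,
#' and coverage-based deletion calling.
#'
#' @param reference a [ref_genome].
#' @param reads paired-read tibble (`name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), or `NULL` when `alignments` are supplied.
#' @param alignments pre-aligned records (tibble) or `NULL`.
#' @param index optional prebuilt [seq_index()].
#' @param params list from [pipeline_params()].
#' @return list with `alignments`, `coverage`, `snvs`, `svs`,
#'   `coverage_deletions`, `graph`, `candidates`, `median_depth`.
#' @export
call_sample_variants <- function(reference, reads = NULL, alignments = NULL,
                                 index = NULL, params = pipeline_params()) {
  idx <- index %||% seq_index(reference)
  if (is.null(alignments)) {
    stopifnot(!is.null(reads))
    alignments <- align_reads(reads, reference, index = idx,
                              max_mm = params$max_mm,
                              min_split = params$min_split,
                              sd_mult = params$sd_mult)
  }
  cls <- classify_reads(alignments, s_min = params$s_min)
  cov <- coverage_profile(cls, reference)
  snvs <- call_snvs(cls, reference, d_min = params$d_min)
  cands <- extract_candidates(cls, s_min = params$s_min)
  ctgs <- assemble_contigs(cands, k = params$k,
                           min_count = params$min_count,
                           l_min = params$l_min)
  graph <- align_contigs(ctgs, reference, index = idx)
  svs <- call_structural_variants(graph, reference,
                                  min_sv_len = params$min_sv_len)
  covdel <- call_coverage_deletions(cov, reference, eps = params$eps,
                                    r_min = params$r_min)
  list(alignments = cls, coverage = cov, snvs = snvs, svs = svs,
       coverage_deletions = covdel, graph = graph, candidates = cands,
       median_depth = median(cov$depth))
}

#' Iterate genome versioning until no variants are called
#'
#' Repeatedly calls variants for a sample against the current reference,
#' applies the high-confidence set (clean-mutant SNVs with `GT_TYPE = 2`
#' and assembly-method SVs) to produce a new genome version, realigns, and
#' stops when a round calls nothing (converged) or `max_rounds` is reached
#' (flagged unconverged).
#'
#' @param reference starting [ref_genome].
#' @param reads paired-read tibble for the sample.
#' @param max_rounds round cap.
#' @param params list from [pipeline_params()].
#' @return list with `genome` (final [ref_genome]), `rounds` (number of
#'   variant sets applied), `converged`, and `history` (per-round call
#'   counts).
#' @export
iterate_to_convergence <- function(reference, reads, max_rounds = 4,
                                   params = pipeline_params()) {
  current <- reference
  history <- list()
  rounds <- 0L
  repeat {
    res <- call_sample_variants(current, reads = reads, params = params)
    hi_snv <- res$snvs[res$snvs$gt_type == 2L, , drop = FALSE]
    hi_sv <- res$svs[res$svs$method == "assembly", , drop = FALSE]
    n_calls <- nrow(hi_snv) + nrow(hi_sv)
    history[[length(history) + 1L]] <- tibble(
      round = rounds, n_snv = nrow(hi_snv), n_sv = nrow(hi_sv))
    if (n_calls == 0L) {
      return(list(genome = current, rounds = rounds, converged = TRUE,
                  history = bind_rows(history)))
    }
    if (rounds >= max_rounds) {
      return(list(genome = current, rounds = rounds, converged = FALSE,
                  history = bind_rows(history)))
    }
    set <- bind_rows(complete_variants(hi_snv[, intersect(
      names(hi_snv), names(empty_variants()))]),
      complete_variants(hi_sv[, names(empty_variants())]))
    current <- apply_variant_set(current, set)$genome
    rounds <- rounds + 1L
  }
}

#' Read a project configuration file
#'
#' YAML with keys: `reference` (path), `reference_format`, `samples`
#' (manifest CSV path), `out_dir`, optional `params` overrides, `seed`.
#'
#' @param path YAML path.
#' @return config list.
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "strainforge_config_error")
  }
  yaml::read_yaml(path)
}

read_sample_manifest <- function(path) {
  mf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(mf)) {
    abort("sample manifest must have a sample_id column",
          class = "strainforge_config_error")
  }
  if (anyDuplicated(mf$sample_id)) {
    abort("sample_id values must be unique",
          class = "strainforge_config_error")
  }
  mf
}

#' Run a whole project: all samples, merged variants, evidence table
#'
#' The full workflow over a sample manifest: per-sample alignment and
#' variant calling, union of variant sites across samples, per-sample
#' genotyping at every site (so clean wild-type evidence is recorded too),
#' effect annotation, the denormalized evidence table, default triage sets,
#' and all on-disk artifacts (per-sample and merged VCFs, evidence CSV,
#' contig FASTA + junction TSV, set memberships, log).
#'
#' @param config list (see [read_project_config()]) with `reference`,
#'   `reference_format`, `samples` manifest path or tibble, `out_dir`,
#'   optional `params`.
#' @return project list: `reference`, `samples`, `variants`, `calls`,
#'   `evidence`, `sets`, `per_sample`, `out_dir`.
#' @export
run_project <- function(config) {
  for (key in c("reference", "samples", "out_dir")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config is missing required key '%s'", key),
            class = "strainforge_config_error")
    }
  }
  reference <- read_reference(config$reference,
                              config$reference_format %||% "genbank")
  manifest <- if (is.character(config$samples)) {
    read_sample_manifest(config$samples)
  } else {
    as_tibble(config$samples)
  }
  ## validate inputs before any compute
  for (i in seq_len(nrow(manifest))) {
    for (col in intersect(c("fastq1", "fastq2", "sam"), names(manifest))) {
      p <- manifest[[col]][i]
      if (!is.na(p) && nzchar(p) && !file.exists(p)) {
        abort(sprintf("sample %s: input file not found: %s",
                      manifest$sample_id[i], p),
              class = "strainforge_config_error")
      }
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(pipeline_params, config$params %||% list())
  idx <- seq_index(reference)
  log_lines <- c(sprintf("reference: %s", reference$name),
                 sprintf("samples: %d", nrow(manifest)),
                 sprintf("params: %s", paste(names(params), unlist(params),
                                             sep = "=", collapse = " ")))
  per_sample <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    if ("sam" %in% names(manifest) && !is.na(manifest$sam[i]) &&
        nzchar(manifest$sam[i])) {
      aln <- read_alignments(manifest$sam[i], reference)
      res <- call_sample_variants(reference, alignments = aln,
                                  index = idx, params = params)
    } else {
      r1 <- read_fastq(manifest$fastq1[i])
      r2 <- read_fastq(manifest$fastq2[i])
      reads <- tibble(name = sub("/1$", "", r1$name), seq1 = r1$seq,
                      qual1 = r1$qual, seq2 = r2$seq, qual2 = r2$qual)
      res <- call_sample_variants(reference, reads = reads, index = idx,
                                  params = params)
    }
    per_sample[[sid]] <- res
    log_lines <- c(log_lines, sprintf(
      "sample %s: %d SNV call(s), %d assembly SV(s), %d coverage deletion(s)",
      sid, nrow(res$snvs), nrow(res$svs), nrow(res$coverage_deletions)))
  }
  merged <- merge_project_variants(reference, per_sample, params)
  variants <- annotate_variants(merged$variants, reference)
  meta_cols <- setdiff(names(manifest), c("fastq1", "fastq2", "sam"))
  evidence <- build_evidence_table(variants, merged$calls,
                                   manifest[, meta_cols, drop = FALSE])
  cov_stats <- tibble(
    sample_id = names(per_sample),
    median_depth = vapply(per_sample, function(x) x$median_depth,
                          numeric(1)))
  sets <- assign_default_sets(evidence, cov_stats, alpha = params$alpha,
                              beta = params$beta, m_min = params$m_min)
  ## artifacts
  for (sid in names(per_sample)) {
    res <- per_sample[[sid]]
    sample_vars <- merged$variants[
      merged$variants$variant_id %in%
        merged$calls$variant_id[merged$calls$sample_id == sid &
                                  merged$calls$gt_type > 0L], ,
      drop = FALSE]
    write_vcf(sample_vars,
              merged$calls[merged$calls$sample_id == sid, , drop = FALSE],
              file.path(out_dir, paste0(sid, ".vcf")), reference)
    export_contigs(res$graph,
                   file.path(out_dir, paste0(sid, "_contigs.fasta")),
                   file.path(out_dir, paste0(sid, "_junctions.tsv")))
  }
  write_vcf(variants, merged$calls, file.path(out_dir, "project.vcf"),
            reference)
  export_evidence_csv(evidence, file.path(out_dir, "evidence.csv"))
  readr::write_csv(sets, file.path(out_dir, "variant_sets.csv"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  list(reference = reference, samples = manifest, variants = variants,
       calls = merged$calls, evidence = evidence, sets = sets,
       per_sample = per_sample, out_dir = out_dir)
}

## Union of variant sites across samples + per-sample genotypes at every
## site (GT_TYPE 0 rows included). SVs are genotyped presence/absence per
## sample from the assembly calls, with DP taken from local coverage.
merge_project_variants <- function(reference, per_sample, params) {
  snv_union <- bind_rows(lapply(per_sample, function(x)
    x$snvs[, c("variant_id", "replicon", "pos", "type", "ref", "alt",
               "length", "method")]))
  snv_union <- distinct(snv_union, .data$variant_id, .keep_all = TRUE)
  sv_union <- bind_rows(lapply(per_sample, function(x) {
    v <- bind_rows(x$svs[, names(empty_variants())],
                   x$coverage_deletions[, names(empty_variants())])
    v
  }))
  sv_union <- distinct(sv_union, .data$variant_id, .keep_all = TRUE)
  calls <- list()
  for (sid in names(per_sample)) {
    res <- per_sample[[sid]]
    if (nrow(snv_union)) {
      g <- genotype_sites(res$alignments, reference,
                          complete_variants(snv_union))
      calls[[length(calls) + 1L]] <- mutate(g, sample_id = sid)
    }
    if (nrow(sv_union)) {
      own <- c(res$svs$variant_id, res$coverage_deletions$variant_id)
      depth_at <- function(repl, p) {
        d <- res$coverage$depth[res$coverage$replicon == repl &
                                  res$coverage$pos == pmax(p - 1L, 0L)]
        if (length(d)) d[1] else 0L
      }
      calls[[length(calls) + 1L]] <- tibble(
        variant_id = sv_union$variant_id,
        gt = ifelse(sv_union$variant_id %in% own, "1/1", "0/0"),
        gt_type = ifelse(sv_union$variant_id %in% own, 2L, 0L),
        gq = 99,
        dp = mapply(depth_at, sv_union$replicon, sv_union$pos),
        af = ifelse(sv_union$variant_id %in% own, 1, 0),
        mean_mapq = NA_real_, sample_id = sid)
    }
  }
  variants <- bind_rows(complete_variants(snv_union),
                        complete_variants(sv_union))
  list(variants = variants,
       calls = if (length(calls)) bind_rows(calls) else
         tibble(variant_id = character(0), sample_id = character(0),
                gt = character(0), gt_type = integer(0), gq = numeric(0),
                dp = integer(0), af = numeric(0), mean_mapq = numeric(0)))
}

#' Query a project's evidence table
#'
#' @param project project list from [run_project()], or a path to an
#'   evidence CSV.
#' @param query query text.
#' @param view `"melted"` or `"cast"`.
#' @return tibble of matching rows.
#' @export
query_project <- function(project, query, view = "melted") {
  table <- if (is.character(project)) {
    if (!file.exists(project)) {
      abort(sprintf("no evidence table at %s", project),
            class = "strainforge_config_error")
    }
    read_evidence_csv(project)
  } else {
    project$evidence
  }
  evaluate_query(table, query, view = view)
}

#' Apply a named variant set to the project reference (genome versioning)
#'
#' @param project project list from [run_project()].
#' @param set_name set name present in `project$sets` (or a user set
#'   tibble).
#' @param out_prefix path prefix for FASTA/GenBank/lift-map outputs; no
#'   files written when `NULL`.
#' @return list from [apply_variant_set()].
#' @export
version_genome <- function(project, set_name, out_prefix = NULL) {
  sets <- project$sets
  if (!set_name %in% sets$name) {
    abort(sprintf("unknown variant set '%s'. Available sets: %s", set_name,
                  paste(sort(unique(sets$name)), collapse = ", ")),
          class = "strainforge_config_error")
  }
  ids <- unique(sets$variant_id[sets$name == set_name])
  vars <- project$variants[project$variants$variant_id %in% ids, ,
                           drop = FALSE]
  res <- apply_variant_set(project$reference, vars)
  if (!is.null(out_prefix)) {
    write_reference(res$genome, paste0(out_prefix, ".fasta"), "fasta")
    write_reference(res$genome, paste0(out_prefix, ".gb"), "genbank")
    write_liftmap(res$liftmap, paste0(out_prefix, "_liftmap.tsv"))
  }
  res
}

#' Design oligos for a named variant set
#'
#' @param project project list from [run_project()].
#' @param set_name set name in `project$sets`.
#' @param direction `"introduce"` or `"revert"`.
#' @param ori,ter replication origin/terminus (0-based).
#' @param out_prefix path prefix for FASTA/TSV outputs; no files when
#'   `NULL`.
#' @param ... passed to [design_oligos()].
#' @return oligo tibble.
#' @export
design_set_oligos <- function(project, set_name, direction, ori, ter,
                              out_prefix = NULL, ...) {
  sets <- project$sets
  if (!set_name %in% sets$name) {
    abort(sprintf("unknown variant set '%s'. Available sets: %s", set_name,
                  paste(sort(unique(sets$name)), collapse = ", ")),
          class = "strainforge_config_error")
  }
  ids <- unique(sets$variant_id[sets$name == set_name])
  vars <- project$variants[project$variants$variant_id %in% ids, ,
                           drop = FALSE]
  ol <- design_oligos(project$reference, vars, direction = direction,
                      ori = ori, ter = ter, ...)
  if (!is.null(out_prefix)) {
    write_oligos(ol, paste0(out_prefix, ".fasta"), paste0(out_prefix,
                                                          ".tsv"))
  }
  ol
}
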
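# End-to-end orchestration: align (or reuse a hit table), compute the
# similarity matrix, cluster, write outputs. Step-2 results (the hit table
# and the pair table) are cached in <output_dir>/work so clustering and
# reporting can be re-run with different settings without re-aligning or
# recomputing similarities — the expensive steps.

#' Run the full intergenomic-similarity workflow
#'
#' Four steps: (1) all-vs-all BLASTN alignment of the input genomes (skipped
#' when `reuse_hits` points at a previously produced tabular hit file);
#' (2) per-pair overlap de-replication and similarity/indicator computation;
#' (3) hierarchical clustering of the similarity matrix and threshold-based
#' species/genus assignment; (4) outputs — ordered similarity (and/or
#' distance) matrix TSV, composite heatmap PDF, cluster table TSV,
#' intermediate pair table TSV, and a run log with tool versions, exact
#' aligner command lines and timing. Given the same hit input, every numeric
#' output is identical across runs and thread counts.
#'
#' @param input path to a multi-FASTA of genomes (plain or gzip).
#' @param output_dir output directory, created if needed.
#' @param parameter_set alignment preset 1-4 (see [param_set()]); default 1.
#' @param evalue,max_targets,threads aligner options (see [run_all_vs_all()]).
#' @param method clustering agglomeration method (default `"complete"`).
#' @param species_thr,genus_thr demarcation thresholds (defaults 95 and 70).
#' @param matrix_type which matrix file(s) to write: `"sim"`, `"dist"` or
#'   `"both"`.
#' @param heatmap render the heatmap PDF (default `TRUE`).
#' @param min_length reject genomes shorter than this (default 1).
#' @param n_run_threshold N-run length that triggers a draft-genome warning.
#' @param reuse_hits optional path to a 13-column tabular hit file from a
#'   previous run (skips alignment; steps 2-4 are then fully deterministic).
#' @param label_threshold heatmap cell-number suppression size.
#' @return Invisibly, a list with `manifest` (named vector of written file
#'   paths), `result` (the `igsim_result`), `clusters`, `order`, and
#'   `genomes`.
#' @export
run_pipeline <- function(input, output_dir,
                         parameter_set = 1L, evalue = 1,
                         max_targets = 10000L, threads = 1L,
                         method = "complete",
                         species_thr = 95, genus_thr = 70,
                         matrix_type = c("sim", "dist", "both"),
                         heatmap = TRUE,
                         min_length = 1L, n_run_threshold = 10L,
                         reuse_hits = NULL, label_threshold = 80L) {
  matrix_type <- match.arg(matrix_type)
  t0 <- Sys.time()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  work_dir <- file.path(output_dir, "work")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("igsim ", as.character(utils::packageVersion("igsim"))),
    paste0("R ", R.version.string),
    paste0("started: ", format(t0, usetz = TRUE)),
    paste0("config: input=", input, " parameter_set=", parameter_set,
           " evalue=", evalue, " max_targets=", max_targets,
           " threads=", threads, " method=", method,
           " species_thr=", species_thr, " genus_thr=", genus_thr,
           " matrix_type=", matrix_type, " heatmap=", heatmap,
           " reuse_hits=", reuse_hits %||% "<none>")
  )

  # step 1: genomes in, alignment
  gs <- read_genomes(input, min_length = min_length)
  gs <- validate_genomes(gs, n_run_threshold = n_run_threshold)
  for (w in unlist(gs$warnings)) {
    warning(w, call. = FALSE)
    log_lines <- c(log_lines, paste0("WARNING: ", w))
  }
  log_lines <- c(log_lines, sprintf("genomes: %d (%d..%d bp)", length(gs),
                                    min(genome_lengths(gs)),
                                    max(genome_lengths(gs))))

  if (is.null(reuse_hits)) {
    hits <- run_all_vs_all(gs, params = param_set(parameter_set),
                           evalue = evalue, max_targets = max_targets,
                           threads = threads, work_dir = work_dir)
    log_lines <- c(log_lines, attr(hits, "log"))
    hit_table <- attr(hits, "hit_table")
  } else {
    hits <- parse_hit_table(reuse_hits, gs = gs)
    hit_table <- reuse_hits
    log_lines <- c(log_lines, paste0("alignment skipped; hits reused from ",
                                     reuse_hits))
  }
  log_lines <- c(log_lines, sprintf("hits: %d (after self-hit removal)",
                                    nrow(hits)))

  # step 2: similarity core (cached as the reusable pair table)
  result <- compute_matrix(gs, hits)

  # step 3: clustering + thresholds
  clust <- cluster_matrix(result$sim, method = method)
  clusters <- assign_clusters(result$sim, clust,
                              species_thr = species_thr,
                              genus_thr = genus_thr)
  m_ord <- order_matrix(result$sim, clust$order)

  # step 4: outputs
  manifest <- c(hit_table = hit_table)
  manifest <- c(manifest, stats::setNames(
    write_intermediates(result, work_dir, cluster_table = NULL),
    "pair_table"
  ))
  if (matrix_type %in% c("sim", "both")) {
    p <- file.path(output_dir, "similarity_matrix.tsv")
    write_matrix(m_ord, p, type = "sim")
    manifest <- c(manifest, sim_matrix = p)
  }
  if (matrix_type %in% c("dist", "both")) {
    p <- file.path(output_dir, "distance_matrix.tsv")
    write_matrix(m_ord, p, type = "dist")
    manifest <- c(manifest, dist_matrix = p)
  }
  p <- file.path(output_dir, "cluster_table.tsv")
  utils::write.table(as.data.frame(clusters), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(manifest, cluster_table = p)
  if (isTRUE(heatmap)) {
    spec <- heatmap_spec(m_ord, result$af, genome_lengths(gs),
                         label_threshold = label_threshold)
    p <- file.path(output_dir, "heatmap.pdf")
    render_heatmap(spec, p)
    manifest <- c(manifest, heatmap = p)
  }

  t1 <- Sys.time()
  log_lines <- c(log_lines,
                 sprintf("wall time: %.2f s",
                         as.numeric(difftime(t1, t0, units = "secs"))),
                 "outputs:",
                 paste0("  ", names(manifest), ": ", manifest))
  log_path <- file.path(output_dir, "run.log")
  writeLines(log_lines, log_path)
  manifest <- c(manifest, run_log = log_path)

  invisible(list(manifest = manifest, result = result, clusters = clusters,
                 order = clust$order, genomes = gs))
}
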
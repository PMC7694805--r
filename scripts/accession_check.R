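#!/usr/bin/env Rscript
# OPTIONAL, NETWORK-REQUIRED integration check (not part of the offline test
# suite): downloads two public genome pairs from NCBI and verifies the
# published anchor values —
#   * Escherichia phage T7 (NC_001604.1) vs Pelagibacter phage HTVC011P
#     (NC_020483.1): intergenomic similarity ~0.34%
#   * MG969412.1 vs MG969413.1: similarity ~62.4% with genome length ratio
#     ~0.3
# Usage:  Rscript scripts/accession_check.R [workdir]
# Exits nonzero on disagreement beyond +/- 0.1 similarity points (aligner
# version drift caveat applies).

suppressPackageStartupMessages(library(igsim))

workdir <- commandArgs(trailingOnly = TRUE)[1]
if (is.na(workdir)) workdir <- tempfile("igsim_accession_")
dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

fetch <- function(acc) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", acc, "&rettype=fasta&retmode=text")
  dest <- file.path(workdir, paste0(acc, ".fasta"))
  if (!file.exists(dest)) utils::download.file(url, dest, quiet = TRUE)
  dest
}

check_pair <- function(acc1, acc2, sim_expect, tol = 0.1,
                       length_ratio_expect = NA) {
  f1 <- fetch(acc1); f2 <- fetch(acc2)
  combined <- file.path(workdir, paste0(acc1, "_", acc2, ".fasta"))
  writeLines(c(readLines(f1), readLines(f2)), combined)
  gs <- read_genomes(combined)
  res <- compute_matrix(gs, run_all_vs_all(gs, param_set(1L)))
  sim <- res$pairs$sim[1]
  lr <- res$pairs$length_ratio[1]
  ok <- abs(sim - sim_expect) <= tol
  cat(sprintf("%s vs %s: sim %.3f (expect %.2f +/- %.1f) %s\n",
              acc1, acc2, sim, sim_expect, tol, if (ok) "OK" else "MISMATCH"))
  if (!is.na(length_ratio_expect)) {
    cat(sprintf("  length ratio %.2f (expect ~%.1f)\n", lr,
                length_ratio_expect))
    ok <- ok && abs(lr - length_ratio_expect) <= 0.05
  }
  ok
}

ok <- check_pair("NC_001604.1", "NC_020483.1", 0.34)
ok <- check_pair("MG969412.1", "MG969413.1", 62.4,
                 length_ratio_expect = 0.3) && ok
quit(status = if (ok) 0L else 1L)
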
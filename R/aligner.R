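# Aligner backend: BLASTN parameter presets, the all-vs-all driver, and the
# tabular-hit parser/normalizer. Everything downstream consumes the canonical
# hit table produced here: 0-based half-open intervals, strand carried
# separately, self-hits removed.

HIT_COLS <- c("query_id", "subject_id", "q_start", "q_end",
              "s_start", "s_end", "s_strand", "align_len", "n_ident",
              "bitscore", "evalue")

BLAST_OUTFMT <- paste("6 qseqid sseqid pident length mismatch gapopen",
                      "qstart qend sstart send evalue bitscore nident")

#' BLASTN alignment parameter presets
#'
#' Four presets ranging from "relaxed" (set 1, the default: finds regions
#' down to ~65% identity / 140 bp) to "very stringent" (set 4: much faster,
#' only near-identical regions align, so similarities between distant genomes
#' drop). Set 1: `-word_size 7 -reward 2 -penalty -3 -gapopen 5 -gapextend 2`;
#' set 2 the same with `-word_size 11`; set 3: `-word_size 20 -reward 1
#' -penalty -2`; set 4: the same with `-word_size 28` (sets 3 and 4 use
#' BLASTN's default gap costs).
#'
#' @param set_id integer 1-4.
#' @return A list of class `param_set` with fields `set_id`, `word_size`,
#'   `reward`, `penalty`, `gapopen`, `gapextend` (the last two `NULL` for
#'   sets 3 and 4).
#' @export
param_set <- function(set_id = 1L) {
  if (!set_id %in% 1:4) input_stop("'set_id' must be one of 1, 2, 3, 4")
  presets <- list(
    list(set_id = 1L, word_size = 7L,  reward = 2L, penalty = -3L,
         gapopen = 5L, gapextend = 2L),
    list(set_id = 2L, word_size = 11L, reward = 2L, penalty = -3L,
         gapopen = 5L, gapextend = 2L),
    list(set_id = 3L, word_size = 20L, reward = 1L, penalty = -2L,
         gapopen = NULL, gapextend = NULL),
    list(set_id = 4L, word_size = 28L, reward = 1L, penalty = -2L,
         gapopen = NULL, gapextend = NULL)
  )
  structure(presets[[set_id]], class = "param_set")
}

param_set_args <- function(p) {
  args <- c("-word_size", p$word_size, "-reward", p$reward,
            "-penalty", p$penalty)
  if (!is.null(p$gapopen))   args <- c(args, "-gapopen", p$gapopen)
  if (!is.null(p$gapextend)) args <- c(args, "-gapextend", p$gapextend)
  as.character(args)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             s_strand = character(0), align_len = integer(0),
             n_ident = numeric(0), bitscore = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Normalize raw tabular hit coordinates
#'
#' BLAST tabular output uses 1-based inclusive coordinates and encodes the
#' subject strand by coordinate order (`s.start > s.end` on the minus
#' strand). This converts to the internal convention: 0-based half-open
#' intervals with `start < end` and the strand in its own column, which makes
#' the interval arithmetic of de-replication straightforward.
#'
#' @param raw data frame with 1-based columns `query_id`, `subject_id`,
#'   `qstart`, `qend`, `sstart`, `send`, `align_len`, `n_ident`, `bitscore`,
#'   `evalue`.
#' @return Canonical hit data frame with columns `query_id`, `subject_id`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `s_strand`, `align_len`,
#'   `n_ident`, `bitscore`, `evalue`.
#' @export
normalize_hits <- function(raw) {
  if (nrow(raw) == 0L) return(empty_hits())
  if (any(raw$qstart > raw$qend)) {
    input_stop("query coordinates with qstart > qend are not expected")
  }
  minus <- raw$sstart > raw$send
  s_lo <- ifelse(minus, raw$send, raw$sstart)
  s_hi <- ifelse(minus, raw$sstart, raw$send)
  out <- data.frame(
    query_id = as.character(raw$query_id),
    subject_id = as.character(raw$subject_id),
    q_start = as.integer(raw$qstart) - 1L,
    q_end = as.integer(raw$qend),
    s_start = as.integer(s_lo) - 1L,
    s_end = as.integer(s_hi),
    s_strand = ifelse(minus, "-", "+"),
    align_len = as.integer(raw$align_len),
    n_ident = as.numeric(raw$n_ident),
    bitscore = as.numeric(raw$bitscore),
    evalue = as.numeric(raw$evalue),
    stringsAsFactors = FALSE
  )
  if (any(out$q_end <= out$q_start) || any(out$s_end <= out$s_start)) {
    input_stop("zero-length alignment interval in hit table")
  }
  bad <- out$n_ident > out$align_len |
    out$n_ident > (out$q_end - out$q_start) |
    out$n_ident > (out$s_end - out$s_start)
  if (any(bad)) {
    input_stop(paste0(sum(bad), " hit(s) with n_ident exceeding the aligned",
                      " interval length"))
  }
  out
}

#' Parse a precomputed BLAST tabular hit file
#'
#' Accepts the standard 12-column tabular dialect (outfmt 6) extended with
#' the identical-match count (`nident`) as the 13th column — the format
#' written by [run_all_vs_all()]. Self-hits (query id equal to subject id)
#' are dropped; coordinates are normalized via [normalize_hits()].
#'
#' @param path tab-separated hit file.
#' @param gs optional `genome_set`; when supplied, hits referencing unknown
#'   genome ids raise an error.
#' @return Canonical hit data frame.
#' @export
parse_hit_table <- function(path, gs = NULL) {
  if (!file.exists(path)) input_stop(paste0("hit table not found: ", path))
  if (file.size(path) == 0L) return(empty_hits())
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#",
                      colClasses = NA),
    error = function(e) input_stop(paste0("malformed hit table '", path,
                                          "': ", conditionMessage(e)))
  )
  if (nrow(tab) == 0L) return(empty_hits())
  if (ncol(tab) < 13L) {
    input_stop(paste0("hit table needs >= 13 columns (std 12 + nident), got ",
                      ncol(tab)))
  }
  raw <- data.frame(
    query_id = as.character(tab[[1L]]), subject_id = as.character(tab[[2L]]),
    qstart = tab[[7L]], qend = tab[[8L]],
    sstart = tab[[9L]], send = tab[[10L]],
    evalue = tab[[11L]], bitscore = tab[[12L]],
    align_len = tab[[4L]], n_ident = tab[[13L]],
    stringsAsFactors = FALSE
  )
  num_cols <- c("qstart", "qend", "sstart", "send", "evalue", "bitscore",
                "align_len", "n_ident")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v)) input_stop(paste0("non-numeric values in column '", cn,
                                    "' of hit table"))
    raw[[cn]] <- v
  }
  raw <- raw[raw$query_id != raw$subject_id, , drop = FALSE]
  hits <- normalize_hits(raw)
  if (!is.null(gs)) {
    ids <- genome_ids(gs)
    unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
    if (length(unknown) > 0L) {
      input_stop(paste0("hit table references unknown genome id(s): ",
                        paste(unknown, collapse = ", ")))
    }
  }
  hits
}

#' Write hits back to the BLAST tabular dialect
#'
#' Inverse of [parse_hit_table()]: emits the 12 standard columns plus
#' `nident`, converting internal 0-based half-open coordinates back to
#' 1-based inclusive with minus-strand subject coordinates swapped.
#' `pident`/`mismatch`/`gapopen` are reconstructed from `n_ident` and
#' `align_len` (gap opens as 0: the tabular dialect does not locate gaps).
#'
#' @param hits canonical hit data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  minus <- hits$s_strand == "-"
  tab <- data.frame(
    hits$query_id, hits$subject_id,
    sprintf("%.3f", 100 * hits$n_ident / pmax(hits$align_len, 1L)),
    hits$align_len,
    as.integer(hits$align_len - hits$n_ident), 0L,
    hits$q_start + 1L, hits$q_end,
    ifelse(minus, hits$s_end, hits$s_start + 1L),
    ifelse(minus, hits$s_start + 1L, hits$s_end),
    format(hits$evalue), hits$bitscore, hits$n_ident
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

blast_binary <- function(name) {
  p <- Sys.which(name)
  if (p == "") {
    aligner_stop(paste0("external aligner '", name, "' not found on PATH;",
                        " install NCBI BLAST+ or supply a precomputed hit",
                        " table"))
  }
  unname(p)
}

run_logged <- function(bin, args, log_lines) {
  cmd <- paste(c(bin, args), collapse = " ")
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    aligner_stop(paste0("'", basename(bin), "' exited with status ", status,
                        ":\n", paste(out, collapse = "\n")))
  }
  c(log_lines, cmd)
}

#' All-vs-all local alignment of a genome set
#'
#' Runs `makeblastdb` on the genome set and aligns every genome against the
#' database (both directions of every pair come out of the single query-all
#' run). Core parameters follow the method's defaults: `-evalue 1
#' -max_target_seqs 10000`, alignment scoring from the chosen [param_set()].
#' Self-hits are removed; self-similarity is fixed at 100 downstream by
#' definition.
#'
#' @param gs a `genome_set` with at least 2 genomes.
#' @param params a [param_set()] (default set 1).
#' @param evalue BLASTN expectation-value cutoff (default 1).
#' @param max_targets `-max_target_seqs` (default 10000; raise for datasets
#'   with more genomes).
#' @param threads `-num_threads` for the alignment step (results are
#'   thread-count invariant).
#' @param work_dir directory for the FASTA/database/hit-table artifacts;
#'   created if missing. Defaults to a session temporary directory.
#' @return Canonical hit data frame, with attributes `log` (aligner version
#'   and exact command lines) and `hit_table` (path of the raw tabular file).
#' @export
run_all_vs_all <- function(gs, params = param_set(1L), evalue = 1,
                           max_targets = 10000L, threads = 1L,
                           work_dir = tempfile("igsim_blast_")) {
  if (!inherits(gs, "genome_set")) input_stop("'gs' must be a genome_set")
  if (length(gs) < 2L) input_stop("need at least 2 genomes to align")
  if (!inherits(params, "param_set")) params <- param_set(params)
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)

  makeblastdb <- blast_binary("makeblastdb")
  blastn <- blast_binary("blastn")
  ver <- suppressWarnings(system2(blastn, "-version", stdout = TRUE))[1L]
  log_lines <- paste0("aligner: ", ver)

  fasta <- file.path(work_dir, "genomes.fasta")
  write_genomes(gs, fasta)
  db <- file.path(work_dir, "genomes_db")
  log_lines <- run_logged(
    makeblastdb, c("-in", fasta, "-dbtype", "nucl", "-out", db), log_lines
  )

  hit_file <- file.path(work_dir, "hits.tsv")
  args <- c("-query", fasta, "-db", db,
            "-evalue", format(evalue),
            "-max_target_seqs", format(max_targets, scientific = FALSE),
            "-num_threads", as.integer(threads),
            param_set_args(params),
            "-outfmt", shQuote(BLAST_OUTFMT),
            "-out", hit_file)
  log_lines <- run_logged(blastn, args, log_lines)
  if (!file.exists(hit_file)) {
    aligner_stop("aligner produced no output file")
  }
  hits <- parse_hit_table(hit_file, gs = gs)
  attr(hits, "log") <- log_lines
  attr(hits, "hit_table") <- hit_file
  hits
}
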
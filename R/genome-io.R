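# Reading, validating and writing genome sets.

IUPAC_DNA <- c("A", "C", "G", "T", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a genome set
#'
#' A genome set is the package's container for the input genomes of one run:
#' a named [Biostrings::DNAStringSet] (uppercased, IUPAC alphabet) plus
#' per-genome validation warnings. Iteration order is the input order and
#' determines the default (pre-clustering) matrix order.
#'
#' @param seqs named character vector or `DNAStringSet` of nucleotide
#'   sequences; names are the genome identifiers.
#' @param warnings optional named list of character vectors of validation
#'   notes, one element per genome.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(seqs, warnings = NULL) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == "")) {
    input_stop("genomes must be a named character vector or DNAStringSet")
  }
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    input_stop(paste0("duplicate genome id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(seqs)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
    any(!ch %in% IUPAC_DNA)
  }, logical(1L))
  if (any(bad)) {
    input_stop(paste0(
      "non-nucleotide characters (beyond IUPAC codes) in: ",
      paste(ids[bad], collapse = ", ")
    ))
  }
  if (any(nchar(seqs) < 1L)) {
    input_stop(paste0("empty sequence(s): ",
                      paste(ids[nchar(seqs) < 1L], collapse = ", ")))
  }
  w <- vector("list", length(ids))
  names(w) <- ids
  if (!is.null(warnings)) w[names(warnings)] <- warnings
  structure(
    list(seq = Biostrings::DNAStringSet(seqs), warnings = w),
    class = "genome_set"
  )
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set of %d genome(s), lengths %s..%s bp\n",
              length(x$seq), min(genome_lengths(x)), max(genome_lengths(x))))
  nw <- sum(lengths(x$warnings) > 0L)
  if (nw > 0L) cat(sprintf("  %d genome(s) carry validation warnings\n", nw))
  invisible(x)
}

#' @export
length.genome_set <- function(x) length(x$seq)

#' Genome identifiers and lengths
#'
#' @param gs a `genome_set`.
#' @return `genome_ids()`: character vector of identifiers in input order.
#'   `genome_lengths()`: named integer vector of genome lengths (the `lA`,
#'   `lB` of the similarity formula).
#' @export
genome_ids <- function(gs) names(gs$seq)

#' @rdname genome_ids
#' @export
genome_lengths <- function(gs) {
  stats::setNames(Biostrings::width(gs$seq), names(gs$seq))
}

#' Read genomes from a multi-FASTA file
#'
#' Each FASTA record is treated as one complete genome; the identifier is the
#' first whitespace-delimited token of the header (matching BLAST tabular
#' naming, so alignment hits join back to genomes unambiguously). Sequences
#' are uppercased; soft-masking is discarded. Plain and gzip-compressed
#' files are accepted.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @param min_length minimum accepted genome length; shorter records raise
#'   an error naming them.
#' @return A [genome_set].
#' @export
read_genomes <- function(path, min_length = 1L) {
  if (!file.exists(path)) input_stop(paste0("input file not found: ", path))
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) input_stop(paste0("cannot parse FASTA '", path, "': ",
                                          conditionMessage(e)))
  )
  if (length(raw) == 0L) input_stop(paste0("no FASTA records in: ", path))
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1L), 1L)
  seqs <- stats::setNames(as.character(raw), ids)
  if (length(seqs) < 2L) {
    input_stop("fewer than 2 genomes: pairwise comparison needs at least 2")
  }
  short <- nchar(seqs) < min_length
  if (any(short)) {
    input_stop(paste0("genome(s) shorter than min_length (", min_length,
                      "): ", paste(ids[short], collapse = ", ")))
  }
  genome_set(seqs)
}

#' Write a genome set to FASTA
#'
#' Identifiers are written verbatim (no description), so a round trip through
#' [read_genomes()] reproduces ids, sequences and lengths exactly. This is
#' also the file handed to the external aligner.
#'
#' @param gs a `genome_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(gs, path) {
  Biostrings::writeXStringSet(gs$seq, path)
  invisible(path)
}

#' Flag genomes with long runs of N
#'
#' BLASTN skips long ambiguous stretches, so draft (scaffold-level) genomes
#' containing runs of `N` yield underestimated similarities. Following the
#' method's advice this only warns; flagged genomes still participate in all
#' downstream computation unchanged.
#'
#' @param gs a `genome_set`.
#' @param n_run_threshold minimum run length of consecutive `N` that triggers
#'   a warning (default 10).
#' @return `gs` with per-genome warnings attached.
#' @export
validate_genomes <- function(gs, n_run_threshold = 10L) {
  if (!inherits(gs, "genome_set")) input_stop("'gs' must be a genome_set")
  if (n_run_threshold < 1L) input_stop("'n_run_threshold' must be >= 1")
  pat <- paste0("N{", n_run_threshold, ",}")
  seqs <- as.character(gs$seq)
  for (i in seq_along(seqs)) {
    m <- gregexpr(pat, seqs[[i]])[[1L]]
    if (m[1L] != -1L) {
      runs <- attr(m, "match.length")
      gs$warnings[[i]] <- c(
        gs$warnings[[i]],
        sprintf(paste0("genome '%s' contains %d run(s) of >= %d consecutive",
                       " N (longest %d); similarity will be underestimated",
                       " because the aligner ignores these regions"),
                names(seqs)[i], length(runs), n_run_threshold, max(runs))
      )
    }
  }
  gs
}
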
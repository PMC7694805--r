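# Test helpers: an independent brute-force de-replication oracle, hit-row
# constructors, and small random-case generators.

# Brute-force coverage-painting oracle for dereplicate_hits(): walk the hits
# in the same priority order and paint per-base credit on the query, crediting
# each base to the first (highest-priority) hit covering it, with that hit's
# identical bases spread uniformly over its query interval. Deliberately
# per-base and O(length): shares no code with the interval implementation.
oracle_dereplicate <- function(hits, query_len = 2000L) {
  if (nrow(hits) == 0L) return(list(ident_sum = 0, aligned_query_bases = 0L))
  ord <- order(-hits$n_ident, -hits$bitscore, hits$q_start, hits$s_start)
  hits <- hits[ord, , drop = FALSE]
  credit <- rep(NA_real_, query_len)
  for (k in seq_len(nrow(hits))) {
    span <- (hits$q_start[k] + 1L):hits$q_end[k]  # 0-based -> 1-based index
    per_base <- hits$n_ident[k] / (hits$q_end[k] - hits$q_start[k])
    free <- span[is.na(credit[span])]
    credit[free] <- per_base
  }
  list(ident_sum = sum(credit, na.rm = TRUE),
       aligned_query_bases = sum(!is.na(credit)))
}

# one canonical hit row
make_hit <- function(q_start, q_end, n_ident,
                     query_id = "A", subject_id = "B",
                     s_start = q_start, s_end = q_end,
                     s_strand = "+", bitscore = 2 * n_ident, evalue = 0) {
  data.frame(query_id = query_id, subject_id = subject_id,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, s_strand = s_strand,
             align_len = max(q_end - q_start, s_end - s_start),
             n_ident = n_ident, bitscore = bitscore, evalue = evalue,
             stringsAsFactors = FALSE)
}

# random small hit set for one ordered pair, intervals within [0, max_pos)
random_hit_set <- function(n_hits, max_pos = 1000L) {
  rows <- lapply(seq_len(n_hits), function(i) {
    s <- sample.int(max_pos - 1L, 1L) - 1L
    e <- s + sample.int(max_pos - s, 1L)
    len <- e - s
    make_hit(s, e, n_ident = sample.int(len, 1L),
             s_start = s, s_end = e,
             bitscore = round(stats::runif(1L, 10, 500), 1L))
  })
  do.call(rbind, rows)
}

# genome set wrapper for raw sequences
gs_from <- function(...) genome_set(c(...))

# write a genome set to a temporary FASTA, return the path
temp_fasta <- function(gs) {
  f <- tempfile(fileext = ".fasta")
  write_genomes(gs, f)
  f
}

blast_available <- function() {
  Sys.which("blastn") != "" && Sys.which("makeblastdb") != ""
}
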
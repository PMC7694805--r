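# Similarity core: per-directed-pair overlap de-replication, the
# dual-length-normalized similarity/distance formulas, and matrix assembly.
# This is the method's central computation: the identical-base count idAB is
# summed over de-replicated query regions when A is aligned to B, and
#   simAB = (idAB + idBA) * 100 / (lA + lB),  distAB = 100 - simAB,
# so partial alignments cannot inflate the similarity the way
# alignment-length-normalized statistics (ANI and relatives) can.

#' De-replicate the hits of one directed genome pair
#'
#' BLASTN can report overlapping local alignments for one (query, subject)
#' pair. So that every genome region — on either side of the alignment — is
#' counted exactly once, hits are processed in priority order (descending
#' `n_ident`, ties by descending `bitscore`, then ascending `q_start`, then
#' ascending `s_start`) and each hit is clipped against the union of
#' already-retained query intervals and, independently, the union of
#' already-retained subject intervals. A hit contributes
#' `n_ident * min(retained_query_fraction, retained_subject_fraction)`
#' (identical bases are assumed uniformly spread along the hit, since the
#' tabular format does not locate them); hits whose query interval is fully
#' covered contribute nothing and are dropped. The subject-side cap is what
#' makes tandem/terminal repeats count once: without it, a duplicated region
#' aligning twice onto a single-copy relative would be credited twice in the
#' duplicated genome's direction, and the pair's similarity would not show
#' the repeat-driven underestimation expected of the method.
#'
#' @param hits canonical hit data frame, all rows sharing one
#'   `(query_id, subject_id)` pair (may be empty).
#' @param query_id,subject_id required when `hits` is empty; otherwise taken
#'   from (and checked against) the rows.
#' @return A `directed_summary`: list with `query_id`, `subject_id`,
#'   `ident_sum` (real; the directed identical-base sum, idAB), `aligned_query_bases`
#'   (length of the union of retained query intervals), and
#'   `retained` (data frame of hits with their retained lengths and
#'   contributions).
#' @export
dereplicate_hits <- function(hits, query_id = NULL, subject_id = NULL) {
  if (nrow(hits) == 0L) {
    if (is.null(query_id) || is.null(subject_id)) {
      input_stop("empty hit set: supply query_id and subject_id explicitly")
    }
    return(structure(
      list(query_id = query_id, subject_id = subject_id,
           ident_sum = 0, aligned_query_bases = 0L,
           retained = data.frame()),
      class = "directed_summary"
    ))
  }
  qs <- unique(hits$query_id)
  ss <- unique(hits$subject_id)
  if (length(qs) != 1L || length(ss) != 1L) {
    input_stop("dereplicate_hits() expects hits of a single ordered pair")
  }
  if (!is.null(query_id) && query_id != qs) {
    input_stop("hits do not match the stated query_id")
  }
  if (!is.null(subject_id) && subject_id != ss) {
    input_stop("hits do not match the stated subject_id")
  }

  ord <- order(-hits$n_ident, -hits$bitscore, hits$q_start, hits$s_start)
  hits <- hits[ord, , drop = FALSE]

  kept_q <- matrix(numeric(0), ncol = 2L)
  kept_s <- matrix(numeric(0), ncol = 2L)
  n <- nrow(hits)
  retained_len <- numeric(n)
  contrib <- numeric(n)
  for (k in seq_len(n)) {
    qs_k <- hits$q_start[k]; qe_k <- hits$q_end[k]
    ss_k <- hits$s_start[k]; se_k <- hits$s_end[k]
    q_len <- qe_k - qs_k
    s_len <- se_k - ss_k
    rq <- q_len - interval_overlap_len(qs_k, qe_k, kept_q)
    rs <- s_len - interval_overlap_len(ss_k, se_k, kept_s)
    retained_len[k] <- rq
    if (rq > 0) {
      # identity scaled by whichever side lost more to de-replication; the
      # query bound keeps ident_sum <= aligned_query_bases <= query length
      contrib[k] <- hits$n_ident[k] * min(rq / q_len, rs / s_len)
      kept_q <- interval_union_add(kept_q, qs_k, qe_k)
      if (rs > 0) kept_s <- interval_union_add(kept_s, ss_k, se_k)
    }
  }
  keep <- retained_len > 0
  retained <- hits[keep, , drop = FALSE]
  retained$retained_query_len <- as.integer(retained_len[keep])
  retained$ident_contribution <- contrib[keep]
  structure(
    list(query_id = qs, subject_id = ss,
         ident_sum = sum(contrib),
         aligned_query_bases = interval_total_len(kept_q),
         retained = retained),
    class = "directed_summary"
  )
}

#' Intergenomic similarity and distance of one pair
#'
#' `sim = (id_ab + id_ba) * 100 / (l_a + l_b)` and `dist = 100 - sim`:
#' identical aligned bases from both alignment directions, normalized to the
#' sum of BOTH genome lengths (not to the alignment length).
#'
#' @param id_ab,id_ba de-replicated identical-base sums for the two
#'   directions (A aligned to B, B aligned to A).
#' @param l_a,l_b genome lengths.
#' @return List with `sim` and `dist`, both in `[0, 100]`.
#' @export
pair_similarity <- function(id_ab, id_ba, l_a, l_b) {
  if (l_a < 1L || l_b < 1L) input_stop("genome lengths must be >= 1")
  if (id_ab < 0 || id_ba < 0) {
    internal_stop("negative identical-base sum (de-replication bug)")
  }
  if (id_ab > l_a || id_ba > l_b) {
    internal_stop("identical-base sum exceeds genome length (de-replication bug)")
  }
  sim <- ((id_ab + id_ba) * 100) / (l_a + l_b)
  list(sim = sim, dist = 100 - sim)
}

#' Alignment-quality indicators of one pair
#'
#' Three indicators of how well the alignment captures the pair's
#' relatedness: the fraction of each genome covered by the de-replicated
#' aligned regions, and the genome length ratio (smaller/bigger length). A
#' high similarity together with a low length ratio flags a partial-genome or
#' nested-genome comparison that needs inspection before classification.
#'
#' @param summary_ab,summary_ba `directed_summary` objects for the two
#'   directions of one pair (A->B, then B->A).
#' @param l_a,l_b genome lengths of A and B.
#' @return List with `af_1` (aligned fraction of genome A), `length_ratio`,
#'   and `af_2` (aligned fraction of genome B), all in `[0, 1]`.
#' @export
pair_indicators <- function(summary_ab, summary_ba, l_a, l_b) {
  if (summary_ab$query_id != summary_ba$subject_id ||
      summary_ab$subject_id != summary_ba$query_id) {
    input_stop("summaries are not the two directions of one pair")
  }
  list(
    af_1 = summary_ab$aligned_query_bases / l_a,
    length_ratio = min(l_a, l_b) / max(l_a, l_b),
    af_2 = summary_ba$aligned_query_bases / l_b
  )
}

#' Similarity matrix and per-pair table for a genome set
#'
#' Assembles the full symmetric intergenomic-similarity matrix from the
#' normalized hit collection: per ordered pair, hits are de-replicated
#' ([dereplicate_hits()]); per unordered pair, similarity/distance and the
#' three indicators are computed. Pairs with no hits in either direction get
#' similarity 0; the diagonal is 100 by definition, never computed. Pair
#' results depend only on that pair's hits, so evaluation order (or any
#' parallel split over pairs) cannot change the result.
#'
#' @param gs a `genome_set`.
#' @param hits canonical hit data frame (normalized, self-hits removed),
#'   e.g. from [run_all_vs_all()] or [parse_hit_table()].
#' @return List of class `igsim_result` with elements `sim` (named square
#'   matrix, percent scale), `af` (named square matrix, `af[i, j]` = aligned
#'   fraction of genome `i` against genome `j`, diagonal 1), `pairs` (one row
#'   per unordered pair: `id_a`, `id_b`, `sim`, `dist`, `af_1`,
#'   `length_ratio`, `af_2`, directional ident sums and aligned-base counts,
#'   genome lengths), and `ids`.
#' @export
compute_matrix <- function(gs, hits) {
  if (!inherits(gs, "genome_set")) input_stop("'gs' must be a genome_set")
  ids <- genome_ids(gs)
  n <- length(ids)
  if (n < 2L) input_stop("need at least 2 genomes")
  lens <- genome_lengths(gs)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown) > 0L) {
    input_stop(paste0("hits reference genome id(s) absent from the set: ",
                      paste(unknown, collapse = ", ")))
  }
  if (nrow(hits) > 0L && any(hits$query_id == hits$subject_id)) {
    input_stop("self-hits present: normalize/filter hits first")
  }

  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(sim) <- 100
  af <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(af) <- 1

  by_pair <- if (nrow(hits) > 0L) {
    split(hits, paste(hits$query_id, hits$subject_id, sep = "\r"))
  } else list()

  pair_rows <- vector("list", n * (n - 1L) %/% 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- ids[i]; b <- ids[j]
      h_ab <- by_pair[[paste(a, b, sep = "\r")]]
      h_ba <- by_pair[[paste(b, a, sep = "\r")]]
      s_ab <- dereplicate_hits(h_ab %||% empty_hits(),
                               query_id = a, subject_id = b)
      s_ba <- dereplicate_hits(h_ba %||% empty_hits(),
                               query_id = b, subject_id = a)
      sd <- pair_similarity(s_ab$ident_sum, s_ba$ident_sum,
                            lens[[a]], lens[[b]])
      ind <- pair_indicators(s_ab, s_ba, lens[[a]], lens[[b]])
      sim[i, j] <- sim[j, i] <- sd$sim
      af[i, j] <- ind$af_1
      af[j, i] <- ind$af_2
      k <- k + 1L
      pair_rows[[k]] <- data.frame(
        id_a = a, id_b = b, sim = sd$sim, dist = sd$dist,
        af_1 = ind$af_1, length_ratio = ind$length_ratio, af_2 = ind$af_2,
        ident_sum_ab = s_ab$ident_sum, ident_sum_ba = s_ba$ident_sum,
        aligned_bases_a = s_ab$aligned_query_bases,
        aligned_bases_b = s_ba$aligned_query_bases,
        len_a = lens[[a]], len_b = lens[[b]],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(sim = sim, af = af, pairs = do.call(rbind, pair_rows), ids = ids),
    class = "igsim_result"
  )
}

#' @export
print.igsim_result <- function(x, ...) {
  cat(sprintf("igsim_result: %d genomes, %d pairs; similarity range %.3f..%.3f\n",
              length(x$ids), nrow(x$pairs),
              min(x$pairs$sim), max(x$pairs$sim)))
  invisible(x)
}
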
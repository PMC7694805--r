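# Synthetic genome and hit-table generators. These emulate the structure of
# real phage benchmark data — genomes of tens of kb at a chosen GC content,
# pairs at controlled identity, circular permutations, reverse complements,
# implanted shared regions, tandem duplications, N runs — so the whole
# pipeline is testable without downloads. All generators are pure functions
# of their arguments and the seed: the same inputs give byte-identical
# sequences without disturbing the caller's RNG stream.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random genome sequence
#'
#' I.i.d. bases with expected GC content `gc` (C and G equiprobable, likewise
#' A and T). Defaults emulate a typical T7-like phage genome: ~40 kb at
#' ~48% GC.
#'
#' @param length sequence length in bases (>= 1).
#' @param gc expected GC fraction in (0, 1).
#' @param seed integer seed; same seed, same sequence.
#' @return A single character string.
#' @export
generate_genome <- function(length = 39937L, gc = 0.484, seed = NULL) {
  if (length < 1L) input_stop("'length' must be >= 1")
  if (is.na(gc) || gc <= 0 || gc >= 1) input_stop("'gc' must be in (0, 1)")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Point-mutate a genome
#'
#' Substitution-only mutation: each base is independently replaced by one of
#' the three other bases with probability `p`. Length is preserved and the
#' expected pairwise identity to the original is exactly `1 - p`, which makes
#' this the driver for parameter-recovery tests. (No indel model: expected
#' identity stays analytic.)
#'
#' @param seq character string genome.
#' @param p per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return Mutated sequence, same length.
#' @export
mutate_genome <- function(seq, p, seed = NULL) {
  if (is.na(p) || p < 0 || p > 1) input_stop("'p' must be in [0, 1]")
  if (p == 0) return(seq)
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < p)
    if (length(hit) > 0L) {
      # pick uniformly among the 3 bases differing from the current one;
      # non-ACGT characters are substituted by a uniform random base
      cur <- match(ch[hit], DNA_BASES)           # NA for N/ambiguity codes
      shift <- sample.int(3L, length(hit), replace = TRUE)
      idx <- ifelse(is.na(cur), sample.int(4L, length(hit), replace = TRUE),
                    ((cur - 1L + shift) %% 4L) + 1L)
      ch[hit] <- DNA_BASES[idx]
    }
    paste(ch, collapse = "")
  })
}

#' Circularly permute a genome
#'
#' Linearizes the same circular sequence at a different origin: the result
#' starts at position `offset + 1` of the input. Intergenomic similarity is
#' expected to be invariant to this.
#'
#' @param seq character string genome.
#' @param offset rotation in bases, in `[0, length)`.
#' @return Rotated sequence.
#' @export
permute_genome <- function(seq, offset) {
  n <- nchar(seq)
  if (is.na(offset) || offset < 0L || offset >= n) {
    input_stop("'offset' must be in [0, genome length)")
  }
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, n), substr(seq, 1L, offset))
}

#' Reverse-complement a genome
#'
#' @param seq character string genome (IUPAC codes allowed).
#' @return The reverse complement; applying it twice returns the input.
#' @export
reverse_complement_genome <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Randomly shuffle the bases of a genome
#'
#' Emulates a sequence-scrambling control: base composition (and length) are
#' exactly preserved while all positional signal is destroyed.
#'
#' @param seq character string genome.
#' @param seed integer seed.
#' @return Shuffled sequence.
#' @export
scramble_genome <- function(seq, seed = NULL) {
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    paste(sample(ch), collapse = "")
  })
}

#' Implant a shared region into a genome
#'
#' Copies `region_length` bases of `donor` starting at `donor_start` into
#' `recipient` at `recipient_start` (replacing what was there), after
#' degrading the copy to the requested percent `identity` by substitution.
#' Used to probe the aligner's detection floor for short/diverged shared
#' regions between otherwise unrelated genomes.
#'
#' @param donor,recipient character string genomes.
#' @param region_length implant length in bases.
#' @param identity target identity of the implant to the donor region, in
#'   percent (0-100].
#' @param donor_start,recipient_start 1-based start positions (defaults:
#'   region centers).
#' @param seed integer seed (drives which bases are degraded).
#' @return The modified recipient sequence.
#' @export
implant_region <- function(donor, recipient, region_length, identity,
                           donor_start = NULL, recipient_start = NULL,
                           seed = NULL) {
  ld <- nchar(donor); lr <- nchar(recipient)
  if (region_length < 1L || region_length > ld || region_length > lr) {
    input_stop("'region_length' must fit inside both genomes")
  }
  if (is.na(identity) || identity <= 0 || identity > 100) {
    input_stop("'identity' must be in (0, 100] percent")
  }
  donor_start <- donor_start %||% ((ld - region_length) %/% 2L + 1L)
  recipient_start <- recipient_start %||% ((lr - region_length) %/% 2L + 1L)
  if (donor_start < 1L || donor_start + region_length - 1L > ld) {
    input_stop("'donor_start' out of bounds")
  }
  if (recipient_start < 1L || recipient_start + region_length - 1L > lr) {
    input_stop("'recipient_start' out of bounds")
  }
  region <- substr(donor, donor_start, donor_start + region_length - 1L)
  region <- mutate_genome(region, 1 - identity / 100, seed = seed)
  paste0(substr(recipient, 1L, recipient_start - 1L), region,
         substr(recipient, recipient_start + region_length, lr))
}

#' Tandem-duplicate a region of a genome
#'
#' Inserts a second copy of the region immediately after the original,
#' lengthening the genome. Because overlapping alignments are de-replicated
#' while the similarity stays normalized to the whole genome length, repeats
#' are expected to depress the similarity of the duplicated genome to its
#' single-copy relatives.
#'
#' @param seq character string genome.
#' @param start 1-based start of the region.
#' @param len region length in bases.
#' @return Sequence with the region duplicated in tandem.
#' @export
duplicate_region <- function(seq, start, len) {
  n <- nchar(seq)
  if (start < 1L || len < 1L || start + len - 1L > n) {
    input_stop("duplication region out of bounds")
  }
  region <- substr(seq, start, start + len - 1L)
  paste0(substr(seq, 1L, start + len - 1L), region,
         substr(seq, start + len, n))
}

#' Overwrite a stretch of a genome with N
#'
#' Emulates a scaffold-level draft genome: `len` bases starting at `pos` are
#' replaced by `N` (length unchanged), the situation [validate_genomes()]
#' warns about.
#'
#' @param seq character string genome.
#' @param pos 1-based start position.
#' @param len run length.
#' @return Modified sequence.
#' @export
insert_n_run <- function(seq, pos, len) {
  n <- nchar(seq)
  if (pos < 1L || len < 1L || pos + len - 1L > n) {
    input_stop("N run out of bounds")
  }
  paste0(substr(seq, 1L, pos - 1L), strrep("N", len),
         substr(seq, pos + len, n))
}

#' Build a synthetic hit table from a plan
#'
#' Constructs canonical alignment hits directly (no aligner), for exact,
#' aligner-free tests of the similarity core. The plan uses the internal
#' coordinate convention: 0-based half-open intervals.
#'
#' @param plan data frame with columns `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `n_ident`, and optionally `s_strand`
#'   (default `+`), `bitscore` (default `2 * n_ident`), `evalue` (default 0).
#' @param gs optional `genome_set` for bounds checking of the intervals.
#' @return Canonical hit data frame.
#' @export
synth_hit_table <- function(plan, gs = NULL) {
  if (nrow(plan) == 0L) return(empty_hits())
  need <- c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
            "n_ident")
  miss <- setdiff(need, names(plan))
  if (length(miss) > 0L) {
    input_stop(paste0("plan lacks column(s): ", paste(miss, collapse = ", ")))
  }
  hits <- data.frame(
    query_id = as.character(plan$query_id),
    subject_id = as.character(plan$subject_id),
    q_start = as.integer(plan$q_start), q_end = as.integer(plan$q_end),
    s_start = as.integer(plan$s_start), s_end = as.integer(plan$s_end),
    s_strand = if ("s_strand" %in% names(plan)) as.character(plan$s_strand)
               else "+",
    align_len = as.integer(pmax(plan$q_end - plan$q_start,
                                plan$s_end - plan$s_start)),
    n_ident = as.numeric(plan$n_ident),
    bitscore = if ("bitscore" %in% names(plan)) as.numeric(plan$bitscore)
               else 2 * as.numeric(plan$n_ident),
    evalue = if ("evalue" %in% names(plan)) as.numeric(plan$evalue) else 0,
    stringsAsFactors = FALSE
  )
  if (any(hits$q_start < 0L) || any(hits$q_end <= hits$q_start) ||
      any(hits$s_start < 0L) || any(hits$s_end <= hits$s_start)) {
    input_stop("plan intervals must be non-empty and 0-based half-open")
  }
  if (any(hits$n_ident > (hits$q_end - hits$q_start)) ||
      any(hits$n_ident > (hits$s_end - hits$s_start))) {
    input_stop("plan n_ident exceeds interval length")
  }
  if (any(hits$query_id == hits$subject_id)) {
    input_stop("plan contains self-hits")
  }
  if (!is.null(gs)) {
    lens <- genome_lengths(gs)
    unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(lens))
    if (length(unknown) > 0L) {
      input_stop(paste0("plan references unknown genome id(s): ",
                        paste(unknown, collapse = ", ")))
    }
    if (any(hits$q_end > lens[hits$query_id]) ||
        any(hits$s_end > lens[hits$subject_id])) {
      input_stop("plan intervals exceed genome bounds")
    }
  }
  hits
}

#' Generate a related pair of genomes plus variants
#'
#' Convenience wrapper used by tests and examples: a random ~40 kb genome, a
#' point-mutated partner at substitution rate `p`, and (optionally) a
#' circularly permuted and a reverse-complemented variant of that partner.
#'
#' @param length,gc,seed as in [generate_genome()].
#' @param p substitution rate of the partner.
#' @param variants also return `partner_perm` (rotation by ~1/3 of the
#'   genome) and `partner_rc`.
#' @return A [genome_set].
#' @export
fixture_pair <- function(length = 40000L, gc = 0.5, p = 0.05, seed = 1L,
                         variants = FALSE) {
  base <- generate_genome(length, gc, seed = seed)
  partner <- mutate_genome(base, p, seed = seed + 1L)
  seqs <- c(base = base, partner = partner)
  if (variants) {
    seqs <- c(seqs,
              partner_perm = permute_genome(partner, length %/% 3L),
              partner_rc = reverse_complement_genome(partner))
  }
  genome_set(seqs)
}
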
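# similarity_core: de-replication, the similarity/distance formulas, the
# indicators, and matrix assembly.

test_that("dereplicate_hits worked examples", {
  # non-overlapping hits: sums add
  h <- rbind(make_hit(0, 100, 100), make_hit(200, 300, 90))
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 190)
  expect_equal(s$aligned_query_bases, 200L)

  # partial overlap: weaker hit clipped, identity scaled proportionally
  h <- rbind(make_hit(0, 100, 100), make_hit(50, 150, 80))
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 100 + 80 * 50 / 100)  # 140
  expect_equal(s$aligned_query_bases, 150L)

  # full containment: inner hit dropped entirely
  h <- rbind(make_hit(0, 100, 100), make_hit(10, 60, 50))
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 100)
  expect_equal(s$aligned_query_bases, 100L)
  expect_equal(nrow(s$retained), 1L)

  # empty hit list
  s <- dereplicate_hits(make_hit(0, 1, 1)[0, ], query_id = "A",
                        subject_id = "B")
  expect_equal(s$ident_sum, 0)
  expect_equal(s$aligned_query_bases, 0L)
})

test_that("dereplication priority: strongest hit keeps its full interval", {
  # the 300-ident hit outranks the earlier-starting 100-ident hit
  h <- rbind(make_hit(0, 200, 100), make_hit(100, 400, 300))
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 300 + 100 * 100 / 200)
  expect_equal(s$aligned_query_bases, 400L)
  # n_ident tie broken by bitscore
  h <- rbind(make_hit(0, 100, 80, bitscore = 120),
             make_hit(50, 150, 80, bitscore = 200))
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 80 + 80 * 50 / 100)
})

test_that("re-used subject regions are capped (repeat de-replication)", {
  # two disjoint query regions (a tandem duplication) both aligning onto the
  # SAME subject region: the weaker copy's subject side is fully covered, so
  # it contributes 0 identical bases — each subject region counted once
  h <- rbind(
    make_hit(0, 1000, 990, s_start = 0, s_end = 1000),
    make_hit(1000, 2000, 980, s_start = 0, s_end = 1000)
  )
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 990)
  # both copies still count as aligned query bases (coverage, not credit)
  expect_equal(s$aligned_query_bases, 2000L)

  # partial subject overlap scales by the more-clipped side
  h <- rbind(
    make_hit(0, 1000, 990, s_start = 0, s_end = 1000),
    make_hit(1000, 2000, 980, s_start = 500, s_end = 1500)
  )
  s <- dereplicate_hits(h)
  expect_equal(s$ident_sum, 990 + 980 * 0.5)
})

test_that("dereplicate_hits rejects mixed pairs", {
  h <- rbind(make_hit(0, 10, 5), make_hit(0, 10, 5, subject_id = "C"))
  expect_error(dereplicate_hits(h), "single ordered pair",
               class = "igsim_input_error")
})

test_that("dereplicate_hits matches the brute-force painting oracle", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      h <- random_hit_set(n_hits = sample.int(20L, 1L), max_pos = 1000L)
      got <- dereplicate_hits(h)
      want <- oracle_dereplicate(h, query_len = 1000L)
      expect_equal(got$aligned_query_bases, want$aligned_query_bases)
      expect_equal(got$ident_sum, want$ident_sum, tolerance = 1e-12)
      # structural invariants
      expect_lte(got$ident_sum, got$aligned_query_bases + 1e-9)
    }
  })
})

test_that("pair_similarity implements the dual-length normalization", {
  # identical genomes
  expect_equal(pair_similarity(1000, 1000, 1000, 1000)$sim, 100)
  expect_equal(pair_similarity(1000, 1000, 1000, 1000)$dist, 0)
  # no alignment
  expect_equal(pair_similarity(0, 0, 500, 700)$sim, 0)
  expect_equal(pair_similarity(0, 0, 500, 700)$dist, 100)
  # 80% reciprocal coverage at 95% identity -> exactly 76
  L <- 40000
  id <- 0.95 * 0.8 * L
  expect_identical(pair_similarity(id, id, L, L)$sim, 76)
  # asymmetric lengths, hand arithmetic
  expect_equal(pair_similarity(90, 190, 100, 200)$sim, 28000 / 300)
  # precondition violations signal internal (upstream) bugs
  expect_error(pair_similarity(150, 0, 100, 200), class = "igsim_error")
  expect_error(pair_similarity(10, 10, 0, 10), class = "igsim_input_error")
})

test_that("pair_indicators computes aligned fractions and length ratio", {
  s_ab <- dereplicate_hits(make_hit(0, 100, 95))
  s_ba <- dereplicate_hits(make_hit(0, 150, 130, query_id = "B",
                                    subject_id = "A"))
  ind <- pair_indicators(s_ab, s_ba, l_a = 200, l_b = 300)
  expect_equal(ind$af_1, 0.5)
  expect_equal(ind$af_2, 0.5)
  expect_equal(ind$length_ratio, 2 / 3)
  # equal lengths -> ratio exactly 1
  expect_equal(pair_indicators(s_ab, s_ba, 300, 300)$length_ratio, 1)
  # mismatched directions rejected
  expect_error(pair_indicators(s_ab, s_ab, 200, 300),
               class = "igsim_input_error")
})

test_that("compute_matrix assembles a symmetric matrix with fixed diagonal", {
  gs <- gs_from(A = strrep("ACGT", 250), B = strrep("ACGT", 250),
                C = strrep("GATTACA", 100))
  # no hits at all -> identity-diagonal matrix
  res <- compute_matrix(gs, synth_hit_table(data.frame()))
  expect_equal(unname(res$sim), diag(3) * 100)
  expect_equal(nrow(res$pairs), 3L)
  expect_true(all(res$pairs$sim == 0))

  # full-identity pair under two ids
  plan <- data.frame(query_id = c("A", "B"), subject_id = c("B", "A"),
                     q_start = 0L, q_end = 1000L,
                     s_start = 0L, s_end = 1000L, n_ident = 1000)
  res <- compute_matrix(gs, synth_hit_table(plan, gs))
  expect_equal(res$sim["A", "B"], 100)
  expect_equal(res$sim["B", "A"], 100)
  expect_equal(res$af["A", "B"], 1)
  expect_equal(res$sim["A", "C"], 0)

  # hits in only one direction: sim = (id_ab + 0) * 100 / (l_a + l_b)
  plan <- data.frame(query_id = "A", subject_id = "C",
                     q_start = 0L, q_end = 400L,
                     s_start = 100L, s_end = 500L, n_ident = 350)
  res <- compute_matrix(gs, synth_hit_table(plan, gs))
  expect_equal(res$sim["A", "C"], 350 * 100 / (1000 + 700))
  expect_equal(res$af["A", "C"], 0.4)
  expect_equal(res$af["C", "A"], 0)
})

test_that("compute_matrix validates its inputs", {
  gs <- gs_from(A = strrep("ACGT", 10), B = strrep("ACGT", 10))
  expect_error(compute_matrix(gs, make_hit(0, 10, 10, subject_id = "ZZ")),
               "ZZ", class = "igsim_input_error")
  expect_error(
    compute_matrix(gs, make_hit(0, 10, 10, query_id = "A", subject_id = "A")),
    "self-hits", class = "igsim_input_error")
})

test_that("conservation invariants hold on randomized hit collections", {
  withr::with_seed(7, {
    lens <- c(A = 1000L, B = 1500L, C = 800L, D = 2000L)
    gs <- genome_set(vapply(lens, function(l) {
      generate_genome(l, 0.5, seed = sample.int(1e6, 1))
    }, character(1)))
    for (rep in 1:20) {
      pairs <- t(utils::combn(names(lens), 2L))
      rows <- list()
      for (r in seq_len(nrow(pairs))) {
        for (d in 1:2) {
          q <- pairs[r, d]; s <- pairs[r, 3 - d]
          if (stats::runif(1) < 0.3) next  # some directions empty
          n <- sample.int(5L, 1L)
          qs <- sample.int(lens[[q]] - 1L, n) - 1L
          qe <- qs + pmin(sample.int(200L, n), lens[[q]] - qs)
          ss <- sample.int(lens[[s]] - 200L, n) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = q, subject_id = s, q_start = qs, q_end = qe,
            s_start = ss, s_end = ss + (qe - qs),
            n_ident = floor((qe - qs) * stats::runif(n, 0.5, 1)))
        }
      }
      plan <- do.call(rbind, rows)
      plan <- plan[plan$n_ident >= 1, ]
      res <- compute_matrix(gs, synth_hit_table(plan, gs))
      expect_true(all(res$sim >= 0 & res$sim <= 100))
      expect_identical(res$sim, t(res$sim))
      expect_equal(unname(diag(res$sim)), rep(100, 4))
      expect_equal(res$pairs$dist, 100 - res$pairs$sim)
      expect_true(all(res$pairs$af_1 >= 0 & res$pairs$af_1 <= 1))
      expect_true(all(res$pairs$length_ratio > 0 &
                        res$pairs$length_ratio <= 1))
    }
  })
})

test_that("result is invariant to hit row order", {
  gs <- gs_from(A = generate_genome(2000, 0.5, seed = 1),
                B = generate_genome(2500, 0.5, seed = 2))
  plan <- data.frame(
    query_id = c("A", "A", "A", "B", "B"),
    subject_id = c("B", "B", "B", "A", "A"),
    q_start = c(0L, 50L, 500L, 0L, 100L),
    q_end = c(100L, 200L, 900L, 150L, 300L),
    s_start = c(0L, 40L, 600L, 0L, 90L),
    s_end = c(100L, 190L, 1000L, 150L, 290L),
    n_ident = c(95, 120, 380, 140, 180)
  )
  hits <- synth_hit_table(plan, gs)
  r1 <- compute_matrix(gs, hits)
  r2 <- compute_matrix(gs, hits[rev(seq_len(nrow(hits))), ])
  r3 <- compute_matrix(gs, hits[sample(seq_len(nrow(hits))), ])
  expect_identical(r1$sim, r2$sim)
  expect_identical(r1$sim, r3$sim)
  expect_equal(r1$pairs, r2$pairs)
})

test_that("duplicating a region depresses similarity (repeat caveat)", {
  base <- generate_genome(20000, 0.5, seed = 55)
  dup <- duplicate_region(base, start = 5001, len = 3000)
  gs <- gs_from(single = base, single2 = base, tandem = dup)
  hits <- run_all_vs_all(gs, param_set(1), threads = 1)
  res <- compute_matrix(gs, hits)
  # de-replication counts the repeat once, but the length normalization
  # uses the whole (longer) genome: similarity must drop
  expect_lt(res$sim["single", "tandem"], res$sim["single", "single2"])
  expect_lt(res$sim["single", "tandem"], 100)
  expect_equal(res$sim["single", "single2"], 100, tolerance = 0.01)
})
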
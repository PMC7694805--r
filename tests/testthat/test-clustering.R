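# clustering: linkage on D = 100 - sim, threshold cuts, matrix ordering.

sim_mat <- function(ids, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

set_sim <- function(m, a, b, v) {
  m[a, b] <- m[b, a] <- v
  m
}

test_that("two genomes merge at height 100 - sim", {
  m <- set_sim(sim_mat(c("A", "B")), "A", "B", 93.5)
  cl <- cluster_matrix(m)
  expect_equal(cl$hclust$height, 100 - 93.5)
  expect_setequal(cl$order, c("A", "B"))
})

test_that("hand-run complete linkage on three genomes", {
  # AB=90, AC=10, BC=10: A,B merge at D=10; C joins at D = max(90,90) = 90
  m <- sim_mat(c("A", "B", "C"))
  m <- set_sim(m, "A", "B", 90)
  m <- set_sim(m, "A", "C", 10)
  m <- set_sim(m, "B", "C", 10)
  cl <- cluster_matrix(m, "complete")
  expect_equal(sort(cl$hclust$height), c(10, 90))
  ct <- assign_clusters(m, cl, species_thr = 95, genus_thr = 70)
  # nothing is >= 95 similar: all singleton species
  expect_equal(length(unique(ct$species_cluster)), 3L)
  # A,B are 90 >= 70 similar: one genus; C separate
  expect_equal(length(unique(ct$genus_cluster)), 2L)
  g <- with(ct, split(genome_id, genus_cluster))
  expect_true(any(vapply(g, function(x) setequal(x, c("A", "B")), TRUE)))
})

test_that("identical duplicates merge at height 0 and sit adjacent", {
  m <- sim_mat(c("A", "B", "C"), fill = 20)
  m <- set_sim(m, "A", "C", 100)
  cl <- cluster_matrix(m)
  expect_equal(min(cl$hclust$height), 0)
  pos <- match(c("A", "C"), cl$order)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("threshold semantics: species and genus cuts", {
  ids <- c("A", "B", "C", "D", "E")
  m <- sim_mat(ids, fill = 10)
  m <- set_sim(m, "A", "B", 96)   # same species
  m <- set_sim(m, "C", "D", 80)   # same genus, different species
  ct <- assign_clusters(m)
  stopifnot(identical(attr(ct, "species_thr"), 95))
  sp <- with(ct, setNames(species_cluster, genome_id))
  ge <- with(ct, setNames(genus_cluster, genome_id))
  expect_equal(sp[["A"]], sp[["B"]])
  expect_equal(ge[["A"]], ge[["B"]])
  expect_false(sp[["C"]] == sp[["D"]])
  expect_equal(ge[["C"]], ge[["D"]])
  expect_equal(length(unique(sp)), 4L)  # AB, C, D, E
  expect_equal(length(unique(ge)), 3L)  # AB, CD, E
  # labels are consecutive integers in leaf order
  expect_equal(sort(unique(ct$species_cluster)), 1:4)
  expect_equal(ct$species_cluster, cummax(ct$species_cluster))
})

test_that("borderline chains stay split under complete linkage", {
  # A-B 96, B-C 96, but A-C 50: complete-linkage merges A,B at 4 and C only
  # at 50, so the species cut (h=5) keeps C out — a sub-cluster situation
  # the user must adjudicate
  m <- sim_mat(c("A", "B", "C"))
  m <- set_sim(m, "A", "B", 96)
  m <- set_sim(m, "B", "C", 96)
  m <- set_sim(m, "A", "C", 50)
  ct <- assign_clusters(m, species_thr = 95, genus_thr = 70)
  sp <- with(ct, setNames(species_cluster, genome_id))
  expect_equal(length(unique(sp)), 2L)
  expect_equal(sp[["A"]], sp[["B"]])
  expect_false(sp[["C"]] == sp[["A"]])
  # single linkage would chain them: method actually changes the answer
  ct_s <- assign_clusters(m, cluster_matrix(m, "single"),
                          species_thr = 95, genus_thr = 70)
  expect_equal(length(unique(ct_s$species_cluster)), 1L)
})

test_that("nestedness and refinement monotonicity on random matrices", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      n <- sample(3:8, 1)
      ids <- paste0("g", seq_len(n))
      m <- sim_mat(ids)
      v <- stats::runif(n * (n - 1) / 2, 0, 100)
      m[upper.tri(m)] <- v
      m <- pmax(m, t(m)); diag(m) <- 100
      method <- sample(c("complete", "average", "single"), 1)
      cl <- cluster_matrix(m, method)
      ct <- assign_clusters(m, cl)
      # species clusters nest inside genus clusters
      expect_equal(length(unique(paste(ct$species_cluster,
                                       ct$genus_cluster))),
                   length(unique(ct$species_cluster)))
      # raising a threshold never merges clusters
      for (thr in c(30, 60, 90)) {
        lo <- assign_clusters(m, cl, species_thr = thr, genus_thr = thr)
        hi <- assign_clusters(m, cl, species_thr = min(thr + 25, 100),
                              genus_thr = min(thr + 25, 100))
        expect_gte(length(unique(hi$species_cluster)),
                   length(unique(lo$species_cluster)))
      }
      # cut at 100: only exact duplicates co-cluster
      top <- assign_clusters(m, cl, species_thr = 100, genus_thr = 0)
      spl <- split(top$genome_id, top$species_cluster)
      for (grp in spl[lengths(spl) > 1]) {
        expect_true(all(m[grp, grp] == 100))
      }
      # cut at 0: one cluster
      expect_equal(length(unique(top$genus_cluster)), 1L)
    }
  })
})

test_that("order_matrix permutes rows and columns consistently", {
  ids <- c("A", "B", "C", "D")
  m <- sim_mat(ids)
  m[upper.tri(m)] <- c(10, 20, 30, 40, 50, 60)
  m <- pmax(m, t(m)); diag(m) <- 100
  expect_identical(order_matrix(m, ids), m)               # identity
  rev_ids <- rev(ids)
  expect_identical(order_matrix(order_matrix(m, rev_ids), rev_ids)[ids, ids],
                   m)                                      # involution
  perm <- c("C", "A", "D", "B")
  mo <- order_matrix(m, perm)
  expect_identical(mo, t(mo))
  expect_setequal(mo[upper.tri(mo)], m[upper.tri(m)])      # conservation
  expect_error(order_matrix(m, c("A", "B")), class = "igsim_input_error")
  expect_error(order_matrix(m, c("A", "A", "B", "C")),
               class = "igsim_input_error")
})

test_that("invalid matrices and thresholds are rejected", {
  m <- sim_mat(c("A", "B"))
  m["A", "B"] <- 50  # asymmetric
  expect_error(cluster_matrix(m), "symmetric", class = "igsim_input_error")
  m <- set_sim(sim_mat(c("A", "B")), "A", "B", 50)
  expect_error(cluster_matrix(m, "fancy"), "unknown",
               class = "igsim_input_error")
  expect_error(assign_clusters(m, species_thr = 70, genus_thr = 95),
               class = "igsim_input_error")
  expect_error(assign_clusters(m, species_thr = 101, genus_thr = 70),
               class = "igsim_input_error")
  bad <- m; diag(bad) <- 99
  expect_error(cluster_matrix(bad), "diagonal", class = "igsim_input_error")
})
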
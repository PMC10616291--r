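# Two-stage screen: categorization, fuzzy clustering, consistency selection
# and intersection.

test_that("category assignment follows the hyper/hypo/inconsistent rule", {
  expect_identical(assign_category(c("ns", "hyper", "ns")), "Hyper")
  expect_identical(assign_category(c("hypo", "ns")), "Hypo")
  expect_identical(assign_category(c("hyper", "hypo")), "Inconsistent")
  expect_identical(assign_category(c("ns", "ns")), "None")
  expect_error(assign_category(character(0)), "empty")
  expect_error(assign_category(c("hyper", "up")), "unknown")
  # matrix form agrees with row-wise application, and every called gene
  # lands in exactly one category
  set.seed(8)
  m <- matrix(sample(c("hyper", "hypo", "ns"), 300, TRUE,
                     prob = c(0.2, 0.2, 0.6)), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  cats <- assign_category(m)
  for (g in seq_len(60)) expect_identical(unname(cats[g]), assign_category(m[g, ]))
  called <- rowSums(m != "ns") > 0
  expect_true(all(cats[called] %in% c("Hyper", "Hypo", "Inconsistent")))
  expect_true(all(cats[!called] == "None"))
})

test_that("fuzzy c-means separates planted profile shapes", {
  set.seed(19)
  tps <- 5
  flat <- matrix(rep(2, 50 * tps) + rnorm(50 * tps, 0, 0.1), 50)
  peak <- matrix(rep(c(0.2, 3, 0.2, 0.2, 0.2), each = 50) +
                   rnorm(50 * tps, 0, 0.1), 50)
  prof <- rbind(flat, peak)
  rownames(prof) <- sprintf("g%03d", 1:100)
  cl <- cluster_time_profiles(prof, n_clusters = 2, seed = 4)
  truth <- rep(1:2, each = 50)
  expect_gte(adjusted_rand(cl$hard, truth), 0.9)
  # membership rows sum to one; objective non-increasing
  expect_equal(unname(rowSums(cl$membership)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(diff(cl$objective) <= 1e-8 * max(cl$objective)))
  # deterministic under a fixed seed
  cl2 <- cluster_time_profiles(prof, n_clusters = 2, seed = 4)
  expect_identical(cl$membership, cl2$membership)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  prof <- rbind(matrix(rnorm(40 * 4, 0, 0.2), 40),
                matrix(rnorm(40 * 4, 0, 0.2) + rep(c(0, 2, 0, -2), each = 40), 40))
  rownames(prof) <- sprintf("g%03d", 1:80)
  centered <- prof - rowMeans(prof)
  cl <- cluster_time_profiles(prof, n_clusters = 2, seed = 9)
  set.seed(9)
  ref <- e1071::cmeans(centered, centers = 2, m = 2)
  expect_gte(adjusted_rand(cl$hard, ref$cluster), 0.95)
  # z-scoring mode agrees with the reference implementation on z-profiles
  z <- t(apply(prof, 1, function(r) (r - mean(r)) / sd(r)))
  clz <- cluster_time_profiles(prof, n_clusters = 2, seed = 9, scale = "z")
  set.seed(9)
  refz <- e1071::cmeans(z, centers = 2, m = 2)
  expect_gte(adjusted_rand(clz$hard, refz$cluster), 0.95)
})

test_that("degenerate clustering inputs are handled symmetrically", {
  prof <- matrix(rep(c(1, 2, 3), each = 10), 10, byrow = FALSE)
  rownames(prof) <- sprintf("g%02d", 1:10)
  cl <- cluster_time_profiles(prof, n_clusters = 2, seed = 1)
  # all profiles identical: every membership is 1/2
  expect_equal(as.vector(cl$membership), rep(0.5, 20))
  # constant profiles standardize to the zero vector; under z-scoring the
  # undefined scale is flagged
  const <- matrix(5, 4, 3, dimnames = list(letters[1:4], NULL))
  clc <- cluster_time_profiles(const, n_clusters = 2, seed = 1)
  expect_equal(as.vector(clc$membership), rep(0.5, 8))
  expect_warning(cluster_time_profiles(const, n_clusters = 2, seed = 1,
                                       scale = "z"),
                 "constant")
  expect_error(cluster_time_profiles(prof[1, , drop = FALSE], n_clusters = 2),
               "fewer genes")
})

test_that("consistent-cluster selection follows the centroid sign rule", {
  prof <- rbind(matrix(1 + rnorm(20 * 3, 0, 0.05), 20),      # all-positive
                matrix(rep(c(-1, 1, -1), each = 20) +
                         rnorm(20 * 3, 0, 0.05), 20))        # sign-changing
  rownames(prof) <- sprintf("g%03d", 1:40)
  cl <- cluster_time_profiles(prof, n_clusters = 2, seed = 2)
  sel <- select_consistent(prof, cl, "Hyper")
  expect_setequal(sel, sprintf("g%03d", 1:20))
  # both clusters sign-changing: empty set
  prof2 <- rbind(matrix(rep(c(-1, 1, -1), each = 20) + rnorm(60, 0, 0.05), 20),
                 matrix(rep(c(1, -1, 1), each = 20) + rnorm(60, 0, 0.05), 20))
  rownames(prof2) <- sprintf("h%03d", 1:40)
  cl2 <- cluster_time_profiles(prof2, n_clusters = 2, seed = 2)
  expect_length(select_consistent(prof2, cl2, "Hyper"), 0)
  expect_error(select_consistent(prof, cl2, "Hyper"), "match")
})

test_that("candidate intersection is exact set algebra with provenance", {
  s <- list(a = c("a", "b", "c"), b = c("b", "c", "d"), c = c("c", "e"))
  res <- intersect_candidates(s)
  expect_identical(res$genes, "c")
  expect_identical(res$provenance, c("a", "b", "c"))
  expect_length(intersect_candidates(list(x = "a", y = "b"))$genes, 0)
  expect_error(intersect_candidates(list(a = "x")), "two sets")
  # brute-force membership oracle on random sets
  set.seed(3)
  universe <- sprintf("g%04d", 1:1000)
  sets <- lapply(1:3, function(i) sample(universe, 100))
  names(sets) <- c("s1", "s2", "s3")
  res2 <- intersect_candidates(sets)
  brute <- character(0)
  for (g in universe) {
    if (g %in% sets$s1 && g %in% sets$s2 && g %in% sets$s3) brute <- c(brute, g)
  }
  expect_setequal(res2$genes, brute)
  # subset property: never returns a gene absent from any stage
  for (nm in names(sets)) expect_true(all(res2$genes %in% sets[[nm]]))
})

test_that("end-to-end screen recovers planted consistent-hyper genes", {
  pl <- planted_signals(30, 15, 10, effect = 4)
  sim <- make_screen_sim(n_genes = 400, planted = pl, noise = 0.1, seed = 101)
  sc <- screen_two_stage(m6a_level_matrix(sim), seed = 101)
  truth <- pl$gene_id[pl$pattern == "consistent_hyper"]
  sens <- mean(truth %in% sc$candidates$genes)
  fdp <- if (length(sc$candidates$genes) > 0) {
    mean(!sc$candidates$genes %in% truth)
  } else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
  # candidates are a subset of every contributing stage set
  expect_true(all(sc$candidates$genes %in% sc$consistent_hyper))
  for (s2 in sc$stage2) expect_true(all(sc$candidates$genes %in% s2))
})

test_that("permuting gene order permutes screen outputs identically", {
  pl <- planted_signals(10, 5, 5, effect = 4)
  sim <- make_screen_sim(n_genes = 100, planted = pl, noise = 0.1, seed = 55)
  mat <- m6a_level_matrix(sim)
  calls <- differential_by_timepoint(mat)
  perm <- sample(nrow(mat$level))
  mat2 <- mat
  mat2$level <- mat$level[perm, ]
  mat2$quantity <- mat$quantity[perm, ]
  calls2 <- differential_by_timepoint(mat2)
  for (tp in names(calls)) {
    reord <- calls2[[tp]][match(calls[[tp]]$gene_id, calls2[[tp]]$gene_id), ]
    rownames(reord) <- NULL
    expect_equal(reord, calls[[tp]])
  }
})
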
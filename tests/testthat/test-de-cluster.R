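# NB moment/Wald differential expression and response-group clustering.

test_that("DE log2 fold changes follow the pseudocounted mean ratio", {
  # size factors fixed at 1: normalized means are the raw means
  m <- matrix(c(80, 75, 85,
                10, 11, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "up2"),
                              c("a1", "a2", "a3")))
  m <- rbind(m, m)  # 4 genes so BH has a family
  rownames(m) <- c("g1", "g2", "g3", "g4")
  m6 <- cbind(m, m)  # duplicate columns as group B
  colnames(m6) <- c(paste0("a", 1:3), paste0("b", 1:3))
  counts <- counts_tbl(m6)
  sf <- setNames(rep(1, 6), colnames(m6))

  # identical groups: LFC exactly 0, p ~ 1
  de0 <- nb_moment_de(counts, paste0("a", 1:3), paste0("b", 1:3),
                      size_factors = sf)
  expect_equal(de0$log2_fold_change, rep(0, 4))
  expect_true(all(de0$p_raw > 0.99))

  # planted ratio: mean A 80, mean B 10 -> LFC = log2(80.5 / 10.5)
  m2 <- matrix(c(80, 80, 80, 10, 10, 10,
                 50, 50, 50, 50, 50, 50), nrow = 2, byrow = TRUE,
               dimnames = list(c("hit", "null"),
                               c("a1", "a2", "a3", "b1", "b2", "b3")))
  de <- nb_moment_de(counts_tbl(m2), paste0("a", 1:3), paste0("b", 1:3),
                     size_factors = setNames(rep(1, 6), colnames(m2)))
  expect_equal(de$log2_fold_change[de$gene_id == "hit"],
               log2(80.5 / 10.5), tolerance = 1e-12)

  # swapping the groups negates the LFC exactly
  sw <- nb_moment_de(counts_tbl(m2), paste0("b", 1:3), paste0("a", 1:3),
                     size_factors = setNames(rep(1, 6), colnames(m2)))
  expect_equal(sw$log2_fold_change, -de$log2_fold_change)
  expect_equal(sw$p_raw, de$p_raw)

  expect_error(nb_moment_de(counts_tbl(m2), c("a1", "a2"), c("a2", "b1")),
               "disjoint")
  expect_error(nb_moment_de(counts_tbl(m2), "a1", paste0("b", 1:3)),
               "2 replicates")
})

test_that("DE keeps power on planted folds while controlling the FDR", {
  n_genes <- 1000
  n_planted <- 100
  power <- fdp <- numeric(20)
  for (s in 1:20) {
    mu <- rep(100, n_genes)
    counts <- withr::with_seed(s, {
      a <- sapply(1:3, function(i) rnbinom(n_genes, mu = mu, size = 1 / 0.05))
      mu_b <- mu
      mu_b[seq_len(n_planted)] <- mu_b[seq_len(n_planted)] * 4
      b <- sapply(1:3, function(i) rnbinom(n_genes, mu = mu_b, size = 1 / 0.05))
      cbind(a, b)
    })
    dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                             c(paste0("a", 1:3), paste0("b", 1:3)))
    # equal-depth libraries by construction: unit size factors
    de <- nb_moment_de(counts_tbl(counts), paste0("b", 1:3), paste0("a", 1:3),
                       size_factors = setNames(rep(1, 6), colnames(counts)))
    hits <- de$gene_id[!is.na(de$p_adj) & de$p_adj < 0.05]
    planted <- sprintf("g%04d", seq_len(n_planted))
    power[s] <- mean(planted %in% hits)
    fdp[s] <- sum(!(hits %in% planted)) / max(length(hits), 1)
  }
  expect_gte(mean(power), 0.8)
  expect_lte(mean(fdp), 0.08)
})

test_that("correlation distance has exact values and metric properties", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  d <- pearson_distance(counts_tbl(m))
  expect_equal(d["g1", "g2"], 0)           # duplicated profile
  expect_equal(d["g1", "g3"], 2)           # perfectly anti-correlated
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  # hand Pearson on an irregular 3-gene toy
  m2 <- matrix(c(1, 5, 2, 8,
                 2, 1, 9, 3,
                 7, 7, 1, 4), nrow = 3, byrow = TRUE,
               dimnames = list(c("x", "y", "z"), paste0("s", 1:4)))
  d2 <- pearson_distance(counts_tbl(m2))
  expect_equal(d2["x", "y"], 1 - cor(m2["x", ], m2["y", ]), tolerance = 1e-12)
  expect_equal(d2["x", "z"], 1 - cor(m2["x", ], m2["z", ]), tolerance = 1e-12)
  expect_true(all(d2 >= 0 & d2 <= 2))

  const <- counts_tbl(matrix(c(1, 1, 1, 1, 2, 3), 2, byrow = TRUE,
                             dimnames = list(c("c", "v"), paste0("s", 1:3))))
  expect_error(pearson_distance(const), "constant")
})

test_that("average linkage reproduces a hand-traced agglomeration", {
  # d(A,B)=1, d(C,D)=2, cross-block distances average to 6:
  # merges: {A,B}@1, {C,D}@2, {AB,CD}@mean(4,5,7,8)=6
  d <- matrix(c(0, 1, 4, 7,
                1, 0, 5, 8,
                4, 5, 0, 2,
                7, 8, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- hierarchical_cluster(d, "average")
  expect_equal(tree$height, c(1, 2, 6))
  expect_true(all(diff(tree$height) >= 0))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))

  # label permutation gives an isomorphic tree (equal cophenetic distances)
  perm <- c(3, 1, 4, 2)
  dp <- d[perm, perm]
  tp <- hierarchical_cluster(dp, "average")
  cp <- as.matrix(stats::cophenetic(tp))[LETTERS[1:4], LETTERS[1:4]]
  co <- as.matrix(stats::cophenetic(tree))[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, co)

  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("tree cuts produce the requested groups and recover planted blocks", {
  d <- matrix(c(0, 1, 4, 7,
                1, 0, 5, 8,
                4, 5, 0, 2,
                7, 8, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- hierarchical_cluster(d)
  expect_equal(nrow(dplyr::distinct(cut_clusters(tree, k = 4), cluster_id)), 4)
  expect_equal(nrow(dplyr::distinct(cut_clusters(tree, k = 1), cluster_id)), 1)
  expect_error(cut_clusters(tree, k = 9), "out of range")
  expect_error(cut_clusters(tree), "exactly one")

  # two planted correlation blocks, recovered exactly at k = 2
  t_grid <- seq(0, 2 * pi, length.out = 24)
  prof1 <- sin(t_grid)
  prof2 <- cos(3 * t_grid)
  rows <- withr::with_seed(77, {
    rbind(
      t(sapply(1:10, function(i) prof1 + rnorm(24, sd = 0.1))),
      t(sapply(1:10, function(i) prof2 + rnorm(24, sd = 0.1)))
    )
  })
  dimnames(rows) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:24))
  tree2 <- hierarchical_cluster(pearson_distance(counts_tbl(rows)))
  cl <- cut_clusters(tree2, k = 2)
  truth <- rep(1:2, each = 10)
  got <- cl$cluster_id[match(sprintf("g%02d", 1:20), cl$gene_id)]
  # adjusted Rand index against the planted partition, via mclust
  expect_equal(mclust::adjustedRandIndex(truth, got), 1)
  # singleton heights are 0; merged genes carry their last merge height
  expect_true(all(cl$linkage_height >= 0))
})

test_that("pairwise day-36 comparisons stack per-substrate tables", {
  catal <- generate_gene_catalog(200, seed = 61)
  des <- default_design(days = c(8, 36), sulfate = "plusS")
  sim <- simulate_counts(catal, des, sim_params(), seed = 62)
  de <- de_pairwise(sim$counts, sim$design)
  expect_setequal(unique(de$group_b), "none")
  expect_equal(sort(unique(de$group_a)),
               sort(setdiff(substrate_levels(), "none")))
  # activity-coupled genes dominate the significant set
  sig <- significant_genes(de)
  expect_gte(length(sig), 5)
  cats <- catal$category[match(sig, catal$gene_id)]
  expect_gt(mean(cats %in% activity_categories()), 0.5)

  all_pairs <- de_pairwise(sim$counts, sim$design, comparisons = "all_pairs")
  expect_equal(length(unique(all_pairs$comparison)), choose(6, 2))
})

test_that("dendrograms export as Newick", {
  d <- matrix(c(0, 1, 4, 7,
                1, 0, 5, 8,
                4, 5, 0, 2,
                7, 8, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- hierarchical_cluster(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, LETTERS[1:4])
})
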
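test_that("Dice similarity matches hand counts and conventions", {
  expect_equal(dice_similarity(c(1L, 1L, 0L), c(1L, 1L, 0L)), 1)
  expect_equal(dice_similarity(c(1L, 1L, 0L), c(1L, 0L, 1L)), 0.5)
  expect_equal(dice_similarity(c(1L, 0L), c(0L, 1L)), 0)
  # two all-absent profiles are defined identical
  expect_equal(dice_similarity(c(0L, 0L), c(0L, 0L)), 1)
  # missing positions are skipped pairwise-complete
  expect_equal(dice_similarity(c(1L, NA, 0L), c(1L, 1L, 1L)), 2 / 3)
  expect_error(dice_similarity(c(NA, 1L), c(1L, NA)), "no band scored")
  expect_error(dice_similarity(c(1L, 0L), c(1L)), "length")
})

test_that("similarity matrix equals the brute-force pairwise loop", {
  for (mr in c(0, 0.15)) {
    bm <- random_band_matrix(n = 10, n_bands = 50, seed = 4, missing_rate = mr)
    gs <- genetic_similarity(bm)$gs
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(gs[i, j], dice_similarity(bm$values[i, ], bm$values[j, ]),
                   tolerance = 1e-12)
    }
    expect_true(isSymmetric(unname(gs)))
  }
})

test_that("similarity reporting finds the extreme pairs", {
  bm <- random_band_matrix(n = 8, n_bands = 40, seed = 6)
  dup <- bm
  dup$values <- rbind(bm$values, A99 = bm$values[1, ])
  g <- glance(genetic_similarity(dup))
  expect_equal(g$gs_max, 1)
  expect_setequal(c(g$max_pair_1, g$max_pair_2), c("A01", "A99"))
})

test_that("UPGMA reproduces the hand-worked 3-taxon tree", {
  d <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(as.dist(d))
  # merge heights 0.2 then 0.6; ultrametric node depths half that
  expect_equal(tr$hclust$height, c(0.2, 0.6))
  depths <- ape::node.depth.edgelength(tr$phylo)
  expect_equal(max(depths), 0.3)
  cp <- as.matrix(stats::cophenetic(tr$hclust))
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.6)
  # ultrametric input is reproduced exactly
  expect_equal(cp[rownames(d), colnames(d)], d)
})

test_that("UPGMA agrees with an O(n^3) reference on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(6 * 4), 6)
    rownames(pts) <- letters[1:6]
    D <- as.matrix(dist(pts))
    tr <- upgma(as.dist(D))
    expect_equal(as.matrix(stats::cophenetic(tr$hclust)),
                 ref_upgma_cophenetic(D)[tr$hclust$labels, tr$hclust$labels],
                 tolerance = 1e-10)
  }
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("bootstrap supports behave at the extremes", {
  bm <- random_band_matrix(n = 6, n_bands = 40, seed = 8)
  one <- bootstrap_upgma(bm, replicates = 1, seed = 1)
  expect_true(all(one$support$support %in% c(0, 100)))
  # duplicated accessions are always sister
  dup <- bm
  dup$values <- rbind(bm$values, A99 = bm$values[1, ])
  tr <- bootstrap_upgma(dup, replicates = 100, seed = 2)
  pair <- tr$support[tr$support$members %in%
                       c("A01|A99", "A99|A01"), ]
  expect_equal(pair$support, 100)
})

test_that("well-separated groups get near-full bootstrap support", {
  bm <- two_pop_matrix(n_per = 5, n_diag = 25, n_shared = 5, seed = 3)
  tr <- bootstrap_upgma(bm, replicates = 200, seed = 7)
  grp_key <- paste(sprintf("A%02d", 1:5), collapse = "|")
  sup <- tr$support$support[tr$support$members == grp_key]
  expect_gte(sup, 95)
})

test_that("supports are stable under band reordering (within MC error)", {
  bm <- two_pop_matrix(n_per = 4, n_diag = 15, n_shared = 5, seed = 5)
  perm <- bm
  set.seed(1)
  ord <- sample(ncol(bm$values))
  perm$values <- bm$values[, ord]
  perm$band_to_primer <- bm$band_to_primer[ord]
  s1 <- bootstrap_upgma(bm, replicates = 300, seed = 11)$support
  s2 <- bootstrap_upgma(perm, replicates = 300, seed = 12)$support
  key <- paste(sprintf("A%02d", 1:4), collapse = "|")
  expect_lt(abs(s1$support[s1$members == key] - s2$support[s2$members == key]), 10)
})

test_that("clade cutting respects the similarity threshold", {
  d <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(as.dist(d))
  expect_equal(cut_clades(tr, 1)$clade, c(1, 2, 3))
  expect_equal(unique(cut_clades(tr, 0)$clade), 1)
  cl <- cut_clades(tr, 0.7)
  expect_equal(cl$clade[cl$accession_id %in% c("A", "B")], c(1, 1))
  expect_equal(length(unique(cl$clade)), 2L)
})

test_that("PCoA recovers collinear configurations and Euclidean geometry", {
  # points on a line: one positive axis carrying all variance
  x <- c(0, 1, 3, 7)
  ordn <- pcoa(dist(x))
  pct <- ordn$percent$percent
  expect_equal(sum(!is.na(pct)), 1L)
  expect_equal(pct[1], 100)
  # Euclidean input: full-dimension coordinates reproduce distances
  set.seed(2)
  pts <- matrix(rnorm(9 * 4), 9)
  ordn2 <- pcoa(dist(pts))
  coords <- as.matrix(ordn2$coordinates[, -1])
  expect_equal(as.numeric(dist(coords)), as.numeric(dist(pts)),
               tolerance = 1e-8)
  expect_equal(sum(ordn2$percent$percent, na.rm = TRUE), 100)
  # eigenvalues sorted decreasing over the positive axes
  pos <- ordn2$percent$eigenvalue[!is.na(ordn2$percent$percent)]
  expect_true(all(diff(pos) <= 1e-9))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("Dice distance is a semimetric and ordination is label-stable", {
  bm <- random_band_matrix(n = 7, n_bands = 30, seed = 9)
  d <- as.matrix(genetic_similarity(bm)$dist)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(diag(d), setNames(rep(0, 7), rownames(d)))
  perm <- subset_accessions(bm, rev(accession_ids(bm)))
  d2 <- as.matrix(genetic_similarity(perm)$dist)
  expect_equal(d2[rownames(d), colnames(d)], d)
})

test_that("Newick export carries branch lengths and supports", {
  bm <- two_pop_matrix(n_per = 3, n_diag = 10, n_shared = 2, seed = 2)
  tr <- bootstrap_upgma(bm, replicates = 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, accession_ids(bm))
  expect_true(any(nzchar(reread$node.label)))
})
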
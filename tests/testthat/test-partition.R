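test_that("group diversity handles fixed bands and the uHe identity", {
  vals <- cbind(P1.b1 = c(1L, 1L, 1L, 0L, 0L, 0L),
                P1.b2 = c(1L, 1L, 1L, 1L, 1L, 1L),
                P1.b3 = c(0L, 0L, 0L, 1L, 0L, 1L))
  rownames(vals) <- sprintf("A%d", 1:6)
  bm <- band_matrix(vals)
  meta <- tibble::tibble(accession_id = rownames(vals),
                         geo_group = rep(c("X", "Y"), each = 3))
  gd <- group_diversity(bm, meta)
  x <- gd[gd$geo_group == "X", ]
  # every band fixed within X
  expect_equal(x$na, 1)
  expect_equal(x$ne, 1)
  expect_equal(x$he, 0)
  expect_equal(x$hj, 0)
  expect_equal(x$pct_poly, 0)
  y <- gd[gd$geo_group == "Y", ]
  expect_gt(y$he, 0)
  expect_equal(y$uhe / y$he, 6 / 5)   # 2n/(2n-1) at n = 3
  expect_true(all(gd$na >= 1 & gd$na <= 2))
  expect_true(all(gd$ne >= 1))
})

test_that("group diversity refuses singleton groups and unknown accessions", {
  bm <- random_band_matrix(n = 5, n_bands = 20, seed = 1)
  meta <- tibble::tibble(accession_id = accession_ids(bm),
                         geo_group = c("X", "X", "X", "X", "lone"))
  expect_error(group_diversity(bm, meta), "size 1")
  expect_error(group_diversity(bm, meta[-1, ]), "missing from metadata")
})

test_that("AMOVA sums of squares match the deviation-based reference", {
  for (seed in 1:4) {
    bm <- random_band_matrix(n = 6, n_bands = 25, seed = seed)
    meta <- tibble::tibble(accession_id = accession_ids(bm),
                           geo_group = rep(c("X", "Y"), each = 3))
    fit <- amova(bm, meta, permutations = 0, bands = "all")
    ref <- ref_amova_ss(bm$values, rep(c("X", "Y"), each = 3))
    expect_equal(fit$table$ss[3], unname(ref["total"]), tolerance = 1e-9)
    expect_equal(fit$table$ss[2], unname(ref["within"]), tolerance = 1e-9)
    expect_equal(fit$table$ss[1], unname(ref["among"]), tolerance = 1e-9)
    # additivity and percentage closure
    expect_equal(fit$table$ss[1] + fit$table$ss[2], fit$table$ss[3],
                 tolerance = 1e-9)
    expect_equal(fit$table$pct[1] + fit$table$pct[2], 100)
    expect_lte(fit$phi_pt, 1)
  }
})

test_that("PhiPT hits its theoretical extremes", {
  # identical multisets of profiles in both groups: no differentiation
  base <- random_band_matrix(n = 4, n_bands = 30, seed = 7)
  vals <- rbind(base$values,
                `B1` = base$values[1, ], `B2` = base$values[2, ],
                `B3` = base$values[3, ], `B4` = base$values[4, ])
  bm <- band_matrix(vals)
  meta <- tibble::tibble(accession_id = rownames(vals),
                         geo_group = rep(c("X", "Y"), each = 4))
  fit <- amova(bm, meta, permutations = 199, seed = 3, bands = "all")
  expect_equal(fit$phi_pt, 0)
  expect_gt(fit$p_value, 0.5)
  # complementary fixed band sets: near-total differentiation
  sep <- two_pop_matrix(n_per = 4, n_diag = 20, n_shared = 0, seed = 1)
  meta2 <- tibble::tibble(accession_id = accession_ids(sep),
                          geo_group = rep(c("X", "Y"), each = 4))
  fit2 <- amova(sep, meta2, permutations = 199, seed = 3, bands = "all")
  expect_gt(fit2$phi_pt, 0.95)
  expect_lt(fit2$p_value, 0.05)
})

test_that("PhiPT is invariant to band order and p-values use +1 correction", {
  bm <- two_pop_matrix(n_per = 4, n_diag = 8, n_shared = 12, seed = 4)
  meta <- tibble::tibble(accession_id = accession_ids(bm),
                         geo_group = rep(c("X", "Y"), each = 4))
  fit <- amova(bm, meta, permutations = 99, seed = 5, bands = "all")
  perm <- bm
  set.seed(2)
  ord <- sample(ncol(bm$values))
  perm$values <- bm$values[, ord]
  perm$band_to_primer <- bm$band_to_primer[ord]
  fit_p <- amova(perm, meta, permutations = 99, seed = 5, bands = "all")
  expect_equal(fit_p$phi_pt, fit$phi_pt, tolerance = 1e-12)
  expect_gte(fit$p_value, 1 / 100)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(31)
  pvals <- replicate(150, {
    vals <- matrix(rbinom(12 * 20, 1L, rep(runif(20, 0.2, 0.8), each = 12)),
                   12, 20)
    dimnames(vals) <- list(sprintf("A%02d", 1:12), paste0("P1.b", 1:20))
    meta <- tibble::tibble(accession_id = rownames(vals),
                           geo_group = rep(c("X", "Y"), each = 6))
    amova(band_matrix(vals), meta, permutations = 199,
          seed = sample.int(1e6, 1), bands = "all")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise PhiPT agrees with two-group AMOVA and is label-symmetric", {
  sim <- simulate_bands(sim_config(n_per_group = c(5, 5, 4)), seed = 3)
  pp <- pairwise_phipt(sim$matrix, sim$meta, permutations = 49, seed = 2)
  expect_equal(nrow(pp), 3L)
  pair <- pp[pp$group_1 == "GSC" & pp$group_2 == "SCC", ]
  ids <- sim$meta$accession_id[sim$meta$geo_group %in% c("GSC", "SCC")]
  direct <- amova(subset_accessions(sim$matrix, ids), sim$meta,
                  permutations = 0)
  expect_equal(pair$phi_pt, direct$phi_pt, tolerance = 1e-12)
  # relabeling the groups leaves PhiPT unchanged
  meta_sw <- sim$meta
  meta_sw$geo_group <- chartr("XS", "SX", meta_sw$geo_group)
  pp_sw <- pairwise_phipt(sim$matrix, meta_sw, permutations = 0)
  expect_setequal(round(pp_sw$phi_pt, 10), round(pp$phi_pt, 10))
})

test_that("Nei group distance is zero for identical groups and symmetric", {
  base <- random_band_matrix(n = 4, n_bands = 30, seed = 9)
  vals <- rbind(base$values, `B1` = base$values[1, ], `B2` = base$values[2, ],
                `B3` = base$values[3, ], `B4` = base$values[4, ])
  bm <- band_matrix(vals)
  meta <- tibble::tibble(accession_id = rownames(vals),
                         geo_group = rep(c("X", "Y"), each = 4))
  nd <- nei_group_distance(bm, meta)
  expect_equal(nd$distance, 0, tolerance = 1e-12)
  expect_equal(nd$identity, 1, tolerance = 1e-12)
})

test_that("Nei distance matches a hand computation on a two-band toy", {
  # group X: band freqs (0.5, 0); group Y: (0, 0.5)
  vals <- cbind(P1.b1 = c(1L, 0L, 0L, 0L), P1.b2 = c(0L, 0L, 1L, 0L))
  rownames(vals) <- c("x1", "x2", "y1", "y2")
  bm <- band_matrix(vals)
  meta <- tibble::tibble(accession_id = rownames(vals),
                         geo_group = c("X", "X", "Y", "Y"))
  nd <- nei_group_distance(bm, meta)
  q_poly <- sqrt(0.5); p_poly <- 1 - q_poly
  jxx <- mean(c(p_poly^2 + q_poly^2, 1))          # band1 segregating, band2 absent
  jxy <- mean(c(p_poly * 0 + q_poly * 1, 0 * p_poly + 1 * q_poly))
  d_hand <- -log(jxy / sqrt(jxx * jxx))
  expect_equal(nd$distance, d_hand, tolerance = 1e-12)
})

test_that("AMOVA tidiers expose the partition table", {
  sim <- simulate_bands(sim_config(n_per_group = c(5, 4, 3)), seed = 5)
  fit <- amova(sim$matrix, sim$meta, permutations = 49, seed = 1)
  td <- tidy(fit)
  expect_equal(td$source, c("Among groups", "Within groups", "Total"))
  expect_equal(td$df, c(2, 9, 11))
  g <- glance(fit)
  expect_equal(g$pct_among + g$pct_within, 100)
})
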
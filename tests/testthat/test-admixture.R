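test_that("K = 1 collapses to the no-structure model", {
  bm <- random_band_matrix(n = 6, n_bands = 20, seed = 1)
  fit <- fit_admixture(bm, k = 1, burnin = 50, sweeps = 300, thin = 5,
                       seed = 3, bands = "all")
  expect_equal(unname(fit$q[, 1]), rep(1, 6))
  expect_true(is.finite(fit$ln_pd))
  expect_true(all(fit$f > 0 & fit$f < 1))
})

test_that("sampler input validation", {
  bm <- random_band_matrix(n = 4, n_bands = 10, seed = 2)
  expect_error(fit_admixture(bm, k = 5, bands = "all"), "exceeds")
  expect_error(fit_admixture(bm, k = 2, burnin = 100, sweeps = 100,
                             bands = "all"), "exceed")
})

test_that("two complementary populations are recovered as pure clusters", {
  bm <- two_pop_matrix(n_per = 6, n_diag = 25, n_shared = 5, seed = 2)
  fit <- fit_admixture(bm, k = 2, burnin = 300, sweeps = 1500, thin = 5,
                       seed = 4, bands = "all")
  q1 <- fit$q[1:6, ]
  q2 <- fit$q[7:12, ]
  # every accession pure, partition matching truth up to label swap
  expect_true(all(apply(fit$q, 1, max) >= 0.95))
  lead <- which.max(q1[1, ])
  expect_true(all(apply(q1, 1, which.max) == lead))
  expect_true(all(apply(q2, 1, which.max) == 3 - lead))
})

test_that("duplicated accessions get matching memberships", {
  bm <- two_pop_matrix(n_per = 4, n_diag = 15, n_shared = 5, seed = 6)
  dup <- bm
  dup$values <- rbind(bm$values, A99 = bm$values[1, ])
  fit <- fit_admixture(dup, k = 2, burnin = 300, sweeps = 1800, thin = 5,
                       seed = 9, bands = "all")
  expect_lt(max(abs(fit$q["A01", ] - fit$q["A99", ])), 0.05)
})

test_that("fits are reproducible from the seed", {
  bm <- random_band_matrix(n = 8, n_bands = 25, seed = 3)
  f1 <- fit_admixture(bm, 2, burnin = 50, sweeps = 250, thin = 5, seed = 11,
                      bands = "all")
  f2 <- fit_admixture(bm, 2, burnin = 50, sweeps = 250, thin = 5, seed = 11,
                      bands = "all")
  expect_identical(f1$ln_pd, f2$ln_pd)
  expect_identical(f1$q, f2$q)
})

test_that("the scan produces one record per (K, run) with distinct seeds", {
  bm <- random_band_matrix(n = 8, n_bands = 20, seed = 4)
  scan <- admixture_scan(bm, k_range = 2:4, runs = 4, seed = 21,
                         burnin = 20, sweeps = 120, thin = 5, bands = "all")
  expect_equal(nrow(scan), 12L)
  expect_equal(anyDuplicated(scan$seed), 0L)
  scan2 <- admixture_scan(bm, k_range = 2:4, runs = 4, seed = 21,
                          burnin = 20, sweeps = 120, thin = 5, bands = "all")
  expect_identical(scan$ln_pd, scan2$ln_pd)
  expect_error(admixture_scan(bm, runs = 1), "at least 2 runs")
})

test_that("delta-K algebra follows its definition", {
  # hand-built scan: means -10, -6, -5, -4.8 at K = 2..5
  means <- c(-10, -6, -5, -4.8)
  scan <- tidyr::expand_grid(k = 2:5, run = 1:3)
  scan$ln_pd <- means[scan$k - 1] + c(-0.2, 0, 0.2)[scan$run]
  ev <- evanno_delta_k(scan)
  expect_equal(ev$mean_ln_pd, means)
  expect_equal(ev$l_prime, c(NA, 4, 1, 0.2))
  expect_equal(ev$l_second, c(NA, 3, 0.8, NA))
  expect_equal(ev$delta_k[2], 3 / sd(c(-0.2, 0, 0.2) - 6), tolerance = 1e-12)
  expect_equal(attr(ev, "best_k"), 3)
  g <- glance(ev)
  expect_equal(g$best_k, 3)
})

test_that("linear likelihood profiles select no K", {
  scan <- tidyr::expand_grid(k = 2:6, run = 1:3)
  scan$ln_pd <- -10 * scan$k + c(-0.5, 0, 0.5)[scan$run]
  ev <- evanno_delta_k(scan)
  expect_true(all(ev$delta_k[!is.na(ev$delta_k)] == 0))
  expect_true(is.na(attr(ev, "best_k")))
})

test_that("zero run-to-run sd is flagged infinite with a warning", {
  scan <- tidyr::expand_grid(k = 2:4, run = 1:2)
  scan$ln_pd <- c(-30, -30, -20, -20, -18, -18)[order(order(scan$k))]
  scan$ln_pd <- rep(c(-30, -20, -18), each = 2)
  expect_warning(ev <- evanno_delta_k(scan), "zero run-to-run sd")
  expect_true(is.infinite(ev$delta_k[2]))
})

test_that("evanno rejects sparse or gappy scans", {
  scan <- tidyr::expand_grid(k = c(2, 4, 5), run = 1:2)
  scan$ln_pd <- rnorm(nrow(scan))
  expect_error(evanno_delta_k(scan), "consecutive")
  expect_error(evanno_delta_k(scan[scan$k == 2, ]), "at least 3")
})

test_that("purity calls apply the 0.8 threshold and group percentages", {
  q <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.15, 0.85))
  rownames(q) <- c("a", "b", "c")
  colnames(q) <- c("q1", "q2")
  fit <- structure(list(q = q, f = matrix(0.5, 2, 1), k = 2),
                   class = "admixture_fit")
  pc <- purity_calls(fit)
  expect_equal(pc$cluster, c(1L, 1L, 2L))
  expect_equal(pc$pure, c(TRUE, FALSE, TRUE))
  # 6 pure out of 9 -> 66.67%
  q9 <- cbind(c(rep(0.95, 6), rep(0.6, 3)), c(rep(0.05, 6), rep(0.4, 3)))
  rownames(q9) <- paste0("s", 1:9)
  fit9 <- structure(list(q = q9, k = 2), class = "admixture_fit")
  meta <- tibble::tibble(accession_id = rownames(q9), geo_group = "SCC")
  pc9 <- purity_calls(fit9, meta)
  expect_equal(round(attr(pc9, "group_summary")$pct_pure, 2), 66.67)
})

test_that("run alignment matches permuted cluster columns", {
  bm <- two_pop_matrix(n_per = 5, n_diag = 20, n_shared = 5, seed = 8)
  f1 <- fit_admixture(bm, 2, burnin = 200, sweeps = 1000, thin = 5, seed = 1,
                      bands = "all")
  f2 <- f1
  f2$q <- f2$q[, 2:1]
  colnames(f2$q) <- c("q1", "q2")
  f2$f <- f2$f[2:1, ]
  aligned <- align_runs(list(f1, f2))
  expect_equal(aligned[[2]]$q, f1$q)
})
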
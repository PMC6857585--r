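# shared fixture builders; everything generated in code

random_band_matrix <- function(n = 10, n_bands = 50, seed = 1, missing_rate = 0,
                               n_primers = 5) {
  set.seed(seed)
  vals <- matrix(rbinom(n * n_bands, 1L, runif(n_bands, 0.1, 0.9)[rep(seq_len(n_bands), each = n)]),
                 n, n_bands)
  if (missing_rate > 0) vals[runif(n * n_bands) < missing_rate] <- NA_integer_
  primer <- rep_len(paste0("P", seq_len(n_primers)), n_bands)
  bids <- paste0(primer, ".b", stats::ave(seq_len(n_bands), primer, FUN = seq_along))
  dimnames(vals) <- list(sprintf("A%02d", seq_len(n)), bids)
  band_matrix(vals, band_to_primer = stats::setNames(primer, bids))
}

# two groups fixed for complementary band sets, plus shared noise bands
two_pop_matrix <- function(n_per = 5, n_diag = 20, n_shared = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  g1 <- cbind(matrix(1L, n_per, n_diag), matrix(0L, n_per, n_diag))
  g2 <- cbind(matrix(0L, n_per, n_diag), matrix(1L, n_per, n_diag))
  shared <- matrix(rbinom(n * n_shared, 1L, 0.5), n, n_shared)
  vals <- cbind(rbind(g1, g2), shared)
  colnames(vals) <- paste0("P1.b", seq_len(ncol(vals)))
  rownames(vals) <- sprintf("A%02d", seq_len(n))
  band_matrix(vals)
}

two_pop_meta <- function(n_per = 5) {
  tibble::tibble(
    accession_id = sprintf("A%02d", seq_len(2 * n_per)),
    geo_group = rep(c("N", "S"), each = n_per),
    latitude = rep(c(44, 32), each = n_per),
    longitude = rep(c(84, 102), each = n_per),
    altitude = rep(c(1000, 3000), each = n_per),
    mat = rep(c(6, 8), each = n_per),
    map_mm = rep(c(300, 700), each = n_per),
    apg_mm = rep(c(200, 500), each = n_per)
  )
}

# independent O(n^3) UPGMA reference returning the cophenetic matrix
ref_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labs <- rownames(D)
  clusters <- lapply(seq_len(n), identity)
  d <- D
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b && d[active[a], active[b]] < bd) {
          bd <- d[active[a], active[b]]; best <- c(active[a], active[b])
        }
      }
    }
    i <- best[1]; j <- best[2]
    mi <- clusters[[i]]; mj <- clusters[[j]]
    coph[mi, mj] <- bd; coph[mj, mi] <- bd
    ni <- length(mi); nj <- length(mj)
    for (k in setdiff(active, best)) {
      d[i, k] <- d[k, i] <- (ni * d[i, k] + nj * d[j, k]) / (ni + nj)
    }
    clusters[[i]] <- c(mi, mj)
    active <- setdiff(active, j)
  }
  coph
}

# AMOVA sums of squares straight from the deviation definition
ref_amova_ss <- function(m, groups) {
  xbar <- colMeans(m)
  ss_total <- sum(sweep(m, 2, xbar)^2)
  ss_within <- sum(vapply(split(seq_len(nrow(m)), groups), function(idx) {
    gb <- colMeans(m[idx, , drop = FALSE])
    sum(sweep(m[idx, , drop = FALSE], 2, gb)^2)
  }, numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

write_temp_matrix_csv <- function(text) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(text, path)
  path
}
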
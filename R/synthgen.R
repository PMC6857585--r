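#' Configuration for the synthetic band-matrix generator
#'
#' Defaults emulate the study design the package targets: 25 accessions in 3
#' geographic groups of 13, 9 and 3, genotyped with 35 primers (30 EST-SSR,
#' 5 G-SSR) amplifying roughly 250 bands in total, with moderate group
#' differentiation. Group divergence follows a Balding-Nichols island model:
#' each band has an ancestral frequency drawn from `base_freq_dist =
#' Beta(a, b)`, and each group's frequency is drawn from
#' `Beta(pi (1-F)/F, (1-pi)(1-F)/F)` so that `F` (`divergence`) is the
#' expected differentiation.
#'
#' @param n_groups Number of geographic groups.
#' @param n_per_group Accessions per group (recycled to `n_groups`).
#' @param n_primers Number of primers.
#' @param bands_per_primer Integer range (min, max) of bands per primer,
#'   drawn uniformly.
#' @param prop_est Proportion of primers labelled `"EST-SSR"` (the rest
#'   `"G-SSR"`).
#' @param divergence Balding-Nichols `F` in \[0, 1).
#' @param base_freq_dist `c(a, b)` of the ancestral-frequency Beta.
#' @param admixture_alpha Optional Dirichlet concentration; when set, each
#'   accession's group memberships are Dirichlet-drawn (centred on its own
#'   group) and its band frequencies are the membership-weighted mixture.
#' @param ibd_strength Slope coupling latitude to band-frequency drift,
#'   producing isolation by distance when positive.
#' @param env_coupling Logical; when `TRUE` environmental variables differ by
#'   group mean, when `FALSE` they share one mean (noise only).
#' @param missing_rate Fraction of cells masked as missing, in \[0, 0.5\].
#' @param coding `"haploid"` (band presence drawn directly from the band
#'   frequency) or `"dominant"` (frequency interpreted as a dominant allele
#'   frequency; presence iff at least one dominant allele under HWE).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3, n_per_group = c(13, 9, 3),
                       n_primers = 35, bands_per_primer = c(4, 11),
                       prop_est = 30 / 35,
                       divergence = 0.2, base_freq_dist = c(1.2, 1.8),
                       admixture_alpha = NULL, ibd_strength = 0,
                       env_coupling = TRUE, missing_rate = 0,
                       coding = c("haploid", "dominant")) {
  coding <- match.arg(coding)
  n_per_group <- rep_len(n_per_group, n_groups)
  stopifnot(n_groups >= 1, all(n_per_group >= 1), n_primers >= 1,
            length(bands_per_primer) == 2, bands_per_primer[1] >= 1,
            divergence >= 0, divergence < 1,
            missing_rate >= 0, missing_rate <= 0.5)
  if (any(base_freq_dist <= 0)) stop("invalid Beta parameters", call. = FALSE)
  structure(
    list(n_groups = n_groups, n_per_group = n_per_group, n_primers = n_primers,
         bands_per_primer = bands_per_primer, prop_est = prop_est,
         divergence = divergence, base_freq_dist = base_freq_dist,
         admixture_alpha = admixture_alpha, ibd_strength = ibd_strength,
         env_coupling = env_coupling, missing_rate = missing_rate,
         coding = coding),
    class = "sim_config"
  )
}

# group centroids and environmental means for up to 6 groups; values chosen
# to resemble the western-China collection sites the generator emulates
sim_geo_defaults <- function(n_groups) {
  lat <- c(44, 32, 36, 40, 29, 47)[seq_len(n_groups)]
  lon <- c(84, 102, 103, 95, 99, 88)[seq_len(n_groups)]
  alt <- c(1200, 3400, 2900, 2200, 3800, 900)[seq_len(n_groups)]
  mat <- c(6, 7, 5, 4, 6, 5)[seq_len(n_groups)]
  map <- c(300, 700, 550, 400, 650, 250)[seq_len(n_groups)]
  apg <- c(200, 500, 420, 280, 480, 170)[seq_len(n_groups)]
  list(lat = lat, lon = lon, alt = alt, mat = mat, map = map, apg = apg)
}

#' Simulate a band matrix, metadata and ground truth
#'
#' See [sim_config()] for the generative model. Outputs are byte-identical
#' for identical `(config, seed)`.
#'
#' @param config A `sim_config` (default: [sim_config()]).
#' @param seed Integer seed.
#' @return A list of class `band_sim` with components `matrix` (a
#'   [band_matrix()]), `meta` (metadata tibble) and `truth` (ancestral and
#'   group band frequencies, per-accession admixture `q`, the divergence
#'   parameter, group environmental means).
#' @export
simulate_bands <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  k <- config$n_groups
  n_i <- config$n_per_group
  n <- sum(n_i)
  group_labels <- paste0("G", seq_len(k))
  if (k == 3L) group_labels <- c("XJC", "SCC", "GSC")
  grp <- rep(group_labels, n_i)
  acc <- sprintf("Ee%02d", seq_len(n))

  bpp <- sample(seq(config$bands_per_primer[1], config$bands_per_primer[2]),
                config$n_primers, replace = TRUE)
  n_est <- round(config$prop_est * config$n_primers)
  primer_ids <- c(sprintf("ES%02d", seq_len(n_est)),
                  sprintf("GS%02d", seq_len(config$n_primers - n_est)))
  primer_class <- stats::setNames(
    c(rep("EST-SSR", n_est), rep("G-SSR", config$n_primers - n_est)),
    primer_ids)
  band_ids <- unlist(lapply(seq_len(config$n_primers), function(i) {
    paste0(primer_ids[i], ".b", seq_len(bpp[i]))
  }))
  b2p <- stats::setNames(rep(primer_ids, bpp), band_ids)
  B <- length(band_ids)

  pi_b <- stats::rbeta(B, config$base_freq_dist[1], config$base_freq_dist[2])
  pi_b <- pmin(pmax(pi_b, 1e-4), 1 - 1e-4)
  F <- config$divergence
  group_freq <- if (F > 0) {
    t(vapply(seq_len(k), function(g) {
      stats::rbeta(B, pi_b * (1 - F) / F, (1 - pi_b) * (1 - F) / F)
    }, numeric(B)))
  } else {
    matrix(pi_b, k, B, byrow = TRUE)
  }
  group_freq <- pmin(pmax(group_freq, 1e-4), 1 - 1e-4)
  rownames(group_freq) <- group_labels

  geo <- sim_geo_defaults(k)
  g_idx <- match(grp, group_labels)
  lat <- geo$lat[g_idx] + stats::rnorm(n, 0, 1)
  lon <- geo$lon[g_idx] + stats::rnorm(n, 0, 1)

  # admixture proportions
  q <- matrix(0, n, k, dimnames = list(acc, group_labels))
  if (is.null(config$admixture_alpha)) {
    q[cbind(seq_len(n), g_idx)] <- 1
  } else {
    a0 <- config$admixture_alpha
    for (i in seq_len(n)) {
      a <- rep(a0, k)
      a[g_idx[i]] <- a0 + 1
      g <- stats::rgamma(k, a)
      q[i, ] <- g / sum(g)
    }
  }
  p_acc <- q %*% group_freq

  # isolation by distance: a latitude gradient shared by nearby accessions
  if (config$ibd_strength > 0) {
    eta <- stats::rnorm(B)
    shift <- config$ibd_strength * outer(lat - mean(lat), eta)
    p_acc <- stats::plogis(stats::qlogis(pmin(pmax(p_acc, 1e-6), 1 - 1e-6)) + shift)
  }

  pres_prob <- if (config$coding == "dominant") 1 - (1 - p_acc)^2 else p_acc
  vals <- matrix(stats::rbinom(n * B, 1L, pres_prob), n, B,
                 dimnames = list(acc, band_ids))
  if (config$missing_rate > 0) {
    vals[stats::runif(n * B) < config$missing_rate] <- NA_integer_
  }

  env_mean <- if (config$env_coupling) {
    cbind(alt = geo$alt, mat = geo$mat, map = geo$map, apg = geo$apg)
  } else {
    matrix(c(mean(geo$alt), mean(geo$mat), mean(geo$map), mean(geo$apg)),
           k, 4, byrow = TRUE, dimnames = list(NULL, c("alt", "mat", "map", "apg")))
  }
  meta <- tibble::tibble(
    accession_id = acc,
    geo_group = grp,
    latitude = lat,
    longitude = lon,
    altitude = env_mean[g_idx, "alt"] + stats::rnorm(n, 0, 100),
    mat = env_mean[g_idx, "mat"] + stats::rnorm(n, 0, 0.5),
    map_mm = env_mean[g_idx, "map"] + stats::rnorm(n, 0, 30),
    apg_mm = env_mean[g_idx, "apg"] + stats::rnorm(n, 0, 20)
  )
  structure(
    list(
      matrix = band_matrix(vals, band_to_primer = b2p, primer_class = primer_class),
      meta = meta,
      truth = list(ancestral_freq = pi_b, group_freq = group_freq, q = q,
                   divergence = F, env_means = env_mean,
                   group_labels = group_labels)
    ),
    class = "band_sim"
  )
}

#' @export
print.band_sim <- function(x, ...) {
  cat(sprintf("<band_sim> %d accessions (%s), %d bands, divergence F = %.2f\n",
              nrow(x$matrix$values),
              paste(table(x$meta$geo_group)[unique(x$meta$geo_group)], collapse = "+"),
              ncol(x$matrix$values), x$truth$divergence))
  invisible(x)
}

#' Build a band matrix from prescribed band frequencies
#'
#' A fixture builder: in exact mode each band gets exactly `round(freq * n)`
#' presences (which must match `freq` to within rounding error), laid out
#' deterministically over the first accessions; in sampled mode presences are
#' Bernoulli draws.
#'
#' @param freqs Numeric vector of target band frequencies.
#' @param n Number of accessions.
#' @param exact Logical; exact placement (default) or Bernoulli sampling.
#' @param seed Seed for sampled mode.
#' @param primer_ids Optional primer id per band (default one shared primer).
#' @param primer_class Optional named class vector for the primers.
#' @return A [band_matrix()].
#' @export
band_matrix_from_frequencies <- function(freqs, n, exact = TRUE, seed = 1L,
                                         primer_ids = NULL, primer_class = NULL) {
  check_freq(freqs)
  B <- length(freqs)
  if (is.null(primer_ids)) primer_ids <- rep("P1", B)
  band_ids <- paste0(primer_ids, ".b", stats::ave(seq_len(B), primer_ids,
                                                  FUN = seq_along))
  if (exact) {
    kk <- freqs * n
    if (any(abs(kk - round(kk)) > 1e-9)) {
      stop("frequency not representable as k/", n, " in exact mode", call. = FALSE)
    }
    kk <- as.integer(round(kk))
    vals <- vapply(kk, function(ones) c(rep(1L, ones), rep(0L, n - ones)),
                   integer(n))
  } else {
    set.seed(seed)
    vals <- vapply(freqs, function(p) stats::rbinom(n, 1L, p), integer(n))
  }
  dimnames(vals) <- list(sprintf("A%02d", seq_len(n)), band_ids)
  band_matrix(vals, band_to_primer = stats::setNames(primer_ids, band_ids),
              primer_class = primer_class)
}
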
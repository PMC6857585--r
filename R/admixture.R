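#' Bayesian admixture model for binary band profiles
#'
#' A Gibbs sampler for a simplified STRUCTURE-style admixture model that
#' treats each band as a haploid biallelic locus: the latent cluster of
#' origin of accession `i` at band `b` is `z[i,b] ~ Categorical(q[i, ])`,
#' and the observed presence is `x[i,b] | z ~ Bernoulli(f[z, b])`. Conjugate
#' updates are used throughout: `f[k,b] | z ~ Beta(1 + ones, 1 + zeros)` and
#' `q[i, ] | z ~ Dirichlet(alpha + counts)`. Reported `q` and `f` are
#' posterior means over kept sweeps; `ln_pd` is the STRUCTURE-style model
#' evidence proxy, the mean per-sweep log-likelihood minus half its variance.
#'
#' Missing cells contribute nothing to the likelihood (their latent origin is
#' drawn from `q` alone and they are excluded from the frequency counts).
#'
#' @param x A `band_matrix`; only its polymorphic bands are used.
#' @param k Number of clusters (>= 1, <= number of accessions).
#' @param burnin Discarded initial sweeps.
#' @param sweeps Total sweeps (must exceed `burnin`).
#' @param thin Keep every `thin`-th post-burnin sweep.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration of the admixture prior (default 1).
#' @param bands `"polymorphic"` (default) or `"all"`.
#' @param keep_z Also accumulate posterior cluster-origin frequencies per
#'   cell (used for validation against exact enumeration).
#' @return An object of class `admixture_fit`: `q` (accessions x k), `f`
#'   (k x bands), `ln_pd`, `k`, sampler settings, and with `keep_z` also
#'   `z_freq` (accession x band x k occupancy frequencies) and `coassign`
#'   (accession x accession co-assignment probabilities, label-invariant).
#' @export
fit_admixture <- function(x, k, burnin = 2000, sweeps = 10000, thin = 10,
                          seed = 1L, alpha = 1, bands = c("polymorphic", "all"),
                          keep_z = FALSE) {
  stopifnot(inherits(x, "band_matrix"))
  bands <- match.arg(bands)
  m <- if (bands == "polymorphic") keep_polymorphic(x)$values else x$values
  n <- nrow(m); B <- ncol(m)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k exceeds the number of accessions", call. = FALSE)
  if (sweeps <= burnin) stop("sweeps must exceed burnin", call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0L)) stop("accession with no scored band", call. = FALSE)
  obs <- !is.na(m)
  x1 <- m == 1L & obs
  x0 <- m == 0L & obs
  set.seed(seed)
  q <- matrix(1 / k, n, k)
  f <- matrix(stats::runif(k * B, 0.2, 0.8), k, B)
  q_acc <- matrix(0, n, k)
  f_acc <- matrix(0, k, B)
  z_acc <- if (keep_z) array(0, c(n, B, k)) else NULL
  co_acc <- if (keep_z) matrix(0, n, n) else NULL
  ll_kept <- numeric(0)
  kept <- 0L
  for (s in seq_len(sweeps)) {
    # per-cluster cell likelihoods and z draw
    p_cum <- matrix(0, n, B)
    u <- matrix(stats::runif(n * B), n, B)
    z <- matrix(k, n, B)
    tot <- matrix(0, n, B)
    lik <- vector("list", k)
    for (kk in seq_len(k)) {
      fk <- matrix(f[kk, ], n, B, byrow = TRUE)
      lk <- matrix(1, n, B)
      lk[x1] <- fk[x1]
      lk[x0] <- 1 - fk[x0]
      lik[[kk]] <- q[, kk] * lk
      tot <- tot + lik[[kk]]
    }
    undecided <- matrix(TRUE, n, B)
    for (kk in seq_len(k - 1L)) {
      p_cum <- p_cum + lik[[kk]] / tot
      hit <- undecided & (u < p_cum)
      z[hit] <- kk
      undecided <- undecided & !hit
    }
    # f update
    for (kk in seq_len(k)) {
      zk <- z == kk
      s1 <- colSums(zk & x1)
      s0 <- colSums(zk & x0)
      f[kk, ] <- stats::rbeta(B, 1 + s1, 1 + s0)
    }
    # q update (counts over all cells, scored or not)
    cnt <- matrix(0, n, k)
    for (kk in seq_len(k)) cnt[, kk] <- rowSums(z == kk)
    g <- matrix(stats::rgamma(n * k, shape = alpha + cnt), n, k)
    q <- g / rowSums(g)
    if (s > burnin && (s - burnin) %% thin == 0L) {
      kept <- kept + 1L
      q_acc <- q_acc + q
      f_acc <- f_acc + f
      if (keep_z) {
        for (kk in seq_len(k)) {
          zk <- z == kk
          z_acc[, , kk] <- z_acc[, , kk] + zk
          co_acc <- co_acc + tcrossprod(zk)
        }
      }
      # mixture log-likelihood of the scored cells given current q, f
      mix <- matrix(0, n, B)
      for (kk in seq_len(k)) {
        fk <- matrix(f[kk, ], n, B, byrow = TRUE)
        lk <- matrix(1, n, B)
        lk[x1] <- fk[x1]
        lk[x0] <- 1 - fk[x0]
        mix <- mix + q[, kk] * lk
      }
      ll_kept <- c(ll_kept, sum(log(mix[obs])))
    }
  }
  q_hat <- q_acc / kept
  f_hat <- f_acc / kept
  dimnames(q_hat) <- list(rownames(m), paste0("q", seq_len(k)))
  dimnames(f_hat) <- list(paste0("cluster", seq_len(k)), colnames(m))
  ln_pd <- mean(ll_kept) - stats::var(ll_kept) / 2
  if (length(ll_kept) < 2L) ln_pd <- mean(ll_kept)
  structure(
    list(q = q_hat, f = f_hat, ln_pd = ln_pd, k = k,
         burnin = burnin, sweeps = sweeps, thin = thin, seed = seed,
         alpha = alpha, bands = bands, kept = kept,
         z_freq = if (keep_z) z_acc / kept else NULL,
         coassign = if (keep_z) co_acc / (kept * B) else NULL),
    class = "admixture_fit"
  )
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d accessions, %d bands; ln P(D) = %.2f (%d kept sweeps)\n",
              x$k, nrow(x$q), ncol(x$f), x$ln_pd, x$kept))
  invisible(x)
}

#' @rdname fit_admixture
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(accession_id = rownames(x$q)),
                   tibble::as_tibble(x$q))
}

#' @rdname fit_admixture
#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, ln_pd = x$ln_pd, kept_sweeps = x$kept,
                 mean_max_q = mean(apply(x$q, 1L, max)))
}

#' Multiple admixture runs across a range of K
#'
#' Runs the Gibbs sampler several times per cluster count with distinct,
#' reproducible seeds derived from a master seed.
#'
#' @param x A `band_matrix`.
#' @param k_range Cluster counts to scan (default 2:10).
#' @param runs Independent runs per K (default 4).
#' @param seed Master seed.
#' @param ... Passed to [fit_admixture()].
#' @return A tibble: `k`, `run`, `seed`, `ln_pd`, `fit` (list column).
#' @export
admixture_scan <- function(x, k_range = 2:10, runs = 4, seed = 1L, ...) {
  if (runs < 2L) stop("need at least 2 runs per K", call. = FALSE)
  set.seed(seed)
  grid <- tidyr::expand_grid(k = k_range, run = seq_len(runs))
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  grid$fit <- purrr::map2(grid$k, grid$seed,
                          function(k, s) fit_admixture(x, k, seed = s, ...))
  grid$ln_pd <- purrr::map_dbl(grid$fit, "ln_pd")
  grid[, c("k", "run", "seed", "ln_pd", "fit")]
}

#' Evanno delta-K model selection
#'
#' Summarises a multi-run scan: per K the mean and standard deviation of
#' ln P(D) over runs, the first and absolute second differences of the means,
#' and `delta_k = |second difference| / sd`. The best K is the interior K
#' maximising delta_k; K values with zero run-to-run standard deviation are
#' flagged infinite and excluded from the argmax with a warning.
#'
#' @param scan A tibble from [admixture_scan()] (columns `k`, `run`, `ln_pd`).
#' @return An object of class `evanno_table`: tibble with `k`, `n_runs`,
#'   `mean_ln_pd`, `sd_ln_pd`, `l_prime`, `l_second`, `delta_k`; the selected
#'   K is in attribute `best_k` (also via [glance()]).
#' @export
evanno_delta_k <- function(scan) {
  agg <- scan |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(n_runs = dplyr::n(), mean_ln_pd = mean(.data$ln_pd),
                     sd_ln_pd = stats::sd(.data$ln_pd), .groups = "drop") |>
    dplyr::arrange(.data$k)
  if (nrow(agg) < 3L) stop("need at least 3 consecutive K values", call. = FALSE)
  if (any(diff(agg$k) != 1L)) stop("K values must be consecutive", call. = FALSE)
  if (any(agg$n_runs < 2L)) stop("need at least 2 runs per K", call. = FALSE)
  L <- agg$mean_ln_pd
  nk <- nrow(agg)
  l_prime <- c(NA, diff(L))
  l_second <- c(NA, abs(diff(L, differences = 2)), NA)
  delta_k <- l_second / agg$sd_ln_pd
  inf_flag <- !is.na(l_second) & agg$sd_ln_pd == 0
  if (any(inf_flag)) {
    delta_k[inf_flag] <- Inf
    warning("zero run-to-run sd at K = ",
            paste(agg$k[inf_flag], collapse = ", "),
            "; excluded from best-K selection", call. = FALSE)
  }
  eligible <- which(!is.na(delta_k) & is.finite(delta_k) & delta_k > 0)
  best_k <- if (length(eligible) > 0) agg$k[eligible[which.max(delta_k[eligible])]]
            else NA_integer_
  out <- dplyr::bind_cols(agg, tibble::tibble(l_prime = l_prime,
                                              l_second = l_second,
                                              delta_k = delta_k))
  structure(out, class = c("evanno_table", class(out)), best_k = best_k)
}

#' @rdname evanno_delta_k
#' @param x An `evanno_table`.
#' @param ... Unused.
#' @method glance evanno_table
#' @export
glance.evanno_table <- function(x, ...) {
  tibble::tibble(best_k = attr(x, "best_k"),
                 k_min = min(x$k), k_max = max(x$k),
                 max_delta_k = suppressWarnings(
                   max(x$delta_k[is.finite(x$delta_k)], na.rm = TRUE)))
}

#' Plot of the delta-K profile
#' @param object An `evanno_table`.
#' @param ... Unused.
#' @method autoplot evanno_table
#' @export
autoplot.evanno_table <- function(object, ...) {
  df <- object[is.finite(object$delta_k) & !is.na(object$delta_k), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Membership purity calls
#'
#' An accession is called pure when its largest admixture proportion meets
#' the threshold (0.8 by convention).
#'
#' @param fit An `admixture_fit`.
#' @param meta Optional metadata with `accession_id` and `geo_group`; adds a
#'   per-group pure-percentage attribute (also returned by the
#'   `group_summary` attribute).
#' @param threshold Purity threshold on the maximum membership (default 0.8).
#' @return A tibble: `accession_id`, `cluster`, `max_q`, `pure` (+
#'   `geo_group` when `meta` is given); per-group percentages in attribute
#'   `group_summary`.
#' @export
purity_calls <- function(fit, meta = NULL, threshold = 0.8) {
  stopifnot(inherits(fit, "admixture_fit"))
  max_q <- unname(apply(fit$q, 1L, max))
  out <- tibble::tibble(
    accession_id = rownames(fit$q),
    cluster = unname(apply(fit$q, 1L, which.max)),
    max_q = max_q,
    pure = max_q >= threshold
  )
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, meta[, c("accession_id", "geo_group")],
                            by = "accession_id")
    gs <- out |>
      dplyr::group_by(.data$geo_group) |>
      dplyr::summarise(n = dplyr::n(), n_pure = sum(.data$pure),
                       pct_pure = 100 * mean(.data$pure), .groups = "drop")
    attr(out, "group_summary") <- gs
  }
  out
}

#' Align cluster labels across admixture runs
#'
#' Greedy matching of cluster columns by correlation of membership vectors
#' against a reference run, so that averaged or stacked Q matrices from
#' independent runs are comparable. Alignment only relabels columns; it does
#' not change ln P(D).
#'
#' @param fits List of `admixture_fit` objects with equal K.
#' @param reference Index of the reference run (default 1).
#' @return The list with cluster columns permuted to match the reference.
#' @export
align_runs <- function(fits, reference = 1L) {
  stopifnot(length(fits) >= 1L)
  ks <- vapply(fits, function(f) as.integer(f$k), integer(1))
  if (length(unique(ks)) != 1L) stop("runs differ in K", call. = FALSE)
  ref <- fits[[reference]]$q
  lapply(fits, function(f) {
    k <- f$k
    if (k == 1L) return(f)
    cors <- suppressWarnings(stats::cor(ref, f$q))
    cors[is.na(cors)] <- 0
    perm <- integer(k)
    taken <- rep(FALSE, k)
    for (j in seq_len(k)) {
      cand <- order(cors[j, ], decreasing = TRUE)
      perm[j] <- cand[!taken[cand]][1L]
      taken[perm[j]] <- TRUE
    }
    f$q <- f$q[, perm, drop = FALSE]
    colnames(f$q) <- paste0("q", seq_len(k))
    f$f <- f$f[perm, , drop = FALSE]
    f
  })
}

#' Stacked-bar plot of admixture proportions
#'
#' @param object An `admixture_fit`.
#' @param meta Optional metadata (`accession_id`, `geo_group`) used to order
#'   and facet accessions by group.
#' @param ... Unused.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, meta = NULL, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(-"accession_id", names_to = "cluster", values_to = "q")
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta[, c("accession_id", "geo_group")],
                           by = "accession_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$accession_id, .data$q,
                                        fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(meta)) {
    p + ggplot2::facet_grid(~geo_group, scales = "free_x", space = "free_x")
  } else p
}
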
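#' Per-group diversity indices for dominant markers
#'
#' For each geographic group and each band, the within-group band frequency is
#' converted to Hardy-Weinberg allele frequencies (`q = sqrt(1 - p_band)`),
#' from which the indices follow: number of observed phenotype-level alleles
#' `na` (2 iff the band segregates within the group, else 1), effective allele
#' number `ne = 1 / (p_allele^2 + q_allele^2)`, Shannon index `hj`, expected
#' heterozygosity `he = 2 p_allele q_allele` and its small-sample-unbiased
#' version `uhe = he * 2n / (2n - 1)`. Group values are means over bands with
#' standard errors; `pct_poly` is the percentage of bands segregating within
#' the group.
#'
#' @param x A `band_matrix` (typically already restricted to the study's
#'   polymorphic bands).
#' @param meta Metadata tibble with `accession_id` and `geo_group` covering
#'   every accession of `x`.
#' @return A tibble with one row per group: `geo_group`, `n`, then
#'   `<index>`/`<index>_se` for `na`, `ne`, `hj`, `he`, `uhe`, and `pct_poly`.
#' @export
group_diversity <- function(x, meta) {
  stopifnot(inherits(x, "band_matrix"))
  groups <- group_assignment(x, meta)
  purrr::map_dfr(split(names(groups), groups), function(ids) {
    n <- length(ids)
    if (n < 2L) {
      stop("group of size 1: ", meta$geo_group[match(ids, meta$accession_id)][1],
           call. = FALSE)
    }
    sub <- x$values[ids, , drop = FALSE]
    scored <- colSums(!is.na(sub))
    p <- colSums(sub == 1L, na.rm = TRUE) / scored
    p <- p[scored > 0]
    af <- dominant_allele_freq(p)
    na_b <- ifelse(p > 0 & p < 1, 2, 1)
    ne_b <- 1 / (af$p_allele^2 + af$q_allele^2)
    he_b <- 2 * af$p_allele * af$q_allele
    hj_b <- -xlogx(af$p_allele) - xlogx(af$q_allele)
    uhe_b <- he_b * 2 * n / (2 * n - 1)
    se <- function(v) stats::sd(v) / sqrt(length(v))
    tibble::tibble(
      n = n,
      na = mean(na_b), na_se = se(na_b),
      ne = mean(ne_b), ne_se = se(ne_b),
      hj = mean(hj_b), hj_se = se(hj_b),
      he = mean(he_b), he_se = se(he_b),
      uhe = mean(uhe_b), uhe_se = se(uhe_b),
      pct_poly = 100 * mean(p > 0 & p < 1)
    )
  }, .id = "geo_group") |>
    tibble::as_tibble()
}

group_assignment <- function(x, meta) {
  ids <- rownames(x$values)
  idx <- match(ids, meta$accession_id)
  if (anyNA(idx)) {
    stop("accession(s) missing from metadata: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(meta$geo_group[idx]), ids)
}

# squared Euclidean distances between band profiles; missing cells handled
# pairwise-complete, rescaled to the full band count
squared_band_distance <- function(m) {
  n <- nrow(m)
  if (!anyNA(m)) {
    g <- tcrossprod(m)
    s <- diag(g)
    d2 <- outer(s, s, "+") - 2 * g
  } else {
    d2 <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        d2[i, j] <- d2[j, i] <-
          ncol(m) * mean((m[i, ok] - m[j, ok])^2)
      }
    }
  }
  dimnames(d2) <- list(rownames(m), rownames(m))
  d2
}

amova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(split(seq_len(n), groups), function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phi_from_ss <- function(ss, n_per_group, n, k) {
  df_among <- k - 1L
  df_within <- n - k
  ms_among <- ss[["among"]] / df_among
  ms_within <- ss[["within"]] / df_within
  n0 <- (n - sum(n_per_group^2) / n) / df_among
  va <- (ms_among - ms_within) / n0
  vw <- ms_within
  va_f <- max(va, 0)
  phi <- if (va_f + vw > 0) va_f / (va_f + vw) else 0
  # raw (unfloored) ratio: the permutation test statistic
  phi_raw <- if (va + vw != 0) va / (va + vw) else 0
  list(df_among = df_among, df_within = df_within, ms_among = ms_among,
       ms_within = ms_within, va = va, vw = vw, phi_pt = phi,
       phi_raw = phi_raw)
}

#' Non-hierarchical AMOVA with permutation-tested PhiPT
#'
#' Analysis of molecular variance on squared Euclidean distances between band
#' profiles, partitioning variation among versus within geographic groups.
#' PhiPT (the dominant-marker analogue of Fst) is the among-group fraction of
#' the variance components; its p-value comes from permuting accession group
#' labels. Negative among-group variance estimates are reported as estimated
#' but floored at zero in PhiPT and in the percentage split; the permutation
#' test compares the unfloored variance-component ratio, so null p-values
#' remain approximately uniform rather than piling up at 1.
#'
#' @param x A `band_matrix`.
#' @param meta Metadata with `accession_id` and `geo_group`.
#' @param permutations Label permutations for the PhiPT test (default 9999).
#' @param seed Integer seed for the permutations.
#' @param bands `"polymorphic"` (default) or `"all"`.
#' @return An object of class `amova`: `table` (source, df, ss, ms, est_var,
#'   pct), `phi_pt`, `p_value`, `n_permutations`.
#' @export
amova <- function(x, meta, permutations = 9999, seed = 1L,
                  bands = c("polymorphic", "all")) {
  stopifnot(inherits(x, "band_matrix"))
  bands <- match.arg(bands)
  groups <- group_assignment(x, meta)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "),
         call. = FALSE)
  }
  m <- if (bands == "polymorphic") keep_polymorphic(x)$values else x$values
  d2 <- squared_band_distance(m)
  n <- nrow(d2)
  k <- length(tab)
  ss <- amova_ss(d2, groups)
  comp <- phi_from_ss(ss, as.numeric(tab), n, k)
  va_f <- max(comp$va, 0)
  pct_among <- if (va_f + comp$vw > 0) 100 * va_f / (va_f + comp$vw) else 0
  p_value <- NA_real_
  if (permutations > 0) {
    set.seed(seed)
    hits <- 0L
    g <- unname(groups)
    for (b in seq_len(permutations)) {
      perm <- sample(g)
      ss_p <- amova_ss(d2, perm)
      phi_p <- phi_from_ss(ss_p, as.numeric(table(perm)), n, k)$phi_raw
      if (phi_p >= comp$phi_raw) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (permutations + 1)
  }
  structure(
    list(
      table = tibble::tibble(
        source = c("Among groups", "Within groups", "Total"),
        df = c(comp$df_among, comp$df_within, n - 1L),
        ss = c(ss[["among"]], ss[["within"]], ss[["total"]]),
        ms = c(comp$ms_among, comp$ms_within, NA_real_),
        est_var = c(comp$va, comp$vw, va_f + comp$vw),
        pct = c(pct_among, 100 - pct_among, 100)
      ),
      phi_pt = comp$phi_pt,
      p_value = p_value,
      n_permutations = permutations,
      bands = bands
    ),
    class = "amova"
  )
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("<amova> PhiPT = %.3f, p = %s (%d permutations, %s bands)\n",
              x$phi_pt, format.pval(x$p_value), x$n_permutations, x$bands))
  print(x$table)
  invisible(x)
}

#' @rdname amova
#' @method tidy amova
#' @export
tidy.amova <- function(x, ...) x$table

#' @rdname amova
#' @method glance amova
#' @export
glance.amova <- function(x, ...) {
  tibble::tibble(
    phi_pt = x$phi_pt,
    p_value = x$p_value,
    pct_among = x$table$pct[1],
    pct_within = x$table$pct[2],
    n_permutations = x$n_permutations
  )
}

#' Pairwise PhiPT between geographic groups
#'
#' Runs a two-group [amova()] for every pair of groups.
#'
#' @inheritParams amova
#' @return A tibble: `group_1`, `group_2`, `phi_pt`, `p_value`.
#' @export
pairwise_phipt <- function(x, meta, permutations = 999, seed = 1L,
                           bands = c("polymorphic", "all")) {
  bands <- match.arg(bands)
  groups <- group_assignment(x, meta)
  lv <- sort(unique(unname(groups)))
  prs <- utils::combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    ids <- names(groups)[groups %in% prs[, j]]
    sub <- subset_accessions(x, ids)
    fit <- amova(sub, meta, permutations = permutations,
                 seed = seed + j, bands = bands)
    tibble::tibble(group_1 = prs[1L, j], group_2 = prs[2L, j],
                   phi_pt = fit$phi_pt, p_value = fit$p_value)
  })
}

#' Nei (1972) genetic distance between groups
#'
#' Allele frequencies per group and band come from the Hardy-Weinberg
#' transform of within-group band frequencies. The genetic identity between
#' two groups is `I = Jxy / sqrt(Jx * Jy)` with the `J` terms averaged
#' arithmetically over bands, and the distance is `D = -ln I`.
#'
#' @param x A `band_matrix`.
#' @param meta Metadata with `accession_id` and `geo_group`.
#' @return A tibble: `group_1`, `group_2`, `identity`, `distance`.
#' @export
nei_group_distance <- function(x, meta) {
  groups <- group_assignment(x, meta)
  tab <- table(groups)
  if (any(tab < 2L)) stop("group(s) of size 1", call. = FALSE)
  lv <- sort(names(tab))
  freq <- lapply(lv, function(g) {
    sub <- x$values[names(groups)[groups == g], , drop = FALSE]
    scored <- colSums(!is.na(sub))
    p <- colSums(sub == 1L, na.rm = TRUE) / pmax(scored, 1L)
    dominant_allele_freq(p)
  })
  names(freq) <- lv
  prs <- utils::combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    fx <- freq[[prs[1L, j]]]; fy <- freq[[prs[2L, j]]]
    jxy <- mean(fx$p_allele * fy$p_allele + fx$q_allele * fy$q_allele)
    jx <- mean(fx$p_allele^2 + fx$q_allele^2)
    jy <- mean(fy$p_allele^2 + fy$q_allele^2)
    id <- jxy / sqrt(jx * jy)
    if (id <= 0) stop("non-positive genetic identity", call. = FALSE)
    tibble::tibble(group_1 = prs[1L, j], group_2 = prs[2L, j],
                   identity = id, distance = -log(id))
  })
}
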
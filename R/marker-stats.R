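#' Per-band informativeness measures for dominant markers
#'
#' For a dominant (presence/absence) marker the band phenotype frequency
#' `p` is observed directly; the underlying allele frequencies are estimated
#' under Hardy-Weinberg equilibrium as `q_allele = sqrt(1 - p)` (frequency of
#' the null allele) and `p_allele = 1 - q_allele`.
#'
#' * `pic_band()`: polymorphic information content on the phenotype
#'   frequency, `1 - p^2 - q^2 = 2 p (1 - p)`, maximal (0.5) at `p = 0.5`.
#' * `dominant_allele_freq()`: HWE allele frequencies from a band frequency.
#' * `nei_h_band()`: Nei's gene diversity `2 * p_allele * q_allele` on the
#'   HWE allele frequencies, maximal at band frequency 0.75.
#' * `shannon_i_band()`: Shannon index
#'   `-p_allele log(p_allele) - q_allele log(q_allele)` with `0 log 0 = 0`.
#' * `band_informativeness()`: `Ib = 1 - 2 |0.5 - p|`, the per-band term of
#'   resolving power.
#' * `resolving_power()`: `Rp = sum(Ib)` over a primer's polymorphic bands.
#'
#' All are vectorized over `p`.
#'
#' @param p Band (phenotype) frequency in \[0, 1\].
#' @return Numeric vector; `dominant_allele_freq()` returns a tibble with
#'   columns `p_allele` and `q_allele`.
#' @name band_measures
NULL

check_freq <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("band frequency must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' @rdname band_measures
#' @export
pic_band <- function(p) {
  check_freq(p)
  2 * p * (1 - p)
}

#' @rdname band_measures
#' @export
dominant_allele_freq <- function(p) {
  check_freq(p)
  q_allele <- sqrt(1 - p)
  tibble::tibble(p_allele = 1 - q_allele, q_allele = q_allele)
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' @rdname band_measures
#' @export
nei_h_band <- function(p) {
  af <- dominant_allele_freq(p)
  2 * af$p_allele * af$q_allele
}

#' @rdname band_measures
#' @export
shannon_i_band <- function(p) {
  af <- dominant_allele_freq(p)
  -xlogx(af$p_allele) - xlogx(af$q_allele)
}

#' @rdname band_measures
#' @export
band_informativeness <- function(p) {
  check_freq(p)
  1 - 2 * abs(0.5 - p)
}

#' @rdname band_measures
#' @export
resolving_power <- function(p) {
  if (length(p) == 0L) return(0)
  sum(band_informativeness(p))
}

#' Per-primer marker statistics
#'
#' Computes, for each primer of a band matrix, the total number of bands
#' (`tnb`), number of polymorphic bands by the strict 5-95% frequency rule
#' (`npb`), percentage of polymorphic bands (`ppb`), and -- averaged or summed
#' over the primer's polymorphic bands only -- polymorphic information content
#' (`pic`), marker index (`mi = pic * npb`), resolving power (`rp`), Nei's
#' gene diversity (`h`) and Shannon index (`i`). Primers with no polymorphic
#' band report 0 for all informativeness measures.
#'
#' @param x A `band_matrix`.
#' @param primer Optional primer id(s) to restrict to.
#' @return A tibble with one row per primer: `primer_id`, `class`, `tnb`,
#'   `npb`, `ppb`, `pic`, `mi`, `rp`, `h`, `i`.
#' @export
marker_stats <- function(x, primer = NULL) {
  stopifnot(inherits(x, "band_matrix"))
  bf <- band_frequencies(x)
  if (!is.null(primer)) {
    unknown <- setdiff(primer, unique(bf$primer_id))
    if (length(unknown) > 0L) {
      stop("unknown primer(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    bf <- dplyr::filter(bf, .data$primer_id %in% primer)
  }
  cls <- x$primer_class
  bf |>
    dplyr::group_by(.data$primer_id) |>
    dplyr::summarise(
      tnb = dplyr::n(),
      npb = sum(.data$polymorphic),
      ppb = 100 * npb / tnb,
      pic = if (npb > 0) mean(pic_band(.data$p_band[.data$polymorphic])) else 0,
      mi = pic * npb,
      rp = resolving_power(.data$p_band[.data$polymorphic]),
      h = if (npb > 0) mean(nei_h_band(.data$p_band[.data$polymorphic])) else 0,
      i = if (npb > 0) mean(shannon_i_band(.data$p_band[.data$polymorphic])) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(class = unname(cls[.data$primer_id]), .after = "primer_id") |>
    dplyr::arrange(match(.data$primer_id, unique(unname(x$band_to_primer))))
}

#' Panel-level summary of per-primer marker statistics
#'
#' Aggregates a per-primer statistics table (from [marker_stats()] or an
#' externally published panel table with the same columns) into per-metric
#' min/max/mean, class-wise means, pairwise Pearson correlations among the
#' informativeness metrics, and a two-sided Wilcoxon rank-sum comparison of
#' PIC between the two marker classes.
#'
#' The Wilcoxon p-value uses the exact distribution when both classes have at
#' most 8 primers and there are no ties, otherwise the normal approximation
#' with midrank ties and no continuity correction; the method used is
#' recorded in the result.
#'
#' @param stats A tibble with columns `primer_id`, `class`, `tnb`, `npb`,
#'   `ppb`, `pic`, `mi`, `rp`, `h`, `i`.
#' @param metrics Metrics to correlate (default the five informativeness
#'   measures).
#' @return An object of class `panel_summary` with components `summary`
#'   (metric, min, max, mean), `totals` (n_primers, tnb_total, npb_total),
#'   `class_means`, `correlations` (long tibble of metric pairs),
#'   `wilcoxon` (list: statistic, p_value, method, classes) or `NULL` when
#'   fewer than two classes are present.
#' @export
panel_summary <- function(stats, metrics = c("pic", "mi", "rp", "h", "i")) {
  if (nrow(stats) < 2L) stop("need at least 2 primers", call. = FALSE)
  all_metrics <- c("tnb", "npb", "ppb", metrics)
  summary_tbl <- tidyr::pivot_longer(stats[, c("primer_id", all_metrics)],
                                     -"primer_id",
                                     names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     mean = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$metric, all_metrics))
  totals <- tibble::tibble(
    n_primers = nrow(stats),
    tnb_total = sum(stats$tnb),
    npb_total = sum(stats$npb)
  )
  class_means <- stats |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(all_metrics), mean),
                     n = dplyr::n(), .groups = "drop")
  pairs <- utils::combn(metrics, 2L)
  correlations <- tibble::tibble(
    metric_1 = pairs[1L, ],
    metric_2 = pairs[2L, ],
    r = purrr::map2_dbl(pairs[1L, ], pairs[2L, ], function(a, b) {
      suppressWarnings(stats::cor(stats[[a]], stats[[b]],
                                  use = "pairwise.complete.obs"))
    })
  )
  classes <- sort(unique(stats$class))
  wilcoxon <- NULL
  if (length(classes) >= 2L) {
    g1 <- stats$pic[stats$class == classes[1L]]
    g2 <- stats$pic[stats$class == classes[2L]]
    ties <- anyDuplicated(c(g1, g2)) > 0L
    exact <- length(g1) <= 8L && length(g2) <= 8L && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = exact, correct = FALSE)
    )
    wilcoxon <- list(
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      method = if (exact) "exact" else "normal approximation, no continuity correction",
      classes = classes[1:2]
    )
  }
  structure(
    list(summary = summary_tbl, totals = totals, class_means = class_means,
         correlations = correlations, wilcoxon = wilcoxon),
    class = "panel_summary"
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>", x$totals$n_primers, "primers,",
      x$totals$tnb_total, "bands,", x$totals$npb_total, "polymorphic\n")
  print(x$summary)
  if (!is.null(x$wilcoxon)) {
    cat(sprintf("PIC by class (%s vs %s): W = %g, p = %.4g [%s]\n",
                x$wilcoxon$classes[1], x$wilcoxon$classes[2],
                x$wilcoxon$statistic, x$wilcoxon$p_value, x$wilcoxon$method))
  }
  invisible(x)
}

#' @rdname panel_summary
#' @param x A `panel_summary`.
#' @param ... Unused.
#' @method tidy panel_summary
#' @export
tidy.panel_summary <- function(x, ...) x$summary

#' @rdname panel_summary
#' @method glance panel_summary
#' @export
glance.panel_summary <- function(x, ...) {
  means <- stats::setNames(x$summary$mean, paste0("mean_", x$summary$metric))
  out <- dplyr::bind_cols(x$totals, tibble::as_tibble(as.list(means)))
  if (!is.null(x$wilcoxon)) {
    out$wilcox_statistic <- x$wilcoxon$statistic
    out$wilcox_p <- x$wilcoxon$p_value
  }
  out
}

#' Bundled published SSR panel table
#'
#' Loads the bundled per-primer marker statistics of a published 35-primer
#' SSR panel (30 EST-SSR, 5 G-SSR) scored on 25 wild *Elymus excelsus*
#' accessions: for each primer its total and polymorphic band counts and the
#' informativeness measures computed from the original band matrix. Used as a
#' worked example and as a reference input for panel-level summaries.
#'
#' @return A tibble with the [marker_stats()] columns.
#' @export
ssr_panel_example <- function() {
  path <- system.file("extdata", "elymus_excelsus_ssr_panel.csv",
                      package = "bandpop", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
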
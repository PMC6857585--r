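#' Great-circle geographic distance matrix
#'
#' Haversine distances between accession collection sites, on a sphere of
#' radius 6371 km.
#'
#' @param meta Metadata tibble with `accession_id`, `latitude`, `longitude`.
#' @return A [stats::dist] in kilometres, labelled by accession id.
#' @export
geographic_distance <- function(meta) {
  if (anyNA(meta$latitude) || anyNA(meta$longitude)) {
    bad <- meta$accession_id[is.na(meta$latitude) | is.na(meta$longitude)]
    stop("missing coordinates for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  validate_meta(meta)
  n <- nrow(meta)
  pts <- cbind(meta$longitude, meta$latitude)
  d <- matrix(0, n, n, dimnames = list(meta$accession_id, meta$accession_id))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  km <- geosphere::distHaversine(pts[idx[, 1L], , drop = FALSE],
                                 pts[idx[, 2L], , drop = FALSE],
                                 r = 6371000) / 1000
  d[idx] <- km
  stats::as.dist(t(d))
}

#' Environmental distance matrix
#'
#' Absolute pairwise difference of one environmental variable.
#'
#' @param meta Metadata tibble.
#' @param variable One of the metadata's numeric columns, e.g. `"altitude"`,
#'   `"mat"`, `"map_mm"`, `"apg_mm"`.
#' @return A [stats::dist] labelled by accession id.
#' @export
env_distance <- function(meta, variable) {
  if (!variable %in% names(meta)) {
    stop("variable not in metadata: ", variable, call. = FALSE)
  }
  v <- meta[[variable]]
  if (anyNA(v)) {
    stop("missing ", variable, " for: ",
         paste(meta$accession_id[is.na(v)], collapse = ", "), call. = FALSE)
  }
  d <- stats::dist(v, method = "manhattan")
  attr(d, "Labels") <- meta$accession_id
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, tested by jointly
#' permuting rows and columns of the second matrix. P-values use the +1
#' correction; the default tail is upper (one-sided), matching directional
#' isolation-by-distance hypotheses.
#'
#' @param d1,d2 [stats::dist] objects (or symmetric matrices) on the same
#'   labels; `d2` is reordered to `d1`'s labels when both are labelled.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param tail `"upper"` (default) or `"two-sided"`.
#' @return A one-row tibble: `r`, `p_value`, `n_perm`, `tail`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L,
                        tail = c("upper", "two-sided")) {
  tail <- match.arg(tail)
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  n <- attr(d1, "Size")
  if (n < 4L) stop("need at least 4 labels", call. = FALSE)
  if (attr(d2, "Size") != n) stop("matrices differ in size", call. = FALSE)
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) stop("matrices have different labels", call. = FALSE)
    if (!identical(l1, l2)) {
      m2 <- as.matrix(d2)[l1, l1]
      d2 <- stats::as.dist(m2)
    }
  }
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) {
    stop("zero variance in a distance matrix; Mantel r undefined", call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  r <- unname(fit$statistic)
  p <- if (tail == "upper") {
    fit$signif
  } else {
    (sum(abs(fit$perm) >= abs(r)) + 1) / (n_perm + 1)
  }
  tibble::tibble(r = r, p_value = p, n_perm = n_perm, tail = tail, n = n)
}

#' Mantel suite over scopes and variables
#'
#' Runs Mantel tests of a genetic distance matrix against geographic distance
#' and a set of environmental variables, at species level, within each
#' geographic group, and within optional merged groups (e.g. amalgamating two
#' adjacent groups into one region). Scopes with fewer than `min_n`
#' accessions are reported as unavailable (`r = NA`) rather than tested.
#'
#' @param gen_d Genetic [stats::dist] labelled by accession id (e.g. the
#'   `dist` component of [genetic_similarity()]).
#' @param meta Metadata tibble.
#' @param variables Environmental variables to test (besides geographic
#'   distance).
#' @param merge_groups Named list of group-label vectors defining merged
#'   scopes, e.g. `list(QTP = c("SCC", "GSC"))`.
#' @param n_perm,seed,tail Passed to [mantel_test()].
#' @param min_n Minimum scope size for a test (default 4).
#' @return A tibble: `scope`, `n`, `variable`, `r`, `p_value`, `note`.
#' @export
mantel_suite <- function(gen_d, meta, variables = c("altitude", "mat",
                                                    "map_mm", "apg_mm"),
                         merge_groups = NULL, n_perm = 999, seed = 1L,
                         tail = "upper", min_n = 4L) {
  labs <- attr(stats::as.dist(gen_d), "Labels")
  if (is.null(labs)) stop("genetic distance matrix must be labelled", call. = FALSE)
  meta <- meta[match(labs, meta$accession_id), ]
  if (anyNA(meta$accession_id)) stop("metadata missing accessions", call. = FALSE)
  scopes <- c(list(species = labs),
              split(meta$accession_id, meta$geo_group),
              lapply(merge_groups, function(gr) {
                meta$accession_id[meta$geo_group %in% gr]
              }))
  gm <- as.matrix(gen_d)
  vars <- c("geographic", variables)
  purrr::imap_dfr(scopes, function(ids, scope) {
    sub_meta <- meta[match(ids, meta$accession_id), ]
    purrr::map_dfr(vars, function(v) {
      base <- tibble::tibble(scope = scope, n = length(ids), variable = v,
                             r = NA_real_, p_value = NA_real_, note = "")
      if (length(ids) < min_n) {
        base$note <- sprintf("unavailable: scope smaller than %d", min_n)
        return(base)
      }
      dv <- if (v == "geographic") geographic_distance(sub_meta)
            else env_distance(sub_meta, v)
      dg <- stats::as.dist(gm[ids, ids])
      res <- tryCatch(
        mantel_test(dg, dv, n_perm = n_perm,
                    seed = seed + utils::head(which(vars == v), 1L), tail = tail),
        error = function(e) NULL
      )
      if (is.null(res)) {
        base$note <- "unavailable: degenerate distances"
        return(base)
      }
      base$r <- res$r; base$p_value <- res$p_value
      base
    })
  })
}

#' Bubble-matrix plot of a Mantel suite
#'
#' @param object Tibble from [mantel_suite()].
#' @param alpha Significance level used to outline significant cells.
#' @param ... Unused.
#' @export
plot_mantel_suite <- function(object, alpha = 0.05, ...) {
  df <- object[!is.na(object$r), ]
  df$significant <- df$p_value <= alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$variable, .data$scope)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$r), fill = .data$r,
                                     colour = .data$significant), shape = 21) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
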
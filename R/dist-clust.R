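#' Dice similarity between two band profiles
#'
#' `GS = 2a / (2a + b + c)` where `a` counts shared band presences and
#' `b`, `c` presences unique to either profile, over pairwise-complete
#' (both scored) positions. Two profiles with no presences at all are
#' defined to be identical (`GS = 1`).
#'
#' @param x,y Integer vectors of 0/1/`NA`, equal length.
#' @return Similarity in \[0, 1\].
#' @export
dice_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no band scored in both profiles", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  cc <- sum(x == 0L & y == 1L)
  if (a + b + cc == 0L) return(1)
  2 * a / (2 * a + b + cc)
}

#' Pairwise Dice genetic similarity of a band matrix
#'
#' Computes the full accession-by-accession Dice similarity matrix (and its
#' complement, the genetic distance `1 - GS` used by clustering, ordination,
#' and Mantel tests).
#'
#' @param x A `band_matrix`.
#' @param bands Use `"all"` bands (default) or `"polymorphic"` only.
#' @return An object of class `genetic_similarity`: list with `gs` (similarity
#'   matrix), `dist` (a [stats::dist] of `1 - GS`) and `bands`.
#' @export
genetic_similarity <- function(x, bands = c("all", "polymorphic")) {
  stopifnot(inherits(x, "band_matrix"))
  bands <- match.arg(bands)
  m <- if (bands == "polymorphic") keep_polymorphic(x)$values else x$values
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 accessions", call. = FALSE)
  gs <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  if (!anyNA(m)) {
    a <- m %*% t(m)
    rs <- rowSums(m)
    denom <- outer(rs, rs, "+")
    gs <- ifelse(denom == 0, 1, 2 * a / denom)
    diag(gs) <- 1
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gs[i, j] <- gs[j, i] <- dice_similarity(m[i, ], m[j, ])
      }
    }
  }
  structure(list(gs = gs, dist = stats::as.dist(1 - gs), bands = bands),
            class = "genetic_similarity")
}

#' @export
print.genetic_similarity <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<genetic_similarity> %d accessions (%s bands); GS range %.4f (%s-%s) to %.4f (%s-%s), mean %.4f\n",
              nrow(x$gs), x$bands, g$gs_min, g$min_pair_1, g$min_pair_2,
              g$gs_max, g$max_pair_1, g$max_pair_2, g$gs_mean))
  invisible(x)
}

#' @rdname genetic_similarity
#' @param ... Unused.
#' @method tidy genetic_similarity
#' @export
tidy.genetic_similarity <- function(x, ...) {
  labs <- rownames(x$gs)
  idx <- which(upper.tri(x$gs), arr.ind = TRUE)
  tibble::tibble(
    accession_1 = labs[idx[, 1L]],
    accession_2 = labs[idx[, 2L]],
    gs = x$gs[idx],
    distance = 1 - x$gs[idx]
  )
}

#' @rdname genetic_similarity
#' @method glance genetic_similarity
#' @export
glance.genetic_similarity <- function(x, ...) {
  tt <- tidy(x)
  i_min <- which.min(tt$gs); i_max <- which.max(tt$gs)
  tibble::tibble(
    n = nrow(x$gs),
    gs_min = tt$gs[i_min], min_pair_1 = tt$accession_1[i_min],
    min_pair_2 = tt$accession_2[i_min],
    gs_max = tt$gs[i_max], max_pair_1 = tt$accession_1[i_max],
    max_pair_2 = tt$accession_2[i_max],
    gs_mean = mean(tt$gs)
  )
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering: the closest pair of clusters is
#' merged and inter-cluster distance updated as the size-weighted mean of
#' member distances. Node heights follow the ultrametric convention (half the
#' merge distance), so the cophenetic distance between two leaves equals the
#' merge distance of their smallest common cluster.
#'
#' @param d A [stats::dist] or symmetric matrix of dissimilarities.
#' @return An object of class `upgma_tree`: list with `hclust` (merge heights
#'   in full distance units), `phylo` (an [ape::as.phylo] ultrametric tree,
#'   node depths = height / 2) and optional `support` (see
#'   [bootstrap_upgma()]).
#' @export
upgma <- function(d) {
  d <- stats::as.dist(d)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (attr(d, "Size") < 2L) stop("need at least 2 labels", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), support = NULL),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4f%s\n",
              length(x$hclust$labels), max(x$hclust$height) / 2,
              if (is.null(x$support)) "" else
                sprintf(", %d supported splits", nrow(x$support))))
  invisible(x)
}

# leaf-membership sets for each internal merge of an hclust tree
merge_members <- function(hc) {
  n <- length(hc$labels)
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    mem <- integer(0)
    for (k in kids) {
      mem <- c(mem, if (k < 0) -k else out[[k]])
    }
    out[[i]] <- sort(mem)
  }
  out
}

# canonical key of the unrooted split induced by a leaf subset:
# take the side not containing leaf 1 (trivial splits -> NA)
split_key <- function(members, n) {
  size <- length(members)
  if (size <= 1L || size >= n - 1L) return(NA_character_)
  side <- if (1L %in% members) setdiff(seq_len(n), members) else members
  paste(side, collapse = ",")
}

#' Bootstrap split supports for a UPGMA tree
#'
#' Bands (matrix columns) are resampled with replacement; the Dice distance
#' and UPGMA tree are recomputed per replicate, and each internal unrooted
#' split of the original tree is scored by the percentage of replicate trees
#' containing it.
#'
#' @param x A `band_matrix`.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param bands Band set passed to [genetic_similarity()].
#' @return A `upgma_tree` whose `support` component is a tibble
#'   (`node_size`, `members`, `support`) and whose `phylo` carries supports
#'   as internal node labels.
#' @export
bootstrap_upgma <- function(x, replicates = 1000, seed = 1L, bands = "all") {
  stopifnot(inherits(x, "band_matrix"), replicates >= 1)
  gs <- genetic_similarity(x, bands = bands)
  tree <- upgma(gs$dist)
  hc <- tree$hclust
  n <- length(hc$labels)
  mem <- merge_members(hc)
  keys <- vapply(mem, split_key, character(1), n = n)
  counts <- stats::setNames(rep(0, sum(!is.na(keys))), keys[!is.na(keys)])
  m <- if (bands == "polymorphic") keep_polymorphic(x)$values else x$values
  set.seed(seed)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    bx <- x
    bx$values <- m[, cols, drop = FALSE]
    colnames(bx$values) <- paste0("rb", seq_along(cols))
    bx$band_to_primer <- stats::setNames(rep("boot", length(cols)),
                                         colnames(bx$values))
    bx$primer_class <- c(boot = "SSR")
    bhc <- stats::hclust(genetic_similarity(bx)$dist, method = "average")
    bkeys <- vapply(merge_members(bhc), split_key, character(1), n = n)
    hit <- intersect(names(counts), bkeys)
    counts[hit] <- counts[hit] + 1
  }
  support <- tibble::tibble(
    node_size = lengths(mem)[!is.na(keys)],
    members = vapply(mem[!is.na(keys)],
                     function(i) paste(hc$labels[i], collapse = "|"), character(1)),
    support = 100 * unname(counts) / replicates
  )
  tree$support <- support
  node_lab <- rep("", nrow(hc$merge))
  node_lab[!is.na(keys)] <- sprintf("%.0f", support$support)
  tree$phylo$node.label <- internal_node_labels(hc, tree$phylo, node_lab)
  tree
}

# map hclust merge-row labels onto phylo internal node order
internal_node_labels <- function(hc, phy, merge_labels) {
  n <- length(hc$labels)
  mem <- merge_members(hc)
  key_of <- vapply(mem, function(i) paste(sort(hc$labels[i]), collapse = "|"),
                   character(1))
  labs <- stats::setNames(merge_labels, key_of)
  out <- character(phy$Nnode)
  for (node in seq_len(phy$Nnode)) {
    tips <- phy$tip.label[phangorn_descendants(phy, n + node)]
    k <- paste(sort(tips), collapse = "|")
    out[node] <- if (k %in% names(labs)) labs[[k]] else ""
  }
  out
}

# tip indices below an internal node (iterative; avoids extra deps)
phangorn_descendants <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack) > 0L) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- phy$edge[phy$edge[, 1L] == cur, 2L]
    tips <- c(tips, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  tips
}

#' Cut a UPGMA tree into clades at a mean-similarity threshold
#'
#' The tree is cut at genetic similarity `gs_threshold` (cophenetic distance
#' `1 - gs_threshold`); leaves joined strictly below the cut form a clade.
#'
#' @param tree A `upgma_tree`.
#' @param gs_threshold Similarity threshold in \[0, 1\].
#' @return A tibble (`accession_id`, `clade`) with clades numbered in leaf
#'   order of first appearance.
#' @export
cut_clades <- function(tree, gs_threshold) {
  stopifnot(inherits(tree, "upgma_tree"), gs_threshold >= 0, gs_threshold <= 1)
  hc <- tree$hclust
  n <- length(hc$labels)
  cut_h <- 1 - gs_threshold   # cophenetic (merge-distance) units
  comp <- seq_len(n)
  cluster_of_merge <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    if (hc$height[i] < cut_h) {
      kids <- hc$merge[i, ]
      reps <- vapply(kids, function(k) if (k < 0) comp[-k] else cluster_of_merge[k],
                     integer(1))
      comp[comp == reps[2L]] <- reps[1L]
      cluster_of_merge[i] <- reps[1L]
    } else {
      cluster_of_merge[i] <- 0L
    }
  }
  seen <- unique(comp)
  tibble::tibble(accession_id = hc$labels, clade = match(comp, seen))
}

#' Principal coordinates analysis
#'
#' Metric multidimensional scaling: Gower double-centring of the squared
#' distance matrix followed by eigendecomposition. Negative eigenvalues (a
#' 1 - Dice matrix need not be Euclidean) are reported but excluded from the
#' percent-variance denominator; optional Cailliez or Lingoes corrections are
#' available.
#'
#' @param d A [stats::dist] or symmetric matrix.
#' @param correction `"none"` (default), `"cailliez"` or `"lingoes"`.
#' @return An object of class `pcoa_ord`: `coordinates` (tibble,
#'   `accession_id` + `Axis1..k` for positive-eigenvalue axes), `eigenvalues`,
#'   `percent` (tibble per axis).
#' @export
pcoa <- function(d, correction = c("none", "cailliez", "lingoes")) {
  correction <- match.arg(correction)
  if (is.matrix(d) && !isSymmetric(unname(d))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stop("need at least 3 accessions", call. = FALSE)
  if (correction != "none") {
    res <- ape::pcoa(d, correction = correction)
    eig <- res$values$Corr_eig %||% res$values$Eigenvalues
    coords <- res$vectors.cor %||% res$vectors
  } else {
    res <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
    eig <- res$eig
    coords <- res$points
  }
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k_use <- min(length(pos), ncol(coords))
  coords <- coords[, seq_len(k_use), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k_use))
  pct <- rep(NA_real_, length(eig))
  pct[pos] <- 100 * eig[pos] / sum(eig[pos])
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(accession_id = attr(d, "Labels") %||% as.character(seq_len(n))),
        tibble::as_tibble(coords)
      ),
      eigenvalues = eig,
      percent = tibble::tibble(axis = seq_along(eig), eigenvalue = eig,
                               percent = pct),
      correction = correction
    ),
    class = "pcoa_ord"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- sum(!is.na(x$percent$percent))
  cat(sprintf("<pcoa_ord> %d accessions, %d positive axes; Axis1 %.2f%%, Axis2 %.2f%%\n",
              nrow(x$coordinates), k, x$percent$percent[1],
              if (k >= 2) x$percent$percent[2] else NA))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) x$coordinates

#' @rdname pcoa
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coordinates),
    n_positive_axes = sum(!is.na(x$percent$percent)),
    pct_axis1 = x$percent$percent[1],
    pct_axis2 = if (nrow(x$percent) >= 2) x$percent$percent[2] else NA_real_
  )
}

#' Scatter plot of the first two principal coordinates
#'
#' @param object A `pcoa_ord`.
#' @param meta Optional metadata tibble with `accession_id` and `geo_group`
#'   used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, meta = NULL, ...) {
  df <- object$coordinates
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta[, c("accession_id", "geo_group")],
                           by = "accession_id")
  }
  pct <- object$percent$percent
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", pct[1]),
      y = sprintf("PC2 (%.2f%%)", pct[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(meta)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$geo_group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Export a UPGMA tree as Newick
#'
#' Branch lengths are in cophenetic half-distance units; bootstrap supports
#' (when present) are written as internal node labels.
#'
#' @param tree A `upgma_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
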
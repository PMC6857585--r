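#' Construct a dominant band-presence matrix
#'
#' The central data container of the package: a binary accessions-by-bands
#' matrix scored from dominant markers (SSR gel bands), where each band belongs
#' to exactly one primer pair and each primer carries a class label
#' (typically `"EST-SSR"` or `"G-SSR"`). Cells are 1 (band present),
#' 0 (band absent) or `NA` (not scored).
#'
#' @param values Numeric or integer matrix of 0/1/`NA`, with accession ids as
#'   row names and band ids as column names. Band ids in the plain dialect
#'   encode their primer as `"<primer>.<band>"` (e.g. `"ES7.b3"`); otherwise
#'   supply `band_to_primer` explicitly.
#' @param band_to_primer Named character vector mapping band id to primer id.
#'   If `NULL`, primers are parsed from band ids at the last `"."`.
#' @param primer_class Named character vector mapping primer id to a class
#'   label. Defaults to `"SSR"` for every primer.
#'
#' @return An object of class `band_matrix`.
#' @export
band_matrix <- function(values, band_to_primer = NULL, primer_class = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have accession row names and band column names", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  acc <- rownames(values)
  bands <- colnames(values)
  if (anyDuplicated(acc)) {
    stop("duplicate accession id(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(bands)) {
    stop("duplicate band id(s): ",
         paste(unique(bands[duplicated(bands)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(values) < 2L) stop("a band matrix needs at least 2 accessions", call. = FALSE)
  if (ncol(values) < 1L) stop("a band matrix needs at least 1 band", call. = FALSE)
  bad <- which(!(is.na(values) | values == 0L | values == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary cell at accession '%s', band '%s'",
                 acc[bad[1, 1]], bands[bad[1, 2]]), call. = FALSE)
  }
  if (is.null(band_to_primer)) {
    band_to_primer <- parse_primer_ids(bands)
  } else {
    band_to_primer <- band_to_primer[bands]
    if (anyNA(band_to_primer)) {
      stop("band(s) missing from `band_to_primer`: ",
           paste(bands[is.na(band_to_primer)], collapse = ", "), call. = FALSE)
    }
    names(band_to_primer) <- bands
  }
  primers <- unique(unname(band_to_primer))
  if (is.null(primer_class)) {
    primer_class <- stats::setNames(rep("SSR", length(primers)), primers)
  } else {
    primer_class <- primer_class[primers]
    if (anyNA(primer_class)) {
      stop("primer(s) missing from `primer_class`", call. = FALSE)
    }
    names(primer_class) <- primers
  }
  structure(
    list(values = values, band_to_primer = band_to_primer, primer_class = primer_class),
    class = "band_matrix"
  )
}

# plain-dialect band ids carry the primer before the last "."
parse_primer_ids <- function(bands) {
  primer <- sub("\\.[^.]*$", "", bands)
  no_dot <- !grepl("\\.", bands)
  primer[no_dot] <- bands[no_dot]
  stats::setNames(primer, bands)
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("<band_matrix> %d accessions x %d bands, %d primers, %d missing cells\n",
              nrow(x$values), ncol(x$values), length(x$primer_class),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$values)

#' Accession and band ids of a band matrix
#' @param x A `band_matrix`.
#' @return Character vector of ids.
#' @export
accession_ids <- function(x) rownames(x$values)

#' @rdname accession_ids
#' @export
band_ids <- function(x) colnames(x$values)

#' Tidy a band matrix into long format
#'
#' @param x A `band_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per accession-band cell: `accession_id`,
#'   `band_id`, `primer_id`, `class`, `present`.
#' @method tidy band_matrix
#' @export
tidy.band_matrix <- function(x, ...) {
  tibble::tibble(
    accession_id = rep(rownames(x$values), times = ncol(x$values)),
    band_id = rep(colnames(x$values), each = nrow(x$values)),
    primer_id = rep(unname(x$band_to_primer), each = nrow(x$values)),
    class = unname(x$primer_class[rep(unname(x$band_to_primer), each = nrow(x$values))]),
    present = as.integer(x$values)
  )
}

#' Read a band-presence matrix from CSV/TSV
#'
#' First column holds accession ids, remaining columns one band each.
#' The tokens `""`, `"NA"` and `"-9"` are read as missing.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the first line).
#' @param primer_map Optional path to a two-column CSV (`band_id`, `primer_id`)
#'   for files whose headers do not encode the primer.
#' @param primer_class Optional path to a two-column CSV (`primer_id`, `class`).
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path, primer_map = NULL, primer_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  hdr <- strsplit(first, sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr)) {
    stop("duplicate band header(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA", "-9"), stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus at least one band", call. = FALSE)
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("unreadable cell '%s' at accession '%s', band '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  b2p <- if (!is.null(primer_map)) {
    pm <- utils::read.csv(primer_map, stringsAsFactors = FALSE)
    stats::setNames(as.character(pm[[2L]]), as.character(pm[[1L]]))
  } else NULL
  pc <- if (!is.null(primer_class)) {
    cl <- utils::read.csv(primer_class, stringsAsFactors = FALSE)
    stats::setNames(as.character(cl[[2L]]), as.character(cl[[1L]]))
  } else NULL
  band_matrix(num, band_to_primer = b2p, primer_class = pc)
}

#' Write a band matrix to CSV
#'
#' Deterministic row/column order (as stored); missing cells serialized as
#' `"NA"`. Inverse of [read_band_matrix()] for the plain dialect.
#'
#' @param x A `band_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path) {
  stopifnot(inherits(x, "band_matrix"))
  df <- data.frame(accession_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Per-band frequencies and the polymorphic-band rule
#'
#' Band frequency is the fraction of scored (non-missing) accessions carrying
#' the band. A band is called polymorphic when its frequency lies strictly
#' between 5% and 95%; boundary values are non-polymorphic.
#'
#' @param x A `band_matrix`.
#' @return A tibble with columns `band_id`, `primer_id`, `p_band`, `n_scored`,
#'   `polymorphic`.
#' @export
band_frequencies <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  n_scored <- colSums(!is.na(x$values))
  if (any(n_scored == 0L)) {
    stop("band(s) scored in no accession: ",
         paste(colnames(x$values)[n_scored == 0L], collapse = ", "), call. = FALSE)
  }
  p <- colSums(x$values == 1L, na.rm = TRUE) / n_scored
  tibble::tibble(
    band_id = colnames(x$values),
    primer_id = unname(x$band_to_primer),
    p_band = unname(p),
    n_scored = unname(as.integer(n_scored)),
    polymorphic = unname(p > 0.05 & p < 0.95)
  )
}

#' Subset a band matrix by accessions
#'
#' Either pass accession ids directly or a metadata table plus a geographic
#' group label. Band order and primer maps are retained.
#'
#' @param x A `band_matrix`.
#' @param accessions Character vector of accession ids (order preserved).
#' @param meta Optional metadata tibble with `accession_id` and `geo_group`.
#' @param group Group label(s) to keep, resolved through `meta`.
#' @return A `band_matrix` restricted to the requested accessions.
#' @export
subset_accessions <- function(x, accessions = NULL, meta = NULL, group = NULL) {
  stopifnot(inherits(x, "band_matrix"))
  if (is.null(accessions)) {
    if (is.null(meta) || is.null(group)) {
      stop("supply `accessions`, or `meta` plus `group`", call. = FALSE)
    }
    accessions <- meta$accession_id[meta$geo_group %in% group]
  }
  missing_ids <- setdiff(accessions, rownames(x$values))
  if (length(missing_ids) > 0L) {
    stop("unknown accession id(s): ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- x
  out$values <- x$values[accessions, , drop = FALSE]
  out
}

#' Keep only polymorphic bands
#'
#' @param x A `band_matrix`.
#' @return A `band_matrix` restricted to bands with frequency strictly between
#'   5% and 95%.
#' @export
keep_polymorphic <- function(x) {
  bf <- band_frequencies(x)
  keep <- bf$band_id[bf$polymorphic]
  if (length(keep) == 0L) stop("no polymorphic bands in matrix", call. = FALSE)
  out <- x
  out$values <- x$values[, keep, drop = FALSE]
  out$band_to_primer <- x$band_to_primer[keep]
  out$primer_class <- x$primer_class[intersect(names(x$primer_class),
                                               unique(unname(out$band_to_primer)))]
  out
}

#' Read an accession metadata table
#'
#' Expects columns `accession_id`, `geo_group`, `latitude`, `longitude`,
#' `altitude`, `mat` (mean annual temperature, degrees C), `map_mm` (mean
#' annual precipitation) and `apg_mm` (mean May-August precipitation).
#'
#' @param path CSV path.
#' @return A tibble, validated for coordinate ranges.
#' @export
read_accession_meta <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_meta(df)
}

validate_meta <- function(df) {
  need <- c("accession_id", "geo_group", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("metadata missing column(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  if (anyDuplicated(df$accession_id)) stop("duplicate accession ids in metadata", call. = FALSE)
  tibble::as_tibble(df)
}
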
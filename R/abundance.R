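# Site x family abundance matrices: container, category map, pruning and
# site-maximum standardization.

#' Site x family abundance matrix
#'
#' A numeric matrix with site rows and domain-family columns, plus a flag
#' recording whether rows have been standardized by their site maxima.
#'
#' @param values Numeric matrix with row (site) and column (family) names.
#' @param standardized Logical; `TRUE` after [standardize_rows()].
#' @return The matrix with class `abundance_matrix` and attribute
#'   `standardized`.
#' @export
abundance_matrix <- function(values, standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    if (nrow(values) > 0 && is.null(rownames(values)))
      stop("abundance matrix needs site (row) names", call. = FALSE)
    if (ncol(values) > 0 && is.null(colnames(values)))
      stop("abundance matrix needs family (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate site ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate family ids", call. = FALSE)
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (isTRUE(standardized) && nrow(values) > 0 && ncol(values) > 0) {
    mx <- apply(values, 1L, max)
    if (any(mx > 0 & abs(mx - 1) > 1e-8)) {
      stop("standardized matrix must have row maxima of 1", call. = FALSE)
    }
  }
  structure(values, standardized = isTRUE(standardized),
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d sites x %d families (%s)\n",
              nrow(x), ncol(x),
              if (is_standardized(x)) "standardized" else "counts"))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]), ...)
  invisible(x)
}

#' @rdname abundance_matrix
#' @param m An `abundance_matrix`.
#' @export
is_standardized <- function(m) isTRUE(attr(m, "standardized"))

.as_plain <- function(m) {
  structure(unclass(m), standardized = NULL)
}

#' Family-to-category map
#'
#' Maps each domain family to a metabolic category (the COG-derived
#' vocabulary plus `"Photo"` for photobiologically active domains and
#' `"NA"` for unassigned families, domains of unknown function in
#' particular) and flags DUFs and families listed under more than one
#' category.
#'
#' @param family Character vector of family ids (may repeat: a family
#'   appearing with more than one distinct category is flagged
#'   multi-category).
#' @param category Character vector of category codes, same length.
#' @param is_duf Logical (or 0/1) vector, same length.
#' @return Data frame of class `category_map` with one row per family:
#'   `family`, `category` (`NA` when multi-category), `is_duf`,
#'   `multi_category`.
#' @export
category_map <- function(family, category, is_duf = FALSE) {
  family <- as.character(family)
  category <- as.character(category)
  is_duf <- as.logical(as.integer(as.logical(is_duf)))
  n <- length(family)
  stopifnot(length(category) == n)
  if (length(is_duf) == 1L) is_duf <- rep(is_duf, n)
  stopifnot(length(is_duf) == n)
  cats <- tapply(category, family, function(x) unique(x), simplify = FALSE)
  dufs <- tapply(is_duf, family, any)
  fams <- names(cats)
  multi <- vapply(cats, function(x) length(x) > 1L, logical(1L))
  resolved <- vapply(cats, function(x) if (length(x) == 1L) x else NA_character_,
                     character(1L))
  out <- data.frame(family = fams, category = unname(resolved),
                    is_duf = unname(dufs[fams]),
                    multi_category = unname(multi),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- out$family
  class(out) <- c("category_map", "data.frame")
  out
}

#' Read a category map TSV
#'
#' Expects columns `family`, `category`, `is_duf` (0/1), tab-separated,
#' with a header. A family on multiple rows with distinct categories is
#' flagged multi-category.
#'
#' @param path Path to the TSV.
#' @return A [category_map()].
#' @export
read_category_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "integer"),
                         quote = "", comment.char = "")
  category_map(d$family, d$category, d$is_duf)
}

#' Write a category map TSV
#' @param cmap A [category_map()].
#' @param path Output path.
#' @export
write_category_map <- function(cmap, path) {
  rows <- cmap
  rows$category[is.na(rows$category)] <- "MULTI"
  utils::write.table(
    data.frame(family = rows$family, category = rows$category,
               is_duf = as.integer(rows$is_duf)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.lookup_categories <- function(families, cmap) {
  missing <- setdiff(families, cmap$family)
  if (length(missing) > 0L) {
    stop("no category entry for family ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  cmap[families, , drop = FALSE]
}

#' Remove families listed in more than one metabolic category
#'
#' @param m An [abundance_matrix()].
#' @param cmap A [category_map()] covering every family in `m`.
#' @return `m` without the multi-category columns.
#' @export
drop_multicategory <- function(m, cmap) {
  info <- .lookup_categories(colnames(m), cmap)
  keep <- !info$multi_category
  abundance_matrix(.as_plain(m)[, keep, drop = FALSE],
                   standardized = is_standardized(m))
}

#' Prune sparse rows and columns
#'
#' Removes families (columns) with fewer than `min_col_nonzero` non-zero
#' abundances across the input sites and sites (rows) with fewer than
#' `min_row_nonzero` non-zero abundances across the input families. By
#' default both criteria are evaluated on the input matrix in one pass
#' and the flagged rows and columns removed together; `iterative = TRUE`
#' repeats the pass on its own output until stable.
#'
#' The default thresholds (20 and 1,000) are calibrated to an 80-site by
#' 3,587-family survey matrix; scale `min_row_nonzero` for matrices of
#' other widths.
#'
#' @param m An unstandardized [abundance_matrix()].
#' @param min_col_nonzero Minimum non-zero count for a column to be kept.
#' @param min_row_nonzero Minimum non-zero count for a row to be kept.
#' @param iterative Re-apply until a fixed point (default `FALSE`).
#' @return The pruned [abundance_matrix()].
#' @export
prune_sparse <- function(m, min_col_nonzero = 20, min_row_nonzero = 1000,
                         iterative = FALSE) {
  if (min_col_nonzero < 0 || min_row_nonzero < 0) {
    stop("pruning thresholds must be non-negative", call. = FALSE)
  }
  if (is_standardized(m)) {
    stop("prune_sparse expects an unstandardized matrix", call. = FALSE)
  }
  x <- .as_plain(m)
  repeat {
    col_nz <- colSums(x > 0)
    row_nz <- rowSums(x > 0)
    keep_col <- col_nz >= min_col_nonzero
    keep_row <- row_nz >= min_row_nonzero
    done <- all(keep_col) && all(keep_row)
    x <- x[keep_row, keep_col, drop = FALSE]
    if (done || !iterative) break
  }
  abundance_matrix(x, standardized = FALSE)
}

#' Standardize rows by their site maxima
#'
#' Divides each site's abundances by that site's maximum abundance, so
#' the largest value in each (non-empty) row becomes 1. All-zero rows
#' are left as zeros. Standardizing an already standardized matrix is an
#' error, not a silent renormalization.
#'
#' @param m An unstandardized [abundance_matrix()].
#' @return The standardized [abundance_matrix()].
#' @export
standardize_rows <- function(m) {
  if (is_standardized(m)) {
    stop("matrix is already standardized", call. = FALSE)
  }
  x <- .as_plain(m)
  if (nrow(x) > 0 && ncol(x) > 0) {
    mx <- apply(x, 1L, max)
    scale <- ifelse(mx > 0, mx, 1)
    x <- x / scale
  }
  abundance_matrix(x, standardized = TRUE)
}

#' Read / write an abundance matrix TSV
#'
#' Tab-delimited, UTF-8, `.` decimal separator; the first header cell is
#' `site`, remaining header cells are family ids; one row per site.
#'
#' @param path File path.
#' @param standardized Logical flag recorded on the returned matrix.
#' @return [abundance_matrix()] for the reader; `path` (invisibly) for
#'   the writer.
#' @export
read_abundance_tsv <- function(path, standardized = FALSE) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) == 0L || header[1L] != "site") {
    stop("abundance TSV must start with a 'site' header cell", call. = FALSE)
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         row.names = 1L, quote = "", comment.char = "")
  abundance_matrix(as.matrix(d), standardized = standardized)
}

#' @rdname read_abundance_tsv
#' @param m An [abundance_matrix()].
#' @export
write_abundance_tsv <- function(m, path) {
  x <- .as_plain(m)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("site", colnames(x)), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- apply(x, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                           collapse = "\t"))
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Category vocabulary
#'
#' The metabolic category codes used in category maps: COG-derived
#' abbreviations plus `Photo` (photobiologically active domains) and
#' `NA` (unassigned, including DUFs).
#'
#' @return Character vector of category codes.
#' @export
category_vocabulary <- function() {
  c("AA", "Carb", "CellDiv", "CoE", "CWME", "Def", "E", "Ion", "Lip",
    "Nuc", "Photo", "PostModChaps", "RRR", "Sec", "Sig", "Transcr",
    "TransR", "NA")
}
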
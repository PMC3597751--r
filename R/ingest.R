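# Parsing and filtering of HMMER3 per-domain tabular output (domtblout),
# and cross-tabulation of retained hits into a site x family count matrix.

# Standard domtblout column layout (per-domain table, hmmscan orientation:
# the target is the profile HMM, the query is the translated read).
.domtbl_cols <- c(
  model_id = 1L, model_acc = 2L, model_len = 3L,
  query_id = 4L, query_acc = 5L, query_len = 6L,
  full_evalue = 7L, full_score = 8L, full_bias = 9L,
  dom_num = 10L, dom_of = 11L,
  dom_c_evalue = 12L, dom_i_evalue = 13L,
  dom_score = 14L, dom_bias = 15L,
  hmm_from = 16L, hmm_to = 17L,
  ali_from = 18L, ali_to = 19L,
  env_from = 20L, env_to = 21L,
  acc = 22L
)

#' Parse HMMER3 per-domain tabular output
#'
#' Reads the 23+-column per-domain table written by `hmmscan --domtblout`
#' (or `hmmsearch`, with profile and sequence roles swapped accordingly:
#' here the *model* is the profile HMM and the *query* is the searched
#' read). Comment lines (leading `#`) are skipped. The free-text
#' description field (column 23 onward) may contain spaces.
#'
#' @param x Path to a domtblout file, or a character vector of its lines.
#' @return A data frame with one row per domain hit: `query_id`,
#'   `query_len`, `model_id`, `model_len`, `full_score`, `full_bias`,
#'   `dom_score`, `dom_bias`, `dom_i_evalue`, `ali_from`, `ali_to`,
#'   `hmm_from`, `hmm_to`, and `site_id` (`NA` until assigned with
#'   [assign_sites()]).
#' @seealso [filter_hits()], [tabulate_hits()]
#' @export
parse_domtblout <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    as.character(x)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  numeric_cols <- c("query_len", "model_len", "full_score", "full_bias",
                    "dom_score", "dom_bias", "dom_i_evalue",
                    "ali_from", "ali_to", "hmm_from", "hmm_to")
  if (length(idx) == 0L) return(.empty_hits())
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(fields) < length(.domtbl_cols)) {
      stop("domtblout parse error at line ", i, ": expected at least ",
           length(.domtbl_cols) + 1L, " columns, found ", length(fields),
           call. = FALSE)
    }
    rec <- list(
      query_id = fields[.domtbl_cols[["query_id"]]],
      query_len = fields[.domtbl_cols[["query_len"]]],
      model_id = fields[.domtbl_cols[["model_id"]]],
      model_len = fields[.domtbl_cols[["model_len"]]],
      full_score = fields[.domtbl_cols[["full_score"]]],
      full_bias = fields[.domtbl_cols[["full_bias"]]],
      dom_score = fields[.domtbl_cols[["dom_score"]]],
      dom_bias = fields[.domtbl_cols[["dom_bias"]]],
      dom_i_evalue = fields[.domtbl_cols[["dom_i_evalue"]]],
      ali_from = fields[.domtbl_cols[["ali_from"]]],
      ali_to = fields[.domtbl_cols[["ali_to"]]],
      hmm_from = fields[.domtbl_cols[["hmm_from"]]],
      hmm_to = fields[.domtbl_cols[["hmm_to"]]]
    )
    for (col in numeric_cols) {
      v <- suppressWarnings(as.numeric(rec[[col]]))
      if (is.na(v)) {
        stop("domtblout parse error at line ", i, ": non-numeric value '",
             rec[[col]], "' in field ", col, call. = FALSE)
      }
      rec[[col]] <- v
    }
    rows[[k]] <- rec
  }
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  out$site_id <- NA_character_
  .validate_hits(out)
  out
}

.empty_hits <- function() {
  data.frame(
    query_id = character(), query_len = numeric(),
    model_id = character(), model_len = numeric(),
    full_score = numeric(), full_bias = numeric(),
    dom_score = numeric(), dom_bias = numeric(),
    dom_i_evalue = numeric(),
    ali_from = numeric(), ali_to = numeric(),
    hmm_from = numeric(), hmm_to = numeric(),
    site_id = character(), stringsAsFactors = FALSE
  )
}

.validate_hits <- function(hits) {
  bad <- which(hits$ali_from > hits$ali_to | hits$ali_to > hits$query_len |
                 hits$hmm_from > hits$hmm_to | hits$hmm_to > hits$model_len |
                 hits$dom_i_evalue < 0)
  if (length(bad) > 0L) {
    stop("invalid domain hit coordinates/E-value in record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(hits)
}

#' Read a query-to-site map
#'
#' Two-column tab-separated file mapping read (query) identifiers to
#' sampling-site identifiers, without a header line.
#'
#' @param path Path to the TSV.
#' @return Named character vector, names are query ids, values site ids.
#' @export
read_site_map <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(m) != 2L) stop("site map must have exactly 2 columns", call. = FALSE)
  stats::setNames(m[[2L]], m[[1L]])
}

#' Attach site identifiers to domain hits
#'
#' @param hits Data frame from [parse_domtblout()].
#' @param site_map Named character vector (query id -> site id), e.g. from
#'   [read_site_map()].
#' @return `hits` with `site_id` filled in.
#' @export
assign_sites <- function(hits, site_map) {
  missing <- setdiff(unique(hits$query_id), names(site_map))
  if (length(missing) > 0L) {
    stop("no site mapping for query id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  hits$site_id <- unname(site_map[hits$query_id])
  hits
}

#' Hit significance thresholds
#'
#' The conservative domain-detection filter: a hit is retained only if its
#' per-domain independent E-value is at most `max_i_evalue`, its bias
#' composition correction times `bias_ratio` does not exceed its full
#' score (i.e. the bias is at least an order of magnitude below the score
#' at the default ratio of 10), and the alignment covers at least
#' `min_query_cov` of the query and `min_model_cov` of the model.
#'
#' @param max_i_evalue Maximum per-domain independent E-value (default 1e-3).
#' @param bias_ratio Required score/bias ratio (default 10).
#' @param min_query_cov Minimum query alignment coverage in (0, 1] (default 0.20).
#' @param min_model_cov Minimum model alignment coverage in (0, 1] (default 0.20).
#' @param use_domain_score If `TRUE`, apply the bias rule to the per-domain
#'   score/bias columns instead of the full-sequence ones.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_i_evalue = 1e-3, bias_ratio = 10,
                              min_query_cov = 0.20, min_model_cov = 0.20,
                              use_domain_score = FALSE) {
  stopifnot(max_i_evalue > 0, bias_ratio > 0,
            min_query_cov > 0, min_query_cov <= 1,
            min_model_cov > 0, min_model_cov <= 1)
  structure(list(max_i_evalue = max_i_evalue, bias_ratio = bias_ratio,
                 min_query_cov = min_query_cov, min_model_cov = min_model_cov,
                 use_domain_score = isTRUE(use_domain_score)),
            class = "filter_thresholds")
}

#' Filter domain hits by significance
#'
#' Applies the four-part significance rule of [filter_thresholds()].
#' Boundary values pass: an E-value exactly equal to `max_i_evalue`, a
#' bias exactly one `bias_ratio`-th of the score, and a coverage exactly
#' at the minimum are all retained. A non-positive score fails the bias
#' rule regardless of bias. Input order is preserved.
#'
#' @param hits Data frame of domain hits.
#' @param thresholds A [filter_thresholds()] object.
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(hits) == 0L) return(hits)
  .validate_hits(hits)
  score <- if (thresholds$use_domain_score) hits$dom_score else hits$full_score
  bias <- if (thresholds$use_domain_score) hits$dom_bias else hits$full_bias
  qcov <- (hits$ali_to - hits$ali_from + 1) / hits$query_len
  mcov <- (hits$hmm_to - hits$hmm_from + 1) / hits$model_len
  keep <- hits$dom_i_evalue <= thresholds$max_i_evalue &
    score > 0 & bias * thresholds$bias_ratio <= score &
    qcov >= thresholds$min_query_cov &
    mcov >= thresholds$min_model_cov
  hits[keep, , drop = FALSE]
}

#' Cross-tabulate retained hits into a site x family count matrix
#'
#' Counts retained domain hits per family (column) per site (row). Every
#' qualifying domain instance counts once, including multiple domains of
#' the same family on one read.
#'
#' @param hits Data frame of (filtered) hits with `site_id` assigned.
#' @param sites Character vector fixing the row order. Every hit's site
#'   must appear here; sites without hits get all-zero rows.
#' @return An [abundance_matrix()] of integer counts, rows in `sites`
#'   order, columns the distinct families in lexicographic order.
#' @export
tabulate_hits <- function(hits, sites) {
  sites <- as.character(sites)
  if (anyDuplicated(sites)) stop("duplicate site ids", call. = FALSE)
  unknown <- setdiff(unique(hits$site_id), sites)
  if (length(unknown) > 0L) {
    stop("unknown site ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  fams <- sort(unique(hits$model_id))
  m <- matrix(0, nrow = length(sites), ncol = length(fams),
              dimnames = list(sites, fams))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$site_id, levels = sites),
                 factor(hits$model_id, levels = fams))
    m[] <- as.numeric(tab)
  }
  abundance_matrix(m, standardized = FALSE)
}
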
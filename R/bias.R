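# Category-bias statistic for DUFs (the "double" rule) and per-cluster
# taxonomic distribution reports.

.node_is_duf <- function(g, name) {
  as.numeric(igraph::vertex_attr(g, "is_duf", name)) > 0
}

#' Category counts of a DUF's network neighbors
#'
#' Tallies the neighbors of a DUF node by their metabolic category.
#' Neighbors that are themselves DUFs, or carry category `"NA"`, do not
#' contribute to category counts; they are tracked separately in the
#' attributes `n_duf_neighbors` and `n_na_neighbors`.
#'
#' @param g Association network from [build_network()].
#' @param duf Name of a node flagged as a DUF.
#' @return Named integer vector of counts per category (possibly empty),
#'   with attributes `n_duf_neighbors` and `n_na_neighbors`.
#' @export
category_counts <- function(g, duf) {
  if (!duf %in% igraph::V(g)$name) {
    stop("node not in network: ", duf, call. = FALSE)
  }
  if (!.node_is_duf(g, duf)) {
    stop("node is not a DUF: ", duf, call. = FALSE)
  }
  nb <- igraph::neighbors(g, duf)
  cats <- igraph::vertex_attr(g, "category", nb)
  nb_duf <- as.numeric(igraph::vertex_attr(g, "is_duf", nb)) > 0
  informative <- !nb_duf & !is.na(cats) & cats != "NA"
  counts <- table(cats[informative])
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "n_duf_neighbors") <- sum(nb_duf)
  attr(out, "n_na_neighbors") <- sum(!nb_duf & (is.na(cats) | cats == "NA"))
  out
}

#' Detect category bias (the "double" rule)
#'
#' Bias toward a category is declared when the number of a DUF's
#' correlations to that category is at least double the number to every
#' other category. A tie at the maximum means no bias. The secondary
#' category is the largest remaining category with a positive count
#' (alphabetical tie-break), reported with its fraction of the primary
#' count; the double rule forces that fraction to be at most 0.5.
#'
#' @param counts Named non-negative numeric vector of per-category
#'   correlation counts, e.g. from [category_counts()].
#' @return A list of class `bias_record`: `counts`, `primary`,
#'   `secondary` (each a category code or `NA`), `secondary_fraction`
#'   (`NA` when no secondary).
#' @export
detect_bias <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  rec <- function(primary, secondary, fraction) {
    structure(list(counts = counts, primary = primary, secondary = secondary,
                   secondary_fraction = fraction), class = "bias_record")
  }
  if (length(counts) == 0L) return(rec(NA_character_, NA_character_, NA_real_))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  if (length(counts) == 1L) return(rec(names(counts)[1L], NA_character_, NA_real_))
  if (counts[1L] == counts[2L] || counts[1L] < 2 * counts[2L]) {
    return(rec(NA_character_, NA_character_, NA_real_))
  }
  rec(names(counts)[1L], names(counts)[2L],
      unname(counts[2L] / counts[1L]))
}

#' Category-bias table for every DUF in a network
#'
#' Applies [category_counts()] and [detect_bias()] to each DUF node,
#' mirroring the published bias-table layout: one row per DUF with its
#' primary and secondary categories, the secondary's fraction of the
#' primary, and the full count vector as a JSON column.
#'
#' @param g Association network.
#' @return Data frame with columns `duf`, `primary`, `secondary`,
#'   `secondary_fraction`, `n_category_links`, `counts_json`.
#' @export
bias_table <- function(g) {
  dufs <- igraph::V(g)$name[as.numeric(igraph::V(g)$is_duf) > 0]
  dufs <- sort(dufs)
  rows <- lapply(dufs, function(d) {
    counts <- category_counts(g, d)
    b <- detect_bias(counts)
    data.frame(
      duf = d,
      primary = if (is.na(b$primary)) NA_character_ else b$primary,
      secondary = if (is.na(b$secondary)) NA_character_ else b$secondary,
      secondary_fraction = b$secondary_fraction,
      n_category_links = sum(counts),
      counts_json = as.character(jsonlite::toJSON(as.list(b$counts),
                                                  auto_unbox = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(duf = character(), primary = character(),
                      secondary = character(), secondary_fraction = numeric(),
                      n_category_links = integer(), counts_json = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a taxonomy table TSV
#'
#' Columns `family`, `phylum`, `instances` (tab-separated, with header):
#' the number of sequence instances of each family recorded per phylum.
#'
#' @param path Path to the TSV.
#' @return Data frame of class `taxonomy_table`.
#' @export
read_taxonomy_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "numeric"),
                         quote = "", comment.char = "")
  taxonomy_table(d$family, d$phylum, d$instances)
}

#' Taxonomy table constructor
#'
#' @param family,phylum Character vectors.
#' @param instances Non-negative numeric vector of instance counts.
#' @return Data frame of class `taxonomy_table` with columns `family`,
#'   `phylum`, `instances`.
#' @export
taxonomy_table <- function(family, phylum, instances) {
  stopifnot(length(family) == length(phylum),
            length(family) == length(instances), all(instances >= 0))
  d <- data.frame(family = as.character(family), phylum = as.character(phylum),
                  instances = as.numeric(instances), stringsAsFactors = FALSE)
  class(d) <- c("taxonomy_table", "data.frame")
  d
}

#' Write a taxonomy table TSV
#' @param tax A [taxonomy_table()].
#' @param path Output path.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Taxonomic profile of a cluster's members
#'
#' Sums instance counts over the given member families per phylum, then
#' reports phyla holding strictly more than `min_pct` percent of the
#' total. Members absent from the taxonomy table are skipped with a
#' message. Percentages are over all phyla (before filtering) and
#' rounded to 2 decimals.
#'
#' @param members Character vector of family ids (typically a cluster's
#'   DUF members).
#' @param tax A [taxonomy_table()].
#' @param min_pct Strict percentage threshold for reporting (default 5).
#' @return Data frame `phylum`, `instances`, `pct`, sorted by
#'   decreasing instances.
#' @export
cluster_tax_profile <- function(members, tax, min_pct = 5) {
  empty <- data.frame(phylum = character(), instances = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE)
  if (length(members) == 0L) return(empty)
  missing <- setdiff(members, unique(tax$family))
  if (length(missing) > 0L) {
    message("cluster_tax_profile: no taxonomy for ",
            paste(missing, collapse = ", "), " (skipped)")
  }
  sub <- tax[tax$family %in% members, , drop = FALSE]
  if (nrow(sub) == 0L) return(empty)
  agg <- tapply(sub$instances, sub$phylum, sum)
  total <- sum(agg)
  pct <- 100 * agg / total
  d <- data.frame(phylum = names(agg), instances = as.numeric(agg),
                  pct = round(as.numeric(pct), 2L), stringsAsFactors = FALSE)
  d <- d[order(-d$instances, d$phylum), , drop = FALSE]
  rownames(d) <- NULL
  d[100 * d$instances / total > min_pct, , drop = FALSE]
}

#' Per-cluster taxonomy report
#'
#' Profiles the DUF members of each reportable transitivity cluster that
#' has at least `min_members` members and `min_dufs` DUFs, mirroring the
#' published cluster-taxonomy tables.
#'
#' @param tcs A `tc_set` from [transitivity_cluster()].
#' @param g The association network (provides the `is_duf` flag).
#' @param tax A [taxonomy_table()].
#' @param min_members Minimum cluster size to examine (default 4).
#' @param min_dufs Minimum number of DUF members (default 2).
#' @param min_pct Strict percentage threshold per phylum (default 5).
#' @return Data frame `cluster`, `n_duf`, `phylum`, `instances`, `pct`.
#' @export
taxonomy_report <- function(tcs, g, tax, min_members = 4, min_dufs = 2,
                            min_pct = 5) {
  out <- list()
  for (id in names(tcs$reportable)) {
    members <- tcs$reportable[[id]]
    dufs <- members[as.numeric(igraph::vertex_attr(g, "is_duf", members)) > 0]
    if (length(members) < min_members || length(dufs) < min_dufs) next
    prof <- cluster_tax_profile(dufs, tax, min_pct = min_pct)
    if (nrow(prof) == 0L) next
    out[[id]] <- data.frame(cluster = id, n_duf = length(dufs), prof,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(cluster = character(), n_duf = integer(),
                      phylum = character(), instances = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
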
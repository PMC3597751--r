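# End-to-end orchestration of the two analysis branches: UM (raw counts)
# and SM (site-maximum standardized), each running
# correlate -> prune -> network -> transitivity clusters -> bias ->
# taxonomy, with a JSON run manifest.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a domtblout file plus a
#' query-to-site map, a precomputed site x family count matrix TSV, or a
#' [synthetic_spec()].
#'
#' @param domtblout,site_map Paths to a HMMER per-domain table and its
#'   query-to-site map TSV.
#' @param matrix_tsv Path to a site x family count matrix TSV.
#' @param synthetic A [synthetic_spec()].
#' @param categories A [category_map()] or path to a category map TSV.
#'   Optional for synthetic input (the generated map is used).
#' @param taxonomy A [taxonomy_table()] or path to a taxonomy TSV.
#'   Optional; without it taxonomy reports are skipped.
#' @param filter A [filter_thresholds()] (domtblout input only).
#' @param min_col_nonzero,min_row_nonzero,prune_iterative Sparsity
#'   pruning parameters for [prune_sparse()].
#' @param policy A [significance_policy()].
#' @param model An [edit_cost_model()].
#' @param min_report_size Minimum transitivity-cluster size to report
#'   (default 3).
#' @param tax_min_members,tax_min_dufs,tax_min_pct Taxonomy-report
#'   thresholds (defaults 4, 2 and 5).
#' @param branch `"both"` (default), `"um"` or `"sm"`.
#' @param out_dir Output directory (created if needed); `NULL` runs
#'   in-memory only.
#' @param seed Integer seed (controls synthetic generation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(domtblout = NULL, site_map = NULL,
                            matrix_tsv = NULL, synthetic = NULL,
                            categories = NULL, taxonomy = NULL,
                            filter = filter_thresholds(),
                            min_col_nonzero = 20, min_row_nonzero = 1000,
                            prune_iterative = FALSE,
                            policy = significance_policy(),
                            model = edit_cost_model(),
                            min_report_size = 3,
                            tax_min_members = 4, tax_min_dufs = 2,
                            tax_min_pct = 5,
                            branch = c("both", "um", "sm"),
                            out_dir = NULL, seed = 1L) {
  branch <- match.arg(branch)
  sources <- c(domtblout = !is.null(domtblout), matrix = !is.null(matrix_tsv),
               synthetic = !is.null(synthetic))
  if (sum(sources) != 1L) {
    stop("exactly one input source (domtblout, matrix_tsv or synthetic) required",
         call. = FALSE)
  }
  if (!is.null(domtblout) && is.null(site_map)) {
    stop("domtblout input needs a site_map", call. = FALSE)
  }
  structure(list(domtblout = domtblout, site_map = site_map,
                 matrix_tsv = matrix_tsv, synthetic = synthetic,
                 categories = categories, taxonomy = taxonomy,
                 filter = filter, min_col_nonzero = min_col_nonzero,
                 min_row_nonzero = min_row_nonzero,
                 prune_iterative = prune_iterative,
                 policy = policy, model = model,
                 min_report_size = min_report_size,
                 tax_min_members = tax_min_members,
                 tax_min_dufs = tax_min_dufs, tax_min_pct = tax_min_pct,
                 branch = branch, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Published-defaults configuration
#'
#' A [pipeline_config()] carrying every published methods default:
#' E <= 1e-3, bias an order of magnitude below the score, 20% query and
#' model coverage, sparsity pruning at 20 (columns) and 1,000 (rows),
#' rho > 0.80 with the absolute ~1e-6 Bonferroni cutoff, editing
#' threshold T = 0.80, maximum sub-cluster size 50, 2 s loop budget,
#' reportable clusters >= 3 members, taxonomy for clusters with >= 4
#' members and >= 2 DUFs showing phyla > 5%.
#'
#' The row-pruning threshold of 1,000 presumes a ~3,587-family matrix;
#' pass `min_row_nonzero` scaled to your matrix width for narrower data.
#'
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
published_config <- function(...) {
  defaults <- list(
    filter = filter_thresholds(max_i_evalue = 1e-3, bias_ratio = 10,
                               min_query_cov = 0.20, min_model_cov = 0.20),
    min_col_nonzero = 20, min_row_nonzero = 1000,
    policy = significance_policy(rho_min = 0.80, alpha = 0.05,
                                 p_cutoff_override = 1e-6),
    model = edit_cost_model(threshold = 0.80, max_subcluster = 50,
                            time_budget = 2),
    min_report_size = 3, tax_min_members = 4, tax_min_dufs = 2,
    tax_min_pct = 5)
  args <- utils::modifyList(defaults, list(...))
  do.call(pipeline_config, args)
}

.load_categories <- function(config, generated = NULL) {
  if (!is.null(config$categories)) {
    if (is.character(config$categories)) return(read_category_map(config$categories))
    return(config$categories)
  }
  if (!is.null(generated)) return(generated)
  stop("no category map available", call. = FALSE)
}

.load_taxonomy <- function(config, generated = NULL) {
  if (!is.null(config$taxonomy)) {
    if (is.character(config$taxonomy)) return(read_taxonomy_tsv(config$taxonomy))
    return(config$taxonomy)
  }
  generated
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

.run_branch <- function(name, mat, cmap, tax, config) {
  res <- list(branch = name)
  res$matrix <- mat
  res$correlation <- .with_stage(paste0(name, "/correlate"),
                                 spearman_all_pairs(mat))
  res$rho_summary <- .with_stage(paste0(name, "/correlate"),
                                 rho_summary(res$correlation))
  res$pruned <- .with_stage(paste0(name, "/prune_uncorrelated"),
                            prune_uncorrelated(res$correlation, config$policy))
  res$network <- .with_stage(paste0(name, "/network"),
                             build_network(res$pruned, cmap))
  res$clusters <- .with_stage(paste0(name, "/transclust"),
                              transitivity_cluster(
                                res$network, res$pruned, config$model,
                                min_report_size = config$min_report_size))
  res$bias <- .with_stage(paste0(name, "/bias"), bias_table(res$network))
  res$taxonomy_report <- if (!is.null(tax)) {
    .with_stage(paste0(name, "/taxonomy"),
                taxonomy_report(res$clusters, res$network, tax,
                                min_members = config$tax_min_members,
                                min_dufs = config$tax_min_dufs,
                                min_pct = config$tax_min_pct))
  } else NULL
  res
}

.write_branch <- function(res, dir, tag) {
  bdir <- file.path(dir, tag)
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_tsv(res$matrix, file.path(bdir, "matrix.tsv"))
  write_correlation_tsv(res$pruned, file.path(bdir, "correlations.tsv"))
  utils::write.table(
    data.frame(statistic = names(res$rho_summary),
               value = as.numeric(res$rho_summary)),
    file.path(bdir, "rho_summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  export_graph(res$network, file.path(bdir, "network.graphml"), "graphml")
  export_graph(res$network, file.path(bdir, "network_edges.tsv"), "edge-tsv")
  utils::write.table(cluster_report(res$clusters, res$network),
                     file.path(bdir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$bias, file.path(bdir, "bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$taxonomy_report)) {
    utils::write.table(res$taxonomy_report, file.path(bdir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bdir)
}

#' Run the full analysis pipeline
#'
#' Executes ingest (or matrix/synthetic loading), multi-category
#' removal and sparsity pruning, then forks into the UM branch (raw
#' counts) and the SM branch (site-maximum standardized), each running
#' correlation, pruning, network assembly, transitivity clustering,
#' bias detection and taxonomy reporting. When `out_dir` is set, a
#' per-branch report bundle and a JSON run manifest (parameters, seed,
#' stage-by-stage dimensions) are written; a stage failure leaves a
#' `FAILED` marker naming the stage next to any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the shared stages (`input`, `pruned
#'   matrix`), per-branch results (`um`, `sm`), the `truth` (synthetic
#'   input only) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package = "ecodomnet",
    version = as.character(utils::packageVersion("ecodomnet")),
    seed = config$seed,
    branch = config$branch,
    parameters = list(
      filter = unclass(config$filter),
      min_col_nonzero = config$min_col_nonzero,
      min_row_nonzero = config$min_row_nonzero,
      policy = unclass(config$policy),
      model = unclass(config$model),
      min_report_size = config$min_report_size,
      taxonomy = list(min_members = config$tax_min_members,
                      min_dufs = config$tax_min_dufs,
                      min_pct = config$tax_min_pct)),
    stages = list())
  dims <- function(m) list(sites = nrow(m), families = ncol(m))
  out <- list()
  run <- function() {
    gen <- NULL
    truth <- NULL
    if (!is.null(config$synthetic)) {
      spec <- config$synthetic
      spec$seed <- config$seed
      gen <- .with_stage("synthetic", generate_synthetic(spec))
      mat <- gen$matrix
      truth <- gen$truth
    } else if (!is.null(config$matrix_tsv)) {
      mat <- .with_stage("ingest", read_abundance_tsv(config$matrix_tsv))
    } else {
      mat <- .with_stage("ingest", {
        hits <- parse_domtblout(config$domtblout)
        smap <- read_site_map(config$site_map)
        hits <- assign_sites(hits, smap)
        hits <- filter_hits(hits, config$filter)
        tabulate_hits(hits, sort(unique(unname(smap))))
      })
    }
    manifest$stages$input <<- dims(mat)
    cmap <- .load_categories(config, if (!is.null(gen)) gen$categories)
    tax <- .load_taxonomy(config, if (!is.null(gen)) gen$taxonomy)
    mat <- .with_stage("drop_multicategory", drop_multicategory(mat, cmap))
    manifest$stages$drop_multicategory <<- dims(mat)
    mat <- .with_stage("prune_sparse",
                       prune_sparse(mat, config$min_col_nonzero,
                                    config$min_row_nonzero,
                                    iterative = config$prune_iterative))
    manifest$stages$prune_sparse <<- dims(mat)
    out$pruned_matrix <<- mat
    out$truth <<- truth
    if (config$branch %in% c("both", "um")) {
      out$um <<- .run_branch("um", mat, cmap, tax, config)
      manifest$stages$um <<- list(
        families_in = ncol(mat),
        families_retained = length(out$um$pruned$families),
        edges = igraph::ecount(out$um$network),
        reportable_clusters = length(out$um$clusters$reportable))
    }
    if (config$branch %in% c("both", "sm")) {
      sm_mat <- .with_stage("standardize_rows", standardize_rows(mat))
      out$sm <<- .run_branch("sm", sm_mat, cmap, tax, config)
      manifest$stages$sm <<- list(
        families_in = ncol(sm_mat),
        families_retained = length(out$sm$pruned$families),
        edges = igraph::ecount(out$sm$network),
        reportable_clusters = length(out$sm$clusters$reportable))
    }
    invisible(NULL)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    status <- tryCatch({ run(); "ok" }, error = function(e) {
      writeLines(conditionMessage(e), file.path(config$out_dir, "FAILED"))
      stop(e)
    })
    if (!is.null(out$um)) .write_branch(out$um, config$out_dir, "um")
    if (!is.null(out$sm)) .write_branch(out$sm, config$out_dir, "sm")
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    run()
  }
  out$manifest <- manifest
  invisible(out)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the nested
#' mappings `filter`, `policy`, `model` and `synthetic` are forwarded to
#' [filter_thresholds()], [significance_policy()], [edit_cost_model()]
#' and [synthetic_spec()] respectively.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$filter)) args$filter <- do.call(filter_thresholds, y$filter)
  if (!is.null(y$policy)) args$policy <- do.call(significance_policy, y$policy)
  if (!is.null(y$model)) args$model <- do.call(edit_cost_model, y$model)
  if (!is.null(y$synthetic)) {
    syn <- y$synthetic
    if (!is.null(syn$modules)) {
      syn$modules <- lapply(syn$modules, function(m)
        do.call(synthetic_module, m))
    }
    args$synthetic <- do.call(synthetic_spec, syn)
  }
  do.call(pipeline_config, args)
}
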
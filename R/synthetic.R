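# Planted-module synthetic site x family count matrices, with category
# labels, DUF flags, per-site library-size factors and taxonomy tables,
# plus truth-evaluation metrics (adjusted Rand index, bias recall).
#
# Generative model: counts are Poisson-lognormal with a multiplicative
# per-site library factor. Per site s: f_s ~ LogNormal(0, site_factor_sd).
# Per family d: base mean mu_d ~ LogNormal(base_mean_log_mean,
# base_mean_log_sd). Per module m and site s: activity
# a_{m,s} ~ LogNormal(0, strength_m), shared by the module's families.
# X_{s,d} ~ Poisson(f_s * mu_d * a) for module families (a = 1 for
# background), then each cell is independently set to zero with
# probability zero_inflation. The shared site factor reproduces the
# library-size co-variation that site-maximum standardization removes;
# the shared module activity plants genuine co-varying modules.

#' Module description for the synthetic generator
#'
#' @param size Number of families in the module (>= 2).
#' @param category A single category code, or `"mixed"` for per-family
#'   random categories.
#' @param duf_fraction Fraction of the module's families flagged as DUFs
#'   (category `"NA"`).
#' @param strength Log-scale standard deviation of the module's shared
#'   per-site activity (0 = no planted signal).
#' @return A list describing one module.
#' @export
synthetic_module <- function(size, category, duf_fraction = 0.3,
                             strength = 1.0) {
  stopifnot(size >= 2, duf_fraction >= 0, duf_fraction <= 1, strength >= 0)
  list(size = as.integer(size), category = category,
       duf_fraction = duf_fraction, strength = strength)
}

#' Specification of a synthetic site x family survey
#'
#' Defaults emulate the structure of an ocean-survey domain-abundance
#' matrix at reduced width: 80 sites, six 10-family modules with
#' distinct single categories, and 120 background families.
#'
#' @param n_sites Number of sites (default 80).
#' @param n_background Number of background (non-module) families
#'   (default 120).
#' @param modules List of [synthetic_module()] descriptions (default six
#'   modules of 10 families, strength 1.0, 30% DUFs).
#' @param site_factor_sd Log-sd of the per-site library factor
#'   (default 0.3).
#' @param base_mean_log_mean,base_mean_log_sd Lognormal parameters of
#'   the per-family base mean (defaults `log(20)` and 1.0).
#' @param zero_inflation Probability that a sampled count is replaced by
#'   zero, independently per cell (default 0.05).
#' @param background_duf_fraction Fraction of background families
#'   flagged as DUFs (default 0.3).
#' @param background_multi_fraction Fraction of background non-DUF
#'   families listed under two categories, exercising multi-category
#'   removal (default 0.05).
#' @param seed Integer master seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 80, n_background = 120,
                           modules = NULL, site_factor_sd = 0.3,
                           base_mean_log_mean = log(20),
                           base_mean_log_sd = 1.0,
                           zero_inflation = 0.05,
                           background_duf_fraction = 0.3,
                           background_multi_fraction = 0.05,
                           seed = 1L) {
  if (is.null(modules)) {
    cats <- c("Photo", "E", "RRR", "Ion", "Nuc", "CoE")
    modules <- lapply(cats, function(cc) synthetic_module(10L, cc))
  }
  stopifnot(n_sites >= 1, n_background >= 0,
            site_factor_sd >= 0, base_mean_log_sd >= 0,
            zero_inflation >= 0, zero_inflation < 1)
  structure(list(n_sites = as.integer(n_sites),
                 n_background = as.integer(n_background),
                 modules = modules, site_factor_sd = site_factor_sd,
                 base_mean_log_mean = base_mean_log_mean,
                 base_mean_log_sd = base_mean_log_sd,
                 zero_inflation = zero_inflation,
                 background_duf_fraction = background_duf_fraction,
                 background_multi_fraction = background_multi_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.stage_seeds <- function(seed, n = 6L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic survey
#'
#' Draws a site x family count matrix with planted co-varying modules
#' under the spec's Poisson-lognormal model, together with the matching
#' category map, a DUF taxonomy table (each module gets a dominant
#' phylum), and the ground truth. Deterministic for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `matrix` ([abundance_matrix()] of counts),
#'   `categories` ([category_map()]), `taxonomy` ([taxonomy_table()]),
#'   `truth` (data frame `family`, `module`, `category`, `is_duf` plus
#'   attributes `site_factors`, `module_info`, `n_inflated`, `n_cells`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- .stage_seeds(spec$seed, 6L)
  n_sites <- spec$n_sites
  sites <- sprintf("S%03d", seq_len(n_sites))
  n_mod <- length(spec$modules)
  mod_sizes <- vapply(spec$modules, `[[`, integer(1L), "size")
  n_fam <- sum(mod_sizes) + spec$n_background

  # family labels, module assignment, categories, DUF flags
  set.seed(seeds[1L])
  fam <- character(n_fam)
  module <- character(n_fam)
  categ <- character(n_fam)
  is_duf <- logical(n_fam)
  vocab <- setdiff(category_vocabulary(), "NA")
  pos <- 0L
  for (mi in seq_len(n_mod)) {
    mod <- spec$modules[[mi]]
    idx <- pos + seq_len(mod$size)
    n_duf <- round(mod$duf_fraction * mod$size)
    duf_members <- idx[seq_len(n_duf)]
    module[idx] <- paste0("M", mi)
    is_duf[duf_members] <- TRUE
    categ[idx] <- if (identical(mod$category, "mixed"))
      sample(vocab, mod$size, replace = TRUE) else mod$category
    categ[duf_members] <- "NA"
    fam[idx] <- ifelse(is_duf[idx],
                       sprintf("DUF%d%02d", mi, seq_len(mod$size)),
                       sprintf("PF%d%03d", mi, seq_len(mod$size)))
    pos <- pos + mod$size
  }
  if (spec$n_background > 0L) {
    idx <- pos + seq_len(spec$n_background)
    module[idx] <- "background"
    bg_duf <- stats::runif(spec$n_background) < spec$background_duf_fraction
    is_duf[idx] <- bg_duf
    categ[idx] <- sample(vocab, spec$n_background, replace = TRUE)
    categ[idx][bg_duf] <- "NA"
    fam[idx] <- ifelse(bg_duf, sprintf("DUF9%03d", seq_len(spec$n_background)),
                       sprintf("PF9%03d", seq_len(spec$n_background)))
  }

  # rates: site factors, base means, module activities
  set.seed(seeds[2L])
  f_site <- stats::rlnorm(n_sites, 0, spec$site_factor_sd)
  mu <- stats::rlnorm(n_fam, spec$base_mean_log_mean, spec$base_mean_log_sd)
  lambda <- outer(f_site, mu)
  for (mi in seq_len(n_mod)) {
    strength <- spec$modules[[mi]]$strength
    act <- if (strength > 0) stats::rlnorm(n_sites, 0, strength) else rep(1, n_sites)
    cols <- which(module == paste0("M", mi))
    lambda[, cols] <- lambda[, cols] * act
  }

  # counts and zero inflation
  set.seed(seeds[3L])
  x <- matrix(stats::rpois(length(lambda), lambda), nrow = n_sites,
              dimnames = list(sites, fam))
  set.seed(seeds[4L])
  inflate <- matrix(stats::runif(length(x)) < spec$zero_inflation,
                    nrow = n_sites)
  x[inflate] <- 0

  # category map (a slice of background non-DUFs gets a second listing)
  set.seed(seeds[5L])
  cm_family <- fam
  cm_categ <- categ
  bg_nonduf <- which(module == "background" & !is_duf)
  n_multi <- round(spec$background_multi_fraction * length(bg_nonduf))
  if (n_multi > 0L) {
    multi_idx <- sample(bg_nonduf, n_multi)
    second <- vapply(categ[multi_idx], function(cc)
      sample(setdiff(vocab, cc), 1L), character(1L))
    cm_family <- c(cm_family, fam[multi_idx])
    cm_categ <- c(cm_categ, second)
  }
  cmap <- category_map(cm_family, cm_categ,
                       is_duf = is_duf[match(cm_family, fam)])

  # taxonomy for DUFs: module DUFs concentrated in a module phylum
  set.seed(seeds[6L])
  phyla <- c("Proteobacteria", "Cyanobacteria", "Firmicutes",
             "Actinobacteria", "Bacteroidetes", "Viridiplantae", "Fungi",
             "Metazoa")
  mod_phyla <- phyla[1L + (seq_len(n_mod) - 1L) %% length(phyla)]
  tax_rows <- list()
  for (k in which(is_duf)) {
    total <- max(20L, round(stats::rlnorm(1L, log(300), 0.5)))
    if (module[k] == "background") {
      share <- as.vector(stats::rmultinom(1L, total,
                                          prob = rep(1, length(phyla))))
    } else {
      mi <- as.integer(sub("^M", "", module[k]))
      dom_share <- stats::rbeta(1L, 17, 3)   # ~85% in the module phylum
      dom <- round(dom_share * total)
      rest <- as.vector(stats::rmultinom(1L, total - dom,
                                         prob = rep(1, length(phyla) - 1L)))
      share <- integer(length(phyla))
      share[match(mod_phyla[mi], phyla)] <- dom
      share[-match(mod_phyla[mi], phyla)] <- rest
    }
    keep <- share > 0
    tax_rows[[length(tax_rows) + 1L]] <- data.frame(
      family = fam[k], phylum = phyla[keep], instances = share[keep],
      stringsAsFactors = FALSE)
  }
  tax <- if (length(tax_rows) > 0L) {
    d <- do.call(rbind, tax_rows)
    taxonomy_table(d$family, d$phylum, d$instances)
  } else {
    taxonomy_table(character(), character(), numeric())
  }

  truth <- data.frame(family = fam, module = module, category = categ,
                      is_duf = is_duf, stringsAsFactors = FALSE)
  attr(truth, "site_factors") <- stats::setNames(f_site, sites)
  attr(truth, "module_info") <- data.frame(
    module = paste0("M", seq_len(n_mod)),
    category = vapply(spec$modules, function(m) as.character(m$category),
                      character(1L)),
    strength = vapply(spec$modules, `[[`, numeric(1L), "strength"),
    phylum = mod_phyla, stringsAsFactors = FALSE)
  attr(truth, "n_inflated") <- sum(inflate)
  attr(truth, "n_cells") <- length(x)

  list(matrix = abundance_matrix(x, standardized = FALSE),
       categories = cmap, taxonomy = tax, truth = truth)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the
#' same elements: `(Index - Expected) / (Max - Expected)`.
#'
#' @param a,b Vectors of cluster labels over the same elements (matched
#'   by position, or by name when both are fully named).
#' @return The ARI, a number in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) == 0L) stop("empty element set", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different element sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(length(a), 2)
  expected <- sum_i * sum_j / total
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Planted-structure recovery report
#'
#' Measures how well the pipeline recovered the generator's planted
#' structure: the ARI between reportable cluster assignments and planted
#' module labels (over families assigned to any reportable cluster), and
#' the fraction of DUFs planted in single-category modules whose
#' [detect_bias()] primary category equals the planted category.
#'
#' @param truth Truth data frame from [generate_synthetic()].
#' @param tcs A `tc_set` from [transitivity_cluster()].
#' @param g Optional association network; required for `bias_recall`.
#' @return List `ari`, `n_clustered`, `degenerate` (`TRUE` when no
#'   reportable clusters exist and `ari` is reported as 0), and
#'   `bias_recall` (`NA` without a network or without eligible DUFs).
#' @export
recovery_report <- function(truth, tcs, g = NULL) {
  assignment <- unlist(lapply(names(tcs$reportable), function(id)
    stats::setNames(rep(id, length(tcs$reportable[[id]])),
                    tcs$reportable[[id]])))
  if (length(assignment) == 0L) {
    ari <- 0; degenerate <- TRUE; n_clustered <- 0L
  } else {
    fams <- names(assignment)
    planted <- truth$module[match(fams, truth$family)]
    ari <- adjusted_rand(assignment, stats::setNames(planted, fams))
    degenerate <- FALSE
    n_clustered <- length(fams)
  }
  bias_recall <- NA_real_
  if (!is.null(g)) {
    mod_info <- attr(truth, "module_info")
    single_mods <- mod_info$module[mod_info$category != "mixed"]
    eligible <- truth$family[truth$is_duf & truth$module %in% single_mods]
    if (length(eligible) > 0L) {
      hit <- vapply(eligible, function(d) {
        if (!d %in% igraph::V(g)$name) return(FALSE)
        b <- detect_bias(category_counts(g, d))
        planted_cat <- mod_info$category[mod_info$module ==
                                           truth$module[truth$family == d]]
        identical(b$primary, planted_cat)
      }, logical(1L))
      bias_recall <- mean(hit)
    }
  }
  list(ari = ari, n_clustered = n_clustered, degenerate = degenerate,
       bias_recall = bias_recall)
}
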
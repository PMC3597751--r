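# All-pairs Spearman rank correlation with Bonferroni control, and
# removal of families with no qualifying association.

#' All-pairs Spearman rank correlation of family columns
#'
#' Computes the Spearman correlation for every pair of family columns:
#' the product-moment correlation of average-ranked columns (ties get
#' average ranks). Two-sided p-values come from the usual t
#' approximation, `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; `|rho| = 1` gives `p = 0`. Constant columns yield
#' undefined (`NA`) correlations for all their pairs.
#'
#' @param m An [abundance_matrix()] (or plain matrix) with at least 3
#'   rows (sites) and 2 columns (families).
#' @return A list of class `correlation_result`: `families`, symmetric
#'   `rho` (unit diagonal) and `p` (diagonal `NA`) matrices, `n` (number
#'   of sites), and `significant` (`NULL` until [prune_uncorrelated()]).
#' @export
spearman_all_pairs <- function(m) {
  x <- as.matrix(m)
  n <- nrow(x)
  if (n < 3L) stop("insufficient sites: need at least 3, got ", n, call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 families", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ranks <- apply(x, 2L, rank)   # average ranks for ties
  constant <- apply(x, 2L, function(v) min(v) == max(v))
  rho <- suppressWarnings(stats::cor(ranks))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  rho[!is.na(rho)] <- pmin(pmax(rho[!is.na(rho)], -1), 1)
  diag(rho) <- ifelse(constant, NA_real_, 1)
  p <- .spearman_p(rho, n)
  diag(p) <- NA_real_
  structure(list(families = colnames(x), rho = rho, p = p, n = n,
                 significant = NULL),
            class = "correlation_result")
}

.spearman_p <- function(rho, n) {
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  p
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d families over %d sites%s\n",
              length(x$families), x$n,
              if (!is.null(x$significant))
                sprintf(", %d significant pairs",
                        sum(x$significant[upper.tri(x$significant)], na.rm = TRUE))
              else ""))
  invisible(x)
}

#' Significance policy for correlation thresholds
#'
#' Qualifying associations must exceed `rho_min` (strictly) and fall
#' below the Bonferroni-corrected p cutoff (strictly). The cutoff is
#' `alpha / m_tests` unless `p_cutoff_override` is set, which mirrors
#' the published absolute cutoff of ~1e-6.
#'
#' @param rho_min Minimum correlation, strict (default 0.80).
#' @param alpha Family-wise error rate (default 0.05).
#' @param m_tests Number of tests; defaults to the number of unordered
#'   family pairs of the correlation result at evaluation time.
#' @param p_cutoff_override Absolute p cutoff overriding `alpha / m_tests`.
#' @param use_absolute If `TRUE`, apply the rho threshold to `|rho|`
#'   (default `FALSE`: only positive correlations qualify).
#' @return A list of class `significance_policy`.
#' @export
significance_policy <- function(rho_min = 0.80, alpha = 0.05, m_tests = NULL,
                                p_cutoff_override = NULL, use_absolute = FALSE) {
  stopifnot(rho_min >= 0, rho_min <= 1, alpha > 0, alpha < 1)
  if (!is.null(m_tests)) stopifnot(m_tests >= 1)
  structure(list(rho_min = rho_min, alpha = alpha, m_tests = m_tests,
                 p_cutoff_override = p_cutoff_override,
                 use_absolute = isTRUE(use_absolute)),
            class = "significance_policy")
}

#' Bonferroni-corrected p cutoff
#'
#' @param policy A [significance_policy()].
#' @param m_tests Number of tests; used when the policy does not carry
#'   one. Ignored when the policy has an absolute override.
#' @return The p cutoff as a single number.
#' @export
bonferroni_cutoff <- function(policy, m_tests = NULL) {
  if (!is.null(policy$p_cutoff_override)) return(policy$p_cutoff_override)
  m <- if (!is.null(policy$m_tests)) policy$m_tests else m_tests
  if (is.null(m) || m < 1) stop("m_tests must be at least 1", call. = FALSE)
  policy$alpha / m
}

.significance_mask <- function(cres, policy) {
  cutoff <- bonferroni_cutoff(
    policy, m_tests = choose(length(cres$families), 2L))
  r <- if (policy$use_absolute) abs(cres$rho) else cres$rho
  mask <- !is.na(r) & !is.na(cres$p) & r > policy$rho_min & cres$p < cutoff
  diag(mask) <- FALSE
  mask
}

#' Drop families with no qualifying correlation
#'
#' Marks a pair significant when `rho > rho_min` and `p < cutoff` (both
#' strict), then removes families with no significant partner from all
#' matrices.
#'
#' @param cres A `correlation_result` from [spearman_all_pairs()].
#' @param policy A [significance_policy()].
#' @return A pruned `correlation_result` with its `significant` mask set
#'   and the applied `p_cutoff` recorded.
#' @export
prune_uncorrelated <- function(cres, policy = significance_policy()) {
  mask <- .significance_mask(cres, policy)
  keep <- rowSums(mask) > 0
  out <- structure(list(
    families = cres$families[keep],
    rho = cres$rho[keep, keep, drop = FALSE],
    p = cres$p[keep, keep, drop = FALSE],
    n = cres$n,
    significant = mask[keep, keep, drop = FALSE],
    p_cutoff = bonferroni_cutoff(policy,
                                 m_tests = choose(length(cres$families), 2L)),
    policy = policy
  ), class = "correlation_result")
  out
}

#' Mean and standard deviation of pairwise correlations
#'
#' Summarizes the upper triangle of defined rho values: the mean and
#' sample standard deviation. A single defined pair has `sd = 0` by
#' convention.
#'
#' @param cres A `correlation_result`.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
rho_summary <- function(cres) {
  v <- cres$rho[upper.tri(cres$rho)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no defined correlation pairs", call. = FALSE)
  s <- if (length(v) < 2L) 0 else stats::sd(v)
  c(mean = mean(v), sd = s)
}

#' Write correlations as a long-format TSV
#'
#' Columns `family_a`, `family_b`, `rho`, `p`, `significant` (0/1; 0
#' when no mask has been computed), one row per unordered defined pair.
#'
#' @param cres A `correlation_result`.
#' @param path Output path.
#' @export
write_correlation_tsv <- function(cres, path) {
  ut <- upper.tri(cres$rho)
  idx <- which(ut & !is.na(cres$rho), arr.ind = TRUE)
  sig <- if (is.null(cres$significant)) rep(0L, nrow(idx)) else
    as.integer(cres$significant[idx])
  d <- data.frame(
    family_a = cres$families[idx[, 1L]],
    family_b = cres$families[idx[, 2L]],
    rho = cres$rho[idx],
    p = cres$p[idx],
    significant = sig
  )
  d <- d[order(d$family_a, d$family_b), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
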
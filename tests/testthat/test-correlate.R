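test_that("the classical five-point example gives rho 0.8 and the t-based p", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  rownames(m) <- paste0("S", 1:5)
  res <- spearman_all_pairs(m)
  # sum of squared rank differences is 4: rho = 1 - 6*4/120 = 0.8
  expect_equal(res$rho["x", "y"], 0.8, tolerance = 1e-15)
  oracle <- naive_spearman(m[, "x"], m[, "y"])
  expect_equal(res$p["x", "y"], unname(oracle["p"]), tolerance = 1e-12)
  expect_equal(round(res$p["x", "y"], 3), 0.104)
})

test_that("a monotone linear relation gives rho 1 and p 0", {
  x <- c(0.3, 1.1, 2.5, 7, 9.2, 14)
  m <- cbind(x = x, y = 2 * x + 3)
  rownames(m) <- paste0("S", seq_along(x))
  res <- spearman_all_pairs(m)
  expect_equal(res$rho["x", "y"], 1)
  expect_equal(res$p["x", "y"], 0)
})

test_that("correlations are invariant under strictly increasing transforms", {
  set.seed(77)
  m <- matrix(rpois(60, 9), 12, 5, dimnames = list(paste0("S", 1:12),
                                                   paste0("F", 1:5)))
  r1 <- spearman_all_pairs(m)$rho
  m2 <- m
  m2[, 1] <- exp(m2[, 1] / 3)
  m2[, 3] <- m2[, 3]^3 + 0.5
  r2 <- spearman_all_pairs(m2)$rho
  expect_equal(r1, r2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all-pairs results match the naive oracle, including ties", {
  set.seed(42)
  for (rep in 1:8) {
    m <- matrix(rpois(12 * 6, 4), 12, 6)   # small counts force ties
    dimnames(m) <- list(paste0("S", 1:12), paste0("F", 1:6))
    res <- spearman_all_pairs(m)
    for (i in 1:5) for (j in (i + 1):6) {
      o <- naive_spearman(m[, i], m[, j])
      expect_equal(res$rho[i, j], unname(o["rho"]), tolerance = 1e-12)
      expect_equal(res$p[i, j], unname(o["p"]), tolerance = 1e-10)
    }
  }
})

test_that("constant columns give undefined correlations, never NaN leakage", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  rownames(m) <- paste0("S", 1:4)
  res <- spearman_all_pairs(m)
  expect_true(is.na(res$rho["a", "b"]))
  expect_true(is.na(res$p["b", "c"]))
  expect_false(is.na(res$rho["a", "c"]))
  pruned <- prune_uncorrelated(res, significance_policy(rho_min = 0,
                                                        alpha = 0.999))
  expect_false("b" %in% pruned$families)
  expect_false(anyNA(rho_summary(res)))
})

test_that("too few sites is a clean error", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("a", "b")))
  expect_error(spearman_all_pairs(m), "insufficient sites")
})

test_that("the Bonferroni cutoff divides alpha unless overridden", {
  expect_equal(bonferroni_cutoff(significance_policy(alpha = 0.05),
                                 m_tests = 50000), 1e-6)
  expect_equal(bonferroni_cutoff(significance_policy(alpha = 0.05,
                                                     p_cutoff_override = 1e-6),
                                 m_tests = 7), 1e-6)
  expect_equal(bonferroni_cutoff(significance_policy(alpha = 0.05),
                                 m_tests = 1), 0.05)
})

test_that("pruning applies strict thresholds and drops isolated families", {
  fams <- c("a", "b", "c", "d")
  rho <- matrix(0, 4, 4, dimnames = list(fams, fams))
  diag(rho) <- 1
  p <- matrix(1, 4, 4, dimnames = list(fams, fams))
  set_pair <- function(i, j, r, pv) {
    rho[i, j] <<- rho[j, i] <<- r
    p[i, j] <<- p[j, i] <<- pv
  }
  set_pair("a", "b", 0.85, 1e-9)   # qualifies
  set_pair("c", "d", 0.80, 1e-12)  # rho not strictly greater -> out
  set_pair("a", "c", 0.85, 1e-5)   # p not below cutoff -> out
  cres <- make_cres(rho, p, n = 69)
  pol <- significance_policy(rho_min = 0.80, p_cutoff_override = 1e-6)
  pruned <- prune_uncorrelated(cres, pol)
  expect_setequal(pruned$families, c("a", "b"))
  expect_true(pruned$significant["a", "b"])
})

test_that("pruning is monotone in both thresholds", {
  set.seed(5)
  m <- matrix(rlnorm(20 * 12), 20, 12,
              dimnames = list(paste0("S", 1:20), paste0("F", 1:12)))
  mod <- rlnorm(20)
  m[, 1:4] <- m[, 1:4] * mod   # make some structure
  cres <- spearman_all_pairs(m)
  base <- prune_uncorrelated(cres, significance_policy(rho_min = 0.3,
                                                       p_cutoff_override = 0.01))
  for (pol in list(significance_policy(rho_min = 0.5, p_cutoff_override = 0.01),
                   significance_policy(rho_min = 0.3, p_cutoff_override = 1e-4))) {
    tighter <- prune_uncorrelated(cres, pol)
    expect_true(all(tighter$families %in% base$families))
  }
})

test_that("the rho summary reports mean and sample sd of defined pairs", {
  fams <- c("a", "b", "c")
  rho <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3, 3,
                dimnames = list(fams, fams))
  p <- matrix(0.5, 3, 3, dimnames = list(fams, fams))
  s <- rho_summary(make_cres(rho, p, n = 10))
  expect_equal(unname(s["mean"]), 0.4)
  expect_equal(unname(s["sd"]), 0.2)

  flat <- matrix(0.5, 3, 3, dimnames = list(fams, fams))
  diag(flat) <- 1
  s2 <- rho_summary(make_cres(flat, p, n = 10))
  expect_equal(unname(s2["mean"]), 0.5)
  expect_equal(unname(s2["sd"]), 0)

  two <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  s3 <- rho_summary(make_cres(two, two, n = 10))
  expect_equal(unname(s3["sd"]), 0)   # single pair: sd 0 by convention

  allna <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(rho_summary(make_cres(allna, allna, n = 10)), "no defined")
})

test_that("long-format correlation export lists each defined pair once", {
  set.seed(8)
  m <- matrix(rpois(30, 6), 10, 3, dimnames = list(paste0("S", 1:10),
                                                   c("a", "b", "c")))
  res <- spearman_all_pairs(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_tsv(res, f)
  d <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 3L)
  expect_equal(sort(paste(d$family_a, d$family_b)),
               c("a b", "a c", "b c"))
})
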
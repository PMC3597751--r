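test_that("generation is deterministic for a seed and validates its spec", {
  g1 <- generate_synthetic(synthetic_spec(seed = 123))
  g2 <- generate_synthetic(synthetic_spec(seed = 123))
  expect_identical(unclass(g1$matrix), unclass(g2$matrix))
  expect_identical(g1$categories, g2$categories)
  expect_identical(as.data.frame(g1$taxonomy), as.data.frame(g2$taxonomy))
  g3 <- generate_synthetic(synthetic_spec(seed = 124))
  expect_false(identical(unclass(g1$matrix), unclass(g3$matrix)))

  expect_error(synthetic_spec(zero_inflation = 1))
  expect_error(synthetic_module(size = 1, category = "Photo"))
})

test_that("the emitted matrix matches the truth labels and dimensions", {
  spec <- synthetic_spec(n_sites = 40, n_background = 30, seed = 6)
  gen <- generate_synthetic(spec)
  expect_equal(nrow(gen$matrix), 40L)
  expect_equal(ncol(gen$matrix), 60L + 30L)
  expect_setequal(colnames(gen$matrix), gen$truth$family)
  expect_true(all(gen$matrix >= 0))
  expect_true(all(gen$truth$family %in% gen$categories$family))
  # DUFs carry the unassigned category
  dufs <- gen$truth$family[gen$truth$is_duf]
  expect_true(all(gen$categories[dufs, "category"] == "NA"))
  # module members share their module's category
  mi <- attr(gen$truth, "module_info")
  m1 <- gen$truth$family[gen$truth$module == "M1" & !gen$truth$is_duf]
  expect_true(all(gen$categories[m1, "category"] ==
                    mi$category[mi$module == "M1"]))
})

test_that("the zero-inflation rate tracks its parameter", {
  spec <- synthetic_spec(zero_inflation = 0.3, seed = 9)
  gen <- generate_synthetic(spec)
  rate <- attr(gen$truth, "n_inflated") / attr(gen$truth, "n_cells")
  expect_lt(abs(rate - 0.3), 0.02)
})

test_that("without module signal, module families look like background", {
  diffs <- sapply(11:15, function(sd) {
    mods <- lapply(c("Photo", "E", "RRR", "Ion", "Nuc", "CoE"),
                   function(cc) synthetic_module(10L, cc, strength = 0))
    gen <- generate_synthetic(synthetic_spec(modules = mods, seed = sd))
    cr <- spearman_all_pairs(gen$matrix)
    tr <- gen$truth
    inmod <- tr$module != "background"
    same_mod <- outer(tr$module, tr$module, "==") & outer(inmod, inmod, "&")
    diag(same_mod) <- FALSE
    bg <- outer(!inmod, !inmod, "&")
    diag(bg) <- FALSE
    mean(cr$rho[same_mod], na.rm = TRUE) - mean(cr$rho[bg], na.rm = TRUE)
  })
  expect_true(all(abs(diffs) < 0.06))
})

test_that("planted modules co-vary more within than between", {
  hits <- 0L
  for (sd in 1:20) {
    mods <- lapply(c("Photo", "E", "RRR", "Ion", "Nuc"),
                   function(cc) synthetic_module(10L, cc, strength = 1.0))
    spec <- synthetic_spec(n_sites = 80, n_background = 0, modules = mods,
                           zero_inflation = 0.3, seed = 200 + sd)
    gen <- generate_synthetic(spec)
    cr <- spearman_all_pairs(gen$matrix)
    tr <- gen$truth
    same <- outer(tr$module, tr$module, "==")
    diag(same) <- FALSE
    within <- mean(cr$rho[same], na.rm = TRUE)
    between <- mean(cr$rho[!same & upper.tri(cr$rho)], na.rm = TRUE)
    if (within > between) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("the adjusted Rand index matches its pair-counting definition", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(adjusted_rand(c("x", "x", "y", "y"), c(1, 1, 2, 2)), 1.0)
  # {1,2|3,4} vs {1,3|2,4}
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # all singletons vs a partition with non-trivial clusters
  expect_lte(adjusted_rand(1:6, c(1, 1, 1, 2, 2, 2)), 0)
  expect_error(adjusted_rand(integer(0), integer(0)), "empty")
  # named vectors align by element
  a <- c(A = 1, B = 1, C = 2)
  b <- c(C = 9, A = 4, B = 4)
  expect_equal(adjusted_rand(a, b), 1.0)
})

test_that("the hand-rolled ARI agrees with an independent implementation", {
  set.seed(77)
  for (k in 1:25) {
    n <- sample(6:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("recovery reports flag the no-cluster degenerate case", {
  gen <- generate_synthetic(synthetic_spec(seed = 3))
  tcs <- structure(list(reportable = list()), class = "tc_set")
  rep <- recovery_report(gen$truth, tcs)
  expect_equal(rep$ari, 0)
  expect_true(rep$degenerate)
  expect_true(is.na(rep$bias_recall))
})

test_that("the default spec is recovered by the pipeline at high fidelity", {
  aris <- c()
  cond_recall <- c()
  for (sd in 1:6) {
    res <- run_pipeline(synthetic_published_config(synthetic_spec(), seed = sd))
    rep <- recovery_report(res$truth, res$um$clusters, res$um$network)
    aris <- c(aris, rep$ari)
    # conditional recall: planted-category recovery among DUFs that
    # survived correlation pruning
    tr <- res$truth
    mi <- attr(tr, "module_info")
    elig <- tr$family[tr$is_duf & tr$module != "background"]
    present <- elig[elig %in% igraph::V(res$um$network)$name]
    hit <- vapply(present, function(d) {
      b <- detect_bias(category_counts(res$um$network, d))
      identical(b$primary, mi$category[mi$module == tr$module[tr$family == d]])
    }, logical(1))
    cond_recall <- c(cond_recall, mean(hit))
    # reportable clusters containing module families are module-pure
    for (mem in res$um$clusters$reportable) {
      mods <- tr$module[match(mem, tr$family)]
      mods <- mods[mods != "background"]
      if (length(mods) > 0) expect_equal(length(unique(mods)), 1L)
    }
  }
  expect_gte(mean(aris), 0.9)
  expect_gte(mean(cond_recall), 0.8)
})
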
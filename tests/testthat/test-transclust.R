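test_that("the editing cost sums join and separation penalties", {
  m <- edit_cost_model(threshold = 0.8)
  # two clean cliques: all intra above T, all inter below -> zero cost
  nodes <- c("A", "B", "C", "D")
  s <- matrix(0.1, 4, 4, dimnames = list(nodes, nodes))
  s["A", "B"] <- s["B", "A"] <- s["C", "D"] <- s["D", "C"] <- 0.95
  diag(s) <- NA
  expect_equal(editing_cost(list(c("A", "B"), c("C", "D")), s, m), 0)

  expect_equal(editing_cost(list(c("A", "B"), c("C", "D")), p4_sim(), m), 0.1)
  expect_equal(editing_cost(list(c("A", "B", "C")), triangle_sim(), m), 0.3)

  expect_error(editing_cost(list(c("A", "B"), c("B", "C", "D")), p4_sim(), m),
               "overlapping")
  expect_error(editing_cost(list(c("A", "B")), p4_sim(), m), "cover")
})

test_that("the exact solver minimizes over all partitions with canonical ties", {
  m <- edit_cost_model(threshold = 0.8)
  cs <- cluster_exact(p4_sim(), m)
  expect_true(cs$exact)
  expect_equal(cs$clusters, list(c("A", "B"), c("C", "D")))
  expect_equal(cs$total_cost, 0.1)

  tri <- cluster_exact(triangle_sim(), m)
  expect_equal(tri$total_cost, 0.1)
  # tie between {AB|C} and {A|BC}: canonical order picks {A|BC}
  expect_equal(tri$clusters, list("A", c("B", "C")))
  # determinism
  expect_identical(cluster_exact(triangle_sim(), m)$clusters, tri$clusters)

  single <- cluster_exact(matrix(NA_real_, 1, 1, dimnames = list("A", "A")), m)
  expect_equal(single$clusters, list("A"))
  expect_equal(single$total_cost, 0)

  expect_error(cluster_exact(random_similarity(6),
                             edit_cost_model(exact_limit = 5)),
               "cluster_heuristic")
})

test_that("exact costs equal the brute-force minimum on random instances", {
  set.seed(131)
  m <- edit_cost_model(threshold = 0.8)
  for (k in 1:40) {
    s <- random_similarity(sample(4:8, 1))
    cs <- cluster_exact(s, m)
    expect_equal(cs$total_cost, brute_force_min_cost(s, 0.8),
                 tolerance = 1e-9)
    # reported cost is consistent with an independent recomputation
    expect_equal(editing_cost(cs$clusters, s, m), cs$total_cost,
                 tolerance = 1e-9)
  }
})

test_that("the heuristic is sound and recovers clean clique structure", {
  m <- edit_cost_model(threshold = 0.8)
  nodes <- paste0("n", 1:9)
  s <- matrix(0.05, 9, 9, dimnames = list(nodes, nodes))
  for (grp in list(1:3, 4:6, 7:9)) s[grp, grp] <- 0.95
  diag(s) <- NA
  h <- cluster_heuristic(s, m)
  expect_equal(h$total_cost, 0)
  expect_equal(length(h$clusters), 3L)
  expect_false(h$exact)

  set.seed(7)
  for (k in 1:30) {
    sr <- random_similarity(sample(4:8, 1))
    ex <- cluster_exact(sr, m)
    hr <- cluster_heuristic(sr, m)
    expect_gte(hr$total_cost, ex$total_cost - 1e-9)
    n <- nrow(sr)
    trivials <- c(editing_cost(as.list(rownames(sr)), sr, m),
                  editing_cost(list(rownames(sr)), sr, m))
    expect_lte(hr$total_cost, min(trivials) + 1e-9)
  }

  # zero budget skips local search but still returns a valid partition
  h0 <- cluster_heuristic(random_similarity(7),
                          edit_cost_model(time_budget = 0))
  expect_equal(sort(unlist(h0$clusters)), paste0("n", 1:7))
})

test_that("component dispatch reports clusters by size with TC labels", {
  # two 3-cliques joined by one weak edge: separating (cost 0.01) beats joining
  nodes <- data.frame(name = letters[1:6], category = "Photo", is_duf = 0)
  intra <- rbind(t(combn(letters[1:3], 2)), t(combn(letters[4:6], 2)))
  edges <- data.frame(from = c(intra[, 1], "c"), to = c(intra[, 2], "d"),
                      weight = c(rep(0.95, 6), 0.81))
  g <- make_network(edges, nodes)
  tcs <- transitivity_cluster(g, model = edit_cost_model(threshold = 0.8))
  expect_equal(length(tcs$reportable), 2L)
  expect_equal(tcs$reportable$TC1, c("a", "b", "c"))
  expect_equal(tcs$reportable$TC2, c("d", "e", "f"))
  expect_equal(tcs$total_cost, 0.01, tolerance = 1e-9)
  # component cost is reproducible from the realized partition
  sim <- similarity_matrix(g)
  expect_equal(editing_cost(lapply(tcs$clusters, `[[`, "members"), sim,
                            edit_cost_model(threshold = 0.8)),
               tcs$total_cost, tolerance = 1e-9)

  # small components below the reporting size are suppressed
  nodes2 <- data.frame(name = c("a", "b", "c", "x", "y"),
                       category = "Photo", is_duf = 0)
  edges2 <- data.frame(from = c("a", "b", "a", "x"), to = c("b", "c", "c", "y"),
                       weight = 0.9)
  g2 <- make_network(edges2, nodes2)
  tcs2 <- transitivity_cluster(g2, model = edit_cost_model())
  expect_equal(names(tcs2$reportable), "TC1")
  expect_equal(tcs2$reportable$TC1, c("a", "b", "c"))

  empty <- transitivity_cluster(igraph::make_empty_graph(0, directed = FALSE),
                                model = edit_cost_model())
  expect_equal(length(empty$reportable), 0L)
})

test_that("clusters partition each component and a higher threshold never merges", {
  set.seed(55)
  nodes <- data.frame(name = paste0("v", 1:10), category = "Photo", is_duf = 0)
  prs <- t(combn(nodes$name, 2))
  keep <- runif(nrow(prs)) < 0.45
  edges <- data.frame(from = prs[keep, 1], to = prs[keep, 2],
                      weight = runif(sum(keep), 0.81, 0.99))
  g <- make_network(edges, nodes)
  n_at <- sapply(c(0.8, 0.85, 0.9, 0.95), function(tt) {
    tcs <- transitivity_cluster(g, model = edit_cost_model(threshold = tt),
                                min_report_size = 1)
    members <- unlist(lapply(tcs$clusters, `[[`, "members"))
    expect_setequal(members, nodes$name)       # cover
    expect_false(anyDuplicated(members) > 0)   # disjoint
    length(tcs$clusters)
  })
  expect_true(all(diff(n_at) >= 0))
})

test_that("oversized clusters are re-clustered at a raised threshold", {
  # one tight 6-clique; cap at 3 forces a split even though joined is optimal
  nodes <- data.frame(name = paste0("v", 1:6), category = "Photo", is_duf = 0)
  prs <- t(combn(nodes$name, 2))
  w <- rep(0.9, nrow(prs))
  w[prs[, 1] %in% c("v1", "v2", "v3") & prs[, 2] %in% c("v1", "v2", "v3")] <- 0.99
  w[prs[, 1] %in% c("v4", "v5", "v6") & prs[, 2] %in% c("v4", "v5", "v6")] <- 0.99
  g <- make_network(data.frame(from = prs[, 1], to = prs[, 2], weight = w),
                    nodes)
  tcs <- transitivity_cluster(g, model = edit_cost_model(threshold = 0.8,
                                                         max_subcluster = 3))
  sizes <- sort(sapply(tcs$clusters, function(x) length(x$members)))
  expect_true(all(sizes <= 3))
  expect_setequal(unlist(lapply(tcs$clusters, `[[`, "members")), nodes$name)
})

test_that("the cluster report tabulates sizes, DUF counts and solver flags", {
  nodes <- data.frame(name = c("DUF1", "p", "q"), category = c("NA", "E", "E"),
                      is_duf = c(1, 0, 0))
  edges <- data.frame(from = c("DUF1", "DUF1", "p"), to = c("p", "q", "q"),
                      weight = 0.9)
  g <- make_network(edges, nodes)
  tcs <- transitivity_cluster(g, model = edit_cost_model())
  rep <- cluster_report(tcs, g)
  expect_equal(rep$cluster_id, "TC1")
  expect_equal(rep$size, 3L)
  expect_equal(rep$n_duf, 1L)
  expect_true(rep$exact)
})
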
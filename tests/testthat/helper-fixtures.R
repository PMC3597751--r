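# Shared fixtures and independent oracles, all built in code.

# One domtblout record (23 columns, hmmscan orientation: target = model,
# query = read). Defaults describe a clean passing hit.
domtbl_line <- function(model = "PF00001.17", tlen = 100, query = "read001",
                        qlen = 100, full_evalue = 1e-12, score = 50, bias = 0,
                        dom_i = 1L, dom_of = 1L, c_evalue = 1e-10,
                        i_evalue = 1e-6, dscore = 49.5, dbias = 0,
                        hmm_from = 1, hmm_to = 100, ali_from = 1,
                        ali_to = 100, env_from = 1, env_to = 100,
                        acc = 0.95, desc = "synthetic fixture record") {
  paste(model, "PF00001.17", tlen, query, "-", qlen,
        format(full_evalue), score, bias, dom_i, dom_of,
        format(c_evalue), format(i_evalue), dscore, dbias,
        hmm_from, hmm_to, ali_from, ali_to, env_from, env_to, acc, desc)
}

# Ten-record filter fixture: six retained (including every inclusive
# boundary), four rejected with exactly one violated criterion each.
filter_fixture_lines <- function() {
  c("# synthetic domtblout fixture",
    "#",
    domtbl_line(model = "PF_pass1", query = "r01"),
    domtbl_line(model = "PF_pass2", query = "r02", i_evalue = 1e-3),   # E boundary
    domtbl_line(model = "PF_pass3", query = "r03",
                ali_from = 41, ali_to = 60),                           # 20% query cov
    domtbl_line(model = "PF_pass4", query = "r04",
                hmm_from = 1, hmm_to = 20),                            # 20% model cov
    domtbl_line(model = "PF_pass5", query = "r05", bias = 5, score = 50), # bias boundary
    domtbl_line(model = "PF_pass6", query = "r06"),
    domtbl_line(model = "PF_badE", query = "r07", i_evalue = 2e-3),
    domtbl_line(model = "PF_badBias", query = "r08", bias = 5.1, score = 50),
    domtbl_line(model = "PF_badQcov", query = "r09", ali_from = 1, ali_to = 19),
    domtbl_line(model = "PF_badMcov", query = "r10", hmm_from = 1, hmm_to = 19))
}

# Independent Spearman oracle: naive rank-then-Pearson plus the t CDF.
naive_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  c(rho = r, p = p)
}

# All set partitions of n elements as membership vectors (one row per
# partition, restricted-growth enumeration); memoised per n.
.partition_cache <- new.env(parent = emptyenv())
all_partitions_mv <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  res <- list()
  rec <- function(mv, k) {
    i <- length(mv) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- mv
      return()
    }
    for (cl in 1:(k + 1L)) rec(c(mv, cl), max(k, cl))
  }
  rec(integer(0), 0L)
  out <- do.call(rbind, res)
  .partition_cache[[key]] <- out
  out
}

# Brute-force minimum editing cost over all partitions, computed with
# its own direct pair sum (independent of editing_cost()).
brute_force_min_cost <- function(sim, threshold) {
  n <- nrow(sim)
  mv <- all_partitions_mv(n)
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  costs <- numeric(nrow(mv))
  for (r in seq_len(nrow(ut))) {
    i <- ut[r, 1L]
    j <- ut[r, 2L]
    sij <- sim[i, j]
    same <- mv[, i] == mv[, j]
    costs <- costs + ifelse(same, max(0, threshold - sij),
                            max(0, sij - threshold))
  }
  min(costs)
}

# Path A-B-C-D with adjacent similarity 0.9, non-adjacent 0: the optimal
# editing at T = 0.8 separates B-C for cost 0.1.
p4_sim <- function() {
  nodes <- c("A", "B", "C", "D")
  s <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  for (pr in list(c("A", "B"), c("B", "C"), c("C", "D"))) {
    s[pr[1], pr[2]] <- s[pr[2], pr[1]] <- 0.9
  }
  diag(s) <- NA
  s
}

# Triangle with two strong edges (0.9) and one weak (0.5): optimal cost
# 0.1 with a tie between the two 2+1 splits.
triangle_sim <- function() {
  nodes <- c("A", "B", "C")
  s <- matrix(NA_real_, 3, 3, dimnames = list(nodes, nodes))
  s["A", "B"] <- s["B", "A"] <- 0.9
  s["B", "C"] <- s["C", "B"] <- 0.9
  s["A", "C"] <- s["C", "A"] <- 0.5
  s
}

# Random symmetric similarity matrix with named nodes.
random_similarity <- function(n, lo = -0.2, hi = 1) {
  s <- matrix(runif(n * n, lo, hi), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- NA
  nm <- paste0("n", seq_len(n))
  dimnames(s) <- list(nm, nm)
  s
}

# Hand-built correlation result (already "pruned" when a mask is given).
make_cres <- function(rho, p, n, mask = NULL) {
  fams <- rownames(rho)
  structure(list(families = fams, rho = rho, p = p, n = n,
                 significant = mask),
            class = "correlation_result")
}

# Small annotated network from an edge list and node attribute table.
make_network <- function(edges, nodes) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

# The UM-branch pipeline configuration used in synthetic-recovery tests:
# published thresholds with the row-pruning minimum rescaled to the
# synthetic matrix width (1000/3587 of ~180 columns -> 50).
synthetic_published_config <- function(spec, seed, branch = "um") {
  published_config(synthetic = spec, seed = seed, branch = branch,
                     min_row_nonzero = 50)
}
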
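# Weighted transitive-graph-projection (cluster editing) of the
# association network: exact subset dynamic programming for small
# components, a greedy + relocation heuristic with a time budget for
# large ones.
#
# Cost model: for a pair with similarity s and threshold T, keeping the
# pair together costs max(0, T - s) (a missing/weak edge must be added)
# and separating it costs max(0, s - T) (a strong edge must be removed).
# The difference (intra minus inter cost) of a pair is simply T - s,
# which both solvers exploit.

#' Cluster-editing cost model
#'
#' @param threshold Similarity threshold T (default 0.80, matching the
#'   network's correlation threshold: the clustered graph only carries
#'   edges with rho > 0.80).
#' @param missing_similarity Similarity assumed for node pairs with no
#'   edge and no available correlation (default 0, i.e. a join cost of
#'   T).
#' @param exact_limit Largest component size solved exactly (default 12).
#' @param time_budget Seconds allowed for the heuristic's local-search
#'   loop (default 2).
#' @param max_subcluster Clusters larger than this are re-clustered at
#'   an increased threshold (default 50).
#' @return A list of class `edit_cost_model`.
#' @export
edit_cost_model <- function(threshold = 0.80, missing_similarity = 0,
                            exact_limit = 12, time_budget = 2,
                            max_subcluster = 50) {
  stopifnot(exact_limit >= 1, time_budget >= 0, max_subcluster >= 1)
  structure(list(threshold = threshold,
                 missing_similarity = missing_similarity,
                 exact_limit = exact_limit, time_budget = time_budget,
                 max_subcluster = max_subcluster),
            class = "edit_cost_model")
}

#' Pairwise similarity matrix for clustering
#'
#' Node-pair similarities feeding the cluster-editing cost: the edge
#' weight where an edge exists, the full correlation where a
#' `correlation_result` is supplied, and `missing_similarity` otherwise.
#'
#' @param g Association network.
#' @param cres Optional `correlation_result` supplying correlations for
#'   non-adjacent pairs.
#' @param missing_similarity Fallback similarity (default 0).
#' @return Symmetric numeric matrix with `NA` diagonal, node names as
#'   dimnames.
#' @export
similarity_matrix <- function(g, cres = NULL, missing_similarity = 0) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  s <- matrix(missing_similarity, n, n, dimnames = list(nodes, nodes))
  if (!is.null(cres)) {
    common <- intersect(nodes, cres$families)
    sub <- cres$rho[common, common, drop = FALSE]
    sub[is.na(sub)] <- missing_similarity
    s[common, common] <- sub
  }
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) > 0L) {
    s[cbind(el$from, el$to)] <- el$weight
    s[cbind(el$to, el$from)] <- el$weight
  }
  diag(s) <- NA_real_
  s
}

#' Editing cost of a partition
#'
#' Sum over intra-cluster pairs of `max(0, T - s)` plus sum over
#' inter-cluster pairs of `max(0, s - T)`.
#'
#' @param partition List of character vectors partitioning the node set
#'   (the row/column names of `sim`).
#' @param sim Symmetric similarity matrix.
#' @param model An [edit_cost_model()] (only its threshold is used).
#' @return The total editing cost.
#' @export
editing_cost <- function(partition, sim, model = edit_cost_model()) {
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members)) stop("overlapping clusters", call. = FALSE)
  nodes <- rownames(sim)
  if (!setequal(members, nodes)) {
    stop("partition does not cover the node set", call. = FALSE)
  }
  memb <- integer(length(nodes))
  names(memb) <- nodes
  for (k in seq_along(partition)) memb[partition[[k]]] <- k
  tt <- model$threshold
  ut <- upper.tri(sim)
  same <- outer(memb[nodes], memb[nodes], "==")
  intra <- sum(pmax(tt - sim[ut & same], 0))
  inter <- sum(pmax(sim[ut & !same] - tt, 0))
  intra + inter
}

.cluster_set <- function(clusters, total_cost, exact) {
  clusters <- lapply(clusters, function(x) x[order(x)])
  ord <- order(vapply(clusters, `[`, character(1L), 1L))
  structure(list(clusters = clusters[ord], total_cost = total_cost,
                 exact = exact),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, cost %.4g (%s)\n",
              length(x$clusters), x$total_cost,
              if (x$exact) "exact" else "heuristic"))
  invisible(x)
}

#' Exact minimum-cost cluster editing
#'
#' Finds a minimum-editing-cost partition by dynamic programming over
#' vertex subsets (the intra-minus-inter cost of a pair reduces to
#' `T - s`, so the objective decomposes over clusters up to a constant).
#' Runs in O(3^n); components larger than `exact_limit` must go to
#' [cluster_heuristic()]. Ties are broken by preferring fewer clusters,
#' then the lexicographically smallest canonical form (clusters ordered
#' by their smallest member in node order).
#'
#' @param sim Symmetric similarity matrix of one connected component.
#' @param model An [edit_cost_model()].
#' @return A `cluster_set` with `exact = TRUE`.
#' @export
cluster_exact <- function(sim, model = edit_cost_model()) {
  nodes <- rownames(sim)
  n <- length(nodes)
  if (n > model$exact_limit) {
    stop("component of size ", n, " exceeds exact_limit (",
         model$exact_limit, "); use cluster_heuristic()", call. = FALSE)
  }
  if (n == 0L) return(.cluster_set(list(), 0, TRUE))
  if (n == 1L) return(.cluster_set(list(nodes), 0, TRUE))
  tt <- model$threshold
  d <- tt - sim          # intra-pair weight; NA diagonal unused
  diag(d) <- 0
  ut <- upper.tri(sim)
  sep_all <- sum(pmax(sim[ut] - tt, 0))
  npart <- bitwShiftL(1L, n)
  pow <- bitwShiftL(1L, 0:(n - 1L))
  lbidx <- integer(npart)
  lbidx[pow + 1L] <- seq_len(n)
  # cross[i, S+1] = sum_{k in S} d[i, k]
  cross <- matrix(0, n, npart)
  pairsum <- numeric(npart)
  for (S in 1:(npart - 1L)) {
    lb <- bitwAnd(S, -S)
    j <- lbidx[lb + 1L]
    rest <- S - lb
    cross[, S + 1L] <- cross[, rest + 1L] + d[, j]
    pairsum[S + 1L] <- pairsum[rest + 1L] + cross[j, rest + 1L]
  }
  tol <- 1e-9
  f <- numeric(npart)       # best cluster-decomposed cost for mask S
  nc <- integer(npart)      # number of clusters in best solution
  choice <- integer(npart)  # first cluster (mask) of best solution
  reconstruct <- function(S) {
    out <- list()
    while (S > 0L) {
      C <- choice[S + 1L]
      out[[length(out) + 1L]] <- which(bitwAnd(C, pow) != 0L)
      S <- S - C
    }
    out
  }
  flatten <- function(p) unlist(lapply(p, function(cl) c(cl, 0L)))
  canon_less <- function(a, b) {
    fa <- flatten(a); fb <- flatten(b)
    k <- min(length(fa), length(fb))
    diff <- which(fa[seq_len(k)] != fb[seq_len(k)])
    if (length(diff) == 0L) return(length(fa) < length(fb))
    fa[diff[1L]] < fb[diff[1L]]
  }
  for (S in 1:(npart - 1L)) {
    lb <- bitwAnd(S, -S)
    rest <- S - lb
    best <- Inf; best_nc <- NA_integer_; best_C <- NA_integer_
    sub <- rest
    repeat {
      C <- sub + lb
      remainder <- S - C
      v <- pairsum[C + 1L] + f[remainder + 1L]
      k <- nc[remainder + 1L] + 1L
      better <- FALSE
      if (v < best - tol) {
        better <- TRUE
      } else if (v < best + tol) {
        if (k < best_nc) {
          better <- TRUE
        } else if (k == best_nc) {
          cand <- c(list(which(bitwAnd(C, pow) != 0L)), reconstruct(remainder))
          cur <- c(list(which(bitwAnd(best_C, pow) != 0L)),
                   reconstruct(S - best_C))
          if (canon_less(cand, cur)) better <- TRUE
        }
      }
      if (better) { best <- v; best_nc <- k; best_C <- C }
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, rest)
    }
    f[S + 1L] <- best
    nc[S + 1L] <- best_nc
    choice[S + 1L] <- best_C
  }
  full <- npart - 1L
  part_idx <- reconstruct(full)
  clusters <- lapply(part_idx, function(ix) nodes[ix])
  .cluster_set(clusters, sep_all + f[full + 1L], TRUE)
}

#' Heuristic cluster editing
#'
#' Greedy seeded agglomeration in order of descending pair similarity
#' (merging two clusters whenever the merge lowers the editing cost),
#' followed by single-node relocation local search until no improving
#' move remains or the time budget is exhausted. The result never costs
#' more than the all-singletons or the single-cluster partition. With
#' `time_budget = 0` the greedy partition is returned without local
#' search. Deterministic for a given input.
#'
#' @param sim Symmetric similarity matrix of one connected component.
#' @param model An [edit_cost_model()].
#' @return A `cluster_set` with `exact = FALSE`.
#' @export
cluster_heuristic <- function(sim, model = edit_cost_model()) {
  nodes <- rownames(sim)
  n <- length(nodes)
  if (n == 0L) return(.cluster_set(list(), 0, FALSE))
  if (n == 1L) return(.cluster_set(list(nodes), 0, FALSE))
  tt <- model$threshold
  s <- sim
  diag(s) <- -Inf
  memb <- seq_len(n)
  # greedy agglomeration over pairs in descending similarity
  ut <- which(upper.tri(s), arr.ind = TRUE)
  ord <- order(s[ut], -ut[, 1L], -ut[, 2L], decreasing = TRUE)
  merge_delta <- function(a, b) {
    ia <- which(memb == a); ib <- which(memb == b)
    sum(tt - s[ia, ib])
  }
  for (k in ord) {
    i <- ut[k, 1L]; j <- ut[k, 2L]
    a <- memb[i]; b <- memb[j]
    if (a == b) next
    if (merge_delta(a, b) < 0) memb[memb == b] <- a
  }
  # relocation local search under the time budget
  if (model$time_budget > 0) {
    deadline <- Sys.time() + model$time_budget
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        old <- memb[i]
        mates <- which(memb == old); mates <- mates[mates != i]
        leave <- sum(s[i, mates] - tt)      # intra -> inter
        targets <- setdiff(unique(memb), old)
        best_delta <- leave                 # move to a new singleton
        best_target <- 0L
        for (cl in targets) {
          into <- which(memb == cl)
          delta <- leave + sum(tt - s[i, into])
          if (delta < best_delta - 1e-12) {
            best_delta <- delta; best_target <- cl
          }
        }
        if (best_delta < -1e-12) {
          memb[i] <- if (best_target == 0L) max(memb) + 1L else best_target
          improved <- TRUE
        }
      }
      if (!improved || Sys.time() > deadline) break
    }
  }
  part <- lapply(split(seq_len(n), memb), function(ix) nodes[ix])
  cand <- list(unname(part),
               as.list(nodes),        # all singletons
               list(nodes))           # one cluster
  costs <- vapply(cand, editing_cost, numeric(1L), sim = sim, model = model)
  pick <- which.min(costs)
  .cluster_set(cand[[pick]], costs[pick], FALSE)
}

.solve_component <- function(sim, model) {
  if (nrow(sim) <= model$exact_limit) {
    cluster_exact(sim, model)
  } else {
    cluster_heuristic(sim, model)
  }
}

# Re-cluster clusters exceeding max_subcluster at threshold + 0.01
# increments until all fit (similarities are correlations <= 1, so the
# threshold eventually exceeds every similarity and the component falls
# apart into singletons).
.enforce_max_subcluster <- function(cs, sim, model) {
  out <- list()
  queue <- lapply(cs$clusters, function(m) list(members = m,
                                                threshold = model$threshold))
  exact <- cs$exact
  while (length(queue) > 0L) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    if (length(item$members) <= model$max_subcluster) {
      out[[length(out) + 1L]] <- item$members
      next
    }
    sub_model <- model
    sub_model$threshold <- item$threshold + 0.01
    sub <- .solve_component(sim[item$members, item$members, drop = FALSE],
                            sub_model)
    exact <- exact && sub$exact
    if (length(sub$clusters) == 1L) {
      # no split at this threshold: push back with the raised threshold
      queue <- c(queue, list(list(members = item$members,
                                  threshold = sub_model$threshold)))
    } else {
      queue <- c(queue, lapply(sub$clusters, function(m)
        list(members = m, threshold = model$threshold)))
    }
  }
  cost <- editing_cost(out, sim, model)
  .cluster_set(out, cost, exact)
}

#' Transitivity clustering of the association network
#'
#' Partitions each connected component of the network into clique-like
#' clusters by weighted cluster editing: components up to
#' `model$exact_limit` nodes are solved exactly, larger ones
#' heuristically under the model's time budget. Clusters larger than
#' `model$max_subcluster` are re-clustered at threshold + 0.01
#' increments. Clusters with at least `min_report_size` members are
#' labeled TC1, TC2, ... in order of decreasing size (canonical
#' tie-break on the first member).
#'
#' @param g Association network from [build_network()].
#' @param cres Optional `correlation_result` supplying similarities for
#'   non-adjacent pairs (recommended; otherwise
#'   `model$missing_similarity` is used).
#' @param model An [edit_cost_model()].
#' @param min_report_size Minimum cluster size to report (default 3).
#' @return A list of class `tc_set`: `reportable` (named list TC1, ...),
#'   `clusters` (all clusters with members/exact flag/component id),
#'   `component_costs`, `total_cost`, `model`.
#' @export
transitivity_cluster <- function(g, cres = NULL, model = edit_cost_model(),
                                 min_report_size = 3) {
  comps <- network_components(g)
  sim_full <- similarity_matrix(g, cres,
                                missing_similarity = model$missing_similarity)
  all_clusters <- list()
  comp_costs <- numeric(length(comps))
  for (ci in seq_along(comps)) {
    members <- comps[[ci]]
    sim <- sim_full[members, members, drop = FALSE]
    cs <- .solve_component(sim, model)
    cs <- .enforce_max_subcluster(cs, sim, model)
    comp_costs[ci] <- cs$total_cost
    for (cl in cs$clusters) {
      all_clusters[[length(all_clusters) + 1L]] <-
        list(members = cl, exact = cs$exact, component = ci)
    }
  }
  sizes <- vapply(all_clusters, function(x) length(x$members), integer(1L))
  firsts <- vapply(all_clusters, function(x) sort(x$members)[1L], character(1L))
  ord <- order(-sizes, firsts)
  all_clusters <- all_clusters[ord]
  sizes <- sizes[ord]
  rep_idx <- which(sizes >= min_report_size)
  reportable <- lapply(all_clusters[rep_idx], function(x) sort(x$members))
  names(reportable) <- if (length(rep_idx) > 0L)
    paste0("TC", seq_along(rep_idx)) else character(0)
  structure(list(reportable = reportable, clusters = all_clusters,
                 component_costs = comp_costs,
                 total_cost = sum(comp_costs), model = model,
                 min_report_size = min_report_size),
            class = "tc_set")
}

#' @export
print.tc_set <- function(x, ...) {
  cat(sprintf("tc_set: %d clusters (%d reportable, >= %d members), total cost %.4g\n",
              length(x$clusters), length(x$reportable), x$min_report_size,
              x$total_cost))
  invisible(x)
}

#' Tabular cluster report
#'
#' @param tcs A `tc_set`.
#' @param g Optional network supplying the `is_duf` flag for the
#'   `n_duf` column.
#' @return Data frame `cluster_id`, `size`, `n_duf`, `members`
#'   (comma-separated), `component_cost`, `exact` over the reportable
#'   clusters.
#' @export
cluster_report <- function(tcs, g = NULL) {
  ids <- names(tcs$reportable)
  rows <- lapply(seq_along(ids), function(k) {
    members <- tcs$reportable[[k]]
    info <- tcs$clusters[[which(vapply(tcs$clusters, function(x)
      setequal(x$members, members), logical(1L)))[1L]]]
    n_duf <- if (is.null(g)) NA_integer_ else
      sum(as.numeric(igraph::vertex_attr(g, "is_duf", members)) > 0)
    data.frame(cluster_id = ids[k], size = length(members), n_duf = n_duf,
               members = paste(members, collapse = ","),
               component_cost = tcs$component_costs[info$component],
               exact = info$exact, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(cluster_id = character(), size = integer(),
                      n_duf = integer(), members = character(),
                      component_cost = numeric(), exact = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
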
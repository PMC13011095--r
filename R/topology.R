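#' @keywords internal
.as_igraph <- function(network) {
  if (inherits(network, "cooccurrence_network")) network$graph
  else if (igraph::is_igraph(network)) network
  else stop("expected a cooccurrence_network or igraph object")
}

# Distance-derived quantities over connected (finite) ordered pairs only.
#' @keywords internal
.path_metrics <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2)
    return(list(GD = NA_real_, E = NA_real_, HD = NA_real_,
                unreachable = 0L))
  dm <- igraph::distances(g)
  off <- dm[upper.tri(dm)]
  fin <- off[is.finite(off)]
  unreachable <- sum(!is.finite(off))
  if (!length(fin))
    return(list(GD = NA_real_, E = 0, HD = NA_real_,
                unreachable = unreachable))
  e <- mean(1 / fin)
  list(GD = mean(fin), E = e, HD = 1 / e, unreachable = unreachable)
}

# Number-of-geodesics matrix by BFS from every source (unweighted).
#' @keywords internal
.geodesic_counts <- function(g, dm) {
  n <- igraph::vcount(g)
  nb <- igraph::adjacent_vertices(g, seq_len(n))
  nb <- lapply(nb, as.integer)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dm[s, ]
    sig[s, s] <- 1
    maxd <- max(d[is.finite(d)])
    if (maxd < 1) next
    for (lev in seq_len(maxd)) {
      for (v in which(d == lev))
        sig[s, v] <- sum(sig[s, nb[[v]][d[nb[[v]]] == lev - 1]])
    }
  }
  sig
}

#' Stress centrality of every node
#'
#' The number of shortest paths between other node pairs that pass
#' through each node (the unnormalised count analogue of betweenness).
#'
#' @param g an igraph object (treated as undirected, unweighted).
#' @return numeric vector of stress values.
#' @export
stress_centrality <- function(g) {
  g <- .as_igraph(g)
  n <- igraph::vcount(g)
  dm <- igraph::distances(g)
  sig <- .geodesic_counts(g, dm)
  stress <- numeric(n)
  for (v in seq_len(n)) {
    thru <- outer(sig[, v], sig[v, ])           # sigma_sv * sigma_vt
    onpath <- outer(dm[, v], dm[v, ], "+") == dm & is.finite(dm)
    thru[!onpath] <- 0
    thru[v, ] <- 0; thru[, v] <- 0; diag(thru) <- 0
    stress[v] <- sum(thru) / 2                  # unordered pairs
  }
  stress
}

# Krackhardt's connectedness and efficiency for an undirected graph.
# (Hierarchy and Lubness degenerate to 0 and 1 on undirected graphs.)
#' @keywords internal
.krackhardt <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  reach_pairs <- sum(sizes * (sizes - 1) / 2)
  con <- if (n < 2) 1 else reach_pairs / (n * (n - 1) / 2)
  extra <- m - (n - comp$no)                     # edges beyond spanning forests
  max_extra <- sum(sizes * (sizes - 1) / 2) - (n - comp$no)
  eff <- if (max_extra <= 0) 1 else 1 - extra / max_extra
  list(Con = con, Efficiency = eff, Hierarchy = 0, Lubness = 1)
}

#' Topology metric suite of a co-occurrence network
#'
#' Computes the conventional metric vector used to characterise molecular
#' ecological networks: node/edge counts, signed-edge percentages,
#' power-law degree fit, average degree (avgK), average local clustering
#' (avgCC, degree < 2 contributing 0), average geodesic distance (GD),
#' geodesic efficiency (E) and harmonic geodesic distance (HD = 1/E),
#' Freeman centralisations of degree (CD), betweenness (CB), eigenvector
#' (CE) and closeness (CCL), unnormalised stress centralisation (CS),
#' density (D), modularity (M, from [detect_modules()]), transitivity
#' (Trans) and Krackhardt's connectedness, efficiency, hierarchy and
#' lubness (the last two degenerate to 0 and 1 on undirected graphs).
#' Path-based metrics average over connected pairs only; the number of
#' unreachable pairs is reported alongside.
#'
#' @param network a `cooccurrence_network` or igraph object (non-empty).
#' @param include character vector of metric names to compute, or
#'   `"all"` (default).  Restricting the set skips expensive metrics.
#' @return an object of class `topology_summary` (named list of numbers).
#' @export
topology_summary <- function(network, include = "all") {
  g <- .as_igraph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0) stop("empty graph has no topology summary")
  all_metrics <- c("total_nodes", "total_links", "pct_positive",
                   "pct_negative", "powerlaw_r2", "avgK", "avgCC", "GD",
                   "E", "HD", "CD", "CB", "CS", "CE", "CCL", "D", "M",
                   "Trans", "Con", "Efficiency", "Hierarchy", "Lubness",
                   "unreachable_pairs")
  want <- if (identical(include, "all")) all_metrics else include
  out <- list(total_nodes = n, total_links = m)
  if (inherits(network, "cooccurrence_network")) {
    out$pct_positive <- network$pct_positive
    out$pct_negative <- network$pct_negative
  } else {
    out$pct_positive <- NA_real_; out$pct_negative <- NA_real_
  }
  deg <- igraph::degree(g)
  out$avgK <- 2 * m / n
  out$D <- if (n < 2) NA_real_ else m / (n * (n - 1) / 2)
  if ("powerlaw_r2" %in% want)
    out$powerlaw_r2 <- tryCatch(powerlaw_fit(deg)$r_squared,
                                error = function(e) NA_real_)
  if ("avgCC" %in% want) {
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    lc[is.nan(lc)] <- 0
    out$avgCC <- mean(lc)
  }
  if (any(c("GD", "E", "HD", "unreachable_pairs") %in% want)) {
    pm <- .path_metrics(g)
    out$GD <- pm$GD; out$E <- pm$E; out$HD <- pm$HD
    out$unreachable_pairs <- pm$unreachable
  }
  if ("CD" %in% want)
    out$CD <- igraph::centr_degree(g, loops = FALSE)$centralization
  if ("CB" %in% want)
    out$CB <- igraph::centr_betw(g)$centralization
  if ("CS" %in% want) {
    st <- stress_centrality(g)
    out$CS <- sum(max(st) - st)
  }
  if ("CE" %in% want)
    out$CE <- igraph::centr_eigen(g)$centralization
  if ("CCL" %in% want)
    out$CCL <- suppressWarnings(igraph::centr_clo(g)$centralization)
  if ("M" %in% want)
    out$M <- if (m == 0) NA_real_ else detect_modules(g)$modularity
  if ("Trans" %in% want)
    out$Trans <- {
      tr <- igraph::transitivity(g, type = "global")
      if (is.nan(tr)) 0 else tr
    }
  if (any(c("Con", "Efficiency", "Hierarchy", "Lubness") %in% want)) {
    kk <- .krackhardt(g)
    out[c("Con", "Efficiency", "Hierarchy", "Lubness")] <- kk
  }
  structure(out[intersect(all_metrics, c(names(out), want))],
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  v <- unlist(x)
  df <- data.frame(metric = names(v), value = unname(v))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Erdos-Renyi G(n, m) null ensemble of topology metrics
#'
#' Generates uniform random graphs with exactly the empirical node and
#' edge counts (so density and average degree match by construction) and
#' summarises the requested metrics as mean and standard deviation over
#' the replicates — the null reference against which an empirical
#' network's topology is judged non-random.
#'
#' @param n_nodes,n_edges size of each replicate graph.
#' @param metrics metric names (see [topology_summary()]); default a fast
#'   informative subset.
#' @param n_replicates number of random graphs (default 1000).
#' @param seed integer seed.
#' @return an object of class `null_ensemble`: data.frame `summary`
#'   (metric, mean, sd), plus `n_replicates` and `seed`.
#' @export
er_null_ensemble <- function(n_nodes, n_edges,
                             metrics = c("avgCC", "GD", "E", "HD", "D",
                                         "avgK", "M", "Trans", "Con"),
                             n_replicates = 1000L, seed = 1L) {
  max_m <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_m)
    stop("infeasible edge count: ", n_edges, " > ", max_m)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "topology"))
  vals <- matrix(NA_real_, n_replicates, length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(n_replicates)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    ts <- topology_summary(g, include = metrics)
    vals[r, ] <- unlist(ts)[metrics]
  }
  structure(
    list(summary = data.frame(metric = metrics,
                              mean = colMeans(vals),
                              sd = apply(vals, 2, stats::sd),
                              row.names = NULL),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Erdos-Renyi null ensemble (", x$n_replicates, " replicates)\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Random node-removal robustness curves
#'
#' Removes a fraction of nodes uniformly at random and tracks two
#' responses: the size of the largest connected component and the global
#' geodesic efficiency, both normalised to the intact network's node
#' count so that removing every node drives both to zero.
#'
#' @param network a `cooccurrence_network` or igraph object.
#' @param removal_fractions fractions in `[0, 1]`.
#' @param n_replicates random removal replicates per fraction.
#' @param seed integer seed.
#' @return data.frame with columns `fraction`, `lcc_mean`, `lcc_sd`,
#'   `efficiency_mean`, `efficiency_sd`.
#' @export
robustness_curve <- function(network, removal_fractions = seq(0, 1, 0.1),
                             n_replicates = 30L, seed = 1L) {
  if (any(removal_fractions < 0 | removal_fractions > 1))
    stop("removal fractions must lie in [0, 1]")
  g0 <- .as_igraph(network)
  n0 <- igraph::vcount(g0)
  glob_eff <- function(g) {
    if (igraph::vcount(g) < 2) return(0)
    dm <- igraph::distances(g)
    off <- dm[upper.tri(dm)]
    sum(1 / off[is.finite(off) & off > 0]) / (n0 * (n0 - 1) / 2)
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "topology") + 1L)
  rows <- lapply(removal_fractions, function(f) {
    k <- round(f * n0)
    lcc <- eff <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      keep <- if (k == 0) seq_len(n0) else
        setdiff(seq_len(n0), sample.int(n0, k))
      if (!length(keep)) { lcc[r] <- 0; eff[r] <- 0; next }
      gs <- igraph::induced_subgraph(g0, keep)
      lcc[r] <- max(igraph::components(gs)$csize) / n0
      eff[r] <- glob_eff(gs)
    }
    data.frame(fraction = f, lcc_mean = mean(lcc), lcc_sd = stats::sd(lcc),
               efficiency_mean = mean(eff), efficiency_sd = stats::sd(eff))
  })
  do.call(rbind, rows)
}
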
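#' Detect modules by greedy modularity agglomeration
#'
#' Deterministic fast-greedy modularity optimisation on the undirected,
#' unweighted graph.  The returned partition is the single source of
#' truth for both the modularity value reported in the topology summary
#' and the Zi/Pi role classification.
#'
#' @param network a `cooccurrence_network` or igraph object (non-empty).
#' @param seed kept for interface stability; the greedy agglomeration is
#'   deterministic, so the seed only fixes any future tie-breaking.
#' @return an object of class `module_partition`: list with `membership`
#'   (named integer vector), `modularity` (Q), `n_modules`, `algorithm`.
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- .as_igraph(network)
  if (igraph::vcount(g) == 0) stop("empty graph has no module structure")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "roles"))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  mem <- igraph::membership(cl)
  q <- igraph::modularity(g, mem)
  if (q <= 0) {
    # no community structure beats the trivial partition: one module
    mem[] <- 1L
    q <- igraph::modularity(g, mem)
  }
  nm <- igraph::V(g)$name
  memb <- as.integer(mem)
  names(memb) <- if (is.null(nm)) as.character(seq_along(memb)) else nm
  structure(
    list(membership = memb, modularity = q,
         n_modules = length(unique(memb)),
         algorithm = "fast_greedy", seed = as.integer(seed)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules, Q =",
      format(x$modularity, digits = 4), "(", x$algorithm, ")\n")
  invisible(x)
}

#' Within-module connectivity (Zi) and among-module connectivity (Pi)
#'
#' Zi is the z-score of a node's within-module degree relative to the
#' other members of its module (0 when the module's within-degree
#' standard deviation is zero, including singleton modules).  Pi is the
#' participation coefficient `1 - sum_s (k_is / k_i)^2` over modules s —
#' 0 when all edges stay in the node's own module, approaching 1 as they
#' spread evenly across many modules.  Degrees are unweighted.
#'
#' @param network a `cooccurrence_network` or igraph object.
#' @param partition a `module_partition` covering all nodes (default:
#'   computed by [detect_modules()]).
#' @return data.frame with columns `node`, `module`, `degree`, `zi`, `pi`.
#' @export
zi_pi <- function(network, partition = detect_modules(network)) {
  g <- .as_igraph(network)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  mem <- partition$membership[nm]
  if (anyNA(mem)) stop("partition does not cover all nodes")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  modules <- sort(unique(mem))
  # k_is: edges from node i into module s
  k_is <- sapply(modules, function(s) rowSums(adj[, mem == s, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, nrow = n)
  k <- rowSums(k_is)
  # within-module degree of each node
  k_within <- k_is[cbind(seq_len(n), match(mem, modules))]
  zi <- numeric(n)
  for (s in modules) {
    idx <- which(mem == s)
    mu <- mean(k_within[idx]); sdv <- stats::sd(k_within[idx])
    zi[idx] <- if (length(idx) < 2 || is.na(sdv) || sdv == 0) 0
               else (k_within[idx] - mu) / sdv
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((k_is / pmax(k, 1))^2))
  data.frame(node = nm, module = as.integer(mem), degree = k,
             zi = zi, pi = pi, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify topological roles and extract keystone taxa
#'
#' Four-way classification in the Zi-Pi plane: peripherals (low Zi, low
#' Pi), connectors (low Zi, high Pi), module hubs (high Zi, low Pi) and
#' network hubs (high Zi, high Pi), at the customary thresholds Zi = 2.5
#' and Pi = 0.62.  Values exactly on a threshold fall in the lower
#' category (the published definitions use strict inequalities on both
#' sides, leaving the boundary undefined).  Connectors and hubs are
#' flagged as keystone taxa.
#'
#' @param roles data.frame from [zi_pi()] (columns `zi`, `pi`).
#' @param zi_threshold,pi_threshold classification thresholds.
#' @return the input with added `role` (factor: peripheral, connector,
#'   module_hub, network_hub) and logical `keystone` columns.
#' @export
classify_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  if (any(!is.finite(roles$zi)) || any(!is.finite(roles$pi)))
    stop("Zi and Pi must be finite")
  hi_z <- roles$zi > zi_threshold
  hi_p <- roles$pi > pi_threshold
  role <- ifelse(hi_z & hi_p, "network_hub",
                 ifelse(hi_z, "module_hub",
                        ifelse(hi_p, "connector", "peripheral")))
  roles$role <- factor(role, levels = c("peripheral", "connector",
                                        "module_hub", "network_hub"))
  roles$keystone <- roles$role != "peripheral"
  roles
}

#' Full node-role analysis of a network
#'
#' @param network a `cooccurrence_network` or igraph object.
#' @param zi_threshold,pi_threshold see [classify_roles()].
#' @param seed passed to [detect_modules()].
#' @return list with `partition`, `roles` (classified data.frame) and
#'   `keystone` (the keystone subset).
#' @export
node_roles <- function(network, zi_threshold = 2.5, pi_threshold = 0.62,
                       seed = 1L) {
  part <- detect_modules(network, seed = seed)
  roles <- classify_roles(zi_pi(network, part), zi_threshold, pi_threshold)
  list(partition = part, roles = roles,
       keystone = roles[roles$keystone, , drop = FALSE])
}
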
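#' Build the signed co-occurrence network from a SparCC result
#'
#' An edge between two features survives only if it passes every active
#' filter: correlation magnitude at or above the RMT-selected threshold,
#' magnitude strictly above the fixed floor (0.3 by convention), and
#' BH-adjusted q strictly below the ceiling (0.05).  Features left with no
#' surviving edge are dropped from the graph but accounted for in the
#' retention report.
#'
#' @param result a `sparcc_result` with `rho` and `q` filled in (or a
#'   list with those two matrices).
#' @param rmt_threshold magnitude threshold from [rmt_threshold_scan()];
#'   use 0 to disable.
#' @param magnitude_floor fixed magnitude floor (default 0.3).
#' @param q_ceiling FDR ceiling (default 0.05).
#' @param group optional group label to attach.
#' @param taxonomy optional per-feature taxonomy labels (named by feature).
#' @return an object of class `cooccurrence_network`: list with `graph`
#'   (an igraph object whose edges carry `rho` and `sign` attributes),
#'   `edges` (data.frame source/target/rho/sign), `retention` (per-feature
#'   retained flag), counts and signed-edge percentages.
#' @export
build_network <- function(result, rmt_threshold = 0, magnitude_floor = 0.3,
                          q_ceiling = 0.05, group = NA_character_,
                          taxonomy = NULL) {
  rho <- result$rho; q <- result$q
  if (is.null(rho) || is.null(q))
    stop("need both rho and q matrices to build a network")
  if (!all(dim(rho) == dim(q)))
    stop("rho and q matrices have conflicting dimensions")
  d <- nrow(rho)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- sprintf("f%03d", seq_len(d))
  keep <- upper.tri(rho) & abs(rho) >= rmt_threshold &
    abs(rho) > magnitude_floor & !is.na(q) & q < q_ceiling
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                      rho = rho[keep],
                      sign = ifelse(rho[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  retained_ids <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = retained_ids)
  if (!is.null(taxonomy)) {
    tx <- taxonomy[retained_ids]
    igraph::V(g)$taxonomy <- ifelse(is.na(tx), "", tx)
  }
  n_edges <- nrow(edges)
  structure(
    list(graph = g, edges = edges,
         retention = data.frame(feature = ids,
                                retained = ids %in% retained_ids),
         n_nodes = length(retained_ids), n_edges = n_edges,
         pct_positive = if (n_edges) 100 * mean(edges$sign == "positive")
                        else NA_real_,
         pct_negative = if (n_edges) 100 * mean(edges$sign == "negative")
                        else NA_real_,
         group = group,
         filters = list(rmt_threshold = rmt_threshold,
                        magnitude_floor = magnitude_floor,
                        q_ceiling = q_ceiling)),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network", if (!is.na(x$group)) paste0("(", x$group, ")"),
      ":", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  if (x$n_edges)
    cat(sprintf("positive %.2f%%, negative %.2f%%\n",
                x$pct_positive, x$pct_negative))
  invisible(x)
}

#' Log-log least-squares power-law fit of a degree distribution
#'
#' Ordinary least squares of log frequency against log degree over the
#' degrees with nonzero frequency — the conventional scale-free
#' diagnostic for co-occurrence networks (not a maximum-likelihood tail
#' fit).  A CCDF mode is available.
#'
#' @param degrees node degrees (positive degrees are used).
#' @param mode `"frequency"` (default) or `"ccdf"`.
#' @return list with `slope`, `intercept`, `r_squared` and `n_points`.
#' @export
powerlaw_fit <- function(degrees, mode = c("frequency", "ccdf")) {
  mode <- match.arg(mode)
  k <- degrees[degrees > 0]
  tab <- table(k)
  kk <- as.numeric(names(tab))
  if (length(kk) < 3)
    stop("need at least 3 distinct positive degrees for a power-law fit")
  y <- if (mode == "frequency") as.numeric(tab)
       else rev(cumsum(rev(as.numeric(tab)))) / length(k)
  fit <- stats::lm(log(y) ~ log(kk))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_points = length(kk))
}
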
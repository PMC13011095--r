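#' Alpha diversity: observed richness, Chao1 and ACE
#'
#' Sobs is the number of features with positive count.  Chao1 uses the
#' classic estimator `S + F1^2 / (2 F2)` (F1 singletons, F2 doubletons),
#' switching to the bias-corrected form `S + F1 (F1 - 1) / (2 (F2 + 1))`
#' when no doubletons exist; the mode used is recorded.  ACE is the
#' abundance-based coverage estimator with the conventional rare/abundant
#' cutoff at 10: with `N_rare` individuals among `S_rare` rare features,
#' sample coverage `C = 1 - F1 / N_rare`, and squared coefficient of
#' variation `g2 = max(S_rare / C * sum(i (i-1) F_i) / (N_rare (N_rare -
#' 1)) - 1, 0)`, ACE = `S_abund + S_rare / C + F1 / C * g2`.
#'
#' @param counts non-negative integer counts for one sample (at least one
#'   positive), or an `abundance_table` (one result row per sample).
#' @param rare_cutoff ACE rare/abundant boundary (default 10).
#' @return data.frame with columns `sobs`, `chao1`, `chao1_mode`, `ace`
#'   (one row per sample).
#' @export
alpha_diversity <- function(counts, rare_cutoff = 10L) {
  if (inherits(counts, "abundance_table")) {
    res <- do.call(rbind, lapply(seq_len(ncol(counts$counts)), function(j)
      alpha_diversity(counts$counts[, j], rare_cutoff)))
    res <- data.frame(sample = counts$sample_ids, group = counts$group, res)
    return(res)
  }
  x <- counts[counts > 0]
  if (!length(x)) stop("all-zero sample has no diversity estimate")
  if (any(x %% 1 != 0)) stop("richness estimators need integer counts")
  s <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) {
    chao1 <- s; mode <- "classic"
  } else if (f2 > 0) {
    chao1 <- s + f1^2 / (2 * f2); mode <- "classic"
  } else {
    chao1 <- s + f1 * (f1 - 1) / (2 * (f2 + 1)); mode <- "bias_corrected"
  }
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff); s_rare <- length(rare)
  n_rare <- sum(rare)
  if (s_rare == 0 || n_rare == f1) {
    # no rare features, or coverage zero (all rare are singletons):
    # fall back to Chao1-style handling so the estimate stays defined
    ace <- if (s_rare == 0) s else chao1
  } else {
    cace <- 1 - f1 / n_rare
    fi <- tabulate(rare, nbins = rare_cutoff)
    g2 <- max(s_rare / cace * sum(seq_len(rare_cutoff) *
                                    (seq_len(rare_cutoff) - 1) * fi) /
                (n_rare * (n_rare - 1)) - 1, 0)
    ace <- s_abund + s_rare / cace + f1 / cace * g2
  }
  data.frame(sobs = s, chao1 = chao1, chao1_mode = mode, ace = ace,
             stringsAsFactors = FALSE)
}

#' Binary Jaccard distance between samples
#'
#' `d(a, b) = 1 - |shared features| / |union of features|` on the
#' presence/absence profiles.  Two samples with empty presence sets are
#' assigned distance 0 with a warning.
#'
#' @param table an `abundance_table` or features x samples matrix.
#' @return a symmetric `dist`-backed matrix (samples x samples) with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
binary_jaccard <- function(table) {
  counts <- if (inherits(table, "abundance_table")) table$counts
            else as.matrix(table)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pres <- t(counts > 0)                 # samples x features
  if (any(rowSums(pres) == 0))
    warning("sample(s) with empty presence set; distances involving two ",
            "empty samples are 0 by convention")
  shared <- tcrossprod(pres * 1)
  tot <- diag(shared)
  union <- outer(tot, tot, "+") - shared
  d <- 1 - shared / union
  d[union == 0] <- 0                    # both presence sets empty
  diag(d) <- 0
  rownames(d) <- colnames(d) <- colnames(counts)
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centring followed by eigendecomposition (via
#' [stats::cmdscale()]); axes are ordered by eigenvalue and the percent
#' variance of each axis is its eigenvalue over the sum of positive
#' eigenvalues.  Negative eigenvalues (non-Euclidean distances) are
#' reported but excluded from the percent-variance denominator; no
#' Lingoes/Cailliez correction is applied.
#'
#' @param distances square symmetric non-negative matrix (or `dist`).
#' @param k number of axes to return (default all with positive
#'   eigenvalue).
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `percent_variance` (per returned axis).
#' @export
pcoa <- function(distances, k = NULL) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  # cmdscale warns whenever some eigenvalues are non-positive; that is
  # the normal situation for non-Euclidean dissimilarities and the
  # eigenvalues are reported to the caller anyway
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  ev <- fit$eig
  pos <- which(ev > 1e-9 * max(abs(ev)))
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("PCo%d", seq_len(k))
  list(coordinates = coords, eigenvalues = ev,
       percent_variance = 100 * ev[seq_len(k)] / sum(ev[pos]))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones.  With `M = n (n - 1) / 2` dissimilarity
#' pairs ranked over all samples, `R = (mean between-group rank - mean
#' within-group rank) / (M / 2)`; the p-value is
#' `(1 + #\{permuted R >= observed R\}) / (n_permutations + 1)` over
#' random relabellings of the samples.
#'
#' @param distances square symmetric dissimilarity matrix (or `dist`).
#' @param labels group label per sample (at least 2 groups of at least 2).
#' @param n_permutations default 9999.
#' @param seed integer seed for the permutations.
#' @return an object of class `anosim_result`: list with `R`, `p`,
#'   `n_permutations`.
#' @export
anosim <- function(distances, labels, n_permutations = 9999L, seed = 1L) {
  d <- as.matrix(distances)
  labels <- as.factor(labels)
  stopifnot(nrow(d) == length(labels))
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 samples")
  ut <- upper.tri(d)
  rk <- rank(d[ut])
  pair_i <- row(d)[ut]; pair_j <- col(d)[ut]
  m <- length(rk)
  r_stat <- function(lab) {
    within <- lab[pair_i] == lab[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / (m / 2)
  }
  r_obs <- r_stat(labels)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "ecology"))
  exceed <- 0L
  for (b in seq_len(n_permutations))
    exceed <- exceed + (r_stat(sample(labels)) >= r_obs)
  structure(list(R = r_obs, p = (1 + exceed) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  invisible(x)
}

#' Differential feature testing with volcano classification
#'
#' Per-feature two-sided Wilcoxon rank-sum test on relative abundances
#' between the two groups, BH adjustment over all tested features, and
#' log2 fold change of the group mean relative abundances with a
#' pseudo-value of half the smallest nonzero relative abundance in the
#' table.  Features are classified `up` (log2FC >= 1 and q < 0.05),
#' `down` (log2FC <= -1 and q < 0.05) or `ns`; `up` means higher in the
#' first group of `numerator`.
#'
#' @param table an `abundance_table` with exactly two groups.
#' @param numerator which group forms the fold-change numerator (default
#'   the second group level, conventionally the exposed/contaminated one).
#' @param lfc_threshold absolute log2 fold-change cut (default 1).
#' @param q_ceiling FDR ceiling (default 0.05).
#' @return data.frame with `feature`, `mean_num`, `mean_den`, `log2fc`,
#'   `p`, `q`, `status`.
#' @export
differential_features <- function(table, numerator = NULL,
                                  lfc_threshold = 1, q_ceiling = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- levels(table$group)
  stopifnot(length(groups) == 2L)
  if (is.null(numerator)) numerator <- groups[2]
  denominator <- setdiff(groups, numerator)
  rel <- sweep(table$counts, 2, colSums(table$counts), "/")
  present <- rowSums(rel) > 0
  if (any(!present))
    warning(sum(!present), " feature(s) absent from all samples excluded")
  rel <- rel[present, , drop = FALSE]
  eps <- min(rel[rel > 0]) / 2
  in_num <- table$group == numerator
  p <- apply(rel, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[in_num], v[!in_num])$p.value))
  mean_num <- rowMeans(rel[, in_num, drop = FALSE])
  mean_den <- rowMeans(rel[, !in_num, drop = FALSE])
  log2fc <- log2((mean_num + eps) / (mean_den + eps))
  q <- stats::p.adjust(p, method = "BH")
  status <- ifelse(q < q_ceiling & log2fc >= lfc_threshold, "up",
                   ifelse(q < q_ceiling & log2fc <= -lfc_threshold, "down",
                          "ns"))
  data.frame(feature = rownames(rel), mean_num = mean_num,
             mean_den = mean_den, log2fc = log2fc, p = p, q = q,
             status = factor(status, levels = c("up", "down", "ns")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlations between taxa abundances and biomarkers
#'
#' Rank (Spearman, default) or Pearson correlation between each taxon's
#' relative abundance and each biomarker over the subjects shared by the
#' two tables, with the two-star significance tiers used on
#' taxon-biomarker heat maps (** 0.001 < p < 0.01, * p < 0.05).  Taxa may
#' first be aggregated to genus level through the abundance table's
#' taxonomy labels.
#'
#' @param taxa an `abundance_table` whose sample ids identify subjects.
#' @param biomarkers a `biomarker_table` (`subject` column).
#' @param markers biomarker columns to use (default all).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param aggregate_genus if `TRUE` and the table carries taxonomy
#'   labels, rows are summed by label first.
#' @return list with matrices `rho`, `p`, `tier` (taxa x markers) and the
#'   shared subject count `n`.
#' @export
taxa_biomarker_correlations <- function(taxa, biomarkers, markers = NULL,
                                        method = c("spearman", "pearson"),
                                        aggregate_genus = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(taxa, "abundance_table"))
  counts <- taxa$counts
  if (aggregate_genus) {
    if (is.null(taxa$taxonomy))
      stop("no taxonomy labels to aggregate by")
    counts <- rowsum(counts, group = taxa$taxonomy)
  }
  rel <- sweep(counts, 2, colSums(counts), "/")
  if (is.null(markers))
    markers <- setdiff(names(biomarkers), c("subject", "group"))
  shared <- intersect(colnames(rel), biomarkers$subject)
  if (length(shared) < 3) stop("fewer than 3 shared subjects")
  rel <- rel[, shared, drop = FALSE]
  bm <- biomarkers[match(shared, biomarkers$subject), markers, drop = FALSE]
  nt <- nrow(rel); nm <- length(markers)
  rho <- p <- matrix(NA_real_, nt, nm,
                     dimnames = list(rownames(rel), markers))
  for (i in seq_len(nt)) for (j in seq_len(nm)) {
    x <- rel[i, ]; y <- bm[[j]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  tier <- matrix(ifelse(is.na(p), "",
                        ifelse(p < 0.01, "**",
                               ifelse(p < 0.05, "*", ""))),
                 nt, nm, dimnames = dimnames(p))
  list(rho = rho, p = p, tier = tier, n = length(shared), method = method)
}
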
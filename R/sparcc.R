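#' Pairwise log-ratio variation matrix
#'
#' The SparCC building block: `T[i, j]` is the variance over samples of
#' `log(x_i / x_j)`.  Input fractions must be strictly positive; counts
#' are converted with a +1 pseudocount unless already fractional.
#'
#' @param x features x samples matrix of positive fractions, or an
#'   `abundance_table` (counts get a +1 pseudocount and are closed per
#'   sample).
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
variation_matrix <- function(x) {
  f <- .to_fractions(x)
  v <- log(f)
  cc <- stats::cov(t(v))             # feature x feature covariance
  d <- diag(cc)
  tt <- outer(d, d, "+") - 2 * cc
  tt[tt < 0] <- 0                    # numerical noise only
  diag(tt) <- 0
  .symmetrise(tt)
}

#' @keywords internal
.to_fractions <- function(x) {
  if (inherits(x, "abundance_table")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  if (any(rowSums(x) == 0))
    stop("feature with all-zero counts: remove it before SparCC")
  if (!(all(x > 0) && all(x <= 1))) x <- x + 1   # counts: +1 pseudocount
  sweep(x, 2, colSums(x), "/")
}

# Solve the SparCC basis-variance linear system given a variation matrix,
# with iterative exclusion of the strongest correlated pairs.  Returns the
# basis correlation matrix (clamped to [-1, 1]) and the excluded pairs.
#' @keywords internal
.basis_correlations <- function(tt, exclusion_threshold = 0.1,
                                max_exclusions = NULL) {
  d <- nrow(tt)
  if (d < 4)
    stop("SparCC basis system needs at least 4 features (got ", d, ")")
  if (is.null(max_exclusions)) max_exclusions <- d - 4L
  m <- matrix(1, d, d); diag(m) <- d - 1
  tvec <- rowSums(tt)
  solve_rho <- function() {
    omega <- solve(m, tvec)
    if (any(!is.finite(omega)))
      stop("non-finite basis variance: variation matrix is degenerate")
    omega <- pmax(omega, .Machine$double.eps)
    cov <- (outer(omega, rep(1, d)) + outer(rep(1, d), omega) - tt) / 2
    rho <- cov / sqrt(outer(omega, omega))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  excluded <- matrix(integer(0), ncol = 2)
  mask <- matrix(FALSE, d, d)
  for (k in seq_len(max_exclusions)) {
    ar <- abs(rho); ar[mask] <- 0; diag(ar) <- 0
    top <- which(ar == max(ar), arr.ind = TRUE)[1, ]
    if (ar[top[1], top[2]] <= exclusion_threshold) break
    i <- top[1]; j <- top[2]
    mask[i, j] <- mask[j, i] <- TRUE
    excluded <- rbind(excluded, c(min(i, j), max(i, j)))
    m[i, i] <- m[i, i] - 1; m[j, j] <- m[j, j] - 1
    m[i, j] <- m[i, j] - 1; m[j, i] <- m[j, i] - 1
    tvec[i] <- tvec[i] - tt[i, j]
    tvec[j] <- tvec[j] - tt[i, j]
    rho <- solve_rho()
  }
  list(rho = rho, excluded = excluded)
}

# Dirichlet-posterior resample of per-sample fractions (prior 1 per
# component): the SparCC treatment of zero counts.
#' @keywords internal
.dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts))
  sweep(g, 2, colSums(g), "/")
}

#' Estimate SparCC basis correlations
#'
#' Infers correlations between the unobserved basis abundances underlying
#' a compositional count table.  Each inner iteration resamples fractions
#' from the per-sample Dirichlet posterior (or applies a fixed +1
#' pseudocount), computes the log-ratio variation matrix, solves the
#' basis-variance linear system under the sparsity assumption, and
#' iteratively excludes the most strongly correlated pair above
#' `exclusion_threshold` before re-solving.  Estimates are averaged over
#' the inner iterations.
#'
#' @param table an `abundance_table` or features x samples count matrix.
#' @param inner_iterations number of Dirichlet resamples to average over
#'   (default 20, the method's de facto default).
#' @param exclusion_threshold correlation magnitude above which the
#'   strongest pair is excluded from the basis system (default 0.1).
#' @param max_exclusions cap on excluded pairs (default `features - 4`).
#' @param zero_mode `"dirichlet"` (default) or `"pseudocount"` (a single
#'   deterministic +1 pseudocount pass).
#' @param seed integer seed for the Dirichlet resamples.
#' @return an object of class `sparcc_result` with `rho`, `excluded_pairs`
#'   and the settings used; `p`/`q` are filled in by [sparcc_pvalues()] /
#'   [fdr_adjust()] or by [sparcc_analysis()].
#' @export
sparcc_estimate <- function(table, inner_iterations = 20L,
                            exclusion_threshold = 0.1,
                            max_exclusions = NULL,
                            zero_mode = c("dirichlet", "pseudocount"),
                            seed = 1L) {
  zero_mode <- match.arg(zero_mode)
  counts <- if (inherits(table, "abundance_table")) table$counts
            else as.matrix(table)
  if (any(rowSums(counts) == 0))
    stop("feature with all-zero counts: remove it before SparCC")
  d <- nrow(counts)
  if (d < 4) stop("SparCC needs at least 4 features")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "sparcc"))
  iters <- if (zero_mode == "pseudocount") 1L else as.integer(inner_iterations)
  acc <- matrix(0, d, d)
  excluded <- NULL
  for (it in seq_len(iters)) {
    f <- if (zero_mode == "pseudocount") .to_fractions(counts)
         else .dirichlet_fractions(counts)
    tt <- variation_matrix(f)
    bs <- .basis_correlations(tt, exclusion_threshold, max_exclusions)
    acc <- acc + bs$rho
    if (is.null(excluded)) excluded <- bs$excluded
  }
  rho <- acc / iters
  rho <- pmin(pmax(.symmetrise(rho), -1), 1)
  diag(rho) <- 1
  ids <- rownames(counts)
  if (!is.null(ids)) dimnames(rho) <- list(ids, ids)
  structure(
    list(rho = rho, p = NULL, q = NULL, n_bootstrap = 0L,
         excluded_pairs = excluded,
         settings = list(inner_iterations = iters,
                         exclusion_threshold = exclusion_threshold,
                         max_exclusions = max_exclusions,
                         zero_mode = zero_mode, seed = seed)),
    class = "sparcc_result"
  )
}

#' Null-resampling pseudo p-values for SparCC correlations
#'
#' For each feature pair, the two-sided pseudo p-value is
#' `(1 + #{null |rho*| >= |rho_obs|}) / (n_bootstrap + 1)`, bounded below
#' by `1/(n_bootstrap + 1)`.  The default null (`"permutation"`) shuffles
#' each feature's counts across samples independently, destroying all
#' between-feature association while preserving marginals — under this
#' exchangeable null the p-values are approximately uniform.  The
#' `"bootstrap"` mode instead resamples samples (columns) with
#' replacement; its replicates centre on the observed estimate rather
#' than on a null, so it measures estimator stability, not significance.
#'
#' @param table `abundance_table` or count matrix.
#' @param rho_obs observed correlation matrix (e.g. from
#'   [sparcc_estimate()]).
#' @param n_bootstrap number of null datasets (default 100).
#' @param method `"permutation"` (default) or `"bootstrap"`.
#' @param seed integer seed.
#' @param ... settings passed on to [sparcc_estimate()] for the null fits
#'   (`inner_iterations`, `exclusion_threshold`, ...).
#' @return symmetric p matrix with `NA` diagonal.
#' @export
sparcc_pvalues <- function(table, rho_obs, n_bootstrap = 100L,
                           method = c("permutation", "bootstrap"),
                           seed = 1L, ...) {
  method <- match.arg(method)
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  counts <- if (inherits(table, "abundance_table")) table$counts
            else as.matrix(table)
  d <- nrow(counts); n <- ncol(counts)
  stopifnot(nrow(rho_obs) == d)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "sparcc") + 1L)
  exceed <- matrix(0L, d, d)
  obs <- abs(rho_obs)
  for (b in seq_len(n_bootstrap)) {
    null_counts <- if (method == "permutation") {
      t(apply(counts, 1, sample))
    } else {
      counts[, sample.int(n, n, replace = TRUE), drop = FALSE]
    }
    rn <- sparcc_estimate(null_counts, seed = seed + b, ...)$rho
    exceed <- exceed + (abs(rn) >= obs)
  }
  p <- (1 + exceed) / (n_bootstrap + 1)
  p <- .symmetrise(p)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Benjamini-Hochberg adjustment over the pairwise test family
#'
#' The family is the strict upper triangle (each unordered feature pair
#' tested once); the diagonal is never tested.  Step-up BH guarantees
#' `q >= p` and preserves the p-value ordering.
#'
#' @param p symmetric p matrix (diagonal ignored).
#' @return symmetric q matrix.
#' @export
fdr_adjust <- function(p) .bh_upper_triangle(p)

#' Full SparCC analysis: correlations, null p-values and BH q-values
#'
#' @inheritParams sparcc_estimate
#' @inheritParams sparcc_pvalues
#' @return a complete `sparcc_result` with `rho`, `p`, `q`,
#'   `n_bootstrap` and `excluded_pairs`.
#' @export
sparcc_analysis <- function(table, n_bootstrap = 100L,
                            inner_iterations = 20L,
                            exclusion_threshold = 0.1,
                            max_exclusions = NULL,
                            zero_mode = c("dirichlet", "pseudocount"),
                            method = c("permutation", "bootstrap"),
                            seed = 1L) {
  zero_mode <- match.arg(zero_mode); method <- match.arg(method)
  est <- sparcc_estimate(table, inner_iterations, exclusion_threshold,
                         max_exclusions, zero_mode, seed)
  est$p <- sparcc_pvalues(table, est$rho, n_bootstrap, method, seed,
                          inner_iterations = inner_iterations,
                          exclusion_threshold = exclusion_threshold,
                          max_exclusions = max_exclusions,
                          zero_mode = zero_mode)
  est$q <- fdr_adjust(est$p)
  est$n_bootstrap <- as.integer(n_bootstrap)
  est$settings$p_method <- method
  est
}

#' @export
print.sparcc_result <- function(x, ...) {
  d <- nrow(x$rho)
  off <- x$rho[upper.tri(x$rho)]
  cat("SparCC result:", d, "features,",
      nrow(x$excluded_pairs), "excluded pair(s)\n")
  cat(sprintf("off-diagonal rho: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  if (!is.null(x$p))
    cat("p/q matrices from", x$n_bootstrap, "null resamples\n")
  invisible(x)
}
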
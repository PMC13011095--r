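#' Unfold an eigenvalue spectrum to unit mean spacing
#'
#' Fits a cubic smoothing spline to the empirical cumulative spectral
#' density and maps each eigenvalue through `n * F_smooth(lambda)`; the
#' successive differences of the mapped values are the unfolded
#' nearest-neighbour spacings, with mean ~1 by construction.  Tied
#' eigenvalues (a hazard of heavily thresholded correlation matrices) are
#' broken by a tiny seeded jitter with a warning when they saturate the
#' spectrum.
#'
#' @param eigenvalues numeric vector (sorted or not) of real eigenvalues.
#' @param df spline degrees of freedom; default `max(4, n/10)` knots-worth,
#'   the common choice in RMT network analyses.
#' @param jitter_seed seed for tie-breaking jitter.
#' @return numeric vector of `n - 1` non-negative spacings.
#' @export
unfold_eigenvalues <- function(eigenvalues, df = NULL, jitter_seed = 1L) {
  ev <- sort(as.numeric(eigenvalues))
  n <- length(ev)
  if (n < 20) stop("need at least 20 eigenvalues to unfold a spectrum")
  ties <- sum(duplicated(ev))
  if (ties > 0) {
    if (ties >= n / 2)
      warning("spectrum is tie-saturated (", ties, "/", n,
              " duplicates); unfolding is unreliable")
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(jitter_seed)
    ev <- sort(ev + stats::rnorm(n, sd = 1e-10 * max(1, diff(range(ev)))))
  }
  if (is.null(df)) df <- max(4, n / 10)
  ecdf_y <- seq_len(n) / n
  fit <- stats::smooth.spline(ev, ecdf_y, df = df)
  unf <- n * stats::predict(fit, ev)$y
  sp <- diff(unf)
  sp[sp < 0] <- 0                    # spline non-monotonicity guard
  sp
}

# chi-squared goodness of fit of spacings to a target law, over
# equal-probability bins on s in [0, 3].
#' @keywords internal
.spacing_chisq <- function(spacings, law = c("goe", "poisson"),
                           n_bins = 20L) {
  law <- match.arg(law)
  cdf <- switch(law,
    goe = function(s) 1 - exp(-pi * s^2 / 4),        # Wigner surmise
    poisson = function(s) 1 - exp(-s))
  s <- spacings[spacings <= 3]
  if (length(s) < n_bins) return(NA_real_)
  p3 <- cdf(3)
  probs <- seq(0, p3, length.out = n_bins + 1)
  edges <- switch(law,
    goe = sqrt(-4 / pi * log(1 - probs)),
    poisson = -log(1 - probs))
  edges[1] <- 0; edges[n_bins + 1] <- 3
  obs <- tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  expd <- length(s) / n_bins
  sum((obs - expd)^2 / expd)
}

#' Goodness of fit of a spacing distribution to GOE and Poisson laws
#'
#' @param spacings unfolded nearest-neighbour spacings.
#' @param n_bins equal-probability bins over `[0, 3]` (default 20).
#' @return list with `chisq_goe` and `chisq_poisson` (lower = closer).
#' @export
nnsd_gof <- function(spacings, n_bins = 20L) {
  list(chisq_goe = .spacing_chisq(spacings, "goe", n_bins),
       chisq_poisson = .spacing_chisq(spacings, "poisson", n_bins))
}

#' Random-matrix-theory threshold scan of a correlation matrix
#'
#' For each candidate threshold: entries below it in magnitude are zeroed,
#' rows/columns left with no off-diagonal support are dropped, and the
#' nearest-neighbour spacing distribution of the retained matrix's
#' unfolded eigenvalues is scored against the Gaussian orthogonal
#' ensemble (Wigner surmise) and Poisson laws.  Two selection rules are
#' offered: `"transition"` (default) picks the first threshold at which
#' the Poisson fit overtakes the GOE fit — the conventional
#' noise-to-signal transition of RMT-based network construction — while
#' `"best_goe"` picks the threshold with the best GOE fit.
#'
#' @param rho symmetric correlation matrix.
#' @param grid increasing thresholds in (0, 1); default 0.30-0.90 by 0.02.
#' @param rule `"transition"` or `"best_goe"`.
#' @param min_size grid points whose retained matrix is smaller than this
#'   are flagged unusable (default 20).
#' @param n_bins bins for the spacing goodness of fit.
#' @return an object of class `rmt_scan`: data.frame `scan` (threshold,
#'   retained size, chisq_goe, chisq_poisson, usable), `chosen_threshold`
#'   (NA when no usable grid point satisfies the rule), and `rule`.
#' @export
rmt_threshold_scan <- function(rho, grid = seq(0.30, 0.90, by = 0.02),
                               rule = c("transition", "best_goe"),
                               min_size = 20L, n_bins = 20L) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must lie in (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must strictly increase")
  rho <- .symmetrise(rho)
  rows <- lapply(grid, function(th) {
    a <- rho
    a[abs(a) < th] <- 0
    diag(a) <- 1
    keep <- colSums(abs(a) > 0) > 1   # some off-diagonal support
    a <- a[keep, keep, drop = FALSE]
    if (nrow(a) < min_size)
      return(data.frame(threshold = th, size = nrow(a),
                        chisq_goe = NA_real_, chisq_poisson = NA_real_,
                        usable = FALSE))
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    sp <- suppressWarnings(unfold_eigenvalues(ev))
    gof <- nnsd_gof(sp, n_bins)
    data.frame(threshold = th, size = nrow(a),
               chisq_goe = gof$chisq_goe,
               chisq_poisson = gof$chisq_poisson,
               usable = is.finite(gof$chisq_goe) &&
                 is.finite(gof$chisq_poisson))
  })
  scan <- do.call(rbind, rows)
  usable <- scan[scan$usable, , drop = FALSE]
  chosen <- NA_real_
  if (nrow(usable)) {
    if (rule == "transition") {
      hit <- usable$threshold[usable$chisq_poisson < usable$chisq_goe]
      if (length(hit)) chosen <- hit[1]
    } else {
      chosen <- usable$threshold[which.min(usable$chisq_goe)]
    }
  }
  structure(list(scan = scan, chosen_threshold = chosen, rule = rule),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan (", x$rule, " rule): chosen threshold ",
      format(x$chosen_threshold), "\n", sep = "")
  print(x$scan, row.names = FALSE)
  invisible(x)
}
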
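#' Derive a per-stage child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed so that stages are independently reproducible.  The derivation is
#' `(seed + 7919 * stage_index) mod (2^31 - 1)`: 7919 is the 1000th prime,
#' chosen only so that nearby master seeds do not collide across stages.
#'
#' @param seed master integer seed.
#' @param stage stage index (non-negative integer) or one of the named
#'   pipeline stages.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stages <- c(abundance = 1L, soil = 2L, biomarkers = 3L, sparcc = 4L,
              network = 5L, topology = 6L, roles = 7L, ecology = 8L)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stage <- stages[[stage]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 7919 * as.numeric(stage)) %% (2^31 - 1))
}

#' @keywords internal
.assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  invisible(x)
}

# Symmetrise a square matrix by averaging with its transpose.
#' @keywords internal
.symmetrise <- function(m) (m + t(m)) / 2

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Clips eigenvalues below `eps` up to `eps`, reconstructs the matrix, and
#' rescales it to unit diagonal.  Whether the repair actually changed the
#' matrix is recorded in the `"repaired"` attribute so that simulation
#' studies can tell when a requested structure was infeasible as stated.
#'
#' @param m symmetric matrix intended as a correlation matrix.
#' @param eps floor for the eigenvalues (default `1e-8`).
#' @return the repaired matrix with logical attribute `"repaired"`.
#' @export
psd_repair <- function(m, eps = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- .symmetrise(m)
  e <- eigen(m, symmetric = TRUE)
  fired <- any(e$values < eps - 1e-12)
  if (fired) {
    v <- pmax(e$values, eps)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- .symmetrise(m)
    diag(m) <- 1
  }
  attr(m, "repaired") <- fired
  m
}

# BH step-up over the strict upper triangle of a symmetric p matrix;
# returns a symmetric q matrix with 1 on the diagonal.  NA p-values are
# excluded from the family (with a warning) and stay NA.
#' @keywords internal
.bh_upper_triangle <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  q <- p
  ut <- upper.tri(p)
  fam <- p[ut]
  if (anyNA(fam)) warning("NA p-values excluded from the BH family")
  adj <- rep(NA_real_, length(fam))
  ok <- !is.na(fam)
  adj[ok] <- stats::p.adjust(fam[ok], method = "BH")
  q[ut] <- adj
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 1
  q
}

# Three-star significance tiers as used for correlation heat maps.
#' @keywords internal
.sig_tier <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}
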
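#' Systemic immune-inflammation index
#'
#' SII = neutrophil count / lymphocyte count x platelet count, a composite
#' marker of systemic immune status.  Reported in the units of the
#' platelet input (conventionally 1000 cells/uL).
#'
#' @param neutrophils,lymphocytes,platelets cell counts (vectorised).
#' @return numeric SII values.
#' @export
compute_sii <- function(neutrophils, lymphocytes, platelets) {
  if (any(neutrophils < 0) || any(lymphocytes < 0) || any(platelets < 0))
    stop("cell counts must be non-negative")
  if (any(lymphocytes == 0))
    stop("SII undefined when the lymphocyte count is zero")
  neutrophils / lymphocytes * platelets
}

#' Specific-gravity dilution correction for urinary analytes
#'
#' Rescales a raw urinary concentration to a reference specific gravity:
#' `corrected = raw * (reference_sg - 1) / (observed_sg - 1)`.  The
#' reference defaults to 1.020, the conventional population value.
#'
#' @param raw raw analyte concentration (>= 0; vectorised).
#' @param observed_sg specific gravity of the urine sample (> 1).
#' @param reference_sg reference specific gravity (> 1).
#' @return corrected concentrations.
#' @export
dilution_correct <- function(raw, observed_sg, reference_sg = 1.020) {
  if (any(observed_sg <= 1) || any(reference_sg <= 1))
    stop("specific gravities must exceed 1")
  if (any(raw < 0)) stop("raw concentrations must be >= 0")
  raw * (reference_sg - 1) / (observed_sg - 1)
}

#' Creatinine dilution correction for urinary analytes
#'
#' Alternative to the specific-gravity correction: expresses an analyte
#' per gram of urinary creatinine.
#'
#' @param raw raw analyte concentration (per litre).
#' @param creatinine urinary creatinine (g/L, > 0).
#' @return concentration per gram creatinine.
#' @export
creatinine_correct <- function(raw, creatinine) {
  if (any(creatinine <= 0)) stop("creatinine must be > 0")
  if (any(raw < 0)) stop("raw concentrations must be >= 0")
  raw / creatinine
}

#' Compare every biomarker between the two groups
#'
#' Per-marker Mann-Whitney comparison in the shape of a published cohort
#' table: median and interquartile range per group with a two-sided
#' rank-sum p-value.  Missing values are removed per marker; markers with
#' an empty group after removal are skipped with a warning.
#'
#' @param table a `biomarker_table` (data.frame with `subject`, `group`
#'   and one numeric column per marker).
#' @param markers which markers to compare (default: every numeric column
#'   other than `subject`/`group`).
#' @return data.frame with columns `marker`, `group`, `n`, `median`, `q1`,
#'   `q3`, `p`, `method`.
#' @export
compare_biomarkers <- function(table, markers = NULL) {
  if (is.null(markers))
    markers <- setdiff(names(table), c("subject", "group"))
  groups <- levels(as.factor(table$group))
  stopifnot(length(groups) == 2L)
  rows <- lapply(markers, function(m) {
    v <- table[[m]]
    ok <- !is.na(v)
    x <- v[ok & table$group == groups[1]]
    y <- v[ok & table$group == groups[2]]
    if (!length(x) || !length(y)) {
      warning("marker skipped (one group empty after NA removal): ", m)
      return(NULL)
    }
    cmp <- .rank_sum_compare(x, y)
    data.frame(marker = m, group = groups, n = c(length(x), length(y)),
               median = cmp$median, q1 = cmp$q1, q3 = cmp$q3,
               p = cmp$p, method = cmp$method, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation matrix of biomarkers with significance tiers
#'
#' Pairwise-complete Pearson correlations between all markers, with
#' two-sided p-values and the three-star tier labels used on correlation
#' heat maps (*** p < 0.001, ** p < 0.01, * p < 0.05).  Constant markers
#' yield undefined (NA) correlations with a warning.
#'
#' @param table a `biomarker_table`.
#' @param markers marker columns to include (default all).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with matrices `r`, `p`, `tier` and pairwise `n`.
#' @export
biomarker_correlations <- function(table, markers = NULL,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(markers))
    markers <- setdiff(names(table), c("subject", "group"))
  k <- length(markers)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(markers, markers)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    ok <- stats::complete.cases(table[[markers[i]]], table[[markers[j]]])
    xi <- table[[markers[i]]][ok]; xj <- table[[markers[j]]][ok]
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) { r[i, j] <- r[j, i] <- NA_real_; next }
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warning("constant marker; correlation undefined for ",
              markers[i], "/", markers[j])
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(stats::cor.test(xi, xj, method = method))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  tier <- matrix(.sig_tier(p), k, k, dimnames = dimnames(p))
  diag(tier) <- ""
  list(r = r, p = p, tier = tier, n = n, method = method)
}
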
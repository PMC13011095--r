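#' Contamination factor of a metal concentration against its background
#'
#' CF is the ratio of the measured concentration to the regional background
#' value.  Categories follow the conventional cut points at 1, 3 and 6:
#' low (< 1), moderate (1-3), considerable (3-6) and very high (> 6).
#' Values falling exactly on a cut point are assigned to the lower
#' category (the published category definitions use strict inequalities on
#' both sides, leaving the boundary undefined; assigning downwards is the
#' conservative call).
#'
#' @param concentration measured concentration (mg/kg), >= 0; vectorised.
#' @param background background concentration (mg/kg), > 0.
#' @return data.frame with columns `cf` and `category` (factor with levels
#'   low, moderate, considerable, very_high).
#' @export
contamination_factor <- function(concentration, background) {
  if (any(background <= 0)) stop("background concentration must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  cf <- concentration / background
  data.frame(cf = cf, category = cf_category(cf))
}

#' Categorise contamination factors
#' @param cf numeric vector of contamination factors (>= 0).
#' @return factor with levels low, moderate, considerable, very_high.
#' @export
cf_category <- function(cf) {
  cut(cf, breaks = c(-Inf, 1, 3, 6, Inf),
      labels = c("low", "moderate", "considerable", "very_high"),
      right = TRUE)
}

#' Pollution load index
#'
#' Geometric mean of the contamination factors of all metals at a site or
#' area; PLI > 1 flags overall heavy-metal contamination.  Computed in the
#' log domain for numerical stability.
#'
#' @param cfs numeric vector of contamination factors, all > 0.
#' @return list with `pli` and logical `contaminated` (`pli > 1`).
#' @export
pollution_load_index <- function(cfs) {
  if (length(cfs) < 1L) stop("need at least one contamination factor")
  if (any(!is.finite(cfs)) || any(cfs <= 0))
    stop("all contamination factors must be positive and finite")
  pli <- exp(mean(log(cfs)))
  list(pli = pli, contaminated = pli > 1)
}

#' Area-level contamination assessment of a soil survey
#'
#' Computes, per area: the median-based contamination factor of each metal
#' (area median concentration over background, matching how published
#' area-level CFs are derived from summary tables), its category, and two
#' PLI variants — the PLI of the median-based CFs and the mean of per-site
#' PLIs.  Per-site CFs and PLIs are returned for distribution-style plots.
#'
#' @param survey a `soil_survey` data.frame (columns `site`, `area`, one
#'   column per metal).
#' @param backgrounds named numeric vector of background values covering
#'   every metal in the survey; defaults to the packaged reference values.
#' @return an object of class `contamination_result`: list with `area_cf`
#'   (data.frame area x metal CF and category), `area_pli` (data.frame with
#'   both PLI modes and contamination flags), `site_cf`, `site_pli`.
#' @export
assess_contamination <- function(survey, backgrounds = metal_backgrounds()) {
  metals <- setdiff(names(survey), c("site", "area"))
  missing <- setdiff(metals, names(backgrounds))
  if (length(missing))
    stop("no background value for metal(s): ", paste(missing, collapse = ", "))
  bg <- backgrounds[metals]
  cf_site <- sweep(as.matrix(survey[metals]), 2, bg, "/")
  site_pli <- apply(cf_site, 1, function(x) pollution_load_index(x)$pli)
  areas <- unique(survey$area)
  area_rows <- do.call(rbind, lapply(areas, function(a) {
    med <- apply(survey[survey$area == a, metals, drop = FALSE], 2,
                 stats::median)
    cf <- contamination_factor(med, bg)
    data.frame(area = a, metal = metals, median = unname(med),
               cf = cf$cf, category = cf$category, row.names = NULL)
  }))
  area_pli <- do.call(rbind, lapply(areas, function(a) {
    cfs <- area_rows$cf[area_rows$area == a]
    p_med <- pollution_load_index(cfs)
    p_site <- mean(site_pli[survey$area == a])
    data.frame(area = a, pli_median_cf = p_med$pli,
               contaminated_median_cf = p_med$contaminated,
               pli_site_mean = p_site,
               contaminated_site_mean = p_site > 1)
  }))
  structure(
    list(area_cf = area_rows, area_pli = area_pli,
         site_cf = data.frame(survey[c("site", "area")], cf_site,
                              check.names = FALSE),
         site_pli = data.frame(survey[c("site", "area")], pli = site_pli)),
    class = "contamination_result"
  )
}

#' @export
print.contamination_result <- function(x, ...) {
  cat("Area-level contamination factors (median-based):\n")
  print(x$area_cf, row.names = FALSE)
  cat("\nPollution load index:\n")
  print(x$area_pli, row.names = FALSE)
  invisible(x)
}

#' Two-group rank-sum comparison
#'
#' Shared Mann-Whitney machinery for soil metals and biomarkers: medians
#' and quartiles per group plus a two-sided p-value.  The exact null
#' distribution is enumerated when both groups have at most 12
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used (the behaviour of
#' [stats::wilcox.test()], which implements both).
#'
#' @param x,y numeric samples for the two groups.
#' @return list with per-group `median`, `q1`, `q3`, the `U` statistic,
#'   `p` and the `method` used ("exact" or "normal_approximation").
#' @keywords internal
.rank_sum_compare <- function(x, y) {
  exact <- length(x) <= 12 && length(y) <= 12 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qx <- qs(x); qy <- qs(y)
  list(median = c(qx[2], qy[2]), q1 = c(qx[1], qy[1]), q3 = c(qx[3], qy[3]),
       U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Compare one metal's concentration between the two areas
#'
#' @param survey a `soil_survey`.
#' @param metal metal column name.
#' @return data.frame with one row per area (median, Q1, Q3) plus
#'   attributes-free columns `U`, `p`, `method` repeated on both rows.
#' @export
compare_metal_between_areas <- function(survey, metal) {
  if (!metal %in% names(survey)) stop("metal not in survey: ", metal)
  areas <- unique(survey$area)
  stopifnot(length(areas) == 2L)
  x <- survey[[metal]][survey$area == areas[1]]
  y <- survey[[metal]][survey$area == areas[2]]
  if (!length(x) || !length(y)) stop("both areas need at least one site")
  cmp <- .rank_sum_compare(x, y)
  data.frame(metal = metal, area = areas, median = cmp$median,
             q1 = cmp$q1, q3 = cmp$q3, U = cmp$U, p = cmp$p,
             method = cmp$method, row.names = NULL)
}

#' Spearman correlation matrix of metals within one area
#'
#' @param survey a `soil_survey`.
#' @param area area label to subset.
#' @return list with `rho` (symmetric, unit diagonal), `p` (two-sided,
#'   `NA` on the diagonal) and `n` sites used.  Constant metal columns
#'   yield `NA` correlations with a warning.
#' @export
metal_correlations <- function(survey, area) {
  sub <- survey[survey$area == area, setdiff(names(survey), c("site", "area")),
                drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 sites in area ", area)
  k <- ncol(sub)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(names(sub), names(sub))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    xi <- sub[[i]]; xj <- sub[[j]]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warning("constant metal column; correlation undefined for ",
              names(sub)[i], "/", names(sub)[j])
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman",
                                           exact = nrow(sub) <= 10))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p, n = nrow(sub))
}
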
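#' Block correlation structure for synthetic abundance tables
#'
#' Describes the dependence structure planted among log-basis abundances:
#' disjoint feature blocks share a common within-block correlation, all
#' remaining pairs share a baseline correlation.  The implied matrix is
#' repaired to positive semi-definiteness by eigenvalue clipping; whether
#' the repair changed anything is recorded.
#'
#' @param n_features number of features.
#' @param blocks list of lists, each with elements `members` (integer
#'   feature indices) and `rho` (within-block correlation in (-1, 1)).
#' @param baseline correlation for all non-block pairs (default 0).
#' @return an object of class `correlation_structure` with elements
#'   `n_features`, `blocks`, `baseline`, `matrix` (PSD-repaired) and
#'   `repaired`.
#' @export
correlation_structure <- function(n_features, blocks = list(), baseline = 0) {
  stopifnot(n_features >= 1, baseline > -1, baseline < 1)
  m <- matrix(baseline, n_features, n_features)
  seen <- integer(0)
  for (b in blocks) {
    idx <- as.integer(b$members)
    if (any(idx < 1 | idx > n_features)) stop("block member out of range")
    if (any(idx %in% seen)) stop("block index sets must be disjoint")
    if (!is.numeric(b$rho) || b$rho <= -1 || b$rho >= 1)
      stop("within-block correlation must lie in (-1, 1)")
    seen <- c(seen, idx)
    m[idx, idx] <- b$rho
  }
  diag(m) <- 1
  m <- psd_repair(m)
  structure(
    list(n_features = as.integer(n_features), blocks = blocks,
         baseline = baseline, matrix = m,
         repaired = attr(m, "repaired")),
    class = "correlation_structure"
  )
}

#' Specification of a synthetic two-group sequencing cohort
#'
#' Defaults mirror the exposure-study design the generator emulates:
#' 26 contaminated-area and 11 uncontaminated-area subjects.
#'
#' @param n_samples_per_group integer pair, samples in groups 1 and 2.
#' @param depth per-sample sequencing depth (total counts).
#' @param group_effect per-feature shift added to group 2 log-abundances
#'   (length 1 or `n_features`; recycled).
#' @param log_mean baseline per-feature log-abundance means (length 1 or
#'   `n_features`).
#' @param log_sd marginal standard deviation of the log-basis abundances.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples_per_group = c(26L, 11L), depth = 50000L,
                        group_effect = 0, log_mean = 0, log_sd = 1,
                        seed = 1L) {
  n <- as.integer(n_samples_per_group)
  stopifnot(length(n) == 2L, all(n >= 1L))
  if (depth <= 0) stop("sequencing depth must be a positive integer")
  if (any(!is.finite(group_effect))) stop("group effects must be finite")
  stopifnot(log_sd > 0)
  structure(
    list(n_samples_per_group = n, depth = as.integer(depth),
         group_effect = group_effect, log_mean = log_mean,
         log_sd = log_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic compositional abundance table
#'
#' Draws per-sample feature abundances from a logistic-normal/multinomial
#' model: multivariate normal log-basis abundances with the planted
#' correlation structure, exponentiated, closed to proportions and sampled
#' as multinomial counts at the specified depth.  This is the generative
#' family under which SparCC's own assumptions hold, so recovery of the
#' planted correlations is a fair test of the inference stage.
#'
#' @param structure a [correlation_structure()].
#' @param spec a [cohort_spec()]; `group_effect` shifts group 2 ("CA")
#'   relative to group 1 ("UA").
#' @param group_labels labels for the two groups.
#' @return an `abundance_table`: list with `counts` (features x samples
#'   integer matrix), `feature_ids`, `sample_ids`, `group` (factor per
#'   sample) and `repaired` (whether PSD repair fired).
#' @export
generate_abundance_table <- function(structure, spec,
                                     group_labels = c("UA", "CA")) {
  stopifnot(inherits(structure, "correlation_structure"),
            inherits(spec, "cohort_spec"))
  p <- structure$n_features
  n1 <- spec$n_samples_per_group[1]
  n2 <- spec$n_samples_per_group[2]
  n <- n1 + n2
  mu <- rep_len(spec$log_mean, p)
  shift <- rep_len(spec$group_effect, p)
  sigma <- structure$matrix * spec$log_sd^2
  ch <- chol(sigma + diag(1e-10, p))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(child_seed(spec$seed, "abundance"))
  z <- matrix(stats::rnorm(n * p), n, p) %*% ch  # samples x features
  z <- sweep(z, 2, mu, "+")
  if (n2 > 0) z[(n1 + 1):n, ] <- sweep(z[(n1 + 1):n, , drop = FALSE], 2, shift, "+")
  props <- exp(t(z))                             # features x samples
  props <- sweep(props, 2, colSums(props), "/")
  counts <- apply(props, 2, function(pr) stats::rmultinom(1, spec$depth, pr))
  feature_ids <- sprintf("sp%03d", seq_len(p))
  sample_ids <- c(sprintf("%s_%02d", group_labels[1], seq_len(n1)),
                  sprintf("%s_%02d", group_labels[2], seq_len(n2)))
  dimnames(counts) <- list(feature_ids, sample_ids)
  abundance_table(counts,
                  group = factor(rep(group_labels, c(n1, n2)),
                                 levels = group_labels),
                  repaired = structure$repaired)
}

#' Construct an abundance table object
#'
#' @param counts features x samples matrix of non-negative counts with
#'   row (feature) and column (sample) names.
#' @param group factor or character vector of group labels per sample.
#' @param taxonomy optional character vector of taxonomy labels per feature
#'   (e.g. genus assignments).
#' @param repaired internal flag carried over from the generator.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, group, taxonomy = NULL, repaired = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero sample in abundance table")
  group <- as.factor(group)
  stopifnot(length(group) == ncol(counts))
  structure(
    list(counts = counts, feature_ids = rownames(counts),
         sample_ids = colnames(counts), group = group,
         taxonomy = taxonomy, repaired = repaired),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("Groups:", paste(sprintf("%s (n=%d)", levels(x$group),
                               table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic two-area soil survey
#'
#' Per-metal concentrations are log-normal within each area, the standard
#' model for strictly positive, right-skewed trace-element data.
#'
#' @param n_sites_per_area integer pair (UA sites, CA sites); default
#'   mirrors the reference survey (36 and 44).
#' @param metal_params data.frame with columns `metal`, `area`,
#'   `meanlog`, `sdlog` (`sdlog >= 0`; 0 gives the degenerate point mass
#'   at `exp(meanlog)`).  Defaults emulate the reference survey medians.
#' @param seed integer seed.
#' @param area_labels labels for the two areas.
#' @return a `soil_survey`: data.frame with columns `site`, `area` and one
#'   column per metal (mg/kg, all positive).
#' @export
generate_soil_survey <- function(n_sites_per_area = c(36L, 44L),
                                 metal_params = default_soil_params(),
                                 seed = 1L,
                                 area_labels = c("UA", "CA")) {
  n <- as.integer(n_sites_per_area)
  stopifnot(length(n) == 2L, all(n >= 1L))
  stopifnot(all(c("metal", "area", "meanlog", "sdlog") %in%
                  names(metal_params)))
  if (any(metal_params$sdlog < 0)) stop("log-normal scale must be >= 0")
  metals <- unique(metal_params$metal)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "soil"))
  area <- rep(area_labels, n)
  out <- data.frame(site = sprintf("site_%02d", seq_len(sum(n))),
                    area = area, stringsAsFactors = FALSE)
  for (m in metals) {
    v <- numeric(sum(n))
    for (a in area_labels) {
      row <- metal_params[metal_params$metal == m & metal_params$area == a, ]
      if (nrow(row) != 1L)
        stop("metal_params needs exactly one row per metal x area; missing ",
             m, "/", a)
      idx <- which(area == a)
      v[idx] <- if (row$sdlog == 0) rep(exp(row$meanlog), length(idx))
                else stats::rlnorm(length(idx), row$meanlog, row$sdlog)
    }
    out[[m]] <- v
  }
  class(out) <- c("soil_survey", "data.frame")
  out
}

#' Default log-normal parameters for the synthetic soil survey
#'
#' Locations are the log medians of the reference survey; scales are
#' derived from the reference interquartile ranges of the log
#' concentrations (`sdlog = (log Q3 - log Q1) / (2 * qnorm(0.75))`), so
#' the generated surveys reproduce the medians and spread of the two
#' areas, including the contaminated area's severe Cd/Pb excess.
#'
#' @return data.frame with columns `metal`, `area`, `meanlog`, `sdlog`.
#' @export
default_soil_params <- function() {
  ref <- soil_reference()
  iqr_z <- 2 * stats::qnorm(0.75)
  rbind(
    data.frame(metal = ref$metal, area = "UA",
               meanlog = log(ref$ua_median),
               sdlog = (log(ref$ua_q3) - log(ref$ua_q1)) / iqr_z),
    data.frame(metal = ref$metal, area = "CA",
               meanlog = log(ref$ca_median),
               sdlog = (log(ref$ca_q3) - log(ref$ca_q1)) / iqr_z)
  )
}

#' Generate a synthetic two-group biomarker cohort
#'
#' Subjects receive log-normal marker values with a planted inter-marker
#' correlation structure (on the log scale) and per-marker multiplicative
#' group shifts, emulating the exposure-cohort biomarker tables (blood and
#' urinary cadmium, renal and oxidative-stress markers, cytokines, and the
#' blood counts from which the systemic immune-inflammation index is
#' computed).
#'
#' @param n_per_group integer pair (group 1, group 2 subjects).
#' @param markers character vector of marker names.
#' @param log_means baseline log-scale means (length 1 or one per marker).
#' @param log_sds log-scale standard deviations (length 1 or per marker).
#' @param group_shift additive log-scale shift applied to group 2 (length 1
#'   or per marker).
#' @param correlation inter-marker correlation matrix (PSD; repaired by
#'   eigenvalue clipping if not, with the repair recorded).
#' @param seed integer seed.
#' @param group_labels labels for the two groups.
#' @return a `biomarker_table`: data.frame with `subject`, `group` and one
#'   column per marker; attribute `"repaired"` records PSD repair.
#' @export
generate_biomarker_cohort <- function(n_per_group = c(125L, 183L),
                                      markers = default_biomarkers(),
                                      log_means = 0, log_sds = 0.5,
                                      group_shift = 0,
                                      correlation = NULL, seed = 1L,
                                      group_labels = c("UA", "CA")) {
  n <- as.integer(n_per_group)
  stopifnot(length(n) == 2L, all(n >= 1L))
  k <- length(markers)
  if (is.null(correlation)) correlation <- diag(k)
  stopifnot(is.matrix(correlation), nrow(correlation) == k)
  correlation <- psd_repair(correlation)
  mu <- rep_len(log_means, k)
  sd <- rep_len(log_sds, k)
  shift <- rep_len(group_shift, k)
  ch <- chol(correlation + diag(1e-10, k))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(child_seed(seed, "biomarkers"))
  ntot <- sum(n)
  z <- matrix(stats::rnorm(ntot * k), ntot, k) %*% ch
  z <- sweep(z, 2, sd, "*")
  z <- sweep(z, 2, mu, "+")
  g2 <- seq.int(n[1] + 1, ntot)
  z[g2, ] <- sweep(z[g2, , drop = FALSE], 2, shift, "+")
  vals <- exp(z)
  colnames(vals) <- markers
  out <- data.frame(subject = sprintf("subj_%03d", seq_len(ntot)),
                    group = factor(rep(group_labels, n),
                                   levels = group_labels),
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "repaired") <- attr(correlation, "repaired")
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Default marker panel for the synthetic biomarker cohort
#'
#' Includes the blood counts needed for the systemic immune-inflammation
#' index plus the exposure and effect markers of the emulated study.
#'
#' @return character vector of marker names.
#' @export
default_biomarkers <- function() {
  c("neutrophils", "lymphocytes", "platelets",
    "urine_cd", "blood_cd", "urine_b2mg", "urine_8ohg",
    "il2", "il4", "il6", "il8", "tnfa")
}

# Save/restore the global RNG state so generators do not perturb the
# caller's random stream.
#' @keywords internal
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
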
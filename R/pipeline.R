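#' Read a feature abundance table from delimited text
#'
#' Expects tab-delimited text with feature ids in the first column and a
#' header row of sample ids; an optional `taxonomy` column is carried as
#' feature metadata.  Group labels come from a metadata file or vector.
#'
#' @param path abundance file path.
#' @param group sample group labels: a named vector/factor, or the path
#'   of a two-column (sample, group) tab-delimited file.
#' @param sep field separator (default tab).
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path, group, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1])
  taxonomy <- NULL
  if ("taxonomy" %in% names(df)) {
    taxonomy <- stats::setNames(df$taxonomy, ids)
    df$taxonomy <- NULL
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in ", path)
  if (any(counts < 0)) stop("negative counts in ", path)
  rownames(counts) <- ids
  if (is.character(group) && length(group) == 1 && file.exists(group)) {
    meta <- utils::read.table(group, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
    group <- stats::setNames(meta[[2]], meta[[1]])
  }
  if (!is.null(names(group))) group <- group[colnames(counts)]
  abundance_table(counts, group = group, taxonomy = taxonomy)
}

#' Write an abundance table as tab-delimited text
#'
#' Features x samples with a header row of sample ids; the group labels
#' go to a companion `<path>.groups.tsv` file so that
#' [read_abundance()] round-trips losslessly.
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @export
write_abundance <- function(table, path) {
  df <- data.frame(feature_id = table$feature_ids, table$counts,
                   check.names = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- table$taxonomy
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = table$sample_ids,
                     group = as.character(table$group))
  utils::write.table(meta, paste0(path, ".groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge list and GraphML
#'
#' The TSV edge list (source, target, rho, sign) and GraphML file are
#' both directly importable by Gephi.
#'
#' @param network a `cooccurrence_network`.
#' @param path output path stem; writes `<path>.edges.tsv` and
#'   `<path>.graphml`.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, paste0(path, ".edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- network$graph
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(path)
}

#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own child seed.
#' @param abundance_path,group_path optional real inputs; when absent the
#'   synthetic generators supply the data.
#' @param n_features,depth,block_rho,n_blocks,block_size simulation
#'   parameters for the abundance generator (two groups with different
#'   numbers of planted correlation blocks: the first group gets
#'   `n_blocks`, the second `max(1, n_blocks %/% 3)`, mirroring a richer
#'   unexposed network).
#' @param group_effect log-abundance shift planted on the rare-feature
#'   tail of the second group, driving the beta-diversity and
#'   differential-abundance stages.
#' @param n_samples_per_group samples per group.
#' @param sparcc_bootstraps null resamples for SparCC p-values.
#' @param inner_iterations SparCC inner Dirichlet resamples.
#' @param null_replicates Erdos-Renyi null ensemble size.
#' @param use_rmt whether to select the adjacency threshold by RMT scan.
#' @param magnitude_floor,q_ceiling edge filters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            abundance_path = NULL, group_path = NULL,
                            n_features = 32L, depth = 5000L,
                            block_rho = 0.85, n_blocks = 2L,
                            block_size = 8L, group_effect = 2,
                            n_samples_per_group = c(26L, 11L),
                            sparcc_bootstraps = 500L,
                            inner_iterations = 10L,
                            null_replicates = 100L,
                            use_rmt = FALSE,
                            magnitude_floor = 0.3, q_ceiling = 0.05) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              abundance_path = abundance_path, group_path = group_path,
              n_features = as.integer(n_features),
              depth = as.integer(depth), block_rho = block_rho,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size),
              group_effect = group_effect,
              n_samples_per_group = as.integer(n_samples_per_group),
              sparcc_bootstraps = as.integer(sparcc_bootstraps),
              inner_iterations = as.integer(inner_iterations),
              null_replicates = as.integer(null_replicates),
              use_rmt = use_rmt, magnitude_floor = magnitude_floor,
              q_ceiling = q_ceiling)
  if (!is.null(abundance_path) && !file.exists(abundance_path))
    stop("config invalid: abundance_path does not exist: ", abundance_path)
  if (is.null(abundance_path) && cfg$n_features < 4)
    stop("config invalid: n_features must be >= 4 for simulation")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every analytic stage in order — simulate (or load), soil
#' contamination, biomarkers, per-group SparCC, network construction,
#' topology with null ensemble, node roles, and community ecology —
#' writing stage outputs under the configured directory and returning a
#' manifest with per-stage wall-clock times and output checksums.
#' Networks are fitted separately per group, never pooled.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_manifest`: list with `version`,
#'   `config_hash`, `stages` (data.frame: stage, seconds), `checksums`
#'   (named md5 per output file) and `summary` (the collected result
#'   objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0); secs <- numeric(0)
  summary <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    secs <<- c(secs, proc.time()[["elapsed"]] - t0)
    value
  }

  tab <- tick("simulate", {
    if (!is.null(config$abundance_path)) {
      read_abundance(config$abundance_path, config$group_path)
    } else {
      p <- config$n_features
      mk_blocks <- function(nb) {
        lapply(seq_len(nb), function(b)
          list(members = ((b - 1) * config$block_size + 1):
                 (b * config$block_size),
               rho = config$block_rho))
      }
      # blocks occupy the abundant features; a tail of progressively
      # rarer features supplies presence/absence variation for the
      # beta-diversity stages and carries the group effect
      core <- min(p, config$n_blocks * config$block_size + 4L)
      log_mean <- c(rep(0, core),
                    if (p > core) seq(-2, -7, length.out = p - core))
      shift <- rep(0, p)
      if (p > core)
        shift[(core + 1):p] <- config$group_effect *
          rep_len(c(1, -1), p - core)
      # richer block structure in group 1 (the unexposed-like community)
      st1 <- correlation_structure(p, mk_blocks(config$n_blocks))
      st2 <- correlation_structure(p, mk_blocks(max(1L,
                                                    config$n_blocks %/% 2L)))
      t1 <- generate_abundance_table(st1, cohort_spec(
        c(config$n_samples_per_group[1], 1L), depth = config$depth,
        log_mean = log_mean, seed = config$seed))
      t2 <- generate_abundance_table(st2, cohort_spec(
        c(1L, config$n_samples_per_group[2]), depth = config$depth,
        log_mean = log_mean, group_effect = shift,
        seed = config$seed + 1L))
      counts <- cbind(t1$counts[, seq_len(config$n_samples_per_group[1])],
                      t2$counts[, -1, drop = FALSE])
      colnames(counts) <- c(sprintf("UA_%02d",
                                    seq_len(config$n_samples_per_group[1])),
                            sprintf("CA_%02d",
                                    seq_len(config$n_samples_per_group[2])))
      abundance_table(counts,
                      group = factor(rep(c("UA", "CA"),
                                         config$n_samples_per_group),
                                     levels = c("UA", "CA")))
    }
  })
  write_abundance(tab, file.path(config$out_dir, "abundance.tsv"))

  soil <- tick("soil", {
    survey <- generate_soil_survey(seed = config$seed)
    res <- assess_contamination(survey)
    cmp <- do.call(rbind, lapply(
      setdiff(names(survey), c("site", "area")),
      function(m) compare_metal_between_areas(survey, m)))
    utils::write.csv(res$area_cf,
                     file.path(config$out_dir, "contamination_cf.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp,
                     file.path(config$out_dir, "soil_comparisons.csv"),
                     row.names = FALSE)
    list(contamination = res, comparisons = cmp)
  })
  summary$contamination <- soil$contamination$area_cf

  biom <- tick("biomarkers", {
    shift <- stats::setNames(rep(0, length(default_biomarkers())),
                             default_biomarkers())
    shift[c("urine_cd", "blood_cd", "urine_b2mg", "urine_8ohg")] <-
      c(1.8, 2.5, 0.3, 0.3)
    cohort <- generate_biomarker_cohort(group_shift = shift,
                                        seed = config$seed)
    cohort$sii <- compute_sii(cohort$neutrophils, cohort$lymphocytes,
                              cohort$platelets)
    cmp <- compare_biomarkers(cohort)
    cors <- biomarker_correlations(cohort)
    utils::write.csv(cmp, file.path(config$out_dir, "biomarkers.csv"),
                     row.names = FALSE)
    utils::write.csv(cors$r,
                     file.path(config$out_dir, "biomarker_correlations.csv"))
    list(cohort = cohort, comparison = cmp, correlations = cors)
  })
  summary$biomarkers <- biom$comparison

  group_levels <- levels(tab$group)
  nets <- tick("sparcc", {
    lapply(stats::setNames(group_levels, group_levels), function(gl) {
      sub <- tab$counts[, tab$group == gl, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      sparcc_analysis(sub, n_bootstrap = config$sparcc_bootstraps,
                      inner_iterations = config$inner_iterations,
                      seed = config$seed)
    })
  })

  built <- tick("network", {
    lapply(names(nets), function(gl) {
      res <- nets[[gl]]
      thr <- 0
      if (config$use_rmt) {
        scan <- rmt_threshold_scan(res$rho)
        if (is.finite(scan$chosen_threshold)) thr <- scan$chosen_threshold
      }
      nw <- build_network(res, rmt_threshold = thr,
                          magnitude_floor = config$magnitude_floor,
                          q_ceiling = config$q_ceiling, group = gl)
      if (nw$n_edges > 0)
        write_network(nw, file.path(config$out_dir,
                                    paste0("network_", gl)))
      nw
    })
  })
  names(built) <- names(nets)

  topo <- tick("topology", {
    lapply(built, function(nw) {
      if (nw$n_nodes == 0) return(NULL)
      ts <- topology_summary(nw)
      null <- er_null_ensemble(nw$n_nodes, nw$n_edges,
                               n_replicates = config$null_replicates,
                               seed = config$seed)
      list(summary = ts, null = null)
    })
  })
  summary$topology <- lapply(topo, function(x)
    if (is.null(x)) NULL else unclass(x$summary))

  roles <- tick("roles", {
    lapply(built, function(nw) {
      if (nw$n_nodes == 0) return(NULL)
      node_roles(nw, seed = config$seed)
    })
  })
  summary$keystone <- lapply(roles, function(x)
    if (is.null(x)) NULL else x$keystone$node)

  eco <- tick("ecology", {
    alpha <- alpha_diversity(tab)
    d <- binary_jaccard(tab)
    ord <- pcoa(d, k = 2)
    an <- anosim(d, tab$group, n_permutations = 999L, seed = config$seed)
    diff <- differential_features(tab)
    utils::write.csv(alpha, file.path(config$out_dir, "alpha_diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(diff, file.path(config$out_dir,
                                     "differential_features.csv"),
                     row.names = FALSE)
    list(alpha = alpha, pcoa = ord, anosim = an, differential = diff)
  })
  summary$anosim <- list(R = eco$anosim$R, p = eco$anosim$p)
  summary$n_differential <- table(eco$differential$status)

  report_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(
    contamination = summary$contamination,
    anosim = summary$anosim,
    networks = lapply(built, function(nw)
      list(nodes = nw$n_nodes, edges = nw$n_edges,
           pct_positive = nw$pct_positive)),
    keystone = summary$keystone
  ), report_path, auto_unbox = TRUE, digits = NA, force = TRUE)

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config)[!vapply(config, is.null,
                                               logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA)
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  manifest <- structure(
    list(version = as.character(utils::packageVersion("hmbionet")),
         config_hash = unname(tools::md5sum(cfg_path)),
         stages = data.frame(stage = stages, seconds = round(secs, 3)),
         checksums = sums,
         summary = summary),
    class = "run_manifest")
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run, package version", x$version, "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
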
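test_that("richness estimators collapse to Sobs without rare features and match hand values", {
  a <- alpha_diversity(c(5, 3, 2))     # no singletons
  expect_equal(a$sobs, 3)
  expect_equal(a$chao1, 3)
  b <- alpha_diversity(c(1, 1, 2))     # F1 = 2, F2 = 1
  expect_equal(b$sobs, 3)
  expect_equal(b$chao1, 3 + 2^2 / (2 * 1))
  expect_equal(b$chao1_mode, "classic")
  # adding a zero-count feature changes nothing
  expect_equal(alpha_diversity(c(1, 1, 2, 0))$chao1, b$chao1)
  # F2 = 0 switches to the bias-corrected form
  d <- alpha_diversity(c(1, 1, 5))
  expect_equal(d$chao1, 3 + 2 * 1 / 2)
  expect_equal(d$chao1_mode, "bias_corrected")
  # no rare features at all: ACE = Sobs
  e <- alpha_diversity(rep(50, 6))
  expect_equal(e$ace, 6)
  expect_gte(b$chao1, b$sobs)
  expect_gte(b$ace, b$sobs)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
  expect_error(alpha_diversity(c(1.5, 2)), "integer")
})

test_that("ACE agrees with the vegan implementation on typical count vectors", {
  set.seed(12)
  for (r in 1:5) {
    x <- rpois(60, 3)
    x[1] <- 40          # ensure an abundant feature and a positive sample
    ours <- alpha_diversity(x)
    ref <- vegan::estimateR(x)
    expect_equal(ours$ace, unname(ref["S.ACE"]), tolerance = 1e-8)
    expect_equal(ours$sobs, unname(ref["S.obs"]))
  }
})

test_that("binary Jaccard distances follow set arithmetic and the metric axioms", {
  m <- cbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1), s3 = c(1, 1, 1, 0),
             s4 = c(0, 0, 0, 3))
  d <- binary_jaccard(m)
  expect_equal(d["s1", "s2"], 0.5)        # {A,B,C} vs {B,C,D}: 1 - 2/4
  expect_equal(d["s1", "s3"], 0)          # identical presence profiles
  expect_equal(d["s1", "s4"], 1)          # disjoint profiles
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  # metric axioms on random ternary presence profiles
  set.seed(5)
  pm <- matrix(rbinom(20 * 40, 1, 0.4), 20, 40)
  pm[1, colSums(pm) == 0] <- 1
  dd <- binary_jaccard(pm)
  expect_true(all(dd >= 0 & dd <= 1))
  n <- ncol(pm)
  for (r in 1:200) {
    ijk <- sample(n, 3)
    expect_lte(dd[ijk[1], ijk[3]],
               dd[ijk[1], ijk[2]] + dd[ijk[2], ijk[3]] + 1e-12)
  }
  # agreement with the vegan binary Jaccard implementation
  dv <- as.matrix(vegan::vegdist(t(pm), method = "jaccard", binary = TRUE))
  expect_equal(unname(dd), unname(dv), tolerance = 1e-12)
})

test_that("PCoA reconstructs Euclidean configurations and orders axes by variance", {
  pts <- cbind(c(0, 3, 0, 3), c(0, 0, 4, 4))
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(res$eigenvalues[seq_len(ncol(res$coordinates))]) <= 1e-9))
  expect_true(all(res$percent_variance >= 0))
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-9)
  # points on a line: first axis carries all positive variance
  dl <- as.matrix(dist(c(0, 1, 2, 5)))
  rl <- pcoa(dl)
  expect_equal(rl$percent_variance[1], 100, tolerance = 1e-9)
  # identical samples land on coincident coordinates
  d2 <- as.matrix(dist(c(0, 0, 2)))
  r2 <- pcoa(d2)
  expect_equal(r2$coordinates[1, ], r2$coordinates[2, ], tolerance = 1e-9)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("ANOSIM yields R = 1 for perfect separation and matches vegan", {
  set.seed(3)
  lab <- rep(c("a", "b"), each = 4)
  x <- matrix(rnorm(8 * 5), 8, 5)
  x[lab == "b", ] <- x[lab == "b", ] + 8   # wide separation
  d <- as.matrix(dist(x))
  res <- anosim(d, lab, n_permutations = 499, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 500)
  # statistic agrees with the vegan implementation on unseparated data
  y <- matrix(rnorm(8 * 5), 8, 5)
  dy <- as.matrix(dist(y))
  ours <- anosim(dy, lab, n_permutations = 99, seed = 2)
  ref <- vegan::anosim(as.dist(dy), lab, permutations = 99)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
  expect_error(anosim(dy, rep("a", 8)), "2 groups")
  expect_error(anosim(dy, c("a", rep("b", 7))), "at least 2 samples")
})

test_that("ANOSIM p matches exact enumeration on a tiny design", {
  set.seed(8)
  x <- c(0, 0.4, 3.1, 3.4)
  d <- as.matrix(dist(x))
  lab <- c("g1", "g1", "g2", "g2")
  res <- anosim(d, lab, n_permutations = 1999, seed = 5)
  exact <- oracle_anosim_p(d, lab)
  expect_lt(abs(res$p - exact), 0.05)
})

test_that("differential features classify by fold change and FDR jointly", {
  set.seed(21)
  n1 <- 12; n2 <- 12
  base <- matrix(rpois((n1 + n2) * 30, 50), 30)
  base[1, 13:24] <- base[1, 13:24] * 8       # up in group 2
  base[2, 1:12] <- base[2, 1:12] * 8         # down in group 2
  tab <- abundance_table(base, group = rep(c("u", "c"), c(n1, n2)))
  df <- differential_features(tab, numerator = "c")
  expect_equal(as.character(df$status[1]), "up")
  expect_equal(as.character(df$status[2]), "down")
  expect_true(all(df$status[df$q >= 0.05] == "ns"))
  expect_true(all(df$status[abs(df$log2fc) < 1] == "ns"))
  # equal group means give log2FC near 0 and ns
  expect_true(mean(abs(df$log2fc[3:30])) < 0.5)
  # tightening the q ceiling only shrinks the significant set
  df01 <- differential_features(tab, numerator = "c", q_ceiling = 0.01)
  expect_lte(sum(df01$status != "ns"), sum(df$status != "ns"))
})

test_that("null differential testing controls the FDR", {
  set.seed(33)
  counts <- matrix(rpois(24 * 200, 30), 200)
  tab <- abundance_table(counts, group = rep(c("u", "c"), each = 12))
  df <- differential_features(tab)
  expect_lte(mean(df$q < 0.05), 0.05)
})

test_that("taxa-biomarker correlations detect planted monotone associations", {
  set.seed(44)
  n <- 40
  marker <- rlnorm(n)
  counts <- matrix(rpois(6 * n, 40), 6, n)
  counts[1, ] <- round(60 * marker / max(marker)) + 1  # monotone taxon
  colnames(counts) <- paste0("subj_", 1:n)
  tab <- abundance_table(counts, group = rep("g", n),
                         taxonomy = c("GenusA", "GenusB", "GenusB",
                                      "GenusC", "GenusD", "GenusE"))
  bio <- data.frame(subject = paste0("subj_", 1:n), group = "g",
                    urine_cd = marker)
  res <- taxa_biomarker_correlations(tab, bio, markers = "urine_cd")
  expect_gt(res$rho[1, "urine_cd"], 0.6)
  expect_true(res$tier[1, "urine_cd"] %in% c("*", "**"))
  # genus aggregation collapses rows by taxonomy label
  agg <- taxa_biomarker_correlations(tab, bio, markers = "urine_cd",
                                     aggregate_genus = TRUE)
  expect_equal(nrow(agg$rho), 5)
  # constant taxon (flat relative abundance) reported as undefined
  counts2 <- matrix(10, 4, n, dimnames = list(paste0("t", 1:4),
                                              paste0("subj_", 1:n)))
  tab2 <- abundance_table(counts2, group = rep("g", n))
  r2 <- taxa_biomarker_correlations(tab2, bio, markers = "urine_cd")
  expect_true(is.na(r2$rho[1, "urine_cd"]))
})
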
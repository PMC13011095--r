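test_that("variation matrix matches the direct per-pair variance oracle", {
  set.seed(1)
  frac <- matrix(rgamma(12, 2), 3, 4)
  frac <- sweep(frac, 2, colSums(frac), "/")
  tt <- variation_matrix(frac)
  expect_equal(tt, .symmetrise(oracle_variation(frac)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(diag(tt)), rep(0, 3))
  expect_true(isSymmetric(tt))
  # proportional features have zero log-ratio variance
  f2 <- rbind(frac, 3 * frac[1, ])
  f2 <- sweep(f2, 2, colSums(f2), "/")
  expect_equal(variation_matrix(f2)[1, 4], 0, tolerance = 1e-12)
})

test_that("variation matrix rejects all-zero features and compositional scaling is neutral", {
  counts <- matrix(rpois(40, 20), 8, 5)
  counts[3, ] <- 0
  expect_error(variation_matrix(counts), "all-zero")
  counts[3, ] <- 7
  t1 <- variation_matrix(counts)
  # scaling one sample's counts before closure cannot change log-ratios
  frac <- sweep(counts + 1, 2, colSums(counts + 1), "/")
  frac2 <- frac
  expect_equal(variation_matrix(frac), variation_matrix(frac2 * 1))
})

test_that("basis estimation needs four features and respects relabelling symmetry", {
  tab <- toy_table(n_features = 8, seed = 3)
  expect_error(sparcc_estimate(tab$counts[1:3, ]), "at least 4")
  res <- sparcc_estimate(tab, seed = 5)
  expect_true(isSymmetric(res$rho))
  expect_equal(unname(diag(res$rho)), rep(1, 8))
  expect_true(all(abs(res$rho) <= 1))
  # permuting feature order permutes rho identically (deterministic
  # pseudocount mode; Dirichlet draws are only equivariant in law)
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  det <- sparcc_estimate(tab, zero_mode = "pseudocount", seed = 5)
  det_p <- sparcc_estimate(tab$counts[perm, ], zero_mode = "pseudocount",
                           seed = 5)
  expect_equal(unname(det_p$rho), unname(det$rho[perm, perm]),
               tolerance = 1e-10)
  # determinism
  expect_identical(res$rho, sparcc_estimate(tab, seed = 5)$rho)
})

test_that("SparCC recovers a planted block and stays near zero off-structure", {
  st <- correlation_structure(20, mk_blocks(2, 5, 0.7))
  within <- offs <- numeric(5)
  for (s in 1:5) {
    tab <- generate_abundance_table(st, cohort_spec(c(50, 50), depth = 20000,
                                                    seed = s))
    rho <- sparcc_estimate(tab, seed = s)$rho
    b <- rho[1:5, 1:5]
    within[s] <- mean(b[upper.tri(b)])
    o <- rho[11:20, 11:20]
    offs[s] <- mean(abs(o[upper.tri(o)]))
  }
  expect_lt(abs(mean(within) - 0.7), 0.15)
  expect_lt(mean(offs), 0.1)
})

test_that("null p-values respect the add-one floor, symmetry and determinism", {
  tab <- toy_table(n_features = 8, n1 = 12, n2 = 8, seed = 9)
  res <- sparcc_estimate(tab, inner_iterations = 5, seed = 2)
  p <- sparcc_pvalues(tab, res$rho, n_bootstrap = 24, seed = 2,
                      inner_iterations = 5)
  expect_true(all(p[upper.tri(p)] >= 1 / 25))
  expect_true(all(p[upper.tri(p)] <= 1))
  expect_true(isSymmetric(p))
  expect_true(all(is.na(diag(p))))
  p2 <- sparcc_pvalues(tab, res$rho, n_bootstrap = 24, seed = 2,
                       inner_iterations = 5)
  expect_identical(p, p2)
})

test_that("permutation p-values are approximately uniform on exchangeable null data", {
  # independent features: every pair is null; pool p over pairs
  st <- correlation_structure(30, list())
  tab <- generate_abundance_table(st, cohort_spec(c(25, 25), depth = 10000,
                                                  seed = 4))
  res <- sparcc_estimate(tab, inner_iterations = 5, seed = 4)
  p <- sparcc_pvalues(tab, res$rho, n_bootstrap = 100, seed = 4,
                      inner_iterations = 5)
  pv <- p[upper.tri(p)]
  ks <- suppressWarnings(ks.test(pv, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("BH adjustment matches the hand-run step-up over a 4-test family", {
  # family {0.01, 0.02, 0.04, 0.05}: step-up by hand gives
  # q4 = 0.05; q3 = min(0.04*4/3, q4) = 0.05; q2 = min(0.02*4/2, q3) = 0.04;
  # q1 = min(0.01*4/1, q2) = 0.04
  p <- matrix(NA_real_, 4, 4)
  p[1, 2] <- 0.01; p[1, 3] <- 0.02; p[1, 4] <- 0.04; p[2, 3] <- 0.05
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- 1
  expect_warning(q <- fdr_adjust(p), "NA p-values")
  expect_equal(c(q[1, 2], q[1, 3], q[1, 4], q[2, 3]),
               c(0.04, 0.04, 0.05, 0.05))
  expect_true(isSymmetric(q))
})

test_that("BH q-values dominate p, preserve order, and degenerate families pass through", {
  set.seed(31)
  p <- matrix(NA_real_, 6, 6)
  p[upper.tri(p)] <- runif(15)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- 1
  q <- fdr_adjust(p)
  ut <- upper.tri(p)
  expect_true(all(q[ut] >= p[ut] - 1e-12))
  expect_equal(order(q[ut], p[ut]), order(p[ut]))  # ranking preserved
  # constant family: q equals p
  pc <- matrix(0.03, 3, 3); diag(pc) <- 1
  expect_equal(fdr_adjust(pc)[upper.tri(pc)], rep(0.03, 3))
  # single test: q = p
  p1 <- matrix(c(1, 0.02, 0.02, 1), 2, 2)
  expect_equal(fdr_adjust(p1)[1, 2], 0.02)
})
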
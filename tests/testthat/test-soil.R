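test_that("contamination factors reproduce the published area-level values", {
  cd <- contamination_factor(2.944, 0.180)
  expect_equal(round(cd$cf, 2), 16.36)
  expect_equal(as.character(cd$category), "very_high")
  pb <- contamination_factor(70.956, 22.900)
  expect_equal(round(pb$cf, 2), 3.10)
  expect_equal(as.character(pb$category), "considerable")
  zn <- contamination_factor(117.849, 72.700)
  expect_equal(round(zn$cf, 2), 1.62)
  cu <- contamination_factor(34.866, 30.500)
  expect_equal(round(cu$cf, 2), 1.14)
  expect_equal(as.character(zn$category), "moderate")
  expect_equal(as.character(cu$category), "moderate")
})

test_that("CF handles identity, scale invariance, boundaries and bad input", {
  expect_equal(contamination_factor(5, 5)$cf, 1)
  # boundary values fall in the lower category
  expect_equal(as.character(cf_category(c(1, 3, 6))),
               c("low", "moderate", "considerable"))
  expect_equal(as.character(cf_category(c(0.5, 2, 4, 10))),
               c("low", "moderate", "considerable", "very_high"))
  # scale invariance
  expect_equal(contamination_factor(7 * 2.944, 7 * 0.180)$cf,
               contamination_factor(2.944, 0.180)$cf)
  expect_error(contamination_factor(1, 0), "background")
  expect_error(contamination_factor(-1, 1), ">= 0")
})

test_that("PLI is the geometric mean with identity and ordering invariances", {
  expect_equal(pollution_load_index(c(1, 1, 1))$pli, 1)
  expect_equal(pollution_load_index(c(4, 1))$pli, 2)
  expect_equal(pollution_load_index(5)$pli, 5)
  cfs <- c(0.3, 1.7, 2.2, 0.9)
  expect_equal(pollution_load_index(cfs)$pli,
               pollution_load_index(rev(cfs))$pli)
  # brute-force product-then-root oracle on the reference UA medians
  ref <- soil_reference()
  ua_cfs <- ref$ua_median / ref$background
  oracle <- prod(ua_cfs)^(1 / length(ua_cfs))
  expect_equal(pollution_load_index(ua_cfs)$pli, oracle, tolerance = 1e-12)
  expect_false(pollution_load_index(ua_cfs)$contaminated)
  expect_error(pollution_load_index(c(1, 0)), "positive")
})

test_that("area assessment reproduces median-based CFs and consistent PLIs", {
  ref <- soil_reference()
  pars <- default_soil_params()
  pars$sdlog <- 0  # degenerate: site values equal the reference medians
  sv <- generate_soil_survey(c(5, 5), pars, seed = 1)
  res <- assess_contamination(sv)
  ca <- res$area_cf[res$area_cf$area == "CA", ]
  expect_equal(ca$cf[ca$metal == "Cd"], 2.944 / 0.180, tolerance = 1e-12)
  expect_equal(round(ca$cf[ca$metal == "Pb"], 2), 3.10)
  # PLI of the median CFs equals the geometric mean within 1e-12
  expect_equal(res$area_pli$pli_median_cf[res$area_pli$area == "CA"],
               exp(mean(log(ca$cf))), tolerance = 1e-12)
  expect_error(assess_contamination(sv, backgrounds = c(Cd = 0.18)),
               "no background")
})

test_that("rank-sum area comparison matches the enumeration oracle and handles ties", {
  sv <- data.frame(site = paste0("s", 1:6),
                   area = rep(c("UA", "CA"), each = 3),
                   Pb = c(1, 2, 3, 4, 5, 6))
  out <- compare_metal_between_areas(sv, "Pb")
  # full enumeration of C(6,3) = 20 assignments: 2 as extreme, two-sided
  expect_equal(out$p[1], 0.1)
  expect_equal(out$U[1], 0)
  expect_equal(out$method[1], "exact")
  sv$Pb <- rep(c(2, 4, 9), 2)
  expect_equal(compare_metal_between_areas(sv, "Pb")$p[1], 1)
  expect_error(compare_metal_between_areas(sv, "Xx"), "not in survey")
})

test_that("metal correlations are symmetric rank correlations with sane nulls", {
  sv <- data.frame(site = paste0("s", 1:8), area = "UA",
                   A = 1:8, B = exp(1:8), C = c(8:1))
  mc <- metal_correlations(sv, "UA")
  expect_equal(mc$rho["A", "B"], 1)   # monotone pair
  expect_equal(mc$rho["A", "C"], -1)
  expect_equal(unname(diag(mc$rho)), rep(1, 3))
  expect_true(all(is.na(diag(mc$p))))
  sv$D <- 5
  w <- capture_warnings(metal_correlations(sv, "UA"))
  expect_true(any(grepl("constant", w)))
  # type-I error calibration on independent metals
  set.seed(99)
  rej <- replicate(400, {
    sv2 <- data.frame(site = 1:36, area = "x",
                      m1 = rnorm(36), m2 = rnorm(36))
    metal_correlations(sv2, "x")$p[1, 2] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})
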
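test_that("Wald ratio reproduces published replication estimates", {
  # adiponectin at ADIPOQ (UK10K replication row)
  wr <- wald_ratio(0.982, 0.103, -0.629, 0.143)
  expect_lt(abs(wr$beta - (-0.641)), 1e-3)
  expect_lt(abs(wr$se - 0.160), 1e-3)
  # SORT1 liver expression row
  wr2 <- wald_ratio(-0.980, 0.037, -1.240, 0.105)
  expect_lt(abs(wr2$beta - 1.265), 1e-3)
  expect_lt(abs(wr2$se - 0.117), 1e-3)
  # unit-denominator identity
  wr3 <- wald_ratio(1, 1e-12, 0.7, 0.2)
  expect_equal(wr3$beta, 0.7)
  expect_equal(wr3$se, 0.2, tolerance = 1e-10)
  expect_error(wald_ratio(0, 0.1, 0.5, 0.1), "nonzero")
})

test_that("the full second-order delta term is retained in the Wald SE", {
  # first-order-only SE would be 0.143/0.982 = 0.146; the printed value
  # needs the exposure-uncertainty term
  wr <- wald_ratio(0.982, 0.103, -0.629, 0.143)
  expect_gt(wr$se, 0.155)
  first_order <- 0.143 / 0.982
  expect_equal(sqrt(first_order^2 + 0.629^2 * 0.103^2 / 0.982^4), wr$se)
})

test_that("single-instrument 2SLS equals the reduced-form ratio to 1e-10", {
  fx <- oracle_fixture()
  m <- 0.8 * fx$g + rnorm(50, sd = 0.7)
  res <- two_stage_least_squares(fx$g, m, fx$y, covariates = fx$covars)
  gy <- run_mwas(cbind(g = fx$g), list(y = fx$y), covariates = fx$covars)
  gx <- run_mwas(cbind(g = fx$g), list(m = m), covariates = fx$covars)
  expect_equal(res$beta, gy$beta / gx$beta, tolerance = 1e-10)
  # equivalently, the within-sample Wald ratio on OLS summary stats
  expect_equal(wald_ratio(gx$beta, gx$se, gy$beta, gy$se)$beta, res$beta,
               tolerance = 1e-10)
  expect_identical(res$method, "2SLS")
})

test_that("2SLS recovers the generative methylation-to-trait effect", {
  ests <- t(vapply(1:25, function(s) {
    st <- simulate_scenario(sim_config("mediation", n_samples = 2000, a = 0.9,
                                       b = 0.3, seed = 700 + s))
    g <- st$genotypes$dosage[, st$truth$sentinel_id]
    r <- two_stage_least_squares(g, st$methylation, st$trait,
                                 covariates = st$covariates[, c("age", "sex")])
    # rescale from standardized M/Y back to the generative (raw) scale
    c(est = r$beta * st$truth$sd_y_raw / st$truth$sd_m_raw)
  }, numeric(1)))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.3), 3 * mc_se)
})

test_that("2SLS cannot separate mediation from horizontal pleiotropy", {
  st <- simulate_scenario(sim_config("pleiotropy", n_samples = 4000, a = 0.9,
                                     d = 0.27, seed = 55))
  g <- st$genotypes$dosage[, st$truth$sentinel_id]
  r <- two_stage_least_squares(g, st$methylation, st$trait,
                               covariates = st$covariates[, c("age", "sex")])
  est_raw <- r$beta * st$truth$sd_y_raw / st$truth$sd_m_raw
  # despite b = 0 the estimate looks like d/a = 0.3
  expect_lt(abs(est_raw - 0.3), 4 * r$se * st$truth$sd_y_raw / st$truth$sd_m_raw)
  expect_lt(r$p, 0.05)
})

test_that("2SLS degenerate cases error cleanly", {
  fx <- oracle_fixture()
  expect_error(two_stage_least_squares(rep(1, 50), rnorm(50), rnorm(50)),
               "instrument")
  expect_error(multivariable_2sls(fx$g, fx$g, rnorm(50), rnorm(50)), "collinear")
})

test_that("multivariable 2SLS pools independent instruments", {
  set.seed(61)
  n <- 3000
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.3)
  x <- 0.5 * g1 + 0.4 * g2 + rnorm(n)
  y <- 0.4 * x + rnorm(n)
  both <- multivariable_2sls(g1, g2, x, y)
  one <- two_stage_least_squares(g1, x, y)
  expect_identical(both$method, "MV2SLS")
  expect_identical(both$n_instruments, 2L)
  expect_lt(abs(both$beta - 0.4), 3 * both$se)
  expect_lt(both$se, one$se)
  # an irrelevant second instrument leaves the estimate near the single-IV one
  g_null <- rbinom(n, 2, 0.3)
  two <- multivariable_2sls(g1, g_null, x, y)
  expect_lt(abs(two$beta - one$beta), 2 * one$se)
})

test_that("IVW pooling matches hand-computed weights and is order-invariant", {
  one <- ivw(data.frame(beta = 0.5, se = 0.1))
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)
  expect_identical(one$method, "WALD")
  eq <- ivw(data.frame(beta = c(0.5, 0.5), se = c(0.1, 0.1)))
  expect_equal(eq$beta, 0.5)
  expect_equal(eq$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # weights 100 and 25: (0.4*100 + 0.8*25) / 125 = 0.48, se = 1/sqrt(125)
  mix <- ivw(data.frame(beta = c(0.4, 0.8), se = c(0.1, 0.2)))
  expect_equal(mix$beta, 0.48, tolerance = 1e-12)
  expect_equal(mix$se, 0.0894, tolerance = 1e-3)
  rev_order <- ivw(data.frame(beta = c(0.8, 0.4), se = c(0.2, 0.1)))
  expect_equal(rev_order$beta, mix$beta)
  expect_error(ivw(data.frame(beta = numeric(), se = numeric())), "no ratios")
})

test_that("rescaling exposure effects rescales causal estimates inversely", {
  k <- 2.5
  base <- wald_ratio(0.5, 0.05, 0.2, 0.04)
  scaled <- wald_ratio(0.5 * k, 0.05 * k, 0.2, 0.04)
  expect_equal(scaled$beta, base$beta / k, tolerance = 1e-12)
})

test_that("harmonization flips swapped alleles, uses proxies, drops ambiguity", {
  expo <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "A", "C", "A"),
                     other_allele = c("G", "T", "G", "G"),
                     eaf = c(0.3, 0.49, 0.2, 0.3),
                     beta = c(0.5, 0.4, 0.3, 0.2), se = 0.05)
  outc <- data.frame(snp_id = c("rs1", "rs2", "rs3x"),
                     effect_allele = c("G", "A", "T"),
                     other_allele = c("A", "T", "C"),
                     eaf = c(0.7, 0.49, 0.2),
                     beta = c(0.25, 0.1, 0.15), se = 0.04)
  lk <- data.frame(snp_id = "rs3", proxy_id = "rs3x", r2 = 0.85)
  expect_message(h <- harmonize(expo, outc, ld_lookup = lk), "dropped")
  # rs1: swapped alleles -> outcome beta negated
  expect_equal(h$beta_outcome[h$snp_id == "rs1"], -0.25)
  # rs2: palindromic A/T with MAF 0.49 -> dropped
  expect_false("rs2" %in% h$snp_id)
  # rs3: proxy used with its r2 recorded
  expect_equal(h$proxy_id[h$snp_id == "rs3"], "rs3x")
  expect_equal(h$proxy_r2[h$snp_id == "rs3"], 0.85)
  # rs4: no match, no proxy -> dropped and reported
  drops <- attr(h, "dropped")
  expect_true("rs4" %in% drops$snp_id)
  expect_match(drops$reason[drops$snp_id == "rs2"], "palindromic")
})

test_that("reverse MR detects a simulated trait-to-methylation effect", {
  make_stats <- function(seed, c_effect) {
    set.seed(seed)
    k <- 20
    bx <- runif(k, 0.1, 0.3)                 # trait GWAS effects
    sex <- rep(0.02, k)
    by <- c_effect * bx + rnorm(k, 0, 0.03)  # SNP effects on the CpG
    sey <- rep(0.03, k)
    list(
      expo = data.frame(snp_id = paste0("t", 1:k), effect_allele = "A",
                        other_allele = "G", eaf = 0.3, beta = bx, se = sex),
      outc = data.frame(snp_id = paste0("t", 1:k), effect_allele = "A",
                        other_allele = "G", eaf = 0.3, beta = by, se = sey)
    )
  }
  hits <- vapply(1:20, function(s) {
    st <- make_stats(s, c_effect = 0.4)
    reverse_mr(st$expo, st$outc)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # null case: verdicts mostly "unlikely"
  nulls <- vapply(1:20, function(s) {
    st <- make_stats(100 + s, c_effect = 0)
    reverse_mr(st$expo, st$outc)$verdict
  }, character(1))
  expect_gte(mean(nulls == "explanation 2 unlikely"), 0.8)
  # no surviving instruments -> inconclusive, not an error
  empty <- suppressMessages(reverse_mr(
    data.frame(snp_id = "a", effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = 0.2, se = 0.02),
    data.frame(snp_id = "b", effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = 0.1, se = 0.02)))
  expect_identical(empty$verdict, "inconclusive")
  expect_true(is.na(empty$beta))
})
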
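test_that("region construction respects the r2 boundary and ordering", {
  r2 <- c(s = 1, a = 0.95, b = 0.8, c = 0.79, d = 0.2)
  pos <- c(s = 50, a = 10, b = 90, c = 60, d = 70)
  reg <- build_region("s", r2, r2_min = 0.8, positions = pos)
  expect_setequal(reg, c("s", "a", "b"))     # 0.8 boundary included
  expect_identical(reg, c("a", "s", "b"))    # ordered by position
  expect_identical(build_region("s", c(s = 1, x = 0.1)), "s")
  expect_error(build_region("zz", r2), "absent")
  r2_many <- setNames(c(1, runif(59, 0, 0.79)), paste0("v", 1:60))
  r2_many[2:6] <- 0.9
  expect_length(build_region("v1", r2_many), 6L)
})

test_that("the approximate Bayes factor matches its closed form and limits", {
  # hand evaluation: z = 6, shrinkage 0.04/0.0425
  expect_equal(abf(0.3, 0.05, 0.04),
               0.5 * log(0.0025 / 0.0425) + 0.5 * 36 * 0.04 / 0.0425)
  expect_equal(abf(0.3, 0.05, 0.04), 15.5246, tolerance = 1e-3)
  # null data favour H0
  expect_lt(abf(0, 0.1, 0.04), 0)
  # degenerate prior carries no evidence
  expect_equal(abf(0.3, 0.05, 1e-12), 0, tolerance = 1e-6)
  # monotone in |z| at fixed se
  z <- seq(0, 8, by = 0.5)
  expect_true(all(diff(abf(z * 0.05, 0.05, 0.04)) > 0))
  expect_error(abf(0.1, 0, 0.04), "positive")
  expect_error(abf(0.1, 0.05, -1), "positive")
})

test_that("the closed-form ABF agrees with numerical integration to 1e-6", {
  set.seed(31)
  for (i in 1:20) {
    beta <- runif(1, -0.6, 0.6)
    se <- runif(1, 0.02, 0.3)
    W <- runif(1, 0.005, 0.2)
    marg <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sqrt(W)),
                      -Inf, Inf, rel.tol = 1e-12)$value
    oracle <- log(marg) - dnorm(beta, 0, se, log = TRUE)
    expect_equal(abf(beta, se, W), oracle, tolerance = 1e-6)
  }
})

test_that("single-variant posteriors behave as a softmax", {
  expect_equal(single_variant_posteriors(rep(2, 5)), rep(0.2, 5))
  dom <- single_variant_posteriors(c(25, 5, 5))
  expect_gt(dom[1], 0.999)
  expect_equal(single_variant_posteriors(3.7), 1)
  lb <- c(1.2, -0.5, 7, 3)
  p <- single_variant_posteriors(lb)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  perm <- c(3, 1, 4, 2)
  expect_equal(single_variant_posteriors(lb[perm]), p[perm])
  expect_error(single_variant_posteriors(numeric()), "empty")
})

test_that("the K posterior matches a direct multivariate-normal oracle", {
  # small region where the joint Bayes factors can be computed directly from
  # MVN densities, independently of the package's rank-update algebra
  g <- simulate_genotypes(3000, 4, 0.3, ld_rho = 0.85, seed = 91)
  R <- cor(g$dosage)
  z <- c(7.2, 5.1, 1.0, -0.4)
  Wz <- 150
  ldmvn <- function(x, S) {
    ch <- chol(S)
    -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, x, transpose = TRUE)^2))
  }
  null_ld <- ldmvn(z, R)
  bf_set <- function(C) {
    Rc <- R[, C, drop = FALSE]
    ldmvn(z, R + Wz * Rc %*% t(Rc)) - null_ld
  }
  lbf1 <- vapply(1:4, bf_set, numeric(1))
  pairs <- combn(4, 2)
  lbf2 <- vapply(seq_len(ncol(pairs)), function(k) bf_set(pairs[, k]), numeric(1))
  lse <- function(x) max(x) + log(sum(exp(x - max(x))))
  ml <- c(lse(lbf1) - log(4), lse(lbf2) - log(6))
  oracle_post <- exp(ml - max(ml)) / sum(exp(ml - max(ml)))

  got <- k_causal_posterior(z, R, prior_var_z = Wz)
  expect_equal(unname(got$posterior), oracle_post, tolerance = 1e-8)
})

test_that("the K posterior recovers the generative number of causal variants", {
  # vanishing prior effect variance is the no-information limit: the prior
  # is returned unchanged
  R <- diag(4)
  flat <- k_causal_posterior(rep(0, 4), R, prior_k = c(0.3, 0.7), prior_var_z = 1e-12)
  expect_equal(unname(flat$posterior), c(0.3, 0.7), tolerance = 1e-9)
  # with flat z and an informative prior the Occam penalty favours fewer
  # causal variants relative to the prior
  occam <- k_causal_posterior(rep(0, 4), R, prior_k = c(0.3, 0.7), prior_var_z = 100)
  expect_gt(occam$posterior[["1"]], 0.3)
  # two strong independent signals
  two <- k_causal_posterior(c(9, 9, 0.2, -0.1), diag(4), prior_var_z = 100)
  expect_gt(two$posterior[["2"]], 0.9)
  # one causal variant with LD-propagated z profile
  Rar <- 0.9^abs(outer(1:6, 1:6, "-"))
  z1 <- 9 * Rar[, 3]
  one <- k_causal_posterior(z1, Rar, prior_var_z = 100)
  expect_gt(one$posterior[["1"]], 0.7)
})

test_that("bivariate fine mapping and concordance handle agreement and boundaries", {
  m <- 60
  ids <- sprintf("v%02d", 1:m)
  z_m <- c(10, 9.2, 8.8, seq(8, 1, length.out = m - 3))
  # same top variant in both sets: rate 1/60, concordant
  rfm <- finemap_region("v01", ids, beta_meth = z_m, se_meth = rep(1, m),
                        beta_trait = z_m * 0.8, se_trait = rep(1, m))
  expect_equal(sum(rfm$variants$posterior_meth), 1, tolerance = 1e-9)
  expect_equal(sum(rfm$variants$posterior_trait), 1, tolerance = 1e-9)
  cc <- concordance(rfm)
  expect_identical(cc$top_meth_variant, "v01")
  expect_equal(cc$concordance_rate, 1 / 60)
  expect_identical(cc$verdict, "concordant")
  # top methylation variant ranks 3rd for the trait: rate exactly 0.05 is
  # discordant under the strict inequality
  z_t <- z_m
  z_t[1] <- 8.5
  z_t[2] <- 10
  z_t[3] <- 9.0
  rfm2 <- finemap_region("v01", ids, beta_meth = z_m, se_meth = rep(1, m),
                         beta_trait = z_t, se_trait = rep(1, m))
  cc2 <- concordance(rfm2)
  expect_identical(cc2$rank_of_top_meth_in_trait_ranking, 3L)
  expect_equal(cc2$concordance_rate, 0.05)
  expect_identical(cc2$verdict, "discordant")
  # small regions can never be concordant even with perfect agreement
  rfm3 <- finemap_region("w1", sprintf("w%d", 1:10),
                         beta_meth = c(9, rep(2, 9)), se_meth = rep(1, 10),
                         beta_trait = c(9, rep(2, 9)), se_trait = rep(1, 10))
  cc3 <- concordance(rfm3)
  expect_equal(cc3$concordance_rate, 0.1)
  expect_identical(cc3$verdict, "discordant")
})

test_that("Bayes-factor ties are broken deterministically and logged", {
  ids <- c("a", "b", "c")
  rfm <- finemap_region("a", ids, beta_meth = c(5, 5, 1), se_meth = rep(1, 3),
                        beta_trait = c(5, 5, 1), se_trait = rep(1, 3),
                        positions = c(a = 10, b = 2, c = 5))
  expect_message(cc <- concordance(rfm), "tie")
  # equal BF and |z|: smaller position wins
  expect_identical(cc$top_meth_variant, "b")
})

test_that("posterior vectors permute with the variant order", {
  ids <- sprintf("p%d", 1:5)
  bm <- c(4, 3, 2, 1, 0.5)
  rfm <- finemap_region("p1", ids, bm, rep(1, 5), bm * 0.5, rep(1, 5))
  perm <- c(3, 5, 1, 2, 4)
  rfm_p <- finemap_region("p1", ids[perm], bm[perm], rep(1, 5),
                          (bm * 0.5)[perm], rep(1, 5))
  expect_equal(rfm_p$variants$posterior_meth,
               rfm$variants$posterior_meth[perm])
})
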
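#' Build the high-LD region around a sentinel variant
#'
#' Returns the sentinel plus every variant with `r^2 >= r2_min` against it
#' (boundary included), ordered by position when positions are supplied and
#' by input order otherwise.
#'
#' @param sentinel sentinel variant id.
#' @param ld_r2_row named vector of r-squared values between the sentinel
#'   and candidate variants (the sentinel's own entry may be present or
#'   absent).
#' @param r2_min inclusion threshold (default 0.8).
#' @param positions optional named positions used for ordering.
#' @return Character vector of variant ids including the sentinel.
#' @export
build_region <- function(sentinel, ld_r2_row, r2_min = 0.8, positions = NULL) {
  if (is.null(names(ld_r2_row))) stop_domain("ld_r2_row must be named")
  if (!sentinel %in% names(ld_r2_row)) stop_domain("sentinel absent from LD data")
  ids <- union(sentinel, names(ld_r2_row)[!is.na(ld_r2_row) & ld_r2_row >= r2_min])
  if (!is.null(positions)) ids <- ids[order(positions[ids])]
  ids
}

#' Approximate Bayes factor for a single-variant association
#'
#' Wakefield's closed-form log Bayes factor comparing H1 (true effect drawn
#' from `N(0, prior_var_W)`) to H0 (no effect), given an estimated effect
#' and standard error:
#' \deqn{\log BF = \tfrac12 \log\frac{se^2}{se^2 + W} +
#'       \tfrac12 z^2 \frac{W}{se^2 + W}, \quad z = \beta / se.}
#' Monotone increasing in `|z|` at fixed `se`; tends to 0 as `W -> 0`.
#'
#' @param beta estimated effect(s).
#' @param se standard error(s), positive.
#' @param prior_var_W prior variance of the true effect (default 0.04, i.e.
#'   prior SD 0.2 on standardized effects).
#' @return log Bayes factor(s), natural log.
#' @export
abf <- function(beta, se, prior_var_W = 0.04) {
  if (any(se <= 0) || any(prior_var_W <= 0)) stop_domain("se and prior_var_W must be positive")
  z <- beta / se
  0.5 * log(se^2 / (se^2 + prior_var_W)) + 0.5 * z^2 * prior_var_W / (se^2 + prior_var_W)
}

#' Posterior probabilities under a single-causal-variant model
#'
#' Softmax of the per-variant log Bayes factors under a uniform causal
#' prior, computed with max-subtraction for numerical stability.
#'
#' @param log_bfs finite log Bayes factors, at least one.
#' @return Posterior vector summing to 1.
#' @export
single_variant_posteriors <- function(log_bfs) {
  if (length(log_bfs) == 0) stop_domain("empty Bayes-factor vector")
  w <- exp(log_bfs - max(log_bfs))
  w / sum(w)
}

# log Bayes factor for a causal set C against the null, from z-scores and
# the LD matrix R. Under z ~ N(R lambda, R) with lambda_C ~ N(0, Wz I):
#   z ~ N(0, R + Wz R_C R_C') under H_C, and the determinant/Woodbury
# identities collapse everything onto the |C| x |C| blocks:
#   log BF = -1/2 log det(I + Wz R_CC) + Wz/2 z_C' (I + Wz R_CC)^{-1} z_C.
set_log_bf <- function(z, R, C, Wz, ridge = 1e-4) {
  Rcc <- R[C, C, drop = FALSE]
  A <- diag(length(C)) + Wz * Rcc
  sol <- tryCatch(solve(A, z[C]), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    A <- diag(length(C)) + Wz * (Rcc + diag(ridge, length(C)))
    sol <- solve(A, z[C])
    message("near-singular LD for set {", paste(C, collapse = ","),
            "}; ridge fallback applied")
  }
  -0.5 * determinant(A, logarithm = TRUE)$modulus[1] + 0.5 * Wz * sum(z[C] * sol)
}

#' Posterior over the number of causal variants (K = 1 vs K = 2)
#'
#' Evaluates the marginal likelihood of one versus two causal variants in a
#' region by exhaustive enumeration: the K = 1 likelihood averages
#' single-variant Bayes factors and the K = 2 likelihood averages joint
#' Bayes factors over all pairs, using the multivariate-normal z likelihood
#' with LD-induced covariance. Singular pair submatrices fall back to a
#' small ridge (1e-4 on the diagonal) with a logged note. As
#' `prior_var_z -> 0` every Bayes factor tends to 1 and the posterior
#' returns the prior; with informative `prior_var_z` and flat z the Occam
#' penalty of the marginal likelihood favours fewer causal variants.
#'
#' @param z_vector per-variant z-scores.
#' @param ld_matrix square dosage correlation matrix (r, not r-squared).
#' @param prior_k prior over K in `{1, 2}` (default uniform).
#' @param prior_var_z prior variance of the causal non-centrality on the
#'   z scale; roughly `W * n` for prior effect variance `W` on standardized
#'   effects at sample size `n` (default 200, i.e. `0.04 * 5000`).
#' @return list with `posterior` (named probabilities for K = 1, 2 summing
#'   to 1) and the log marginal likelihoods `log_ml`.
#' @export
k_causal_posterior <- function(z_vector, ld_matrix, prior_k = c(0.5, 0.5),
                               prior_var_z = 200) {
  m <- length(z_vector)
  stopifnot(m >= 2, all(dim(ld_matrix) == m), length(prior_k) == 2)
  if (m > 500) stop_domain("region too large for exhaustive enumeration (m > 500)")
  prior_k <- prior_k / sum(prior_k)
  lbf1 <- vapply(seq_len(m), function(i) set_log_bf(z_vector, ld_matrix, i, prior_var_z),
                 numeric(1))
  pairs <- utils::combn(m, 2)
  lbf2 <- vapply(seq_len(ncol(pairs)), function(k) {
    set_log_bf(z_vector, ld_matrix, pairs[, k], prior_var_z)
  }, numeric(1))
  lse <- function(x) max(x) + log(sum(exp(x - max(x))))
  log_ml <- c(`1` = lse(lbf1) - log(m), `2` = lse(lbf2) - log(ncol(pairs)))
  lp <- log(prior_k) + log_ml
  post <- exp(lp - max(lp))
  list(posterior = setNames(post / sum(post), c("1", "2")), log_ml = log_ml)
}

#' Bivariate fine mapping of a sentinel region
#'
#' Computes per-variant approximate Bayes factors and single-causal-variant
#' posteriors for two effect sets over the same variants — SNP effects on
#' methylation and SNP effects on the trait — plus a posterior over the
#' number of causal variants for each set.
#'
#' @param sentinel_id sentinel variant id (must be among `variant_ids`).
#' @param variant_ids region variant ids (from [build_region()]).
#' @param beta_meth,se_meth,beta_trait,se_trait per-variant effects and SEs
#'   for the two sets, in `variant_ids` order.
#' @param ld_matrix dosage correlation matrix (r) over `variant_ids`; used
#'   for the K posterior.
#' @param prior_var_W Wakefield prior effect variance (default 0.04).
#' @param prior_var_z z-scale prior variance for the K posterior; default
#'   derives `prior_var_W / median(se)^2` per effect set.
#' @param positions optional named positions for deterministic tie-breaks.
#' @return A `region_finemap` object: variant table with z-scores, log BFs
#'   and posteriors for both sets, plus `k_posterior_meth` and
#'   `k_posterior_trait`.
#' @export
finemap_region <- function(sentinel_id, variant_ids, beta_meth, se_meth,
                           beta_trait, se_trait, ld_matrix = NULL,
                           prior_var_W = 0.04, prior_var_z = NULL,
                           positions = NULL) {
  m <- length(variant_ids)
  stopifnot(sentinel_id %in% variant_ids, length(beta_meth) == m,
            length(beta_trait) == m, length(se_meth) == m, length(se_trait) == m)
  lbf_m <- abf(beta_meth, se_meth, prior_var_W)
  lbf_t <- abf(beta_trait, se_trait, prior_var_W)
  tab <- data.frame(
    variant_id = variant_ids,
    z_meth = beta_meth / se_meth, z_trait = beta_trait / se_trait,
    log_bf_meth = lbf_m, log_bf_trait = lbf_t,
    posterior_meth = single_variant_posteriors(lbf_m),
    posterior_trait = single_variant_posteriors(lbf_t),
    pos = if (is.null(positions)) seq_len(m) else unname(positions[variant_ids]),
    stringsAsFactors = FALSE
  )
  kp_m <- kp_t <- NULL
  if (!is.null(ld_matrix) && m >= 2) {
    ld_matrix <- ld_matrix[variant_ids, variant_ids]
    wz_m <- prior_var_z %||% (prior_var_W / stats::median(se_meth)^2)
    wz_t <- prior_var_z %||% (prior_var_W / stats::median(se_trait)^2)
    kp_m <- k_causal_posterior(tab$z_meth, ld_matrix, prior_var_z = wz_m)
    kp_t <- k_causal_posterior(tab$z_trait, ld_matrix, prior_var_z = wz_t)
  }
  structure(list(sentinel_id = sentinel_id, variants = tab,
                 k_posterior_meth = kp_m, k_posterior_trait = kp_t,
                 jlim_p = NA_real_),
            class = "region_finemap")
}

#' @export
print.region_finemap <- function(x, ...) {
  cat(sprintf("region_finemap: sentinel %s, %d variants\n",
              x$sentinel_id, nrow(x$variants)))
  if (!is.null(x$k_posterior_meth)) {
    cat(sprintf("  P(K=1) methylation %.3f, trait %.3f\n",
                x$k_posterior_meth$posterior[["1"]],
                x$k_posterior_trait$posterior[["1"]]))
  }
  invisible(x)
}

# descending BF ranking with deterministic tie-breaks:
# larger log BF, then larger |z|, then smaller position, then id
bf_order <- function(log_bf, z, pos, ids) {
  order(-log_bf, -abs(z), pos, ids)
}

#' Concordance rate between the two fine-mapping rankings
#'
#' Locates the top methylation-BF variant within the descending trait-BF
#' ranking and divides its 1-based rank by the number of region variants.
#' A rate strictly below `alpha` (default 0.05) argues that the methylation
#' and trait signals share a causal variant, making the LD-confounding
#' explanation unlikely (`"concordant"`); otherwise the verdict is
#' `"discordant"`. Ties for the top Bayes factor are broken by larger `|z|`,
#' then smaller position, then id, and logged. Note that regions with fewer
#' than `1/alpha` variants can never be called concordant — the statistic is
#' insensitive in small regions by construction.
#'
#' @param region_fm a `region_finemap` object.
#' @param alpha concordance threshold (default 0.05, strict `<`).
#' @return A `concordance_result` list: `top_meth_variant`,
#'   `top_trait_variant`, `rank_of_top_meth_in_trait_ranking`, `m_variants`,
#'   `concordance_rate`, `verdict`.
#' @export
concordance <- function(region_fm, alpha = 0.05) {
  stopifnot(inherits(region_fm, "region_finemap"))
  v <- region_fm$variants
  m <- nrow(v)
  if (anyDuplicated(round(v$log_bf_meth, 12)) || anyDuplicated(round(v$log_bf_trait, 12))) {
    message("tied Bayes factors broken by |z|, position, id")
  }
  ord_m <- bf_order(v$log_bf_meth, v$z_meth, v$pos, v$variant_id)
  ord_t <- bf_order(v$log_bf_trait, v$z_trait, v$pos, v$variant_id)
  top_m <- v$variant_id[ord_m[1]]
  rank_in_t <- match(top_m, v$variant_id[ord_t])
  rate <- rank_in_t / m
  structure(list(
    top_meth_variant = top_m, top_trait_variant = v$variant_id[ord_t[1]],
    rank_of_top_meth_in_trait_ranking = rank_in_t, m_variants = m,
    concordance_rate = rate,
    verdict = if (rate < alpha) "concordant" else "discordant"
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: top meth %s ranks %d/%d in trait ranking; rate %.4f (%s)\n",
              x$top_meth_variant, x$rank_of_top_meth_in_trait_ranking,
              x$m_variants, x$concordance_rate, x$verdict))
  invisible(x)
}
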
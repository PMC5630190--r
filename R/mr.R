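mr_result <- function(exposure_id, outcome_id, method, beta, se, p,
                      instrument_ids, extra = list()) {
  structure(c(list(exposure_id = exposure_id, outcome_id = outcome_id,
                   method = method, beta = beta, se = se, p = p,
                   n_instruments = length(instrument_ids),
                   instrument_ids = instrument_ids), extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR [%s] %s -> %s: beta %.4f (SE %.4f), p %.3g, %d instrument(s)\n",
              x$method, x$exposure_id, x$outcome_id, x$beta, x$se, x$p,
              x$n_instruments))
  invisible(x)
}

#' One-sample Mendelian randomization by two-stage least squares
#'
#' Stage 1 regresses the exposure on the instrument dosage(s) and
#' covariates; stage 2 regresses the outcome on the fitted exposure and
#' covariates. Standard errors use the 2SLS residual convention: stage-2
#' coefficients are applied to the *observed* exposure when forming
#' residuals (the naive OLS-on-fitted SE is anticonservative). With a single
#' instrument the point estimate equals the ratio of the two reduced-form
#' OLS slopes. Per-instrument first-stage F statistics are attached as the
#' `"first_stage_F"` attribute; weak instruments (F < 10) are logged but not
#' dropped.
#'
#' @param G instrument dosage vector or samples-x-instruments matrix.
#' @param X exposure vector.
#' @param Y outcome vector.
#' @param covariates optional data frame of covariates.
#' @param exposure_id,outcome_id labels carried into the result.
#' @return An `mr_result` with method `"2SLS"` (or `"MV2SLS"` for two or
#'   more instruments); p from the t distribution.
#' @export
two_stage_least_squares <- function(G, X, Y, covariates = NULL,
                                    exposure_id = "exposure", outcome_id = "outcome") {
  G <- as.matrix(G)
  n <- nrow(G)
  stopifnot(length(X) == n, length(Y) == n)
  if (n < 50) warning("fewer than 50 shared samples; estimates may be unstable", call. = FALSE)
  if (qr(G)$rank < ncol(G)) stop_domain("instruments are perfectly collinear")
  cv <- covariate_design(covariates)
  C <- cbind(rep(1, n), cv)

  qc <- qr(C)
  Gr <- qr.resid(qc, G)
  Xr <- qr.resid(qc, X)
  Yr <- qr.resid(qc, Y)
  if (all(apply(as.matrix(Gr), 2, sd) < 1e-10)) {
    stop_domain("weak/absent instrument: no dosage variation beyond covariates")
  }

  # first-stage F per instrument (exposure on that instrument, given covariates)
  Fs <- apply(as.matrix(Gr), 2, function(g) {
    sgg <- sum(g^2)
    b <- sum(g * Xr) / sgg
    rss <- sum((Xr - b * g)^2)
    df <- n - ncol(C) - 1L
    (b^2 * sgg) / (rss / df)
  })
  if (any(Fs < 10)) {
    message("weak instrument(s): first-stage F ", paste(round(Fs, 2), collapse = ", "))
  }

  q1 <- qr(Gr)
  Xhat <- qr.fitted(q1, Xr)
  if (sd(Xhat) < 1e-12) stop_domain("weak/absent instrument: fitted exposure is constant")
  b2 <- sum(Xhat * Yr) / sum(Xhat^2)
  # residuals against the observed exposure
  resid <- Yr - b2 * Xr
  k <- ncol(C) + 1L
  sigma2 <- sum(resid^2) / (n - k)
  se <- sqrt(sigma2 / sum(Xhat^2))
  tstat <- b2 / se
  ids <- colnames(G) %||% sprintf("iv%d", seq_len(ncol(G)))
  res <- mr_result(exposure_id, outcome_id,
                   if (ncol(G) >= 2) "MV2SLS" else "2SLS",
                   b2, se, 2 * pt(-abs(tstat), n - k), ids)
  attr(res, "first_stage_F") <- Fs
  res
}

#' Two-stage least squares with two instrument sets jointly
#'
#' Convenience wrapper fitting both instruments in a joint first stage; used
#' when a CpG site carries two pairwise-independent mQTLs. Reduces to
#' [two_stage_least_squares()] behaviour when one column is supplied;
#' perfectly collinear instruments are an error.
#'
#' @param G1,G2 instrument dosage vectors (or matrices).
#' @inheritParams two_stage_least_squares
#' @return An `mr_result` with method `"MV2SLS"`.
#' @export
multivariable_2sls <- function(G1, G2, X, Y, covariates = NULL,
                               exposure_id = "exposure", outcome_id = "outcome") {
  G <- cbind(G1, G2)
  if (is.null(colnames(G))) colnames(G) <- sprintf("iv%d", seq_len(ncol(G)))
  two_stage_least_squares(G, X, Y, covariates, exposure_id, outcome_id)
}

#' Wald ratio with full delta-method standard error
#'
#' Single-instrument two-sample MR estimator: the SNP-outcome effect divided
#' by the SNP-exposure effect, with standard error
#' \deqn{\sqrt{se_{GY}^2 / \beta_{GX}^2 +
#'       \beta_{GY}^2 \, se_{GX}^2 / \beta_{GX}^4}.}
#' Both delta terms are kept: dropping the exposure-uncertainty term
#' understates the SE noticeably when the instrument's effect on the
#' exposure is imprecise. The p-value is two-sided from the standard normal,
#' the usual convention for consortium-scale summary statistics.
#'
#' @param beta_gx,se_gx SNP-exposure effect and SE (`beta_gx != 0`,
#'   `se_gx >= 0`).
#' @param beta_gy,se_gy SNP-outcome effect and SE (`se_gy > 0`).
#' @return list with `beta`, `se`, `p` (vectorized over inputs).
#' @examples
#' wald_ratio(0.982, 0.103, -0.629, 0.143)  # beta -0.641, se 0.160
#' @export
wald_ratio <- function(beta_gx, se_gx, beta_gy, se_gy) {
  if (any(beta_gx == 0)) stop_domain("beta_gx must be nonzero")
  if (any(se_gx < 0) || any(se_gy <= 0)) stop_domain("standard errors must be positive")
  beta <- beta_gy / beta_gx
  se <- sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

is_palindromic <- function(a1, a2) {
  paste0(toupper(a1), toupper(a2)) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches exposure records to outcome records by SNP id, substituting the
#' best LD proxy with `r^2 > 0.8` when the sentinel itself is absent from
#' the outcome set. Outcome effects are flipped in sign when the effect and
#' other alleles are swapped relative to the exposure record; pairs whose
#' alleles cannot be reconciled are dropped. Palindromic (A/T or C/G)
#' variants with minor allele frequency in `(maf_ambiguous, 0.5]` are
#' dropped because strand cannot be resolved. Dropped pairs are reported in
#' the `"dropped"` attribute with a reason.
#'
#' @param exposure_stats,outcome_stats data frames with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, and optionally `eaf`.
#' @param ld_lookup optional proxy table with columns `snp_id`, `proxy_id`,
#'   `r2`.
#' @param maf_ambiguous palindromic ambiguity cutoff (default 0.42).
#' @return data frame of harmonized pairs: `snp_id`, `proxy_id`, `proxy_r2`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `palindromic`.
#' @export
harmonize <- function(exposure_stats, outcome_stats, ld_lookup = NULL,
                      maf_ambiguous = 0.42) {
  req <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  stopifnot(all(req %in% names(exposure_stats)), all(req %in% names(outcome_stats)))
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(exposure_stats))) {
    ex <- exposure_stats[i, ]
    proxy_id <- ex$snp_id
    proxy_r2 <- 1.0
    j <- match(ex$snp_id, outcome_stats$snp_id)
    if (is.na(j) && !is.null(ld_lookup)) {
      cand <- ld_lookup[ld_lookup$snp_id == ex$snp_id & ld_lookup$r2 > 0.8 &
                          ld_lookup$proxy_id %in% outcome_stats$snp_id, , drop = FALSE]
      if (nrow(cand)) {
        cand <- cand[order(-cand$r2, cand$proxy_id), , drop = FALSE]
        proxy_id <- cand$proxy_id[1]
        proxy_r2 <- cand$r2[1]
        j <- match(proxy_id, outcome_stats$snp_id)
      }
    }
    if (is.na(j)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        snp_id = ex$snp_id, reason = "no match or proxy with r2 > 0.8")
      next
    }
    ou <- outcome_stats[j, ]
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    maf <- min(ex$eaf %||% NA_real_, 1 - (ex$eaf %||% NA_real_))
    if (pal && !is.na(maf) && maf > maf_ambiguous) {
      dropped[[length(dropped) + 1]] <- data.frame(
        snp_id = ex$snp_id, reason = sprintf("palindromic with ambiguous MAF %.2f", maf))
      next
    }
    same <- toupper(ou$effect_allele) == toupper(ex$effect_allele) &&
      toupper(ou$other_allele) == toupper(ex$other_allele)
    swapped <- toupper(ou$effect_allele) == toupper(ex$other_allele) &&
      toupper(ou$other_allele) == toupper(ex$effect_allele)
    if (proxy_id != ex$snp_id) {
      # proxy alleles are not comparable across loci; align by sign of r
      same <- TRUE
      swapped <- FALSE
    }
    if (!same && !swapped) {
      dropped[[length(dropped) + 1]] <- data.frame(
        snp_id = ex$snp_id, reason = "allele mismatch")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = ex$snp_id, proxy_id = proxy_id, proxy_r2 = proxy_r2,
      beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = if (swapped) -ou$beta else ou$beta, se_outcome = ou$se,
      palindromic = pal, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    snp_id = character(), proxy_id = character(), proxy_r2 = numeric(),
    beta_exposure = numeric(), se_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(), palindromic = logical())
  drop_df <- if (length(dropped)) do.call(rbind, dropped) else NULL
  if (!is.null(drop_df)) {
    message(nrow(drop_df), " pair(s) dropped during harmonization")
  }
  attr(out, "dropped") <- drop_df
  out
}

#' Fixed-effect inverse-variance-weighted combination of Wald ratios
#'
#' Pools per-SNP Wald ratios with weights `1 / se^2`. With one ratio the
#' output is identical to that ratio. Invariant to instrument ordering.
#'
#' @param ratios data frame (or list) with components `beta` and `se`, e.g.
#'   from applying [wald_ratio()] per harmonized pair.
#' @param exposure_id,outcome_id,instrument_ids labels for the result.
#' @return An `mr_result` with method `"IVW"` (or `"WALD"` for a single
#'   instrument); p from the standard normal.
#' @export
ivw <- function(ratios, exposure_id = "exposure", outcome_id = "outcome",
                instrument_ids = NULL) {
  beta <- ratios$beta
  se <- ratios$se
  if (length(beta) == 0) stop_domain("no ratios to combine")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  mr_result(exposure_id, outcome_id, if (length(beta) == 1) "WALD" else "IVW",
            b, s, 2 * pnorm(-abs(b / s)),
            instrument_ids %||% sprintf("iv%d", seq_along(beta)))
}

#' Reverse Mendelian randomization: does the trait drive methylation?
#'
#' Harmonizes trait GWAS instruments against SNP-methylation summary
#' statistics and combines per-SNP Wald ratios by fixed-effect IVW, with the
#' trait as exposure and CpG methylation as outcome. The verdict flag
#' implements the decision rule: a p-value above `alpha` means the
#' reverse-causation explanation is unlikely. When every instrument is lost
#' in harmonization the verdict is `"inconclusive"` rather than an error.
#' Instruments inside the sentinel's cis window must be excluded upstream.
#'
#' @param trait_instruments exposure summary statistics (trait GWAS).
#' @param cpg_outcome_stats outcome summary statistics (SNP effects on the
#'   CpG).
#' @param ld_lookup optional proxy table, see [harmonize()].
#' @param alpha verdict threshold (default 0.05).
#' @return An `mr_result` with an added `verdict` field:
#'   `"explanation 2 unlikely"`, `"reverse causation plausible"`, or
#'   `"inconclusive"` (with `NA` estimates) when no instruments survive.
#' @export
reverse_mr <- function(trait_instruments, cpg_outcome_stats, ld_lookup = NULL,
                       alpha = 0.05) {
  h <- harmonize(trait_instruments, cpg_outcome_stats, ld_lookup)
  if (nrow(h) == 0) {
    res <- mr_result("trait", "cpg", "IVW", NA_real_, NA_real_, NA_real_,
                     character(0))
    res$verdict <- "inconclusive"
    return(res)
  }
  wr <- wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome)
  res <- ivw(wr, exposure_id = "trait", outcome_id = "cpg",
             instrument_ids = h$snp_id)
  res$verdict <- if (res$p > alpha) "explanation 2 unlikely" else "reverse causation plausible"
  res
}
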
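#' Bonferroni threshold for the mQTL-by-trait scan
#'
#' @param n_variants,n_traits positive test-grid dimensions.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold` (`alpha / (n_variants * n_traits)`, full
#'   precision) and `n_tests`.
#' @examples
#' bonferroni_threshold(37812, 14)  # 529368 tests, 9.45e-8
#' @export
bonferroni_threshold <- function(n_variants, n_traits, alpha = 0.05) {
  if (n_variants < 1 || n_traits < 1) stop_domain("test counts must be positive")
  n_tests <- as.numeric(n_variants) * as.numeric(n_traits)
  list(threshold = alpha / n_tests, n_tests = n_tests)
}

#' mQTL-wide association scan against traits
#'
#' Regresses each trait on each variant's dosage with covariate adjustment
#' (age and sex by default) and an intercept, per pair on complete cases.
#' Two-sided p-values come from the t distribution; `variance_explained` is
#' the partial R-squared of the dosage term (the fraction of
#' covariate-adjusted trait variance explained), or the full-model
#' delta-R-squared when `r2_type = "delta"`. Monomorphic variants and pairs
#' with fewer than `min_n` complete cases are skipped with a message.
#'
#' @param genotypes a `genotype_matrix` or a samples-x-variants dosage
#'   matrix.
#' @param traits data frame (or named list) of numeric trait vectors,
#'   already rank-normalized or standardized.
#' @param covariates data frame of per-sample covariates (default `NULL`).
#' @param r2_type `"partial"` or `"delta"`.
#' @param min_n minimum complete-case count per pair (default 30).
#' @return data frame with one row per (variant, trait): `snp_id`, `trait`,
#'   `n`, `beta` (SD trait per allele when traits are standardized), `se`,
#'   `p`, `variance_explained`.
#' @export
run_mwas <- function(genotypes, traits, covariates = NULL,
                     r2_type = c("partial", "delta"), min_n = 30) {
  r2_type <- match.arg(r2_type)
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  traits <- as.data.frame(traits)
  cv <- covariate_design(covariates)
  skipped <- 0L

  # fast path: no missing data anywhere lets the whole scan share one
  # covariate projection and reduce to closed-form simple regressions
  complete <- !anyNA(dos) && !anyNA(as.matrix(traits)) && (is.null(cv) || !anyNA(cv))
  if (complete && nrow(dos) >= min_n) {
    n <- nrow(dos)
    X0 <- cbind(rep(1, n), cv)
    q0 <- qr(X0)
    Gr <- qr.resid(q0, dos)
    sgg <- colSums(Gr^2)
    poly_ok <- apply(dos, 2, var) > 0
    res <- do.call(rbind, lapply(names(traits), function(tr) {
      yr <- qr.resid(q0, traits[[tr]])
      syy <- sum(yr^2)
      slope <- colSums(Gr * yr) / sgg
      df <- n - ncol(X0) - 1L
      rss <- syy - slope^2 * sgg
      se <- sqrt(rss / df / sgg)
      ve <- if (r2_type == "partial") slope^2 * sgg / syy else
        slope^2 * sgg / sum((traits[[tr]] - mean(traits[[tr]]))^2)
      data.frame(snp_id = colnames(dos), trait = tr, n = n, beta = slope,
                 se = se, p = 2 * pt(-abs(slope / se), df),
                 variance_explained = ve, stringsAsFactors = FALSE)[poly_ok, ]
    }))
    if (any(!poly_ok)) {
      message(sum(!poly_ok) * length(traits),
              " (variant, trait) pair(s) skipped (monomorphic or n < ", min_n, ")")
    }
    rownames(res) <- NULL
    return(res)
  }

  out <- vector("list", ncol(dos) * ncol(traits))
  k <- 0L
  for (tr in names(traits)) {
    y_all <- traits[[tr]]
    for (j in seq_len(ncol(dos))) {
      g_all <- dos[, j]
      cc <- complete.cases(g_all, y_all, if (is.null(cv)) rep(0, length(y_all)) else cv)
      n <- sum(cc)
      if (n < min_n || var(g_all[cc]) == 0) {
        skipped <- skipped + 1L
        next
      }
      y <- y_all[cc]
      g <- g_all[cc]
      X0 <- cbind(rep(1, n), if (is.null(cv)) NULL else cv[cc, , drop = FALSE])
      q0 <- qr(X0)
      yr <- qr.resid(q0, y)
      gr <- qr.resid(q0, g)
      sgg <- sum(gr^2)
      slope <- sum(gr * yr) / sgg
      df <- n - ncol(X0) - 1L
      rss <- sum((yr - slope * gr)^2)
      se <- sqrt(rss / df / sgg)
      tstat <- slope / se
      ve <- if (r2_type == "partial") {
        slope^2 * sgg / sum(yr^2)
      } else {
        slope^2 * sgg / sum((y - mean(y))^2)
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        snp_id = colnames(dos)[j], trait = tr, n = n, beta = slope, se = se,
        p = 2 * pt(-abs(tstat), df), variance_explained = ve,
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0) {
    message(skipped, " (variant, trait) pair(s) skipped (monomorphic or n < ", min_n, ")")
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res)) {
    res <- data.frame(snp_id = character(), trait = character(), n = integer(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      variance_explained = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Plot-ready Manhattan table
#'
#' Joins scan results to variant coordinates and returns a table sorted by
#' chromosome and position with `-log10(p)` and a pass flag at the
#' study-wide threshold. The flag uses a strict inequality: a p-value equal
#' to the threshold fails.
#'
#' @param results data frame from [run_mwas()].
#' @param variant_info data frame with `variant_id`, `chrom`, `pos`.
#' @param threshold study-wide significance threshold.
#' @return data frame with `snp_id`, `trait`, `chrom`, `pos`, `neg_log10_p`,
#'   `pass`.
#' @export
manhattan_table <- function(results, variant_info, threshold) {
  stopifnot(nrow(results) > 0)
  idx <- match(results$snp_id, variant_info$variant_id)
  out <- data.frame(
    snp_id = results$snp_id, trait = results$trait,
    chrom = variant_info$chrom[idx], pos = variant_info$pos[idx],
    neg_log10_p = -log10(results$p), pass = results$p < threshold,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}
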
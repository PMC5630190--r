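#' Friedewald LDL and companion VLDL cholesterol
#'
#' Computes low-density lipoprotein cholesterol from total cholesterol, HDL
#' cholesterol and triglycerides (all mmol/L) as
#' `LDL = TC - (HDL + 0.45 * TG)`, and VLDL as `TC - (HDL + LDL)`. Records
#' with a negative derived LDL are flagged rather than dropped so callers
#' can exclude them downstream.
#'
#' @param tc,hdl,tg total cholesterol, HDL cholesterol, triglycerides
#'   (mmol/L); vectors of equal length, non-negative.
#' @return data frame with columns `ldl`, `vldl`, `flag_negative_ldl`.
#' @examples
#' friedewald_ldl(5.0, 1.5, 1.0)  # ldl 3.05, vldl 0.45
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tc < 0 | hdl < 0 | tg < 0, na.rm = TRUE)) {
    stop_domain("lipid concentrations must be non-negative")
  }
  ldl <- tc - (hdl + 0.45 * tg)
  vldl <- tc - (hdl + ldl)
  data.frame(ldl = ldl, vldl = vldl, flag_negative_ldl = !is.na(ldl) & ldl < 0)
}

#' Mean of duplicate blood-pressure readings
#'
#' Returns the arithmetic mean of two readings; a single available reading
#' passes through with a warning note, and a record with both readings
#' missing yields `NA`.
#'
#' @param reading1,reading2 numeric vectors of readings (positive mmHg).
#' @return Numeric vector of per-sample means.
#' @export
mean_bp <- function(reading1, reading2) {
  stopifnot(length(reading1) == length(reading2))
  if (any(c(reading1, reading2) <= 0, na.rm = TRUE)) {
    stop_domain("blood-pressure readings must be positive")
  }
  single <- xor(is.na(reading1), is.na(reading2))
  if (any(single)) {
    warning(sprintf("%d record(s) with a single reading passed through unaveraged",
                    sum(single)), call. = FALSE)
  }
  out <- rowMeans(cbind(reading1, reading2), na.rm = TRUE)
  out[is.na(reading1) & is.na(reading2)] <- NA_real_
  out
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles of `(rank - 3/8) / (n + 1/4)` (Blom
#' offset), with ties sharing the average rank and `NA`s preserved. The
#' output has mean approximately 0 and SD approximately 1, preserves rank
#' order, and is invariant to monotone transformations of the input.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return Transformed vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop_domain("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  if (length(unique(values[ok])) == 1) {
    warning("all values identical; returning zeros", call. = FALSE)
    out[ok] <- 0
    return(out)
  }
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residualize a matrix on covariates
#'
#' Replaces each column of `matrix` by its OLS residuals against the
#' covariate design (with intercept). Residuals are numerically orthogonal
#' to every covariate; the operation is idempotent.
#'
#' @param matrix numeric matrix (samples x features) or vector.
#' @param covariates data frame or matrix of covariates, or `NULL` for
#'   intercept-only (mean-centering).
#' @return Residual matrix with the dimensions of the input.
#' @export
residualize <- function(matrix, covariates = NULL) {
  x <- as.matrix(matrix)
  design <- cbind(`(Intercept)` = rep(1, nrow(x)), covariate_design(covariates))
  q <- qr(design)
  if (q$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)), q$pivot[seq_len(q$rank)])]
    stop_domain("covariate design is rank deficient; collinear column(s): ",
                paste(bad, collapse = ", "))
  }
  res <- qr.resid(q, x)
  dimnames(res) <- dimnames(x)
  if (is.null(dim(matrix))) as.numeric(res) else res
}

covariate_design <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(NULL)
  cv <- as.data.frame(covariates)
  cv <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  mm <- do.call(cbind, lapply(names(cv), function(nm) {
    col <- cv[[nm]]
    if (is.numeric(col)) {
      m <- cbind(col)
      colnames(m) <- nm
    } else {
      f <- factor(col)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
    }
    m
  }))
  mm
}

#' Select cis mQTL instruments
#'
#' Retains mQTL records whose SNP and CpG lie on the same chromosome within
#' `window_bp` (1-based coordinates, inclusive distance) at `p < p_max`, and
#' then removes *entirely* any SNP that also carries a significant distal
#' (trans) association: instruments must influence methylation only at a
#' proximal CpG site, since variants acting on distant CpGs are more likely
#' to tag independent biological pathways. Records with missing coordinates
#' are rejected with a logged count.
#'
#' @param records data frame of mQTL summary records with columns `snp_id`,
#'   `cpg_id`, `chrom`, `cpg_chrom`, `pos_snp`, `pos_cpg`, `beta`, `se`, `p`.
#' @param window_bp cis window (default 1 Mb).
#' @param p_max significance threshold defining an mQTL (default 1e-14).
#' @return Subset of `records`; the operation is idempotent.
#' @export
select_cis_mqtls <- function(records, window_bp = 1e6, p_max = 1e-14) {
  req <- c("snp_id", "cpg_id", "chrom", "cpg_chrom", "pos_snp", "pos_cpg", "p")
  stopifnot(all(req %in% names(records)))
  has_coord <- !(is.na(records$chrom) | is.na(records$cpg_chrom) |
                   is.na(records$pos_snp) | is.na(records$pos_cpg))
  if (any(!has_coord)) {
    message(sum(!has_coord), " record(s) rejected for missing coordinates")
  }
  rec <- records[has_coord, , drop = FALSE]
  sig <- rec$p < p_max
  cis <- rec$chrom == rec$cpg_chrom & abs(rec$pos_snp - rec$pos_cpg) <= window_bp
  trans_snps <- unique(rec$snp_id[sig & !cis])
  keep <- sig & cis & !(rec$snp_id %in% trans_snps)
  rec[keep, , drop = FALSE]
}

#' Greedy LD clumping to pairwise-independent sentinels
#'
#' Repeatedly takes the most significant remaining variant as a sentinel and
#' discards every variant with `r^2 >= r2_threshold` against it. The result
#' is a set of sentinels with pairwise `r^2` below the threshold. Ties on p
#' are broken by smaller genomic position, then lexicographic id, making the
#' selection deterministic.
#'
#' @param stats data frame with columns `snp_id`, `p`, and optionally `pos`.
#' @param ld_r2_matrix square r-squared matrix with dimnames covering every
#'   `snp_id`.
#' @param r2_threshold clumping threshold (default 0.1).
#' @return Character vector of sentinel ids (possibly empty).
#' @export
ld_clump <- function(stats, ld_r2_matrix, r2_threshold = 0.1) {
  if (nrow(stats) == 0) return(character(0))
  stopifnot(all(stats$snp_id %in% rownames(ld_r2_matrix)))
  pos <- if ("pos" %in% names(stats)) stats$pos else rep(0, nrow(stats))
  ord <- order(stats$p, pos, stats$snp_id)
  remaining <- stats$snp_id[ord]
  sentinels <- character(0)
  while (length(remaining)) {
    top <- remaining[1]
    sentinels <- c(sentinels, top)
    r2 <- ld_r2_matrix[top, remaining]
    remaining <- remaining[r2 < r2_threshold & remaining != top]
  }
  sentinels
}
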
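#' Genotype correlation implied by a latent haplotype correlation
#'
#' The simulator draws haplotypes by thresholding a correlated standard
#' Gaussian at the allele-frequency quantile, so the correlation between two
#' dosages is an attenuated version of the latent correlation. This function
#' evaluates the mapping: for haplotype carrier indicators
#' \eqn{X = 1\{Z > t\}} with \eqn{t = \Phi^{-1}(1 - \mathrm{maf})} and latent
#' correlation \eqn{\rho}, the indicator (and dosage) correlation is
#' \eqn{(P_{11}(\rho) - p^2) / (p(1-p))} where \eqn{P_{11}} is the upper
#' orthant probability of the bivariate normal.
#'
#' @param rho latent Gaussian correlation in `[0, 1)`.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @return Genotype (dosage) correlation, a scalar in `[0, 1)`.
#' @seealso [latent_rho_for_r2()] for the inverse mapping.
#' @export
genotype_r_from_latent <- function(rho, maf) {
  stopifnot(length(rho) == 1, length(maf) == 1)
  if (maf <= 0 || maf > 0.5) stop_domain("maf must be in (0, 0.5]")
  if (rho < 0 || rho >= 1) stop_domain("rho must be in [0, 1)")
  if (rho == 0) return(0)
  t <- qnorm(1 - maf)
  f <- function(z) dnorm(z) * pnorm((t - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
  p11 <- integrate(f, t, Inf, rel.tol = 1e-10)$value
  (p11 - maf^2) / (maf * (1 - maf))
}

#' Latent correlation required to hit a target genotype r-squared
#'
#' Inverse of [genotype_r_from_latent()], solved numerically. Used when the
#' study generator needs variants at a prescribed dosage-scale \eqn{r^2}
#' (for example a trait-causal variant at \eqn{r^2 = 0.3} with the sentinel
#' mQTL).
#'
#' @param r2 target genotype r-squared in `(0, 1)`.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @return Latent Gaussian correlation in `(0, 1)`.
#' @export
latent_rho_for_r2 <- function(r2, maf) {
  if (r2 <= 0 || r2 >= 1) stop_domain("r2 must be in (0, 1)")
  uniroot(function(r) genotype_r_from_latent(r, maf)^2 - r2,
          c(1e-6, 1 - 1e-9), tol = 1e-12)$root
}

#' Simulate genotype dosages with autoregressive linkage disequilibrium
#'
#' Haplotypes are drawn by thresholding a zero-mean Gaussian vector with
#' correlation `ld_rho^|x_i - x_j|` at the `1 - maf` quantile; two haplotypes
#' are summed per sample, so dosages lie in `{0, 1, 2}` and are in
#' Hardy-Weinberg proportions marginally. With the default unit spacing this
#' is an AR(1) haplotype model; supplying `positions` gives
#' distance-dependent (Ornstein-Uhlenbeck) decay, which the scenario
#' generator uses to build block-like regions.
#'
#' @param n_samples number of diploid samples (>= 1).
#' @param n_variants number of variants.
#' @param maf minor allele frequency, scalar or length-`n_variants` vector,
#'   each in `(0, 0.5]`.
#' @param ld_rho adjacent-variant latent correlation in `[0, 1)`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param positions optional numeric positions (strictly increasing) on the
#'   latent-distance scale; defaults to `0:(n_variants - 1)`.
#' @param variant_ids,chrom,pos_bp optional variant metadata; generated when
#'   missing.
#' @return A `genotype_matrix`: list with `dosage` (samples x variants
#'   integer matrix) and `info` (variant metadata data frame with columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`).
#' @examples
#' g <- simulate_genotypes(200, 5, maf = 0.3, ld_rho = 0.9, seed = 1)
#' colMeans(g$dosage) / 2  # close to 0.3
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf, ld_rho, seed = NULL,
                               positions = NULL, variant_ids = NULL,
                               chrom = "1", pos_bp = NULL) {
  if (length(n_samples) != 1 || is.na(n_samples) || n_samples < 1) {
    stop_domain("n_samples must be a positive integer")
  }
  if (length(n_variants) != 1 || is.na(n_variants) || n_variants < 1) {
    stop_domain("n_variants must be a positive integer")
  }
  if (any(maf <= 0 | maf > 0.5)) stop_domain("maf must be in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop_domain("ld_rho must be in [0, 1)")
  m <- as.integer(n_variants)
  maf <- rep_len(maf, m)
  positions <- positions %||% seq_len(m) - 1
  stopifnot(length(positions) == m)

  if (m == 1 || ld_rho == 0) {
    L <- diag(m)
  } else {
    S <- ld_rho^abs(outer(positions, positions, "-"))
    L <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-10, m)))
  }
  t_cut <- qnorm(1 - maf)
  dos <- with_seed(seed, {
    h1 <- matrix(rnorm(n_samples * m), n_samples) %*% L
    h2 <- matrix(rnorm(n_samples * m), n_samples) %*% L
    (sweep(h1, 2, t_cut, ">")) + (sweep(h2, 2, t_cut, ">"))
  })
  storage.mode(dos) <- "integer"
  variant_ids <- variant_ids %||% sprintf("rs%04d", seq_len(m))
  pos_bp <- pos_bp %||% (1e6 + round((positions - min(positions)) * 2e6))
  dimnames(dos) <- list(sprintf("S%05d", seq_len(n_samples)), variant_ids)
  info <- data.frame(
    variant_id = variant_ids, chrom = rep_len(chrom, m), pos = as.integer(pos_bp),
    ref = "A", alt = "G", maf = maf, stringsAsFactors = FALSE
  )
  structure(list(dosage = dos, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (chrom %s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$info$chrom), collapse = ",")))
  invisible(x)
}

#' Region geometry for the scenario generator
#'
#' The default `"blocks"` layout emulates the block-like LD of real sentinel
#' regions: the causal mQTL sits between two tight haplotype blocks whose
#' members have dosage \eqn{r^2} of roughly `r2_inner` down to `r2_outer`
#' with the sentinel (so the fine-mapping region built at \eqn{r^2 \ge 0.8}
#' contains about `2 * n_block + 1` variants), a ladder of variants with
#' decaying LD, and a distal cluster whose first member is the trait-causal
#' variant of the LD-confounding scenario (placed at the scenario's
#' `r2_pair`). The `"uniform"` layout is a plain AR(1) chain with
#' `n_variants_region` variants at adjacent latent correlation `ld_rho`.
#'
#' @param type `"blocks"` or `"uniform"`.
#' @param n_block block size on each side of the sentinel (blocks layout).
#' @param r2_inner,r2_outer target dosage r-squared between the sentinel and
#'   the nearest/farthest block member.
#' @param n_ladder number of intermediate-LD ladder variants.
#' @param n_distal number of variants in the distal cluster (>= 1).
#' @return A `region_geometry` list used by [sim_config()].
#' @export
region_geometry <- function(type = c("blocks", "uniform"), n_block = 21,
                            r2_inner = 0.86, r2_outer = 0.82, n_ladder = 10,
                            n_distal = 5) {
  type <- match.arg(type)
  stopifnot(n_block >= 1, n_distal >= 1, r2_inner > r2_outer, r2_outer > 0.8)
  structure(list(type = type, n_block = n_block, r2_inner = r2_inner,
                 r2_outer = r2_outer, n_ladder = n_ladder, n_distal = n_distal),
            class = "region_geometry")
}

#' Configuration of a synthetic study
#'
#' Collects the generative quantities of one synthetic study: the causal
#' architecture (`scenario`), effect sizes on the standard-deviation scale,
#' the LD geometry of the sentinel region, and the polygenic trait
#' background used as the instrument set for reverse MR. Defaults reflect a
#' well-powered childhood-cohort design: a strong cis effect on methylation
#' (`a = 0.9` SD per allele), a moderate methylation-to-trait effect
#' (`b = 0.3` SD per SD), and 5,000 samples.
#'
#' @param scenario one of `"mediation"`, `"reverse"`, `"ld_confounded"`,
#'   `"pleiotropy"`.
#' @param n_samples diploid sample count (>= 10).
#' @param maf minor allele frequency of every variant, in `(0, 0.5]`.
#' @param a SNP-to-methylation effect, SD of methylation per allele.
#' @param b methylation-to-trait effect, SD per SD (mediation only).
#' @param c trait-to-methylation effect, SD per SD (reverse only).
#' @param d direct SNP-to-trait effect, SD per allele (LD-confounding and
#'   pleiotropy).
#' @param r2_pair target dosage r-squared between the causal mQTL and the
#'   trait-causal variant (LD-confounding only).
#' @param noise_sd_m,noise_sd_y residual standard deviations.
#' @param n_trait_instruments,trait_instrument_beta size and per-SNP effect
#'   of the unlinked polygenic trait background; these SNPs double as the
#'   GWAS instrument set for reverse MR. Present in every scenario because a
#'   complex trait is polygenic regardless of what happens at the sentinel
#'   region.
#' @param n_variants_region,ld_rho region size and adjacent latent
#'   correlation, used only when `geometry$type == "uniform"`.
#' @param geometry a [region_geometry()].
#' @param seed integer seed for [simulate_scenario()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(scenario = c("mediation", "reverse", "ld_confounded", "pleiotropy"),
                       n_samples = 5000, maf = 0.3, a = 0.9, b = 0.3, c = 0.4,
                       d = 0.27, r2_pair = 0.3, noise_sd_m = 1, noise_sd_y = 1,
                       n_trait_instruments = 20, trait_instrument_beta = 0.15,
                       n_variants_region = 60, ld_rho = 0.99,
                       geometry = region_geometry(), seed = 1L) {
  scenario <- match.arg(scenario)
  supplied <- c(b = !missing(b), c = !missing(c), d = !missing(d),
                r2_pair = !missing(r2_pair))
  relevant <- switch(scenario,
    mediation     = "b",
    reverse       = c("c", "d"),
    ld_confounded = c("d", "r2_pair"),
    pleiotropy    = "d"
  )
  irrelevant <- setdiff(names(supplied)[supplied], relevant)
  vals <- c(b = b, c = c, d = d, r2_pair = r2_pair)
  irrelevant <- irrelevant[vals[irrelevant] != 0]
  if (length(irrelevant)) {
    warning(sprintf("parameter(s) %s are not used by scenario '%s'",
                    paste(irrelevant, collapse = ", "), scenario), call. = FALSE)
  }
  for (nm in c("a", "b", "c", "d", "noise_sd_m", "noise_sd_y", "trait_instrument_beta")) {
    v <- get(nm)
    if (!is.finite(v)) stop_domain(nm, " must be finite")
  }
  if (n_samples < 10) stop_domain("n_samples must be >= 10")
  if (maf <= 0 || maf > 0.5) stop_domain("maf must be in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop_domain("ld_rho must be in [0, 1)")
  if (r2_pair <= 0 || r2_pair >= 1) stop_domain("r2_pair must be in (0, 1)")
  if (noise_sd_m <= 0 || noise_sd_y <= 0) stop_domain("noise SDs must be positive")
  stopifnot(inherits(geometry, "region_geometry"))
  structure(list(scenario = scenario, n_samples = as.integer(n_samples),
                 maf = maf, a = a, b = b, c = c, d = d, r2_pair = r2_pair,
                 noise_sd_m = noise_sd_m, noise_sd_y = noise_sd_y,
                 n_trait_instruments = as.integer(n_trait_instruments),
                 trait_instrument_beta = trait_instrument_beta,
                 n_variants_region = as.integer(n_variants_region),
                 ld_rho = ld_rho, geometry = geometry, seed = as.integer(seed)),
            class = "sim_config")
}

# Latent positions for the sentinel region. Returns positions (latent
# distance units, sentinel at 0), the sentinel index and the index of the
# variant targeted at r2_pair with the sentinel.
region_positions <- function(config) {
  g <- config$geometry
  if (g$type == "uniform") {
    m <- config$n_variants_region
    pos <- (seq_len(m) - 1) * -log(max(config$ld_rho, 1e-12))
    sentinel <- ceiling(m / 2)
    r2_theory <- vapply(seq_len(m), function(i) {
      if (i == sentinel) return(Inf)
      genotype_r_from_latent(exp(-abs(pos[i] - pos[sentinel])), config$maf)^2
    }, numeric(1))
    trait_idx <- which.min(abs(r2_theory - config$r2_pair))
  } else {
    d_in <- -log(latent_rho_for_r2(g$r2_inner, config$maf))
    d_out <- -log(latent_rho_for_r2(g$r2_outer, config$maf))
    d_pair <- -log(latent_rho_for_r2(config$r2_pair, config$maf))
    blk <- seq(d_in, d_out, length.out = g$n_block)
    ladder <- seq(d_out * 1.5, d_pair * 0.9, length.out = g$n_ladder)
    distal <- d_pair + seq(0, d_out - d_in, length.out = g$n_distal)
    pos <- c(-rev(blk), 0, blk, ladder, distal)
    sentinel <- g$n_block + 1L
    trait_idx <- 2L * g$n_block + 1L + g$n_ladder + 1L
  }
  list(positions = pos, sentinel = sentinel, trait_idx = trait_idx)
}

#' Generate a synthetic study with known causal architecture
#'
#' Draws genotypes for a sentinel LD region plus an unlinked polygenic
#' background, then wires methylation `M` and trait `Y` according to the
#' configured scenario (with `G` the sentinel dosage, `G2` the distal
#' trait-causal variant, `Gk` the background SNPs, and independent Gaussian
#' residuals):
#'
#' * mediation: `M = a*G + e_M`, `Y = b*M + sum(beta_k*Gk) + e_Y`
#' * reverse: `Y = d*G + sum(beta_k*Gk) + e_Y`, `M = a*G + c*Y + e_M` — the
#'   variant influences the trait through an alternative (non-methylation)
#'   mechanism and the trait feeds back on methylation
#' * ld_confounded: `M = a*G + e_M`, `Y = d*G2 + sum(beta_k*Gk) + e_Y` with
#'   dosage `r^2(G, G2)` targeted at `r2_pair`
#' * pleiotropy: `M = a*G + e_M`, `Y = d*G + sum(beta_k*Gk) + e_Y`
#'
#' Age and sex enter both `M` and `Y` with small fixed effects (0.05 SD) so
#' covariate adjustment downstream is exercised without being material.
#' `M` and `Y` are standardized to zero mean and unit variance after
#' generation; the pre-standardization scale is recorded in `truth` so
#' generative effects remain recoverable.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_study`: list with `genotypes` (a `genotype_matrix`
#'   holding region variants on chromosome 1 and background SNPs on
#'   chromosome 2), `methylation` (named standardized vector), `trait`
#'   (named standardized vector), `covariates` (data frame with `age`,
#'   `sex`), and `truth` (scenario label, generative parameters, sentinel
#'   and trait-variant ids, realized `r2_pair`, and pre-standardization
#'   scales).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- region_positions(config)
  n <- config$n_samples
  m <- length(lay$positions)
  K <- config$n_trait_instruments

  with_seed(config$seed, {
    region <- simulate_genotypes(
      n, m, config$maf, ld_rho = exp(-1), positions = lay$positions,
      variant_ids = sprintf("rs%04d", seq_len(m)), chrom = "1"
    )
    bg <- simulate_genotypes(
      n, K, config$maf, ld_rho = 0,
      variant_ids = sprintf("bg%03d", seq_len(K)), chrom = "2",
      pos_bp = 1e6 + seq_len(K) * 1e5
    )
    age <- rnorm(n, 7.5, 0.15)
    sex <- rbinom(n, 1, 0.5)
    e_m <- rnorm(n, 0, config$noise_sd_m)
    e_y <- rnorm(n, 0, config$noise_sd_y)

    G <- region$dosage[, lay$sentinel]
    G2 <- region$dosage[, lay$trait_idx]
    covar_term <- 0.05 * as.numeric(scale(age)) + 0.05 * as.numeric(scale(sex))
    poly <- as.numeric(bg$dosage %*% rep(config$trait_instrument_beta, K))

    if (config$scenario == "reverse") {
      Y_raw <- config$d * G + poly + covar_term + e_y
      M_raw <- config$a * G + config$c * Y_raw + covar_term + e_m
    } else {
      M_raw <- config$a * G + covar_term + e_m
      Y_raw <- switch(config$scenario,
        mediation     = config$b * M_raw + poly + covar_term + e_y,
        ld_confounded = config$d * G2 + poly + covar_term + e_y,
        pleiotropy    = config$d * G + poly + covar_term + e_y
      )
    }
    dos <- cbind(region$dosage, bg$dosage)
    info <- rbind(region$info, bg$info)
    genotypes <- structure(list(dosage = dos, info = info), class = "genotype_matrix")

    sentinel_id <- region$info$variant_id[lay$sentinel]
    trait_variant_id <- region$info$variant_id[lay$trait_idx]
    cpg_pos <- region$info$pos[lay$sentinel] + 537L
    truth <- list(
      scenario = config$scenario, a = config$a,
      b = if (config$scenario == "mediation") config$b else 0,
      c = if (config$scenario == "reverse") config$c else 0,
      d = if (config$scenario %in% c("ld_confounded", "pleiotropy", "reverse")) config$d else 0,
      sentinel_id = sentinel_id, cpg_id = "cg00000001", cpg_chrom = "1",
      cpg_pos = cpg_pos,
      trait_variant_id = if (config$scenario == "ld_confounded") trait_variant_id else sentinel_id,
      r2_pair_target = if (config$scenario == "ld_confounded") config$r2_pair else NA_real_,
      r2_pair_realized = unname(cor(G, G2)^2),
      trait_instrument_ids = bg$info$variant_id,
      trait_instrument_beta = config$trait_instrument_beta,
      mean_m_raw = mean(M_raw), sd_m_raw = sd(M_raw),
      mean_y_raw = mean(Y_raw), sd_y_raw = sd(Y_raw),
      seed = config$seed
    )
    structure(list(
      genotypes = genotypes,
      methylation = setNames(as.numeric(scale(M_raw)), rownames(dos)),
      trait = setNames(as.numeric(scale(Y_raw)), rownames(dos)),
      covariates = data.frame(sample_id = rownames(dos), age = age, sex = sex,
                              stringsAsFactors = FALSE),
      truth = truth
    ), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: scenario '%s', %d samples, %d variants (sentinel %s)\n",
              x$truth$scenario, length(x$methylation), ncol(x$genotypes$dosage),
              x$truth$sentinel_id))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `genotypes.tsv` (dosages, samples x variants), `variants.tsv`
#' (variant metadata), `methylation.tsv`, `phenotypes.tsv` (trait plus age
#' and sex), `truth.json`, and optionally a minimal VCF 4.2 with a `DS`
#' FORMAT field. The bundle round-trips through [read_study_bundle()].
#'
#' @param study a `synthetic_study` from [simulate_scenario()].
#' @param dir output directory, created if needed.
#' @param vcf also write `genotypes.vcf`?
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir, vcf = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  dos <- study$genotypes$dosage
  tsv(data.frame(sample_id = rownames(dos), dos, check.names = FALSE), "genotypes.tsv")
  tsv(study$genotypes$info, "variants.tsv")
  meth <- data.frame(sample_id = names(study$methylation), study$methylation,
                     check.names = FALSE)
  names(meth)[2] <- study$truth$cpg_id
  tsv(meth, "methylation.tsv")
  tsv(data.frame(sample_id = names(study$trait), trait = study$trait,
                 age = study$covariates$age, sex = study$covariates$sex),
      "phenotypes.tsv")
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (vcf) {
    info <- study$genotypes$info
    con <- file(file.path(dir, "genotypes.vcf"), "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of alternate allele\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", rownames(dos)), collapse = "\t")
    ), con)
    for (j in seq_len(nrow(info))) {
      writeLines(paste(c(info$chrom[j], info$pos[j], info$variant_id[j],
                         info$ref[j], info$alt[j], ".", ".", ".", "DS",
                         dos[, j]), collapse = "\t"), con)
    }
  }
  invisible(dir)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' @param dir bundle directory.
#' @return A `synthetic_study`-shaped list; `truth` is `NULL` when
#'   `truth.json` is absent (real-data bundles).
#' @export
read_study_bundle <- function(dir) {
  geno <- read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE)
  dos <- as.matrix(geno[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- geno$sample_id
  info <- read.delim(file.path(dir, "variants.tsv"), colClasses = c(chrom = "character"))
  meth <- read.delim(file.path(dir, "methylation.tsv"), check.names = FALSE)
  pheno <- read.delim(file.path(dir, "phenotypes.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(
    genotypes = structure(list(dosage = dos, info = info), class = "genotype_matrix"),
    methylation = setNames(meth[[2]], meth$sample_id),
    trait = setNames(pheno$trait, pheno$sample_id),
    covariates = pheno[, c("sample_id", "age", "sex")],
    truth = truth,
    cpg_id = names(meth)[2]
  ), class = "synthetic_study")
}
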
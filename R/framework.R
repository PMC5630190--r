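#' Classify a shared methylation/trait signal into a causal explanation
#'
#' Applies the decision rules over the assembled evidence for one signal, in
#' fixed order of precedence:
#'
#' 1. reverse-MR p <= `alpha`: the trait plausibly drives methylation —
#'    call `"2_reverse"`.
#' 2. fine-mapping concordance verdict `"discordant"`: the mQTL is likely in
#'    LD with a distinct trait-causal variant — call `"3_ld"`.
#' 3. forward-MR p <= `alpha` with reverse causation unlikely and a
#'    concordant region: call `"1_mediation_or_4"`.
#' 4. otherwise `"inconclusive"`.
#'
#' The `1`-vs-`4` ambiguity is deliberate: with a single cis instrument,
#' mediation and horizontal pleiotropy produce identical marginal
#' associations and cannot be separated, so the call label carries both.
#' Missing reverse-MR or concordance evidence degrades the call to
#' `"inconclusive"` (it can never promote to explanation 1). Replication and
#' eQTL two-sample MR results are carried in the evidence trail but never
#' gate the call.
#'
#' @param forward_mr `mr_result` for methylation on trait (required).
#' @param reverse_mr optional `mr_result` from [reverse_mr()].
#' @param concordance optional `concordance_result`.
#' @param k_posterior optional output of [k_causal_posterior()].
#' @param replication_2smr,eqtl_2smr optional supporting `mr_result`s.
#' @param signal optional list of labels (`snp_id`, `cpg_id`, `trait`).
#' @param alpha decision threshold (default 0.05).
#' @return An `explanation_call` with fields `call`, `notes` (which evidence
#'   fired), and the full evidence trail.
#' @export
classify_signal <- function(forward_mr, reverse_mr = NULL, concordance = NULL,
                            k_posterior = NULL, replication_2smr = NULL,
                            eqtl_2smr = NULL, signal = NULL, alpha = 0.05) {
  stopifnot(inherits(forward_mr, "mr_result"))
  if (!is.null(reverse_mr) && !is.null(reverse_mr$verdict) &&
      !is.na(reverse_mr$p)) {
    claimed_unlikely <- reverse_mr$verdict == "explanation 2 unlikely"
    if (claimed_unlikely != (reverse_mr$p > alpha)) {
      stop_domain("contradictory reverse-MR evidence: verdict '",
                  reverse_mr$verdict, "' inconsistent with p = ", reverse_mr$p)
    }
  }
  rev_p <- if (!is.null(reverse_mr)) reverse_mr$p else NA_real_
  if (!is.na(rev_p) && rev_p <= alpha) {
    call <- "2_reverse"
    notes <- sprintf("reverse-MR p = %.3g <= %.2g", rev_p, alpha)
  } else if (!is.null(concordance) && concordance$verdict == "discordant") {
    call <- "3_ld"
    notes <- sprintf("concordance rate %.3f (rank %d of %d) >= 0.05",
                     concordance$concordance_rate,
                     concordance$rank_of_top_meth_in_trait_ranking,
                     concordance$m_variants)
  } else if (forward_mr$p <= alpha && !is.na(rev_p) && rev_p > alpha &&
             !is.null(concordance) && concordance$verdict == "concordant") {
    call <- "1_mediation_or_4"
    notes <- sprintf(paste0("forward-MR p = %.3g; reverse unlikely (p = %.3g); ",
                            "concordant (rate %.3f); mediation and horizontal ",
                            "pleiotropy not separable with a single instrument"),
                     forward_mr$p, rev_p, concordance$concordance_rate)
  } else {
    call <- "inconclusive"
    missing_bits <- c(
      if (is.na(rev_p)) "reverse MR" else NULL,
      if (is.null(concordance)) "concordance" else NULL,
      if (forward_mr$p > alpha) "forward MR evidence" else NULL
    )
    notes <- if (length(missing_bits)) {
      paste("missing or insufficient:", paste(missing_bits, collapse = ", "))
    } else {
      "no rule fired"
    }
  }
  structure(list(signal = signal, call = call, notes = notes,
                 forward_mr = forward_mr, reverse_mr = reverse_mr,
                 concordance = concordance, k_posterior = k_posterior,
                 replication_2smr = replication_2smr, eqtl_2smr = eqtl_2smr),
            class = "explanation_call")
}

#' @export
print.explanation_call <- function(x, ...) {
  lab <- if (is.null(x$signal)) "" else
    sprintf(" [%s]", paste(unlist(x$signal), collapse = "/"))
  cat(sprintf("explanation_call%s: %s\n  %s\n", lab, x$call, x$notes))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param bundle_dir directory holding a study bundle (see
#'   [write_study_bundle()]).
#' @param out_dir output directory for reports.
#' @param cis_window_bp cis window for instrument selection (default 1 Mb).
#' @param mqtl_p_max mQTL instrument threshold (default 1e-14).
#' @param clump_r2 LD clumping threshold (default 0.1).
#' @param region_r2 fine-mapping region threshold (default 0.8).
#' @param concordance_alpha concordance verdict threshold (default 0.05).
#' @param alpha MR decision threshold (default 0.05).
#' @param gwas_p_max trait-instrument selection threshold for reverse MR
#'   (default 5e-8).
#' @param prior_var_W Wakefield prior effect variance (default 0.04).
#' @param seed integer seed for any resampling stage.
#' @return A named list, also writable/readable as YAML.
#' @export
pipeline_config <- function(bundle_dir = NULL, out_dir = NULL,
                            cis_window_bp = 1e6, mqtl_p_max = 1e-14,
                            clump_r2 = 0.1, region_r2 = 0.8,
                            concordance_alpha = 0.05, alpha = 0.05,
                            gwas_p_max = 5e-8, prior_var_W = 0.04, seed = 1L) {
  list(bundle_dir = bundle_dir, out_dir = out_dir,
       cis_window_bp = cis_window_bp, mqtl_p_max = mqtl_p_max,
       clump_r2 = clump_r2, region_r2 = region_r2,
       concordance_alpha = concordance_alpha, alpha = alpha,
       gwas_p_max = gwas_p_max, prior_var_W = prior_var_W, seed = seed)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Analyze one study in memory
#'
#' Runs the per-study analysis chain behind [run_pipeline()] without any
#' file output: methylation scan, cis/significance instrument selection
#' with greedy clumping, trait scan with Bonferroni control, forward 2SLS,
#' reverse MR with trait instruments from outside the CpG's cis window,
#' bivariate fine mapping, concordance, and classification.
#'
#' @param study a `synthetic_study` (from [simulate_scenario()] or
#'   [read_study_bundle()]).
#' @param config list from [pipeline_config()].
#' @return Report list: `calls` (data frame, one row per classified signal),
#'   `signals` (named list of `explanation_call`s), `regions` (named list of
#'   `region_finemap`s), `mqtl_records`, `meth_scan`, `trait_scan`,
#'   `manhattan`, `sentinel_rows`, `threshold`, `log` (character lines).
#' @export
analyze_study <- function(study, config = pipeline_config()) {
  config <- utils::modifyList(pipeline_config(), config)
  dos <- study$genotypes$dosage
  info <- study$genotypes$info
  cpg_id <- study$cpg_id %||% study$truth$cpg_id %||% "cpg"
  cpg_chrom <- as.character(study$truth$cpg_chrom %||% config$cpg_chrom %||% info$chrom[1])
  cpg_pos <- study$truth$cpg_pos %||% config$cpg_pos %||% info$pos[1]
  covars <- study$covariates[, c("age", "sex")]
  log_lines <- c(
    sprintf("samples: %d, variants: %d", nrow(dos), ncol(dos)),
    sprintf("thresholds: mqtl_p_max %g, cis_window_bp %g, clump_r2 %g, region_r2 %g, alpha %g, seed %d",
            config$mqtl_p_max, config$cis_window_bp, config$clump_r2,
            config$region_r2, config$alpha, as.integer(config$seed))
  )

  meth_scan <- run_mwas(study$genotypes, setNames(list(study$methylation), cpg_id),
                        covariates = covars)
  idx <- match(meth_scan$snp_id, info$variant_id)
  mqtl_records <- data.frame(
    snp_id = meth_scan$snp_id, cpg_id = cpg_id,
    chrom = info$chrom[idx], cpg_chrom = cpg_chrom,
    pos_snp = info$pos[idx], pos_cpg = cpg_pos,
    effect_allele = info$alt[idx], other_allele = info$ref[idx],
    beta = meth_scan$beta, se = meth_scan$se, p = meth_scan$p,
    stringsAsFactors = FALSE
  )

  empty_calls <- data.frame(snp_id = character(), cpg_id = character(),
                            trait = character(), call = character(),
                            notes = character(), stringsAsFactors = FALSE)
  report <- list(config = config, calls = empty_calls, signals = list(),
                 regions = list(), mqtl_records = mqtl_records,
                 meth_scan = meth_scan, trait_scan = NULL, manhattan = NULL,
                 sentinel_rows = NULL, threshold = NA_real_, log = log_lines)

  cis <- select_cis_mqtls(mqtl_records, config$cis_window_bp, config$mqtl_p_max)
  if (nrow(cis) == 0) {
    report$log <- c(log_lines, "no mQTL instruments at threshold; no signals to evaluate")
    return(report)
  }
  r2_all <- cor(dos[, cis$snp_id, drop = FALSE])^2
  sentinels <- ld_clump(cis[, c("snp_id", "p")], r2_all, config$clump_r2)
  log_lines <- c(log_lines, sprintf("cis mQTL candidates: %d; sentinels after clumping: %d",
                                    nrow(cis), length(sentinels)))

  trait_scan <- run_mwas(study$genotypes, list(trait = study$trait),
                         covariates = covars)
  bon <- bonferroni_threshold(ncol(dos), 1L)
  manhattan <- manhattan_table(trait_scan, info, bon$threshold)
  sent_rows <- trait_scan[trait_scan$snp_id %in% sentinels, , drop = FALSE]
  hits <- sent_rows$snp_id[sent_rows$p < bon$threshold]
  log_lines <- c(log_lines, sprintf("study-wide threshold %.4g over %d tests; %d sentinel signal(s)",
                                    bon$threshold, as.integer(bon$n_tests), length(hits)))
  report$trait_scan <- trait_scan
  report$manhattan <- manhattan
  report$sentinel_rows <- sent_rows
  report$threshold <- bon$threshold

  calls <- list()
  regions <- list()
  pos_all <- setNames(info$pos, info$variant_id)
  for (snp in hits) {
    fwd <- two_stage_least_squares(dos[, snp], study$methylation, study$trait,
                                   covariates = covars,
                                   exposure_id = cpg_id, outcome_id = "trait")

    snp_idx <- match(trait_scan$snp_id, info$variant_id)
    in_cis <- info$chrom[snp_idx] == cpg_chrom &
      abs(info$pos[snp_idx] - cpg_pos) <= config$cis_window_bp
    iv_ok <- trait_scan$p < config$gwas_p_max & !in_cis
    rev <- NULL
    if (any(iv_ok)) {
      iv_ids <- trait_scan$snp_id[iv_ok]
      r2_iv <- cor(dos[, iv_ids, drop = FALSE])^2
      iv_ids <- ld_clump(trait_scan[iv_ok, c("snp_id", "p")], r2_iv, config$clump_r2)
      mk_stats <- function(scan, ids) {
        rows <- scan[match(ids, scan$snp_id), ]
        j <- match(ids, info$variant_id)
        data.frame(snp_id = ids, effect_allele = info$alt[j],
                   other_allele = info$ref[j], eaf = info$maf[j],
                   beta = rows$beta, se = rows$se, stringsAsFactors = FALSE)
      }
      rev <- reverse_mr(mk_stats(trait_scan, iv_ids),
                        mk_stats(meth_scan, iv_ids), alpha = config$alpha)
    }
    log_lines <- c(log_lines, sprintf("%s: reverse-MR instruments %d",
                                      snp, if (is.null(rev)) 0L else rev$n_instruments))

    r2_row <- as.numeric(cor(dos, dos[, snp]))^2
    names(r2_row) <- colnames(dos)
    region <- build_region(snp, r2_row, config$region_r2, positions = pos_all)
    ri <- match(region, meth_scan$snp_id)
    ti <- match(region, trait_scan$snp_id)
    rfm <- finemap_region(
      snp, region,
      beta_meth = meth_scan$beta[ri], se_meth = meth_scan$se[ri],
      beta_trait = trait_scan$beta[ti], se_trait = trait_scan$se[ti],
      ld_matrix = cor(dos[, region, drop = FALSE]),
      prior_var_W = config$prior_var_W, positions = pos_all
    )
    conc <- concordance(rfm, config$concordance_alpha)

    calls[[snp]] <- classify_signal(
      fwd, reverse_mr = rev, concordance = conc,
      k_posterior = rfm$k_posterior_trait,
      signal = list(snp_id = snp, cpg_id = cpg_id, trait = "trait"),
      alpha = config$alpha
    )
    regions[[snp]] <- rfm
  }

  call_df <- if (length(calls)) {
    out <- do.call(rbind, lapply(calls, function(cl) data.frame(
      snp_id = cl$signal$snp_id, cpg_id = cl$signal$cpg_id,
      trait = cl$signal$trait,
      forward_beta = cl$forward_mr$beta, forward_p = cl$forward_mr$p,
      reverse_p = if (is.null(cl$reverse_mr)) NA_real_ else cl$reverse_mr$p,
      concordance_rate = cl$concordance$concordance_rate,
      m_variants = cl$concordance$m_variants,
      call = cl$call, notes = cl$notes, stringsAsFactors = FALSE
    )))
    rownames(out) <- NULL
    out
  } else {
    empty_calls
  }
  report$calls <- call_df
  report$signals <- calls
  report$regions <- regions
  report$log <- log_lines
  report
}

#' Run the full triage pipeline on a study bundle
#'
#' Reads a study bundle, runs [analyze_study()], and writes reports
#' (`mqtls.tsv`, `mwas.tsv`, `manhattan.tsv`, `calls.tsv`,
#' `region_<sentinel>.json`, `pipeline_log.txt`) to `config$out_dir`.
#' Outputs contain no timestamps, so re-running with an identical
#' configuration and seed reproduces every file byte for byte. A stage
#' error aborts with a stage-qualified message and removes partial outputs.
#'
#' @param config list from [pipeline_config()] (with `bundle_dir` and
#'   `out_dir` set) or path to an equivalent YAML file.
#' @return Invisibly, the [analyze_study()] report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config(), config)
  if (is.null(config$bundle_dir) || !dir.exists(config$bundle_dir)) {
    stop_domain("[config] bundle_dir missing or not a directory")
  }
  if (is.null(config$out_dir)) stop_domain("[config] out_dir missing")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "prep"
  tryCatch({
    study <- read_study_bundle(config$bundle_dir)
    stage <- "analysis"
    report <- analyze_study(study, config)
    stage <- "report"
    write_tsv(report$mqtl_records, f <- file.path(out, "mqtls.tsv")); written <- c(written, f)
    if (!is.null(report$manhattan)) {
      write_tsv(report$manhattan, f <- file.path(out, "manhattan.tsv")); written <- c(written, f)
      write_tsv(report$sentinel_rows, f <- file.path(out, "mwas.tsv")); written <- c(written, f)
    }
    for (snp in names(report$regions)) {
      rfm <- report$regions[[snp]]
      conc <- report$signals[[snp]]$concordance
      jsonlite::write_json(
        list(sentinel = snp, variants = rfm$variants,
             k_posterior_meth = rfm$k_posterior_meth$posterior,
             k_posterior_trait = rfm$k_posterior_trait$posterior,
             concordance = unclass(conc)),
        f <- file.path(out, paste0("region_", snp, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      written <- c(written, f)
    }
    write_tsv(report$calls, f <- file.path(out, "calls.tsv")); written <- c(written, f)
    if (!is.null(config$enrich_bed) && !is.null(config$enrich_targets) &&
        !is.null(config$enrich_pool)) {
      stage <- "enrichment"
      track <- read_bed(config$enrich_bed)
      targets <- read.delim(config$enrich_targets,
                            colClasses = c(chrom = "character"))
      pool <- read.delim(config$enrich_pool, colClasses = c(chrom = "character"))
      classes <- if ("class" %in% names(targets)) unique(targets$class) else "all"
      enr <- lapply(classes, function(cl) {
        tg <- if ("class" %in% names(targets)) {
          targets[targets$class == cl, , drop = FALSE]
        } else {
          targets
        }
        pl <- pool[pool$target_id %in% tg$id, , drop = FALSE]
        unclass(matched_resample_enrichment(
          tg, pl, track,
          iterations = config$enrich_iterations %||% 10000,
          seed = config$seed
        ))
      })
      names(enr) <- classes
      jsonlite::write_json(enr, f <- file.path(out, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
      report$enrichment <- enr
      stage <- "report"
    }
    writeLines(c("methmr pipeline log", report$log), file.path(out, "pipeline_log.txt"))
    invisible(report)
  }, error = function(e) {
    unlink(written)
    unlink(file.path(out, "pipeline_log.txt"))
    stop_domain(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}
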
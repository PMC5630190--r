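normalize_chrom <- function(x, context = "chromosome names") {
  x <- as.character(x)
  has_prefix <- grepl("^chr", x, ignore.case = TRUE)
  if (any(has_prefix) && !all(has_prefix)) {
    warning("mixed ", context, " ('chr1' vs '1'); normalized by stripping the prefix",
            call. = FALSE)
  }
  sub("^chr", "", x, ignore.case = TRUE)
}

#' Count point positions overlapping an annotation track
#'
#' Positions are 1-based genomic points (SNPs or CpG sites); the track is in
#' BED convention (0-based, half-open). A point `p` hits an interval
#' `[start, end)` exactly when `start < p <= end`, i.e. when the 1-based
#' base `p` lies inside the BED interval. Chromosome-name style (`chr1` vs
#' `1`) is normalized with a warning when mixed.
#'
#' @param positions data frame with columns `chrom`, `pos` (1-based).
#' @param track data frame with BED columns `chrom`, `start`, `end`, or a
#'   `GRanges` (assumed already 1-based, as returned by BED importers).
#' @return Integer count of overlapping positions.
#' @export
overlap_count <- function(positions, track) {
  if (nrow(positions) == 0) return(0L)
  if (inherits(track, "GRanges")) {
    tr <- track
  } else {
    if (nrow(track) == 0) return(0L)
    stopifnot(all(track$start < track$end))
    tr <- GenomicRanges::GRanges(
      normalize_chrom(track$chrom),
      IRanges::IRanges(start = track$start + 1L, end = track$end)
    )
  }
  pts <- GenomicRanges::GRanges(
    normalize_chrom(positions$chrom),
    IRanges::IRanges(start = positions$pos, width = 1L)
  )
  sum(GenomicRanges::countOverlaps(pts, tr) > 0)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N_pop, K_pop, n_draw)`: the
#' probability of drawing at least `k` annotated elements in `n_draw` draws
#' without replacement from a population of `N_pop` elements of which
#' `K_pop` are annotated.
#'
#' @param k observed overlap count.
#' @param K_pop annotated elements in the population.
#' @param n_draw number of draws (targets tested).
#' @param N_pop population size.
#' @return Upper-tail p-value.
#' @examples
#' hypergeometric_p(2, 4, 3, 10)  # 1/3
#' @export
hypergeometric_p <- function(k, K_pop, n_draw, N_pop) {
  ok <- k >= 0 && K_pop >= 0 && n_draw >= 0 && K_pop <= N_pop &&
    n_draw <= N_pop && k <= min(K_pop, n_draw)
  if (!ok) stop_domain("inconsistent hypergeometric counts")
  phyper(k - 1, K_pop, N_pop - K_pop, n_draw, lower.tail = FALSE)
}

#' Matched-control resampling enrichment
#'
#' Compares the observed annotation overlap of a target set (lead SNPs or
#' CpG sites) against the distribution obtained by repeatedly substituting
#' each target with a randomly drawn matched control (without replacement
#' within an iteration), alongside a hypergeometric test over the matched
#' pool. The empirical p-value uses the add-one convention
#' `(1 + #iterations with control overlap >= observed) / (iterations + 1)`,
#' so it can never be exactly zero and its granularity floor halves when
#' iterations double.
#'
#' @param targets data frame with columns `id`, `chrom`, `pos`.
#' @param matched_pool data frame with columns `target_id`, `control_id`,
#'   `chrom`, `pos`; one partition of property-matched controls per target.
#' @param track annotation track, see [overlap_count()].
#' @param iterations resampling iterations (default 10000).
#' @param seed integer seed; resampling is reproducible and leaves global
#'   RNG state untouched.
#' @return An `enrichment_result` list: `n_targets`, `n_overlapping`,
#'   `background_counts` (per-iteration control overlaps),
#'   `hypergeometric_p` (targets + pool as population), `empirical_p`,
#'   `iterations`, `seed`.
#' @export
matched_resample_enrichment <- function(targets, matched_pool, track,
                                        iterations = 10000, seed = 1L) {
  if (iterations < 1) stop_domain("iterations must be >= 1")
  stopifnot(nrow(targets) > 0)
  parts <- split(seq_len(nrow(matched_pool)), matched_pool$target_id)
  missing_part <- setdiff(targets$id, names(parts))
  if (length(missing_part)) {
    stop_domain("empty matched partition for target(s): ",
                paste(missing_part, collapse = ", "))
  }
  obs_k <- overlap_count(targets[, c("chrom", "pos")], track)
  pool_hit <- rep(FALSE, nrow(matched_pool))
  if (nrow(matched_pool)) {
    hit_idx <- overlap_flags(matched_pool[, c("chrom", "pos")], track)
    pool_hit <- hit_idx
  }
  part_idx <- parts[targets$id]
  counts <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      used <- character(0)
      k <- 0L
      for (p in part_idx) {
        avail <- p[!(matched_pool$control_id[p] %in% used)]
        if (!length(avail)) {
          stop_domain("matched pool exhausted within an iteration; ",
                      "provide more controls per target")
        }
        pick <- if (length(avail) == 1) avail else avail[sample.int(length(avail), 1)]
        used <- c(used, matched_pool$control_id[pick])
        k <- k + pool_hit[pick]
      }
      k
    }, integer(1))
  })
  pool_unique <- !duplicated(matched_pool$control_id)
  structure(list(
    n_targets = nrow(targets), n_overlapping = obs_k,
    background_counts = counts,
    hypergeometric_p = hypergeometric_p(
      obs_k,
      K_pop = obs_k + sum(pool_hit[pool_unique]),
      n_draw = nrow(targets),
      N_pop = nrow(targets) + sum(pool_unique)
    ),
    empirical_p = (1 + sum(counts >= obs_k)) / (iterations + 1),
    iterations = iterations, seed = seed
  ), class = "enrichment_result")
}

# per-row logical overlap flags for point positions
overlap_flags <- function(positions, track) {
  if (inherits(track, "GRanges")) {
    tr <- track
  } else {
    stopifnot(all(track$start < track$end))
    tr <- GenomicRanges::GRanges(
      normalize_chrom(track$chrom),
      IRanges::IRanges(start = track$start + 1L, end = track$end)
    )
  }
  pts <- GenomicRanges::GRanges(
    normalize_chrom(positions$chrom),
    IRanges::IRanges(start = positions$pos, width = 1L)
  )
  GenomicRanges::countOverlaps(pts, tr) > 0
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d targets overlap; hypergeometric p %.3g, empirical p %.3g (%d iterations)\n",
              x$n_overlapping, x$n_targets, x$hypergeometric_p, x$empirical_p,
              x$iterations))
  invisible(x)
}

#' Read a BED annotation track
#'
#' Reads the first three BED columns (`chrom`, `start`, `end`; 0-based
#' half-open), skipping `track` and comment lines. Additional columns are
#' ignored.
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t")
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)),
    end = as.numeric(vapply(parts, `[[`, "", 3)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$start < out$end))
  out
}

#' Simple property-matched control pool
#'
#' Builds a matched pool by binning candidates on minor allele frequency
#' (`|maf - maf_target| <= maf_tol`) and, when present, an exact categorical
#' match (e.g. relation-to-CpG-island class). Intended for synthetic tests;
#' production analyses should supply an externally constructed pool.
#'
#' @param targets data frame with `id`, `maf`, optionally `category`.
#' @param candidates data frame with `id`, `chrom`, `pos`, `maf`, optionally
#'   `category`.
#' @param maf_tol MAF matching half-width (default 0.05).
#' @return data frame with `target_id`, `control_id`, `chrom`, `pos`.
#' @export
match_controls <- function(targets, candidates, maf_tol = 0.05) {
  out <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    ok <- abs(candidates$maf - t$maf) <= maf_tol & candidates$id != t$id
    if ("category" %in% names(targets) && "category" %in% names(candidates)) {
      ok <- ok & candidates$category == t$category
    }
    cand <- candidates[ok, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    data.frame(target_id = t$id, control_id = cand$id, chrom = cand$chrom,
               pos = cand$pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
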
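---
title: "Triaging shared methylation–trait genetic signals: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triaging shared methylation–trait genetic signals: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmr)
```

## The problem

A cis-acting methylation quantitative trait locus (mQTL) that is also
associated with a cardiovascular trait admits four causal explanations:

1. **Mediation** — the variant changes methylation, and methylation changes
   the trait.
2. **Reverse causation** — the variant changes the trait through some other
   mechanism, and the trait feeds back on methylation.
3. **LD confounding** — the mQTL is merely in linkage disequilibrium with a
   distinct variant that drives the trait.
4. **Horizontal pleiotropy** — one variant drives methylation and trait
   through independent pathways.

methmr assembles the evidence needed to choose among these: an mQTL-by-trait
association scan, one-sample and two-sample Mendelian randomization (MR),
bivariate fine mapping with a concordance statistic, and annotation
enrichment. A crucial caveat is baked into the call labels: with a single
cis instrument, explanations 1 and 4 produce identical marginal and
instrumental-variable associations, so the pipeline reports them jointly as
`1_mediation_or_4` and never pretends to separate them.

## Estimators

**Association scan.** Each trait is regressed on each dosage with age and
sex adjustment; the study-wide threshold is Bonferroni,
$\alpha / (\text{variants} \times \text{traits})$, applied with a strict
inequality. The variance explained is reported as the partial $R^2$ of the
dosage term (configurable to full-model $\Delta R^2$; the two differ only in
whether covariate-explained variance is removed from the denominator, and
neither is singled out as canonical).

**One-sample MR.** Two-stage least squares with the mQTL(s) as instruments:
the exposure (methylation) is regressed on instruments and covariates, then
the outcome on the fitted exposure. Standard errors use stage-2 residuals
formed with the *observed* exposure — the naive OLS-on-fitted SE is
anticonservative. With one instrument the estimate collapses to the ratio of
reduced-form slopes, which the tests verify to $10^{-10}$. Two
pairwise-independent mQTLs at one CpG are handled by a joint first stage
(`multivariable_2sls`). First-stage F statistics are logged; instruments are
never auto-dropped because the selection threshold ($p < 10^{-14}$) already
guards against weak-instrument bias.

**Two-sample MR.** For summary statistics the Wald ratio
$\hat\beta = \beta_{GY} / \beta_{GX}$ is used with the full delta-method SE,
$\sqrt{se_{GY}^2/\beta_{GX}^2 + \beta_{GY}^2 se_{GX}^2 / \beta_{GX}^4}$.
The second term matters: with an imprecise exposure association, dropping it
understates the SE by roughly 10% in the bundled worked examples. p-values
for summary-statistic MR come from the standard normal (consortium-scale
inputs); the one-sample estimator uses the t distribution. Multiple
instruments are pooled by fixed-effect inverse-variance weighting.
Harmonization matches by SNP id, substitutes the best proxy at $r^2 > 0.8$
when the sentinel is absent, flips outcome effects when alleles are swapped,
and drops palindromic variants with MAF above 0.42 (configurable), where
strand cannot be resolved.

**Reverse MR.** Trait GWAS instruments (selected outside the CpG's 1 Mb cis
window at $p < 5\times10^{-8}$, then LD-clumped) are harmonized against
SNP-methylation statistics and combined by IVW. A combined p-value above
0.05 marks reverse causation as unlikely. Fixed-effect IVW is used because
the decision rule needs a single number and it is the standard
first-line combination for summary-statistic MR.

**Fine mapping and concordance.** Per-variant evidence uses Wakefield's
approximate Bayes factor with prior effect variance $W = 0.04$ (prior SD 0.2
on standardized effects) — a deliberate closed-form choice, configurable,
since standardized effect sizes of cis-mQTLs and trait associations in this
setting rarely exceed ±0.6. The region is the sentinel plus all variants at
$r^2 \ge 0.8$. Both effect sets (SNP→methylation, SNP→trait) are fine-mapped
over the same variants under a uniform causal prior; the concordance rate is
the 1-based rank of the top methylation variant within the descending
trait-BF ranking divided by the region size, with rate < 0.05 (strict)
meaning the two signals plausibly share a causal variant. Two consequences
are worth noting: a region with fewer than 21 variants can never be called
concordant, and in very dense LD the top-variant rank is noisy, so a
mediated signal is occasionally called discordant — the statistic inherits
this from its rank-based definition. The posterior over the number of
causal variants ($K \in \{1,2\}$) uses the multivariate-normal z likelihood
with LD covariance; determinant-lemma/Woodbury identities collapse each
set's Bayes factor onto its $|C| \times |C|$ LD block, so exhaustive
enumeration of pairs is cheap up to 500 variants. Near-singular pair blocks
fall back to a $10^{-4}$ ridge with a logged note. As the prior variance
tends to zero every Bayes factor tends to one and the K posterior returns
its prior; with informative priors and flat z-scores the marginal
likelihood's Occam penalty favours fewer causal variants — the
mathematically correct behaviour for a model-size posterior.

**Enrichment.** Observed overlap of lead SNPs/CpGs with annotation tracks
(BED half-open convention; a 1-based point $p$ hits $[s, e)$ iff
$s < p \le e$) is compared against matched controls resampled 10,000 times
(configurable), with the Davison–Hinkley add-one empirical p-value
$(1 + \#\{\text{ties or better}\}) / (N + 1)$, which can never be zero, and
a hypergeometric tail over the matched pool. Matched pools are expected as
input (SNP property matching is a solved problem upstream); a simple
MAF ± 0.05 / category matcher ships for synthetic work.

**Decision rules.** In fixed precedence: reverse-MR $p \le 0.05$ → call 2;
discordant region → call 3; forward MR significant with reverse unlikely
and a concordant region → call `1_mediation_or_4`; otherwise inconclusive.
Missing evidence can only degrade a call, never upgrade it. Replication and
eQTL two-sample MR results ride along in the evidence trail without gating
the call, and a `jlim_p` placeholder field lets externally computed
colocalization p-values be merged into reports.

## The synthetic-study generator

Because individual-level cohort data of this kind are access-controlled, the
package ships a generator whose ground truth exercises every stage.

**Genotypes.** Haplotypes are drawn by thresholding a latent Gaussian with
correlation $\rho^{|x_i - x_j|}$ at the $1-\text{maf}$ quantile and summing
two haplotypes per sample — a Gaussian-copula AR(1)/Ornstein–Uhlenbeck
model that gives a closed-form handle on LD. Thresholding attenuates
correlation, so `genotype_r_from_latent()` maps latent to dosage-scale
correlation (and `latent_rho_for_r2()` inverts it), letting the generator
hit dosage $r^2$ targets exactly in expectation.

**Region geometry.** Real sentinel regions are block-like: a causal variant
accompanied by tens of high-LD proxies, then a decaying ladder. The default
layout places the sentinel between two 21-variant blocks at dosage $r^2$
0.86→0.82 with the sentinel, a 10-variant ladder, and a 5-variant distal
cluster whose first member is the trait-causal variant of the
LD-confounding scenario, positioned at the configured `r2_pair` (default
0.3). This yields fine-mapping regions of ~43 variants — large enough that
the concordance statistic can actually call concordance (1/43 < 0.05), and
matching the scale of reported loci — while keeping the sentinel
distinguishable from its proxies. A uniform AR(1) chain is available via
`region_geometry("uniform")`.

**Scenarios.** With sentinel dosage $G$, distal variant $G_2$, background
SNPs $G_k$, and independent Gaussian noise:

* mediation: $M = aG + \varepsilon_M$, $Y = bM + \sum\beta_k G_k + \varepsilon_Y$;
* reverse: $Y = dG + \sum\beta_k G_k + \varepsilon_Y$, $M = aG + cY + \varepsilon_M$ —
  the direct $dG$ term is what makes the variant trait-associated at all
  under this explanation (the variant acts on the trait through a
  non-methylation mechanism, and the trait feeds back on methylation);
* LD confounding: $M = aG + \varepsilon_M$, $Y = dG_2 + \sum\beta_k G_k + \varepsilon_Y$;
* pleiotropy: $M = aG + \varepsilon_M$, $Y = dG + \sum\beta_k G_k + \varepsilon_Y$.

Defaults: $a = 0.9$ SD/allele (strong cis effects of the kind that pass
$p<10^{-14}$ at a few thousand samples), $b = 0.3$, $c = 0.4$, $d = 0.27$
(so pleiotropy exactly mimics mediation's marginals, $d = ab$), MAF 0.3,
$n = 5{,}000$. The polygenic background (20 unlinked SNPs on a second
chromosome) is present in **every** scenario — a complex trait is polygenic
regardless of the local architecture — and doubles as the reverse-MR
instrument set. Its per-SNP effect, 0.15 SD/allele, is sized so background
SNPs reach genome-wide significance ($z \approx 6.3$) at the default sample
size, emulating GWAS-catalog instruments; smaller effects would leave the
reverse test without instruments at this $n$. Age and sex enter both M and
Y at 0.05 SD so covariate adjustment is exercised without being material.
M and Y are standardized after generation so effects are in SD units; the
pre-standardization scales are recorded in `truth` and the tests use them
to recover generative effects on their original scale.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: realistic recombination maps, allele
frequency spectra (all variants share one MAF), population structure and
relatedness, cell-type heterogeneity of blood methylation, trans-mQTL
networks, batch structure, non-Gaussian trait distributions, and the
winner's-curse geometry of instruments discovered and used in the same
sample.

## Numerical and design choices

* Seeds: one integer seed drives each generator call through a local RNG
  scope (`.Random.seed` is saved and restored), so package calls never
  perturb global random state and identical configurations are
  byte-reproducible, which the tests verify on written reports.
* Cholesky of the latent correlation gets a $10^{-10}$ jitter only if the
  exact factorization fails; positions are distinct so this is rare.
* Rank-normalization uses the Blom offset $(r - 3/8)/(n + 1/4)$; ties share
  average ranks; a constant vector maps to zeros with a warning.
* Clumping and BF ranking break ties by smaller p (or larger $|z|$), then
  smaller position, then lexicographic id — fully deterministic.
* Greedy LD clumping stands in for conditional-joint model selection: it
  reproduces the property actually consumed downstream
  (pairwise-independent sentinels) without needing a reference-panel joint
  model.
* Coordinates are 1-based inclusive; cis distance is $|pos_{SNP} -
  pos_{CpG}|$ on the same chromosome with the 1 Mb boundary included. BED
  tracks are converted on ingestion, and mixed `chr1`/`1` naming is
  normalized with a warning.
* A SNP with any significant trans-mQTL association is excluded from the
  instrument set entirely, even where it also has a stronger cis signal:
  variants acting on distant CpGs are more likely to tag independent
  pathways.
* Empirical p-values use add-one correction, so doubling iterations halves
  the attainable floor.

## Problem sizes used by the test suite

The packaged tests run the generator at the design size ($n = 5{,}000$;
200 seeds for parameter recovery, 100 seeds per scenario for end-to-end
classification) and smaller sizes ($n$ = 300–4,000) for structural checks;
enrichment resampling uses 2,000 iterations where the granularity floor
suffices. These sizes were chosen so the whole suite completes in a couple
of minutes while keeping every Monte-Carlo assertion's error bound explicit
(2–3 MC standard errors).

## Known limitations

* The 1-vs-4 ambiguity is fundamental to single-instrument cis MR; only
  multiple independent instruments per CpG (rare on current arrays) would
  lift it.
* The concordance statistic is rank-based and insensitive in small or
  ultra-dense regions; its 0.05 cut is a convention, not a calibrated test.
* The K-posterior enumerates at most two causal variants; regions with more
  will be summarized as $K = 2$.
* Reverse MR at realistic methylation sample sizes has modest power; an
  "unlikely" verdict is weak evidence of absence.
* Fixed-effect IVW assumes no heterogeneity across instruments; estimators
  that relax this (Egger, weighted median/mode) are out of scope here.
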
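# bundled published two-sample MR summary statistics (nine trait rows, eight
# eQTL rows) used by the replication tests
published_stats <- function() {
  read.delim(system.file("extdata", "replication_summary_stats.tsv",
                         package = "methmr"))
}

# small deterministic one-locus fixture for regression oracles
oracle_fixture <- function(n = 50, seed = 401) {
  g <- simulate_genotypes(n, 1, maf = 0.3, ld_rho = 0, seed = seed)$dosage[, 1]
  set.seed(seed + 1)
  age <- rnorm(n, 7.5, 0.15)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.4 * g + 0.05 * scale(age)[, 1] + rnorm(n)
  list(g = g, age = age, sex = sex, y = y,
       covars = data.frame(age = age, sex = sex))
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
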
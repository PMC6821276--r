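# Fixture builders used across the suite. Everything is generated in code;
# no data files are read from disk unless a test writes them first.

makeContinuousCohort <- function(mat, name = "TEST", source = "mRNA") {
  colnames(mat) <- colnames(mat) %||% sprintf("S%03d", seq_len(ncol(mat)))
  cohort(name, mat, data.frame(source = source, dtype = "continuous"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small cohort mixing all dtypes, deterministic
makeMixedCohort <- function(n = 40, seed = 7) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n))
  vals <- rbind(
    G1.RNA = rnorm(n), G2.RNA = rnorm(n),
    M1.Mut = rbinom(n, 1, 0.4), M2.Mut = rbinom(n, 1, 0.3),
    C1.GISTIC = sample(-2:2, n, replace = TRUE),
    OS.Survival = rexp(n, 0.01))
  colnames(vals) <- samples
  ev <- matrix(NA_real_, nrow(vals), n, dimnames = dimnames(vals))
  ev["OS.Survival", ] <- rbinom(n, 1, 0.6)
  info <- data.frame(
    source = c("mRNA", "mRNA", "Mutation", "Mutation", "CNV", "Survival"),
    dtype = c("continuous", "continuous", "binary", "binary", "ordinal",
              "survival"))
  cohort("MIX", vals, info, ev)
}

# construct two vectors of length n with EXACT sample correlation r
# (unit sample variance), for closed-form covariance fixtures
exactCorrPair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); y <- rnorm(n)
  x <- scale(x)[, 1]
  y <- scale(residuals(lm(y ~ x)))[, 1]
  cbind(x = x, y = r * x + sqrt(1 - r^2) * y)
}

expect_aligned <- function(ch) {
  v <- SummarizedExperiment::assay(ch, "values")
  expect_identical(colnames(v), sampleIds(ch))
}
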
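# hand-built RAM specs for closed-form checks
ramTwoVar <- function(freeCov = TRUE) {
  fm <- data.frame(matrix = c("S", "S", if (freeCov) "S"),
                   i = c(1L, 2L, if (freeCov) 1L),
                   j = c(1L, 2L, if (freeCov) 2L),
                   label = c("x~~x", "y~~y", if (freeCov) "x~~y"))
  new("RAMSpec", variables = c("x", "y"), nObserved = 2L,
      A = matrix(0, 2, 2), S = matrix(0, 2, 2), freeMap = fm,
      start = c(1, 1, if (freeCov) 0))
}

test_that("compilation counts free parameters by the RAM rules", {
  m <- matrix(rnorm(60), 3, dimnames = list(c("X.RNA", "Y.RNA", "Z.RNA"),
                                            NULL))
  ch <- makeContinuousCohort(m)
  g <- modelGraph(nodes = c("X.RNA", "Y.RNA"),
                  edges = data.frame(src = "X.RNA", dst = "Y.RNA",
                                     type = "regression"))
  comp <- compileGraph(g, ch)
  fm <- comp$ram@freeMap
  expect_equal(sum(fm$matrix == "A"), 1)  # one path
  expect_equal(sum(fm$matrix == "S"), 2)  # var(X), resid(Y)
  expect_equal(nFreeParameters(comp$ram), 3)
})

test_that("a 3-indicator factor compiles to the standard CFA parameter count", {
  set.seed(5)
  m <- matrix(rnorm(400), 4,
              dimnames = list(c("I1.RNA", "I2.RNA", "I3.RNA", "X.RNA"), NULL))
  ch <- makeContinuousCohort(m)
  g <- graphFromModelText("F =~ I1.RNA + I2.RNA + I3.RNA")
  # observed node ids equal variable ids here
  comp <- compileGraph(g, ch)
  fm <- comp$ram@freeMap
  expect_equal(sum(fm$matrix == "A"), 2)       # first loading fixed to 1
  expect_equal(comp$ram@A["I1.RNA", "F"], 1)
  expect_equal(sum(fm$matrix == "S" & fm$i == fm$j), 4) # 3 resid + factor var
  expect_equal(nFreeParameters(comp$ram), 6)   # saturated: df = 6 - 6 = 0
})

test_that("survival-only graphs are flagged and skipped by the compiler", {
  ch <- makeMixedCohort()
  g <- modelGraph(nodes = c("M1.Mut", "OS.Survival"),
                  edges = data.frame(src = "M1.Mut", dst = "OS.Survival",
                                     type = "regression"))
  comp <- compileGraph(g, ch)
  expect_null(comp$ram)
  expect_true(comp$survivalOnly)
})

test_that("implied covariance follows the RAM identity", {
  ram <- ramTwoVar()
  expect_equal(impliedCovariance(ram, c(2, 3, 0)), diag(c(2, 3)),
               ignore_attr = TRUE)
  # single path y = b x: Sigma = [[phi, b phi], [b phi, b^2 phi + psi]]
  fm <- data.frame(matrix = c("A", "S", "S"), i = c(2L, 1L, 2L),
                   j = c(1L, 1L, 2L), label = c("y~x", "x~~x", "y~~y"))
  ram2 <- new("RAMSpec", variables = c("x", "y"), nObserved = 2L,
              A = matrix(0, 2, 2), S = matrix(0, 2, 2), freeMap = fm,
              start = c(0.1, 1, 1))
  b <- 0.7; phi <- 2; psi <- 0.5
  expect_equal(impliedCovariance(ram2, c(b, phi, psi)),
               matrix(c(phi, b * phi, b * phi, b^2 * phi + psi), 2),
               ignore_attr = TRUE)
})

test_that("a stable 2-cycle matches the truncated path-series oracle", {
  fm <- data.frame(matrix = c("A", "A", "S", "S"), i = c(2L, 1L, 1L, 2L),
                   j = c(1L, 2L, 1L, 2L),
                   label = c("y~x", "x~y", "x~~x", "y~~y"))
  ram <- new("RAMSpec", variables = c("x", "y"), nObserved = 2L,
             A = matrix(0, 2, 2), S = matrix(0, 2, 2), freeMap = fm,
             start = c(0.1, 0.1, 1, 1))
  a <- 0.5; b <- 0.4
  theta <- c(a, b, 1, 1)
  A <- matrix(c(0, a, b, 0), 2, 2)   # A[2,1]=a (y~x), A[1,2]=b (x~y)
  # series oracle: (I-A)^-1 = sum_k A^k, truncated
  Bser <- diag(2)
  Ak <- diag(2)
  for (k in 1:200) { Ak <- Ak %*% A; Bser <- Bser + Ak }
  SigSer <- Bser %*% diag(2) %*% t(Bser)
  expect_equal(impliedCovariance(ram, theta), SigSer, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("ML discrepancy has its closed-form values and PD guards", {
  S <- diag(2)
  expect_equal(mlDiscrepancy(S, S), 0)
  Sr <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mlDiscrepancy(Sr, diag(2)), -log(0.75), tolerance = 1e-12)
  expect_equal(mlDiscrepancy(matrix(2), matrix(1)), 1 - log(2),
               tolerance = 1e-12)
  expect_error(mlDiscrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("just-identified regression reproduces least squares exactly", {
  set.seed(10)
  n <- 200
  x <- rnorm(n); y <- 0.8 * x + rnorm(n)
  m <- rbind(X.RNA = x, Y.RNA = y)
  ch <- makeContinuousCohort(m)
  g <- modelGraph(nodes = c("X.RNA", "Y.RNA"),
                  edges = data.frame(src = "X.RNA", dst = "Y.RNA",
                                     type = "regression"))
  comp <- compileGraph(g, ch)
  fit <- fitSem(comp$ram, comp$data)
  expect_true(fit@converged)
  slope <- cov(x, y) / var(x)
  expect_equal(fit@estimates$estimate[1], slope, tolerance = 1e-8)
  expect_lt(fit@indices$chisq, 1e-8)
  # saturated: implied covariance equals the sample covariance
  expect_equal(fit@impliedCov, fit@sampleCov, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_lt(fit@indices$fml, 1e-10)
})

test_that("acyclic single-response models equal the normal-equation oracle", {
  set.seed(11)
  n <- 300
  X <- matrix(rnorm(3 * n), n, 3)
  y <- X %*% c(0.5, -0.2, 0.3) + rnorm(n)
  m <- rbind(A.RNA = X[, 1], B.RNA = X[, 2], C.RNA = X[, 3], Y.RNA = y[, 1])
  ch <- makeContinuousCohort(m)
  g <- modelGraph(nodes = rownames(m),
                  edges = data.frame(src = c("A.RNA", "B.RNA", "C.RNA"),
                                     dst = "Y.RNA", type = "regression"))
  fit <- fitSem(compileGraph(g, ch)$ram, compileGraph(g, ch)$data)
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))[-1]
  est <- fit@estimates
  expect_equal(est$estimate[est$op == "~"], beta, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("CFA simulation recovers loadings within 3 reported SEs", {
  sim <- simulateCohort(simSpecDriverFactor(n = 2000), seed = 99)
  g <- graphFromModelText("CellCycle =~ CCNB1.RNA + PCNA.RNA + MKI67.RNA
                           CellCycle ~ Driver.Mut")
  res <- semFit(g, sim$cohort)
  est <- parameterTable(res)
  truth <- c("CellCycle=~PCNA.RNA" = 0.8, "CellCycle=~MKI67.RNA" = 0.6,
             "CellCycle~Driver.Mut" = 0.5)
  for (lab in names(truth)) {
    row <- est[paste0(est$lhs, est$op, est$rhs) == lab, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$estimate - truth[[lab]]), 3 * row$se)
  }
})

test_that("the independence baseline matches its closed form and an explicit fit", {
  xy <- exactCorrPair(101, 0.5)
  S <- cov(xy)
  bl <- baselineChisq(S, 101)
  expect_equal(bl$chisq, -100 * log(0.75), tolerance = 1e-9)
  expect_equal(bl$df, 1)
  expect_equal(baselineChisq(diag(3), 50)$chisq, 0)
  # self-consistency: equals fitSem on a variances-only RAMSpec
  ram0 <- ramTwoVar(freeCov = FALSE)
  colnames(xy) <- c("x", "y")
  fit0 <- fitSem(ram0, xy)
  expect_equal(fit0@indices$chisq, bl$chisq, tolerance = 1e-6)
})

test_that("fit indices follow their definitions", {
  # chisq_b/df_b = 10 and chisq_m/df_m = 1 give TLI exactly 1
  idx <- fitIndices(chisqM = 5, dfM = 5, chisqB = 100, dfB = 10, n = 101,
                    sampleCov = diag(2), implied = diag(2))
  expect_equal(idx$TLI, 1)
  expect_equal(idx$SRMR, 0)
  # RMSEA closed form
  idx2 <- fitIndices(50, 10, 500, 20, 101, diag(2), diag(2))
  expect_equal(idx2$RMSEA, sqrt(40 / 1000))
  # zero model df: ratio indices not applicable
  idx3 <- fitIndices(0, 0, 100, 10, 101, diag(2), diag(2))
  expect_true(is.na(idx3$TLI) && is.na(idx3$RMSEA))
  expect_equal(idx3$CFI, 1)
})

test_that("chisq and indices are invariant to sample order; SRMR to rescaling", {
  sim <- simulateCohort(simSpecDriverFactor(n = 300), seed = 21)
  g <- graphFromModelText("CellCycle =~ CCNB1.RNA + PCNA.RNA + MKI67.RNA
                           CellCycle ~ Driver.Mut")
  comp <- compileGraph(g, sim$cohort)
  fit <- fitSem(comp$ram, comp$data)
  perm <- comp$data[sample(nrow(comp$data)), ]
  fitP <- fitSem(comp$ram, perm)
  for (k in c("chisq", "TLI", "CFI", "RMSEA", "SRMR"))
    expect_equal(fitP@indices[[k]], fit@indices[[k]], tolerance = 1e-6)
  # per-variable rescaling leaves SRMR unchanged (correlation metric)
  sc <- comp$data %*% diag(c(10, 0.2, 3, 5))
  colnames(sc) <- colnames(comp$data)
  comp2 <- comp
  # refit with rescaled data but identical structure
  fitS <- fitSem(comp$ram, sc)
  expect_equal(fitS@indices$SRMR, fit@indices$SRMR, tolerance = 1e-5)
})

test_that("effect decomposition traces paths and respects stability", {
  fm <- data.frame(matrix = c("A", "A", "A", "S", "S", "S"),
                   i = c(2L, 3L, 3L, 1L, 2L, 3L),
                   j = c(1L, 2L, 1L, 1L, 2L, 3L),
                   label = c("m~x", "y~m", "y~x", "x~~x", "m~~m", "y~~y"))
  ram <- new("RAMSpec", variables = c("x", "m", "y"), nObserved = 3L,
             A = matrix(0, 3, 3), S = matrix(0, 3, 3), freeMap = fm,
             start = rep(1, 6))
  dec <- effectDecomposition(ram, c(0.5, 0.4, 0.1, 1, 1, 1), "x", "y")
  expect_equal(dec$direct, 0.1)
  expect_equal(dec$indirect, 0.2)
  expect_equal(dec$total, 0.3)
  expect_identical(dec$direct + dec$indirect, dec$total)
  # no path: all zero
  dec0 <- effectDecomposition(ram, c(0, 0.4, 0, 1, 1, 1), "x", "y")
  expect_equal(unlist(dec0), c(direct = 0, indirect = 0, total = 0))
  # 2-cycle geometric series
  fm2 <- data.frame(matrix = c("A", "A", "S", "S"), i = c(2L, 1L, 1L, 2L),
                    j = c(1L, 2L, 1L, 2L),
                    label = c("y~x", "x~y", "x~~x", "y~~y"))
  ram2 <- new("RAMSpec", variables = c("x", "y"), nObserved = 2L,
              A = matrix(0, 2, 2), S = matrix(0, 2, 2), freeMap = fm2,
              start = rep(1, 4))
  dec2 <- effectDecomposition(ram2, c(0.5, 0.4, 1, 1), "x", "y")
  expect_equal(dec2$total, 0.5 / (1 - 0.2))
  expect_error(effectDecomposition(ram2, c(1.2, 1.1, 1, 1), "x", "y"),
               "unstable")
})

test_that("factor scores are linear, centered, and symmetric in equal loadings", {
  sim <- simulateCohort(simSpecDriverFactor(n = 400, loadings = c(1, 1, 1)),
                        seed = 31)
  g <- graphFromModelText("CellCycle =~ CCNB1.RNA + PCNA.RNA + MKI67.RNA")
  comp <- compileGraph(g, sim$cohort)
  fit <- fitSem(comp$ram, comp$data)
  sc <- factorScores(fit, comp$data)
  expect_equal(mean(sc[, "CellCycle"]), 0, tolerance = 1e-10)
  # exactly equal loadings and residuals: scores proportional to the
  # indicator mean (fix all measurement parameters, leave the factor
  # variance free)
  A <- matrix(0, 4, 4); A[1:3, 4] <- 1
  S <- diag(c(1, 1, 1, 0))
  fmE <- data.frame(matrix = "S", i = 4L, j = 4L, label = "F~~F")
  ramE <- new("RAMSpec", variables = c(colnames(comp$data), "F"),
              nObserved = 3L, A = A, S = S, freeMap = fmE, start = 1)
  fitE <- fitSem(ramE, comp$data)
  scE <- factorScores(fitE, comp$data)
  im <- rowMeans(comp$data)
  expect_equal(cor(scE[, "F"], im), 1, tolerance = 1e-10)
  # degenerate single indicator with loading 1 and zero residual variance
  fmD <- data.frame(matrix = "S", i = 2L, j = 2L, label = "F~~F")
  A <- matrix(c(0, 0, 1, 0), 2, 2)   # y <- F loading 1
  ramD <- new("RAMSpec", variables = c("y", "F"), nObserved = 1L,
              A = A, S = matrix(0, 2, 2), freeMap = fmD, start = 1)
  y <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "y"))
  fitD <- fitSem(ramD, y)
  scD <- factorScores(fitD, y)
  expect_equal(scD[, "F"], y[, 1] - mean(y[, 1]), tolerance = 1e-6)
})

test_that("multi-cohort fits give per-cohort rows and monotone dose response", {
  cohorts <- lapply(c(0, 0.3, 0.6), function(b) {
    sim <- simulateCohort(
      simSpec(500, continuous = c("X.RNA", "Y.RNA"),
              paths = data.frame(src = "X.RNA", dst = "Y.RNA", coef = b)),
      seed = 100 + round(b * 10), name = sprintf("EFF%.1f", b))
    sim$cohort
  })
  g <- modelGraph(nodes = c("X.RNA", "Y.RNA"),
                  edges = data.frame(src = "X.RNA", dst = "Y.RNA",
                                     type = "regression"))
  mc <- fitMultiCohort(g, cohorts)
  tb <- mc$table
  zz <- tb$z[tb$op == "~" & tb$rhs == "X.RNA"]
  expect_equal(length(zz), 3)
  expect_true(all(diff(zz) > 0))  # z grows with the simulated effect
  # same cohort twice gives identical rows
  mc2 <- fitMultiCohort(g, list(cohorts[[2]], cohorts[[2]]))
  expect_equal(mc2$table$estimate[mc2$table$cohort == "EFF0.3"],
               mc2$table$estimate[mc2$table$cohort == "EFF0.3"])
  half <- mc2$table[, setdiff(names(mc2$table), "cohort")]
  expect_equal(half[seq_len(nrow(half) / 2), ],
               half[-seq_len(nrow(half) / 2), ], ignore_attr = TRUE)
  # cohorts lacking a node are skipped with a warning
  g2 <- modelGraph(nodes = c("X.RNA", "NOPE.RNA"),
                   edges = data.frame(src = "X.RNA", dst = "NOPE.RNA",
                                      type = "regression"))
  expect_warning(mc3 <- fitMultiCohort(g2, cohorts[1]), "skipped")
  expect_null(mc3$table)
})

test_that("non-identified models error before optimization", {
  m <- matrix(rnorm(40), 2, dimnames = list(c("X.RNA", "Y.RNA"), NULL))
  ch <- makeContinuousCohort(m)
  g <- modelGraph(nodes = c("X.RNA", "Y.RNA"),
                  edges = data.frame(src = c("X.RNA", "X.RNA"),
                                     dst = c("Y.RNA", "Y.RNA"),
                                     type = c("regression", "covariance")))
  comp <- compileGraph(g, ch)
  expect_error(fitSem(comp$ram, comp$data), "not identified")
})
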
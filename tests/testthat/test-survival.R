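test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # censoring shrinks the risk set without an event step
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)
  # all censored: survival stays at 1
  km3 <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
})

test_that("KM curves start at 1, are non-increasing, and equal the ECDF without censoring", {
  set.seed(4)
  tt <- rexp(60, 0.1)
  km <- kmEstimate(tt, rep(1, 60))
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  # no censoring: product-limit == empirical survival function
  ecdfS <- sapply(km$time, function(t0) mean(tt > t0))
  expect_equal(km$survival, ecdfS)
})

test_that("log-rank is zero for identical groups and matches a permutation oracle", {
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(1, 8)
  gr <- rep(c("a", "b"), each = 4)
  res <- logrankTest(tt, ev, gr)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_error(logrankTest(tt, ev, rep("a", 8)), "2 groups")
  # group relabeling leaves the statistic unchanged
  res2 <- logrankTest(tt, ev, c("b", "a")[match(gr, c("a", "b"))])
  expect_equal(res2$statistic, res$statistic)
  # exact permutation oracle over all 8!/(4!4!) = 70 label assignments
  set.seed(8)
  tt <- c(2, 5, 7, 9, 1, 3, 4, 12)
  ev <- c(1, 1, 0, 1, 1, 1, 1, 0)
  obs <- logrankTest(tt, ev, gr)$statistic
  combos <- combn(8, 4)
  perms <- apply(combos, 2, function(ix) {
    g <- rep("b", 8); g[ix] <- "a"
    logrankTest(tt, ev, g)$statistic
  })
  permP <- mean(perms >= obs - 1e-12)
  # chi-square p and exact permutation p agree within small-sample error
  expect_lt(abs(logrankTest(tt, ev, gr)$p - permP), 0.2)
})

test_that("Cox estimation matches a dense grid search of the partial likelihood", {
  tt <- c(2, 4, 5, 7, 9, 11)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- coxFit(tt, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  # Breslow log partial likelihood on a beta grid
  lpl <- function(b) {
    ord <- order(tt)
    t0 <- tt[ord]; e0 <- ev[ord]; x0 <- x[ord]
    sum(sapply(which(e0 == 1), function(i) {
      risk <- which(t0 >= t0[i])
      b * x0[i] - log(sum(exp(b * x0[risk])))
    }))
  }
  grid <- seq(-4, 4, by = 1e-4)
  bhat <- grid[which.max(sapply(grid, lpl))]
  expect_lt(abs(fit$table$estimate - bhat), 1e-3)
})

test_that("Cox is invariant to covariate shifts, inverse to scaling, and Breslow-stable under duplication", {
  set.seed(12)
  n <- 120
  x <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(0.5 * x))
  ev <- rbinom(n, 1, 0.8)
  b0 <- coxFit(tt, ev, cbind(x = x))$table$estimate
  bShift <- coxFit(tt, ev, cbind(x = x + 100))$table$estimate
  expect_equal(bShift, b0, tolerance = 1e-6)
  bScale <- coxFit(tt, ev, cbind(x = 2 * x))$table$estimate
  expect_equal(bScale, b0 / 2, tolerance = 1e-6)
  # doubling every record (creating ties) leaves the Breslow estimate fixed
  bDup <- coxFit(rep(tt, 2), rep(ev, 2), cbind(x = rep(x, 2)))$table$estimate
  expect_equal(bDup, b0, tolerance = 1e-6)
})

test_that("a covariate independent of outcome is rarely significant", {
  hits <- 0
  for (r in 1:40) {
    set.seed(1000 + r)
    n <- 300
    tt <- rexp(n, 0.02)
    ev <- rbinom(n, 1, 0.7)
    x <- rnorm(n)  # independent of (tt, ev) by construction
    z <- coxFit(tt, ev, cbind(x = x))$table$z
    if (abs(z) >= 3) hits <- hits + 1
  }
  expect_lte(hits / 40, 0.01 + 0.05)  # |z|>=3 ~ p<0.0027 under the null
})

test_that("survival edges fit one Cox model per node with all parents", {
  sim <- simulateCohort(simSpecDriverFactor(n = 600), seed = 51)
  g1 <- graphFromModelText("OS.Survival ~ Driver.Mut")
  s1 <- survivalLinkEstimates(g1, sim$cohort)
  sd <- survivalData(sim$cohort)
  direct <- coxFit(sd$time, sd$event,
                   cbind(Driver.Mut = variableValues(sim$cohort,
                                                     "Driver.Mut")))
  expect_equal(s1$estimate, direct$table$estimate, tolerance = 1e-10)
  expect_identical(s1$lhs, "OS.Survival")
  # latent parent enters through factor scores
  g2 <- graphFromModelText("CellCycle =~ CCNB1.RNA + PCNA.RNA + MKI67.RNA
                            CellCycle ~ Driver.Mut
                            OS.Survival ~ CellCycle + Driver.Mut")
  res <- semFit(g2, sim$cohort)
  sv <- res$survival
  expect_setequal(sv$rhs, c("CellCycle", "Driver.Mut"))
  expect_gt(sv$z[sv$rhs == "CellCycle"], 2)  # factor carries the hazard
})

test_that("mediation: adjusting for the mediator abolishes the driver's direct effect", {
  sim <- simulateCohort(simSpecMediation(n = 1000), seed = 61)
  ch <- sim$cohort
  unadj <- survivalLinkEstimates(
    graphFromModelText("OS.Survival ~ Driver.Mut"), ch)
  adj <- survivalLinkEstimates(
    graphFromModelText("Mediator.RNA ~ Driver.Mut
                        OS.Survival ~ Driver.Mut + Mediator.RNA"), ch)
  pU <- unadj$p[unadj$rhs == "Driver.Mut"]
  pA <- adj$p[adj$rhs == "Driver.Mut"]
  expect_lt(pU, 0.01)
  expect_gt(pA, 0.05)
  expect_lt(abs(adj$z[adj$rhs == "Driver.Mut"]),
            abs(unadj$z[unadj$rhs == "Driver.Mut"]))
})

test_that("confounding: controlling for a co-occurring alteration attenuates the driver", {
  sim <- simulateCohort(simSpecConfounder(n = 1000), seed = 71)
  ch <- sim$cohort
  unadj <- survivalLinkEstimates(
    graphFromModelText("OS.Survival ~ Driver.Mut"), ch)
  adj <- survivalLinkEstimates(
    graphFromModelText("OS.Survival ~ Driver.Mut + Conf.Mut"), ch)
  zU <- unadj$z[unadj$rhs == "Driver.Mut"]
  zA <- adj$z[adj$rhs == "Driver.Mut"]
  expect_lt(abs(zA), abs(zU))
})

test_that("median split stratifies factor scores into KM-ready groups", {
  expect_identical(medianSplit(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_error(medianSplit(c(2, 2, 2)), "distinct")
  set.seed(9)
  v <- rnorm(101)
  sp <- medianSplit(v)
  expect_lte(abs(sum(sp == "low") - sum(sp == "high")), 1)
  # end to end: factor scores -> median split -> two KM curves
  sim <- simulateCohort(simSpecDriverFactor(n = 300), seed = 81)
  g <- graphFromModelText("CellCycle =~ CCNB1.RNA + PCNA.RNA + MKI67.RNA")
  comp <- compileGraph(g, sim$cohort)
  fit <- fitSem(comp$ram, comp$data)
  sc <- factorScores(fit, comp$data)[, "CellCycle"]
  sd <- survivalData(sim$cohort)
  km <- kmEstimate(sd$time, sd$event, medianSplit(sc))
  expect_setequal(unique(km$group), c("low", "high"))
  for (gset in split(km, km$group))
    expect_true(all(diff(gset$survival) <= 0))
})
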
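test_that("perfect correlation caps z at 38 and identical groups give z = 0", {
  n <- 20
  x <- rnorm(n)
  vals <- rbind(X.RNA = x, Y.RNA = 2 * x,
                M.Mut = rep(c(0, 1), each = n / 2),
                FLATDIFF.RNA = rep(c(1, 2), n / 2))
  colnames(vals) <- sprintf("S%02d", 1:n)
  ch <- cohort("T", vals, data.frame(
    source = c("mRNA", "mRNA", "Mutation", "mRNA"),
    dtype = c("continuous", "continuous", "binary", "continuous")))
  r <- pairwiseAssociation(ch, "X.RNA", "Y.RNA")
  expect_identical(r$stat, "pearson")
  expect_equal(r$estimate, 1)
  expect_equal(r$z, 38)
  # binary groups with identical continuous means
  r2 <- pairwiseAssociation(ch, "M.Mut", "FLATDIFF.RNA")
  expect_identical(r2$stat, "point_biserial")
  expect_equal(r2$z, 0, tolerance = 1e-12)
})

test_that("binary-binary association is the Haldane-corrected log odds ratio", {
  a <- rep(c(1, 0), each = 10)
  b <- rep(c(1, 0), each = 10)   # table [[10,0],[0,10]]: perfect co-occurrence
  vals <- rbind(A.Mut = a, B.Mut = b)
  colnames(vals) <- sprintf("S%02d", 1:20)
  ch <- cohort("T", vals, data.frame(source = "Mutation", dtype = "binary"))
  r <- pairwiseAssociation(ch, "A.Mut", "B.Mut")
  expect_identical(r$stat, "log_odds_ratio")
  expect_equal(r$estimate, log(10.5^2 / 0.5^2), tolerance = 1e-12)
  expect_gt(r$z, 0)  # co-occurrence is positive
  # mutual exclusivity flips the sign
  vals2 <- rbind(A.Mut = a, B.Mut = 1 - b)
  colnames(vals2) <- colnames(vals)
  ch2 <- cohort("T", vals2, data.frame(source = "Mutation", dtype = "binary"))
  expect_lt(pairwiseAssociation(ch2, "A.Mut", "B.Mut")$z, 0)
})

test_that("association against survival uses the Cox Wald z", {
  sim <- simulateCohort(simSpecMediation(n = 400), seed = 14)
  r <- pairwiseAssociation(sim$cohort, "Mediator.RNA", "OS.Survival")
  expect_identical(r$stat, "cox_wald")
  sd <- survivalData(sim$cohort)
  direct <- coxFit(sd$time, sd$event,
                   cbind(x = variableValues(sim$cohort, "Mediator.RNA")))
  expect_equal(r$estimate, direct$table$estimate, tolerance = 1e-10)
  expect_gt(r$z, 2)
})

test_that("association is symmetric in |z| for the symmetric statistics", {
  ch <- makeMixedCohort(n = 60, seed = 15)
  for (pair in list(c("G1.RNA", "G2.RNA"), c("M1.Mut", "M2.Mut"),
                    c("M1.Mut", "G1.RNA"), c("C1.GISTIC", "G2.RNA"))) {
    ab <- pairwiseAssociation(ch, pair[1], pair[2])
    ba <- pairwiseAssociation(ch, pair[2], pair[1])
    expect_equal(abs(ab$z), abs(ba$z), tolerance = 1e-12)
  }
})

test_that("zero-variance candidates yield NA records that count in the FDR denominator", {
  vals <- rbind(X.RNA = rnorm(10), FLAT.RNA = rep(1, 10), Y.RNA = rnorm(10))
  colnames(vals) <- sprintf("S%02d", 1:10)
  ch <- cohort("T", vals, data.frame(source = "mRNA", dtype = "continuous"))
  sc <- screenVariable(ch, "X.RNA")
  expect_equal(nrow(sc), 2)
  expect_true(is.na(sc$z[sc$candidate == "FLAT.RNA"]))
  # BH denominator includes the degenerate test
  pY <- sc$p[sc$candidate == "Y.RNA"]
  expect_equal(sc$q[sc$candidate == "Y.RNA"], min(pY * 2, 1))
})

test_that("screening equals the brute-force pairwise loop with identical ranking", {
  ch <- makeMixedCohort(n = 50, seed = 16)
  sc <- screenVariable(ch, "M1.Mut", includeSurvival = TRUE)
  cand <- setdiff(variableIds(ch), "M1.Mut")
  brute <- do.call(rbind, lapply(
    setdiff(cand, "OS.Survival"),
    function(cc) pairwiseAssociation(ch, "M1.Mut", cc)))
  brute <- rbind(brute, pairwiseAssociation(ch, "M1.Mut", "OS.Survival"))
  brute$q <- bhFdr(brute$p, nTests = nrow(brute))
  brute <- brute[order(-abs(brute$z), brute$candidate, na.last = TRUE), ]
  expect_equal(sc, brute, ignore_attr = TRUE)
  expect_false("M1.Mut" %in% sc$candidate)
})

test_that("BH adjustment matches hand computation and preserves order", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.04, 0.001, 0.3)
  q <- bhFdr(p)
  expect_identical(order(p), order(q))
})

test_that("compound screens intersect includes and honor exclusions", {
  set.seed(17)
  n <- 200
  a <- rnorm(n)
  hit <- a + rnorm(n, 0, 0.5)      # associated with both seeds
  onlyA <- a + rnorm(n, 0, 0.5)
  b <- a + rnorm(n, 0, 0.5)
  vals <- rbind(SeedA.RNA = a, SeedB.RNA = b, HIT.RNA = hit,
                ONLYA.RNA = onlyA, NOISE.RNA = rnorm(n))
  colnames(vals) <- sprintf("S%03d", 1:n)
  ch <- cohort("T", vals, data.frame(source = "mRNA", dtype = "continuous"))
  sa <- screenVariable(ch, "SeedA.RNA")
  sb <- screenVariable(ch, "SeedB.RNA")
  both <- compoundScreen(list(sa, sb), q = 0.05)
  expect_true("HIT.RNA" %in% both$candidate)
  expect_false("NOISE.RNA" %in% both$candidate)
  # excluding the A-screen's hits empties the A-correlated candidates
  excl <- compoundScreen(list(sb), exclude = list(sa), q = 0.05)
  expect_false("HIT.RNA" %in% excl$candidate)
})

test_that("precompute-then-query equals the on-the-fly screen", {
  ch <- makeMixedCohort(n = 50, seed = 18)
  store <- file.path(tempdir(), "pairstore-test")
  unlink(store, recursive = TRUE)
  precomputeStore(ch, store, chunkSize = 7L)  # force several chunks
  direct <- screenVariable(ch, "G1.RNA", includeSurvival = TRUE)
  viaStore <- queryTop(store, "G1.RNA", k = Inf)
  expect_equal(viaStore[, c("candidate", "stat", "estimate", "z", "p", "q")],
               direct[, c("candidate", "stat", "estimate", "z", "p", "q")],
               ignore_attr = TRUE, tolerance = 1e-12)
  # repeated queries are identical (pure function of the store)
  expect_identical(queryTop(store, "G1.RNA", k = 3),
                   queryTop(store, "G1.RNA", k = 3))
  # k beyond the store returns everything; q filter returns a subset
  expect_lte(nrow(queryTop(store, "G1.RNA", k = Inf, maxQ = 0.05)),
             nrow(viaStore))
  # version guard
  mf <- file.path(store, "manifest.json")
  m <- jsonlite::fromJSON(mf)
  m$version <- 999
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  expect_error(queryTop(store, "G1.RNA"), "version")
})

test_that("a global-null screen controls the false discovery rate", {
  set.seed(19)
  n <- 300; k <- 200
  vals <- rbind(SEED.RNA = rnorm(n),
                matrix(rnorm(n * k), k,
                       dimnames = list(sprintf("N%03d.RNA", 1:k), NULL)))
  colnames(vals) <- sprintf("S%03d", 1:n)
  ch <- cohort("NULL", vals, data.frame(source = "mRNA",
                                        dtype = "continuous"))
  sc <- screenVariable(ch, "SEED.RNA")
  fdr <- mean(sc$q < 0.05, na.rm = TRUE)
  expect_lte(fdr, 0.05 + 3 * sqrt(0.05 * 0.95 / k))
})
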
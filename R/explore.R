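#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment with monotonicity enforcement; the returned q-values
#' are order-aligned with the input. \code{nTests} lets a screen count
#' degenerate (untestable) candidates in the denominator, which is the
#' conservative choice.
#'
#' @param p p-values in [0, 1] (NA allowed, returned as NA)
#' @param nTests denominator for the adjustment (defaults to
#'   \code{length(p)} counting NAs)
#' @return q-values, \code{q >= p} elementwise
#' @export
bhFdr <- function(p, nTests = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH", n = max(nTests, sum(!is.na(p))))
}

.Z_CAP <- 38  # beyond double-precision p underflow; keeps rankings finite

.capZ <- function(z) {
  ifelse(is.na(z), NA_real_, sign(z) * pmin(abs(z), .Z_CAP))
}

.assocRecord <- function(seed, candidate, kind, estimate, z, p, n) {
  data.frame(seed = seed, candidate = candidate, stat = kind,
             estimate = estimate, z = z, p = p, q = NA_real_, n_used = n,
             row.names = NULL)
}

# numeric coding for association statistics: binary/two-level categoricals
# as 0/1, ordinal as its integer code; NULL for unsupported dtypes
.assocNumeric <- function(x, id) {
  dt <- variableInfo(x)$dtype[match(id, variableIds(x))]
  v <- variableValues(x, id)
  switch(dt,
         continuous = v, ordinal = v, binary = v,
         categorical = {
           labs <- variableLabels(x, id)
           if (length(labs) != 2) NULL else v - 1
         },
         NULL)
}

.isBinaryLike <- function(x, id) {
  dt <- variableInfo(x)$dtype[match(id, variableIds(x))]
  dt == "binary" ||
    (dt == "categorical" && length(variableLabels(x, id)) == 2)
}

#' Association between two cohort variables
#'
#' Dispatch by data-type pair, mirroring how an all-against-all correlation
#' resource must mix statistics across omics layers:
#' \itemize{
#'   \item continuous/continuous (and ordinal, on its integer code):
#'     Pearson r; z is the t-statistic
#'     \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.
#'   \item binary/continuous: point-biserial correlation (the pooled
#'     two-sample t), signed so positive means higher values in the
#'     1/"Mutant" group.
#'   \item binary/binary: log odds ratio with the Haldane-Anscombe 0.5
#'     correction and Woolf standard error; positive z = co-occurrence,
#'     negative = mutual exclusivity.
#'   \item anything/survival: Wald z of a univariate Cox model.
#' }
#' |z| is capped at 38 so perfect associations stay rankable. A
#' zero-variance side yields a record with missing statistics (still
#' counted by the screen's FDR denominator).
#'
#' @param x a \linkS4class{Cohort}
#' @param seedId,candidateId variable ids (either may be the survival
#'   variable)
#' @return one-row data.frame: seed, candidate, stat, estimate, z, p, q
#'   (NA here; filled by \code{\link{screenVariable}}), n_used
#' @export
pairwiseAssociation <- function(x, seedId, candidateId) {
  info <- variableInfo(x)
  dts <- structure(info$dtype, names = info$id)
  for (id in c(seedId, candidateId))
    if (!id %in% info$id) stop(sprintf("unknown variable '%s'", id))
  survSide <- c(dts[[seedId]], dts[[candidateId]]) == "survival"
  if (all(survSide)) stop("cannot associate two survival variables")
  if (any(survSide)) {
    survId <- if (survSide[1]) seedId else candidateId
    otherId <- if (survSide[1]) candidateId else seedId
    v <- .assocNumeric(x, otherId)
    if (is.null(v))
      return(.assocRecord(seedId, candidateId, "cox_wald",
                          NA_real_, NA_real_, NA_real_, 0L))
    sd <- survivalData(x, survId)
    keep <- !(is.na(v) | is.na(sd$time) | is.na(sd$event))
    n <- sum(keep)
    if (n < 3 || length(unique(v[keep])) < 2 || sum(sd$event[keep]) < 1)
      return(.assocRecord(seedId, candidateId, "cox_wald",
                          NA_real_, NA_real_, NA_real_, n))
    cf <- tryCatch(coxFit(sd$time[keep], sd$event[keep],
                          matrix(v[keep], ncol = 1,
                                 dimnames = list(NULL, otherId))),
                   error = function(e) NULL)
    if (is.null(cf))
      return(.assocRecord(seedId, candidateId, "cox_wald",
                          NA_real_, NA_real_, NA_real_, n))
    z <- .capZ(cf$table$z[1])
    return(.assocRecord(seedId, candidateId, "cox_wald",
                        cf$table$estimate[1], z,
                        2 * stats::pnorm(-abs(z)), n))
  }
  a <- .assocNumeric(x, seedId); b <- .assocNumeric(x, candidateId)
  if (is.null(a) || is.null(b))
    return(.assocRecord(seedId, candidateId, "unsupported",
                        NA_real_, NA_real_, NA_real_, 0L))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]; n <- length(a)
  binA <- .isBinaryLike(x, seedId); binB <- .isBinaryLike(x, candidateId)
  if (n < 3 || stats::var(a) == 0 || stats::var(b) == 0) {
    kind <- if (binA && binB) "log_odds_ratio" else
      if (binA || binB) "point_biserial" else "pearson"
    return(.assocRecord(seedId, candidateId, kind,
                        NA_real_, NA_real_, NA_real_, n))
  }
  if (binA && binB) {
    # Haldane-Anscombe corrected 2x2; positive = co-occurrence
    n11 <- sum(a == 1 & b == 1) + 0.5
    n10 <- sum(a == 1 & b == 0) + 0.5
    n01 <- sum(a == 0 & b == 1) + 0.5
    n00 <- sum(a == 0 & b == 0) + 0.5
    logOR <- log(n11 * n00 / (n10 * n01))
    se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
    z <- .capZ(logOR / se)
    return(.assocRecord(seedId, candidateId, "log_odds_ratio",
                        logOR, z, 2 * stats::pnorm(-abs(z)), n))
  }
  kind <- if (binA || binB) "point_biserial" else "pearson"
  r <- stats::cor(a, b)
  if (abs(r) >= 1) {
    z <- .capZ(sign(r) * Inf)
    return(.assocRecord(seedId, candidateId, kind, r, z, 0, n))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  z <- .capZ(tstat)
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  .assocRecord(seedId, candidateId, kind, r, z, p, n)
}

#' Screen one variable against the rest of a cohort
#'
#' All-against-one association scan: the seed is tested against every
#' candidate of the requested source types (optionally plus the survival
#' endpoint), p-values are BH-adjusted over the whole run (degenerate
#' candidates count in the denominator), and records are ranked by |z|
#' (descending, ties broken by candidate id).
#'
#' @param x a \linkS4class{Cohort}
#' @param seedId seed variable id
#' @param types source filter, e.g. \code{c("Mutation", "CNV", "mRNA")};
#'   NULL = all non-survival sources
#' @param includeSurvival also test the survival endpoint
#' @param excludeSameGene drop candidates sharing the seed's gene symbol
#'   (the "<GENE>." prefix)
#' @return data.frame of \code{\link{pairwiseAssociation}} records with q
#'   filled, ranked
#' @export
screenVariable <- function(x, seedId, types = NULL, includeSurvival = FALSE,
                           excludeSameGene = FALSE) {
  info <- variableInfo(x)
  cand <- info$id[info$dtype != "survival" & info$id != seedId]
  if (!is.null(types))
    cand <- cand[info$source[match(cand, info$id)] %in% types]
  if (excludeSameGene) {
    gene <- sub("\\..*$", "", seedId)
    cand <- cand[sub("\\..*$", "", cand) != gene]
  }
  if (includeSurvival) cand <- c(cand, survivalIds(x))
  if (!length(cand)) stop("empty candidate set")
  recs <- do.call(rbind, lapply(cand, function(cc)
    pairwiseAssociation(x, seedId, cc)))
  recs$q <- bhFdr(recs$p, nTests = nrow(recs))
  recs[order(-abs(recs$z), recs$candidate, na.last = TRUE), , drop = FALSE]
}

#' Intersect screens with include/exclude q-value conditions
#'
#' Reproduces compound exploratory queries of the form "candidates
#' significantly associated with seed A AND seed B but NOT with seed C":
#' a candidate passes when its q-value is below \code{q} in every
#' \code{include} screen and at or above \code{q} in every \code{exclude}
#' screen.
#'
#' @param include list of screen results (data.frames from
#'   \code{\link{screenVariable}})
#' @param exclude optional list of screens a passing candidate must NOT be
#'   significant in
#' @param q significance threshold on the BH q-value
#' @return data.frame of passing candidates with per-screen z and q columns
#' @export
compoundScreen <- function(include, exclude = list(), q = 0.05) {
  stopifnot(length(include) >= 1)
  sig <- function(s) s$candidate[!is.na(s$q) & s$q < q]
  pass <- Reduce(intersect, lapply(include, sig))
  for (s in exclude) pass <- setdiff(pass, sig(s))
  out <- data.frame(candidate = sort(pass))
  for (k in seq_along(include)) {
    s <- include[[k]]
    m <- match(out$candidate, s$candidate)
    out[[paste0("z_", s$seed[1])]] <- s$z[m]
    out[[paste0("q_", s$seed[1])]] <- s$q[m]
  }
  out
}

#' Precompute an all-against-all association store
#'
#' Computes every unordered pair of variables of the requested source
#' types (optionally every variable against the survival endpoint) in
#' chunks, and writes a columnar store: a \code{manifest.json} index plus
#' chunked TSV column files. The same code path serves a unit-test fixture
#' and a full cohort — only the chunk count grows.
#'
#' @param x a \linkS4class{Cohort}
#' @param path store directory (created; must not already hold a store of
#'   another version)
#' @param types source filter (NULL = all non-survival)
#' @param includeSurvival also store variable-vs-survival records
#' @param chunkSize pair records per chunk file
#' @return invisibly, the manifest list
#' @export
precomputeStore <- function(x, path, types = NULL, includeSurvival = TRUE,
                            chunkSize = 50000L) {
  info <- variableInfo(x)
  ids <- info$id[info$dtype != "survival"]
  if (!is.null(types)) ids <- ids[info$source[match(ids, info$id)] %in% types]
  ids <- sort(ids)
  if (length(ids) < 2) stop("need at least two variables to precompute")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pairs <- utils::combn(ids, 2)
  if (includeSurvival && length(survivalIds(x)))
    pairs <- cbind(pairs, rbind(ids, rep(survivalIds(x)[1], length(ids))))
  nPairs <- ncol(pairs)
  chunkFiles <- character()
  buf <- list()
  flush <- function() {
    if (!length(buf)) return(invisible())
    ck <- sprintf("chunk-%03d.tsv", length(chunkFiles))
    df <- do.call(rbind, buf)
    utils::write.table(df, file.path(path, ck), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    chunkFiles <<- c(chunkFiles, ck)
    buf <<- list()
  }
  for (k in seq_len(nPairs)) {
    buf[[length(buf) + 1L]] <-
      pairwiseAssociation(x, pairs[1, k], pairs[2, k])
    if (length(buf) >= chunkSize) flush()
  }
  flush()
  manifest <- list(format = "pairstore", version = 1L,
                   cohort = cohortName(x), n_samples = ncol(x),
                   types = types %||% "all", n_pairs = nPairs,
                   survival = includeSurvival, chunks = chunkFiles)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.readStore <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no store manifest at ", path)
  manifest <- jsonlite::fromJSON(mf)
  if (!identical(manifest$format, "pairstore") || manifest$version != 1L)
    stop("store format/version mismatch")
  recs <- do.call(rbind, lapply(manifest$chunks, function(ck)
    utils::read.delim(file.path(path, ck), sep = "\t",
                      stringsAsFactors = FALSE)))
  list(manifest = manifest, records = recs)
}

#' Query the top associations of a seed from a precomputed store
#'
#' Pure function of the store: reconstructs the seed's screen (both
#' orientations of the stored unordered pairs), recomputes BH q over that
#' screen and returns the top k by |z| — identical to running
#' \code{\link{screenVariable}} on the cohort directly.
#'
#' @param path store directory
#' @param seedId seed variable id
#' @param k number of records (Inf = all)
#' @param maxQ optional q-value filter applied after adjustment
#' @param stat optional statistic-kind filter
#' @return ranked data.frame of association records
#' @export
queryTop <- function(path, seedId, k = 50, maxQ = NULL, stat = NULL) {
  st <- .readStore(path)
  recs <- st$records
  hit <- recs$seed == seedId | recs$candidate == seedId
  recs <- recs[hit, , drop = FALSE]
  if (!nrow(recs)) stop(sprintf("seed '%s' not in store", seedId))
  flip <- recs$candidate == seedId
  tmp <- recs$seed[flip]
  recs$seed[flip] <- recs$candidate[flip]
  recs$candidate[flip] <- tmp
  recs$q <- bhFdr(recs$p, nTests = nrow(recs))
  recs <- recs[order(-abs(recs$z), recs$candidate, na.last = TRUE), ,
               drop = FALSE]
  if (!is.null(stat)) recs <- recs[recs$stat %in% stat, , drop = FALSE]
  if (!is.null(maxQ)) recs <- recs[!is.na(recs$q) & recs$q < maxQ, ,
                                   drop = FALSE]
  utils::head(recs, k)
}
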
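#' Row/column ordering for a clustered heatmap
#'
#' Deterministic hierarchical clustering (average linkage on Euclidean
#' distance) of rows and columns, with optional row z-scaling first; the
#' leaf order follows the dendrogram with ties broken by input index, so
#' the same matrix always yields the same ordering.
#'
#' @param m numeric matrix (>= 2 rows and columns)
#' @param scaleRows z-scale rows (sample sd) before clustering
#' @return list(\code{rowOrder}, \code{colOrder} (permutations of the
#'   input indices), \code{linkage}, \code{scaled}, \code{rowHclust},
#'   \code{colHclust})
#' @export
heatmapOrder <- function(m, scaleRows = FALSE) {
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  if (any(apply(m, 1, function(r) all(is.na(r)))))
    stop("all-missing row(s)")
  mm <- if (scaleRows) suppressWarnings(zscaleRows(m)) else m
  if (all(mm == mm[1], na.rm = TRUE) ||
      isTRUE(all.equal(stats::var(as.vector(mm), na.rm = TRUE), 0))) {
    warning("constant matrix: returning input order")
    return(list(rowOrder = seq_len(nrow(m)), colOrder = seq_len(ncol(m)),
                linkage = "none", scaled = scaleRows,
                rowHclust = NULL, colHclust = NULL))
  }
  hr <- stats::hclust(stats::dist(mm), method = "average")
  hc <- stats::hclust(stats::dist(t(mm)), method = "average")
  list(rowOrder = hr$order, colOrder = hc$order,
       linkage = "average/euclidean", scaled = scaleRows,
       rowHclust = hr, colHclust = hc)
}

#' Co-occurrence / mutual-exclusivity table for two alterations
#'
#' Cross-tabulates two binary alterations (an ordinal CNV side is first
#' collapsed, by default to "loss" = codes < 0, matching the convention
#' that monosomy/shallow loss counts as loss), and reports the
#' Haldane-Anscombe-corrected log odds ratio (positive = co-occurrence,
#' negative = mutual exclusivity) and the Fisher exact p-value (exact
#' hypergeometric enumeration).
#'
#' @param a,b numeric vectors: binary 0/1, or ordinal codes for the side
#'   being collapsed
#' @param collapseB,collapseA optional predicate collapsing an ordinal side
#'   to TRUE/FALSE; the default for \code{b}, used when \code{b} has values
#'   outside 0/1, is \code{function(v) v < 0}
#' @param labels names for the two variables (display only)
#' @return list(\code{table} 2x2 counts (rows = a, cols = b),
#'   \code{logOR}, \code{se}, \code{z}, \code{p}, \code{degenerate})
#' @export
cooccurrenceTable <- function(a, b, collapseA = NULL, collapseB = NULL,
                              labels = c("A", "B")) {
  tobin <- function(v, collapse, default) {
    if (!is.null(collapse)) return(as.numeric(collapse(v)))
    if (all(v %in% c(0, 1) | is.na(v))) return(v)
    as.numeric(default(v))
  }
  a <- tobin(a, collapseA, function(v) v < 0)
  b <- tobin(b, collapseB, function(v) v < 0)
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  tab <- matrix(c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
                  sum(a == 1 & b == 0), sum(a == 1 & b == 1)),
                2, 2, byrow = TRUE,
                dimnames = list(paste0(labels[1], c("=0", "=1")),
                                paste0(labels[2], c("=0", "=1"))))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  h <- tab + 0.5
  logOR <- log(h[2, 2] * h[1, 1] / (h[2, 1] * h[1, 2]))
  se <- sqrt(sum(1 / h))
  z <- logOR / se
  p <- if (degenerate) NA_real_ else stats::fisher.test(tab)$p.value
  if (degenerate) { logOR <- NA_real_; se <- NA_real_; z <- NA_real_ }
  list(table = tab, logOR = logOR, se = se, z = z, p = p,
       degenerate = degenerate)
}

#' Export analysis results with a reproducibility manifest
#'
#' Writes parameter tables and screens as TSV, fit indices as JSON, and
#' Kaplan-Meier curves as TSV (time, survival, at-risk per group), plus a
#' \code{manifest.json} recording the inputs, seed and package version, so
#' that re-running the same deterministic pipeline reproduces the files
#' byte-identically.
#'
#' @param dir output directory
#' @param fits list of \code{\link{semFit}} results or a
#'   \code{\link{fitMultiCohort}} result
#' @param screens named list of screen data.frames
#' @param kmCurves named list of \code{\link{kmEstimate}} data.frames
#' @param seed the seed the pipeline ran under (recorded only)
#' @param inputs named list or character of input descriptors (recorded)
#' @return invisibly, the manifest list
#' @export
exportResults <- function(dir, fits = NULL, screens = NULL, kmCurves = NULL,
                          seed = NULL, inputs = NULL) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  files <- character()
  wtsv <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(fits)) {
    if (!is.null(fits$table)) {               # multi-cohort result
      wtsv(fits$table, "parameters.tsv")
      idx <- lapply(fits$fits, function(f) f$indices)
      jsonlite::write_json(idx, file.path(dir, "fit_indices.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      files <- c(files, "fit_indices.json")
    } else {
      wtsv(parameterTable(fits), "parameters.tsv")
      jsonlite::write_json(fitIndicesOf(fits),
                           file.path(dir, "fit_indices.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      files <- c(files, "fit_indices.json")
    }
  }
  for (nm in names(screens %||% list()))
    wtsv(screens[[nm]], sprintf("screen_%s.tsv", nm))
  for (nm in names(kmCurves %||% list()))
    wtsv(kmCurves[[nm]], sprintf("km_%s.tsv", nm))
  manifest <- list(
    package = "GraphSEM",
    version = as.character(utils::packageVersion("GraphSEM")),
    seed = seed, inputs = inputs, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
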
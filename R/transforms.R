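#' Binarize (categorize) a numeric or ordinal variable
#'
#' Adds a derived two-level categorical variable to the cohort, either by a
#' threshold on a continuous/ordinal variable or by an explicit value-to-
#' label map (e.g. GISTIC codes 0 -> "Diploid", >= 1 -> "Copy Gain").
#' Samples whose value is outside the rule's domain (a code absent from the
#' map) become missing; the original variable is untouched. The rule is
#' recorded as provenance on the derived variable.
#'
#' @param x a \linkS4class{Cohort}
#' @param id source variable id
#' @param newId id of the derived variable
#' @param cutoff threshold for the threshold form; values \code{> cutoff}
#'   (or per \code{op}) take the second label
#' @param op comparison for the threshold form: \code{">"} (default),
#'   \code{">="}, \code{"<"}, \code{"<="}
#' @param map named vector value -> label for the map form (names are the
#'   numeric codes as strings)
#' @param labels category labels, ordered \code{c(negative, positive)};
#'   for the map form the label order of the derived variable (defaults to
#'   order of first appearance in \code{map})
#' @return the cohort with \code{newId} appended (dtype "categorical")
#' @export
binarize <- function(x, id, newId, cutoff = NULL, op = ">", map = NULL,
                     labels = NULL) {
  v <- variableValues(x, id)
  if (!is.null(map)) {
    labs <- if (is.null(labels)) unique(unname(map)) else labels
    out <- rep(NA_real_, length(v))
    hit <- match(as.character(v), names(map))
    out[!is.na(hit)] <- match(unname(map)[hit[!is.na(hit)]], labs)
    rule <- list(op = "binarize", variable = id, map = as.list(map))
  } else {
    if (is.null(cutoff)) stop("give either `cutoff` or `map`")
    labs <- if (is.null(labels)) c("low", "high") else labels
    cmp <- switch(op, ">" = v > cutoff, ">=" = v >= cutoff,
                  "<" = v < cutoff, "<=" = v <= cutoff,
                  stop("op must be one of > >= < <="))
    out <- ifelse(cmp, 2, 1)
    rule <- list(op = "binarize", variable = id, cutoff = cutoff,
                 comparison = op)
  }
  nlev <- length(unique(out[!is.na(out)]))
  if (nlev < 2)
    warning(sprintf("'%s' is degenerate: a single non-missing category",
                    newId))
  .addVariable(x, newId, out, "categorical", labels = labs,
               rule = c(rule, list(labels = labs)))
}

#' Group binary variables into one categorical variable
#'
#' Collapses a set of binary (e.g. per-gene mutation) variables into a
#' single WT/Mutant-style categorical: under \code{mode = "any"} a sample
#' is positive if any member equals 1; under \code{mode = "all"} only if
#' every member equals 1. A custom map from the member-value tuple to a
#' label can be supplied with \code{mode = "custom"}.
#'
#' Missing members: one observed 1 is enough to call a sample "Mutant"
#' under \code{"any"} (and one observed 0 enough for the negative label
#' under \code{"all"}); the output is missing only when the observed
#' members cannot decide the call.
#'
#' @param x a \linkS4class{Cohort}
#' @param memberIds binary member variable ids
#' @param newId id of the derived group variable
#' @param mode "any", "all" or "custom"
#' @param labels \code{c(negative, positive)}, e.g. \code{c("WT","Mutant")}
#' @param customMap for \code{mode="custom"}: function taking the numeric
#'   member tuple (named) and returning a label in \code{labels}
#' @return the cohort with \code{newId} appended
#' @export
groupVariables <- function(x, memberIds, newId, mode = c("any", "all", "custom"),
                           labels = c("WT", "Mutant"), customMap = NULL) {
  mode <- match.arg(mode)
  unknown <- setdiff(memberIds, variableIds(x))
  if (length(unknown))
    stop(sprintf("unknown member id(s): %s", paste(unknown, collapse = ", ")))
  rd <- rowData(x)
  dt <- rd$dtype[match(memberIds, rownames(x))]
  if (!all(dt == "binary"))
    stop("all group members must be binary variables")
  m <- assay(x, "values")[memberIds, , drop = FALSE]
  n <- ncol(m)
  out <- rep(NA_real_, n)
  if (mode == "any") {
    anyOne <- apply(m == 1, 2, any, na.rm = TRUE)
    allZero <- apply(m == 0, 2, all) # FALSE when any NA present
    allZero[is.na(allZero)] <- FALSE
    out[anyOne] <- 2
    out[!anyOne & allZero] <- 1
  } else if (mode == "all") {
    anyZero <- apply(m == 0, 2, any, na.rm = TRUE)
    allOne <- apply(m == 1, 2, all)
    allOne[is.na(allOne)] <- FALSE
    out[allOne] <- 2
    out[!allOne & anyZero] <- 1
  } else {
    if (is.null(customMap)) stop("mode='custom' requires `customMap`")
    for (j in seq_len(n)) {
      tup <- m[, j]
      if (anyNA(tup)) next
      lab <- customMap(structure(tup, names = memberIds))
      k <- match(lab, labels)
      if (is.na(k))
        stop(sprintf("customMap returned '%s', not one of the labels", lab))
      out[j] <- k
    }
  }
  rule <- list(op = "group", members = memberIds, mode = mode,
               labels = labels)
  .addVariable(x, newId, out, "categorical", labels = labels, rule = rule)
}

#' Scale matrix rows to mean 0, sd 1
#'
#' Centering and scaling use the non-missing entries of each row and the
#' sample standard deviation (n-1 denominator). Rows without two distinct
#' non-missing values cannot be scaled and are set to 0 with a warning.
#'
#' @param m numeric matrix
#' @return matrix of the same shape
#' @export
zscaleRows <- function(m) {
  stopifnot(is.matrix(m))
  out <- m
  const <- character()
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      out[i, ] <- ifelse(is.na(v), NA_real_, 0)
      const <- c(const, rownames(m)[i] %||% as.character(i))
    } else {
      out[i, ] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  if (length(const))
    warning(sprintf("constant row(s) left at 0: %s",
                    paste(const, collapse = ", ")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
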
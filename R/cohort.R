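#' Construct a Cohort from aligned value vectors
#'
#' Low-level constructor; most users assemble cohorts from files with
#' \code{\link{assembleCohort}} or simulate them with
#' \code{\link{simulateCohort}}.
#'
#' @param name cohort name (e.g. a cancer-type code such as "LAML").
#' @param values numeric matrix, variables x samples, with dimnames.
#' @param info data.frame with one row per variable: columns \code{source}
#'   and \code{dtype}; optional \code{labels} (list column) and \code{rule}.
#' @param event optional numeric matrix of the same shape holding event
#'   indicators on survival rows (NA elsewhere).
#' @return a \linkS4class{Cohort}.
#' @export
cohort <- function(name, values, info, event = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (nrow(info) == 1L && nrow(values) > 1L)
    info <- info[rep(1L, nrow(values)), , drop = FALSE]
  stopifnot(nrow(info) == nrow(values))
  if (is.null(event)) {
    event <- matrix(NA_real_, nrow(values), ncol(values),
                    dimnames = dimnames(values))
  }
  if (is.null(info$labels)) info$labels <- replicate(nrow(info), NULL)
  if (is.null(info$rule)) info$rule <- NA_character_
  rd <- DataFrame(source = info$source, dtype = info$dtype,
                  rule = info$rule, row.names = rownames(values))
  rd$labels <- info$labels
  se <- SummarizedExperiment(
    assays = SimpleList(values = values, event = event), rowData = rd)
  obj <- new("Cohort", se)
  metadata(obj)$name <- name
  validObject(obj)
  obj
}

#' @describeIn cohort cohort name
#' @param x,object a \code{Cohort}
#' @export
cohortName <- function(x) metadata(x)$name

#' @describeIn cohort variable identifiers (row names)
#' @export
variableIds <- function(x) rownames(x)

#' @describeIn cohort sample identifiers (column names)
#' @export
sampleIds <- function(x) colnames(x)

#' Variable registry of a cohort
#'
#' @param x a \linkS4class{Cohort}
#' @return data.frame with columns \code{id}, \code{source}, \code{dtype}.
#' @export
variableInfo <- function(x) {
  rd <- rowData(x)
  data.frame(id = rownames(x), source = rd$source, dtype = rd$dtype,
             row.names = NULL)
}

#' Extract one variable's sample-aligned vector
#'
#' @param x a \linkS4class{Cohort}
#' @param id variable id
#' @param as \code{"numeric"} returns the stored coding (categorical
#'   variables as 1-based integer codes); \code{"label"} maps categorical
#'   codes to their labels.
#' @return named vector aligned to \code{sampleIds(x)}; \code{NA} marks
#'   missing values.
#' @export
variableValues <- function(x, id, as = c("numeric", "label")) {
  as <- match.arg(as)
  if (!id %in% rownames(x)) stop(sprintf("unknown variable '%s'", id))
  v <- assay(x, "values")[id, ]
  if (as == "label") {
    labs <- rowData(x)$labels[[match(id, rownames(x))]]
    if (is.null(labs) || all(is.na(labs)))
      stop(sprintf("variable '%s' has no category labels", id))
    v <- structure(labs[v], names = names(v))
  }
  v
}

#' @describeIn variableValues category labels of a variable (NULL if none)
#' @export
variableLabels <- function(x, id) {
  labs <- rowData(x)$labels[[match(id, rownames(x))]]
  if (is.null(labs) || all(is.na(labs))) NULL else labs
}

#' Survival endpoint of a cohort
#'
#' @param x a \linkS4class{Cohort}
#' @param id survival variable id; defaults to the single survival row.
#' @return data.frame(sample, time, event), censored records have event 0.
#' @export
survivalData <- function(x, id = NULL) {
  sv <- rownames(x)[rowData(x)$dtype == "survival"]
  if (is.null(id)) {
    if (length(sv) != 1)
      stop("cohort has ", length(sv), " survival variables; give `id`")
    id <- sv
  }
  if (!id %in% sv) stop(sprintf("'%s' is not a survival variable", id))
  data.frame(sample = colnames(x),
             time = assay(x, "values")[id, ],
             event = assay(x, "event")[id, ], row.names = NULL)
}

#' @describeIn survivalData ids of survival variables in the cohort
#' @export
survivalIds <- function(x) rownames(x)[rowData(x)$dtype == "survival"]

setMethod("show", "Cohort", function(object) {
  rd <- rowData(object)
  cat(sprintf("Cohort '%s': %d variables x %d samples\n",
              cohortName(object), nrow(object), ncol(object)))
  tab <- table(rd$source)
  cat("  sources:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  tab <- table(rd$dtype)
  cat("  dtypes: ", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
})

#' Append a derived variable to a cohort
#'
#' Internal helper shared by the transform functions: stores values, type,
#' labels and the provenance rule (as JSON) under source "Derived".
#' @noRd
.addVariable <- function(x, id, values, dtype, labels = NULL, rule = NULL,
                         source = "Derived", event = NULL) {
  if (id %in% rownames(x))
    stop(sprintf("variable '%s' already exists in the cohort", id))
  v <- assay(x, "values"); ev <- assay(x, "event")
  v <- rbind(v, matrix(values, 1, dimnames = list(id, colnames(x))))
  evRow <- if (is.null(event)) rep(NA_real_, ncol(x)) else event
  ev <- rbind(ev, matrix(evRow, 1, dimnames = list(id, colnames(x))))
  rd <- rowData(x)
  newRd <- DataFrame(source = c(rd$source, source),
                     dtype = c(rd$dtype, dtype),
                     rule = c(rd$rule,
                              if (is.null(rule)) NA_character_ else
                                as.character(jsonlite::toJSON(rule, auto_unbox = TRUE))),
                     row.names = c(rownames(x), id))
  newRd$labels <- c(as.list(rd$labels), list(labels))
  se <- SummarizedExperiment(assays = SimpleList(values = v, event = ev),
                             rowData = newRd)
  obj <- new("Cohort", se)
  metadata(obj) <- metadata(x)
  validObject(obj)
  obj
}

#' Numeric design coding of cohort variables
#'
#' Produces the samples x columns numeric matrix used by the SEM compiler
#' and the Cox stage: continuous/binary/ordinal variables pass through
#' unchanged (binary 0/1, ordinal as its integer code), a k-level
#' categorical variable expands into k-1 dummy columns named
#' \code{"id:label"} against the first label as baseline.
#'
#' @param x a \linkS4class{Cohort}
#' @param ids variable ids to code (must not be survival variables)
#' @return list(\code{matrix} samples x columns, \code{columnsOf} named list
#'   mapping each id to its column names).
#' @export
modelMatrixFor <- function(x, ids) {
  rd <- rowData(x)
  cols <- list(); colOf <- list()
  for (id in ids) {
    k <- match(id, rownames(x))
    if (is.na(k)) stop(sprintf("unknown variable '%s'", id))
    dt <- rd$dtype[k]
    if (dt == "survival")
      stop(sprintf("survival variable '%s' cannot enter the design matrix", id))
    v <- assay(x, "values")[id, ]
    if (dt == "categorical") {
      labs <- rd$labels[[k]]
      if (is.null(labs)) stop(sprintf("categorical '%s' lacks labels", id))
      if (length(labs) < 2)
        stop(sprintf("categorical '%s' has a single level", id))
      dums <- lapply(seq_along(labs)[-1], function(j) {
        d <- as.numeric(v == j); d[is.na(v)] <- NA_real_; d
      })
      nm <- paste0(id, ":", labs[-1])
      # two-level categoricals keep the bare id so edges stay addressable
      if (length(labs) == 2) nm <- id
      names(dums) <- nm
      cols <- c(cols, dums)
      colOf[[id]] <- nm
    } else {
      cols[[id]] <- v
      colOf[[id]] <- id
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- colnames(x)
  list(matrix = m, columnsOf = colOf)
}
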
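#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<-
NULL

#' Multi-omics cohort container
#'
#' A \code{Cohort} is a \linkS4class{SummarizedExperiment} whose rows are
#' typed variables (continuous expression, binary mutation indicators,
#' ordinal copy-number codes, categorical or continuous clinical covariates,
#' right-censored survival endpoints) and whose columns are tumor samples.
#'
#' Two assays are carried: \code{"values"} holds the numeric value of every
#' variable (categorical variables are stored as 1-based integer codes whose
#' labels live in \code{rowData()$labels}; survival variables store the
#' follow-up time), and \code{"event"} is \code{NA} everywhere except on
#' survival rows, where it holds the 0/1 event indicator (1 = death
#' observed, 0 = censored).
#'
#' \code{rowData()} columns: \code{source} (one of mRNA, miRNA, RPPA,
#' Mutation, CNV, Clinical, Survival, Derived), \code{dtype} (continuous,
#' binary, ordinal, categorical, survival), \code{labels} (list column of
#' category labels, \code{NA} otherwise) and \code{rule} (provenance of
#' derived variables, as JSON).
#'
#' @seealso \code{\link{assembleCohort}}, \code{\link{variableValues}},
#'   \code{\link{survivalData}}
#' @exportClass Cohort
setClass("Cohort", contains = "SummarizedExperiment")

.validCohort <- function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("source", "dtype")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must contain columns %s",
                          paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variable ids must be unique")
  if (!all(c("values", "event") %in% names(assays(object))))
    msg <- c(msg, "assays 'values' and 'event' are required")
  if (length(msg)) return(msg)
  v <- assay(object, "values")
  ev <- assay(object, "event")
  ord <- rownames(object)[rd$dtype == "ordinal"]
  for (id in ord) {
    x <- v[id, ]
    bad <- !is.na(x) & !(x %in% (-2:2))
    if (any(bad))
      msg <- c(msg, sprintf("ordinal CNV codes of '%s' outside {-2..2}", id))
  }
  sv <- rownames(object)[rd$dtype == "survival"]
  for (id in sv) {
    tt <- v[id, ]; ee <- ev[id, ]
    if (any(tt < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("negative survival time in '%s'", id))
    if (any(!is.na(ee) & !(ee %in% c(0, 1))))
      msg <- c(msg, sprintf("event indicator of '%s' not in {0,1}", id))
  }
  bn <- rownames(object)[rd$dtype == "binary"]
  for (id in bn) {
    x <- v[id, ]
    if (any(!is.na(x) & !(x %in% c(0, 1))))
      msg <- c(msg, sprintf("binary variable '%s' not coded 0/1", id))
  }
  if (length(msg)) msg else TRUE
}
setValidity("Cohort", .validCohort)

#' Hypothesis graph over cohort variables and latent factors
#'
#' Nodes are observed variables (resolving to \linkS4class{Cohort} rows) or
#' latent factors; edges are directed regressions, factor-loading
#' definitions (latent source, observed target) or undirected covariances.
#' Cycles are permitted; survival nodes may only receive edges.
#'
#' @slot name model name.
#' @slot nodes data.frame with columns \code{id}, \code{kind}
#'   (\code{"observed"}/\code{"latent"}) and \code{variable} (cohort
#'   variable id an observed node resolves to; defaults to the node id).
#' @slot edges data.frame with columns \code{src}, \code{dst}, \code{type}
#'   (\code{"regression"}/\code{"loading"}/\code{"covariance"}) and
#'   \code{fixed} (numeric or \code{NA} for a free parameter).
#' @slot derived list of derived-variable rules (see
#'   \code{\link{applyDerived}}) materialized before fitting.
#' @seealso \code{\link{modelGraph}}, \code{\link{buildGraph}},
#'   \code{\link{validateGraph}}
#' @exportClass ModelGraph
setClass("ModelGraph",
  representation(name = "character", nodes = "data.frame",
                 edges = "data.frame", derived = "list"))

.validModelGraph <- function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (anyDuplicated(nd$id))
    msg <- c(msg, sprintf("duplicate node id(s): %s",
                          paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  if (!all(nd$kind %in% c("observed", "latent")))
    msg <- c(msg, "node kind must be 'observed' or 'latent'")
  if (nrow(ed)) {
    dangling <- setdiff(c(ed$src, ed$dst), nd$id)
    if (length(dangling))
      msg <- c(msg, sprintf("edge endpoint(s) not in node set: %s",
                            paste(dangling, collapse = ", ")))
    if (!all(ed$type %in% c("regression", "loading", "covariance")))
      msg <- c(msg, "edge type must be regression, loading or covariance")
    # covariance edges are undirected: canonicalize before checking duplicates
    key <- ifelse(ed$type == "covariance",
                  paste(pmin(ed$src, ed$dst), pmax(ed$src, ed$dst), ed$type),
                  paste(ed$src, ed$dst, ed$type))
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicate edge(s): %s",
                            paste(unique(key[duplicated(key)]), collapse = "; ")))
    lo <- ed[ed$type == "loading", , drop = FALSE]
    if (nrow(lo)) {
      kind <- structure(nd$kind, names = nd$id)
      bad <- lo$src[kind[lo$src] != "latent" | kind[lo$dst] != "observed"]
      if (length(bad))
        msg <- c(msg, "loading edges must run latent -> observed")
    }
  }
  lat <- nd$id[nd$kind == "latent"]
  noInd <- lat[!lat %in% ed$src[ed$type == "loading"]]
  if (length(noInd))
    msg <- c(msg, sprintf("latent node(s) without indicators: %s",
                          paste(noInd, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("ModelGraph", .validModelGraph)

#' RAM matrix form of a compiled model
#'
#' The reticular-action-model parameterization: directed paths \code{A}
#' (entry \code{[i, j]} is the coefficient on edge j -> i), symmetric
#' covariances \code{S} (residual/exogenous variances and covariances) and
#' an observed-selection filter, so that the model-implied covariance of the
#' observed variables is \eqn{\Sigma = F (I - A)^{-1} S (I - A)^{-T} F^T}.
#'
#' @slot variables ordered variable names, observed manifest variables first
#'   then latent factors.
#' @slot nObserved number of observed (manifest) variables; the filter F
#'   selects the first \code{nObserved} rows.
#' @slot A,S numeric templates holding the fixed entries (free entries 0).
#' @slot freeMap data.frame of free parameters: \code{matrix} ("A"/"S"),
#'   \code{i}, \code{j} (1-based indices), \code{label} (e.g. "Y~X",
#'   "F=~I2", "X~~X").
#' @slot start numeric start values, one per free parameter.
#' @seealso \code{\link{compileGraph}}, \code{\link{impliedCovariance}},
#'   \code{\link{fitSem}}
#' @exportClass RAMSpec
setClass("RAMSpec",
  representation(variables = "character", nObserved = "integer",
                 A = "matrix", S = "matrix", freeMap = "data.frame",
                 start = "numeric"))

.validRAMSpec <- function(object) {
  msg <- character()
  p <- length(object@variables)
  if (!all(dim(object@A) == p) || !all(dim(object@S) == p))
    msg <- c(msg, "A and S must be square over all variables")
  if (object@nObserved > p) msg <- c(msg, "nObserved exceeds variable count")
  if (!isSymmetric(unname(object@S))) msg <- c(msg, "S template must be symmetric")
  if (nrow(object@freeMap) &&
      any(object@freeMap$matrix == "S" &
          object@freeMap$i > object@freeMap$j))
    msg <- c(msg, "S free entries must be stored upper-triangular (i <= j)")
  if (length(object@start) != nrow(object@freeMap))
    msg <- c(msg, "one start value per free parameter required")
  if (length(msg)) msg else TRUE
}
setValidity("RAMSpec", .validRAMSpec)

#' Fitted structural equation model
#'
#' @slot ram the compiled \linkS4class{RAMSpec}.
#' @slot theta free-parameter values at the optimum.
#' @slot estimates parameter table: \code{lhs}, \code{op}, \code{rhs},
#'   \code{estimate}, \code{se}, \code{z}, \code{p}. The chi-square p-value
#'   is deliberately not part of the table (it is dominated by sample size
#'   at cohort scale); use \code{fitIndices()} for global fit.
#' @slot indices list of global fit measures (chisq, df, baseline chisq/df,
#'   TLI, CFI, RMSEA, SRMR, n, stable flag).
#' @slot sampleCov,impliedCov sample and model-implied covariance of the
#'   modeled observed variables.
#' @slot n number of listwise-complete samples used.
#' @slot converged,iterations optimizer diagnostics.
#' @slot cohort cohort name the model was fitted in.
#' @exportClass SemFit
setClass("SemFit",
  representation(ram = "RAMSpec", theta = "numeric", estimates = "data.frame",
                 indices = "list", sampleCov = "matrix", impliedCov = "matrix",
                 n = "integer", converged = "logical", iterations = "integer",
                 cohort = "character"))

#' Ground-truth specification for the cohort simulator
#'
#' Describes a known structural model from which synthetic cohorts are
#' drawn: a linear system with Gaussian disturbances over continuous and
#' latent nodes, Bernoulli mutation indicators (marginal or logistic on
#' parents), ordinal copy-number codes obtained by quantile-thresholding a
#' latent Gaussian copy signal, and exponential survival times whose hazard
#' is log-linear in specified parents with independent uniform-horizon
#' censoring.
#'
#' @slot nSamples cohort size.
#' @slot nodes data.frame: \code{id}, \code{kind} (continuous, latent,
#'   mutation, cnv), \code{source} (cohort source tag for observed nodes).
#' @slot paths data.frame \code{src}, \code{dst}, \code{coef}: linear
#'   effects into continuous/latent nodes (sources may be any node).
#' @slot variances named disturbance variances of continuous/latent nodes.
#' @slot prevalence named marginal prevalences of mutation nodes.
#' @slot logistic named list: per mutation node an optional named coefficient
#'   vector over parent nodes (log-odds scale; intercept set from the
#'   marginal prevalence).
#' @slot cnvFreq named list: per CNV node the target frequencies of codes
#'   -2..2 (named "-2".."2", summing to 1).
#' @slot survival list(\code{id}, \code{baselineHazard}, \code{logHR} (named
#'   by parents), \code{censoringRate}) or empty list for no endpoint.
#' @seealso \code{\link{simSpec}}, \code{\link{simulateCohort}}
#' @exportClass SimSpec
setClass("SimSpec",
  representation(nSamples = "integer", nodes = "data.frame",
                 paths = "data.frame", variances = "numeric",
                 prevalence = "numeric", logistic = "list",
                 cnvFreq = "list", survival = "list"))

.validSimSpec <- function(object) {
  msg <- character()
  if (object@nSamples < 1) msg <- c(msg, "nSamples must be positive")
  if (length(object@prevalence) &&
      any(object@prevalence <= 0 | object@prevalence >= 1))
    msg <- c(msg, "mutation prevalences must lie in (0,1)")
  if (length(object@survival)) {
    cr <- object@survival$censoringRate
    if (!is.null(cr) && (cr < 0 || cr >= 1))
      msg <- c(msg, "censoring rate must lie in [0,1)")
  }
  endo <- object@nodes$id[object@nodes$kind %in% c("continuous", "latent")]
  if (nrow(object@paths)) {
    A <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
    pp <- object@paths[object@paths$src %in% endo & object@paths$dst %in% endo, ]
    if (nrow(pp)) {
      A[cbind(match(pp$dst, endo), match(pp$src, endo))] <- pp$coef
      if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
        msg <- c(msg, "unstable cycle: spectral radius of path matrix >= 1")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("SimSpec", .validSimSpec)
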
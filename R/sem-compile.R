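#' Compile a model graph to RAM matrix form
#'
#' Translates the hypothesis graph into the reticular-action-model
#' parameterization over the numerically coded observed variables and the
#' latent factors. Binary variables enter as 0/1, ordinal copy-number
#' variables as their integer code, and k-level categorical variables as
#' k-1 dummy columns (a categorical node may only be a predictor). Each
#' latent factor's scale is identified by fixing its first loading to 1.
#' Survival nodes are excluded here — edges into them are estimated by the
#' Cox stage (\code{\link{survivalLinkEstimates}}).
#'
#' Free parameters: one per regression edge and per non-first loading; a
#' residual/exogenous variance per variable; user covariance edges; and,
#' by default, covariances among all pairs of exogenous observed variables
#' (the standard SEM convention; disable with
#' \code{autoCovaryExogenous = FALSE}).
#'
#' @param graph a validated \linkS4class{ModelGraph}
#' @param x a \linkS4class{Cohort} (derived rules are applied first)
#' @param autoCovaryExogenous free covariances among exogenous observed
#'   pairs (default TRUE)
#' @return list(\code{ram} = \linkS4class{RAMSpec}, \code{data} =
#'   listwise-complete samples x variables matrix, \code{survivalOnly}
#'   flag, \code{survivalNodes}, \code{columnsOf} node -> data columns map)
#' @export
compileGraph <- function(graph, x, autoCovaryExogenous = TRUE) {
  x <- applyDerived(graph, x)
  rep <- validateGraph(graph, x)
  if (length(rep$unresolved))
    stop("unresolved observed node(s): ",
         paste(rep$unresolved, collapse = ", "))
  if (length(rep$unsupportedEdges))
    stop("survival nodes may only be sinks; offending edge(s): ",
         paste(rep$unsupportedEdges, collapse = ", "))
  nd <- graph@nodes; ed <- graph@edges
  survNodes <- .survivalNodes(graph, x)
  modeled <- nd[!(nd$id %in% survNodes), , drop = FALSE]
  obsNodes <- modeled[modeled$kind == "observed", , drop = FALSE]
  latNodes <- modeled$id[modeled$kind == "latent"]
  nonSurvEdges <- ed[!(ed$src %in% survNodes | ed$dst %in% survNodes), ,
                     drop = FALSE]
  if (nrow(obsNodes) == 0L ||
      (nrow(nonSurvEdges) == 0L && !length(latNodes))) {
    # nothing but survival links to estimate: the SEM stage is empty
    return(list(ram = NULL, data = NULL, survivalOnly = TRUE,
                survivalNodes = survNodes, columnsOf = list()))
  }
  mm <- modelMatrixFor(x, unique(obsNodes$variable))
  # map node id -> manifest column names (dummies for categoricals)
  columnsOf <- list()
  for (i in seq_len(nrow(obsNodes)))
    columnsOf[[obsNodes$id[i]]] <- mm$columnsOf[[obsNodes$variable[i]]]
  manifest <- unlist(columnsOf, use.names = FALSE)
  multi <- names(columnsOf)[lengths(columnsOf) > 1]
  if (length(multi)) {
    asDst <- intersect(multi, ed$dst[ed$type %in% c("regression", "loading")])
    if (length(asDst))
      stop("multi-level categorical node(s) may only be predictors: ",
           paste(asDst, collapse = ", "))
  }
  vars <- c(manifest, latNodes)
  pAll <- length(vars)
  nObs <- length(manifest)
  A <- matrix(0, pAll, pAll, dimnames = list(vars, vars))
  S <- matrix(0, pAll, pAll, dimnames = list(vars, vars))
  free <- list()
  addFree <- function(mat, i, j, label, start)
    free[[length(free) + 1L]] <<- list(matrix = mat, i = i, j = j,
                                       label = label, start = start)
  colsOfNode <- function(id) if (id %in% latNodes) id else columnsOf[[id]]
  data <- mm$matrix[, manifest, drop = FALSE]
  keep <- stats::complete.cases(data)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 3L)
    stop("fewer than 3 listwise-complete samples")
  sampVar <- apply(data, 2, stats::var)

  # regression edges (per expanded source column) and loadings
  for (k in seq_len(nrow(ed))) {
    e <- ed[k, ]
    if (e$src %in% survNodes || e$dst %in% survNodes) next
    if (e$type == "regression") {
      for (sc in colsOfNode(e$src)) for (dc in colsOfNode(e$dst)) {
        i <- match(dc, vars); j <- match(sc, vars)
        if (!is.na(e$fixed)) A[i, j] <- e$fixed else
          addFree("A", i, j, sprintf("%s~%s", dc, sc), 0.1)
      }
    } else if (e$type == "covariance") {
      for (sc in colsOfNode(e$src)) for (dc in colsOfNode(e$dst)) {
        i <- min(match(sc, vars), match(dc, vars))
        j <- max(match(sc, vars), match(dc, vars))
        if (!is.na(e$fixed)) S[i, j] <- S[j, i] <- e$fixed else
          addFree("S", i, j, sprintf("%s~~%s", vars[i], vars[j]), 0)
      }
    }
  }
  for (lat in latNodes) {
    ind <- ed$dst[ed$type == "loading" & ed$src == lat]
    first <- TRUE
    for (indNode in ind) {
      for (dc in colsOfNode(indNode)) {
        i <- match(dc, vars); j <- match(lat, vars)
        if (first) { A[i, j] <- 1; first <- FALSE } else
          addFree("A", i, j, sprintf("%s=~%s", lat, dc), 1.0)
      }
    }
  }
  # variances: every manifest and latent variable gets a free (co)variance
  for (v in vars) {
    i <- match(v, vars)
    st <- if (v %in% latNodes) {
      # latent starts at half the variance of its scale indicator
      firstInd <- which(A[, i] == 1)
      if (length(firstInd)) 0.5 * sampVar[vars[firstInd[1]]] else 0.5
    } else 0.5 * sampVar[v]
    addFree("S", i, i, sprintf("%s~~%s", v, v), max(st, 1e-3))
  }
  if (autoCovaryExogenous) {
    freeDf0 <- do.call(rbind, lapply(free, as.data.frame))
    hasIncoming <- function(i)
      any(A[i, ] != 0) ||
        any(freeDf0$matrix == "A" & freeDf0$i == i)
    exo <- which(vapply(seq_len(nObs), hasIncoming, TRUE) == FALSE)
    userCov <- freeDf0[freeDf0$matrix == "S" & freeDf0$i != freeDf0$j, ,
                       drop = FALSE]
    if (length(exo) > 1) {
      for (a in seq_along(exo)[-length(exo)]) for (b in (a + 1):length(exo)) {
        i <- exo[a]; j <- exo[b]
        dup <- any(userCov$i == i & userCov$j == j) || S[i, j] != 0
        if (!dup)
          addFree("S", i, j, sprintf("%s~~%s", vars[i], vars[j]), 0)
      }
    }
  }
  freeDf <- do.call(rbind, lapply(free, function(f)
    data.frame(matrix = f$matrix, i = f$i, j = f$j, label = f$label)))
  start <- vapply(free, `[[`, 0, "start")
  ram <- new("RAMSpec", variables = vars, nObserved = as.integer(nObs),
             A = A, S = S, freeMap = freeDf, start = start)
  validObject(ram)
  list(ram = ram, data = data, survivalOnly = FALSE,
       survivalNodes = survNodes, columnsOf = columnsOf)
}

#' Number of free parameters of a compiled model
#' @param ram a \linkS4class{RAMSpec}
#' @export
nFreeParameters <- function(ram) nrow(ram@freeMap)

setMethod("show", "RAMSpec", function(object) {
  cat(sprintf("RAMSpec: %d observed + %d latent variables, %d free parameters\n",
              object@nObserved,
              length(object@variables) - object@nObserved,
              nrow(object@freeMap)))
})

#' Fill the RAM matrices at a parameter vector
#' @noRd
.ramMatrices <- function(ram, theta) {
  A <- ram@A; S <- ram@S
  fm <- ram@freeMap
  for (k in seq_len(nrow(fm))) {
    if (fm$matrix[k] == "A") A[fm$i[k], fm$j[k]] <- theta[k]
    else { S[fm$i[k], fm$j[k]] <- theta[k]; S[fm$j[k], fm$i[k]] <- theta[k] }
  }
  list(A = A, S = S)
}

#' Model-implied covariance of the observed variables
#'
#' Evaluates \eqn{\Sigma = F (I - A)^{-1} S (I - A)^{-T} F^T} at a free-
#' parameter vector.
#'
#' @param ram a \linkS4class{RAMSpec}
#' @param theta free-parameter values (defaults to the start values)
#' @return covariance matrix over the observed variables
#' @export
impliedCovariance <- function(ram, theta = ram@start) {
  m <- .ramMatrices(ram, theta)
  p <- length(ram@variables)
  ImA <- diag(p) - m$A
  B <- tryCatch(solve(ImA), error = function(e)
    stop("non-invertible path structure (cyclic instability)"))
  full <- B %*% m$S %*% t(B)
  obs <- seq_len(ram@nObserved)
  out <- full[obs, obs, drop = FALSE]
  dimnames(out) <- list(ram@variables[obs], ram@variables[obs])
  (out + t(out)) / 2
}
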
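#' @importFrom survival Surv survfit survdiff coxph coxph.control strata
NULL

#' Kaplan-Meier product-limit estimate
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}, optionally per
#' stratum; censored records leave the risk set without an event step.
#'
#' @param time follow-up times (>= 0)
#' @param event 1 = event observed, 0 = censored
#' @param group optional stratification factor
#' @return data.frame(group, time, n_risk, n_event, n_censor, survival),
#'   one row per distinct observed time within each group, survival
#'   non-increasing from 1
#' @export
kmEstimate <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event), all(time >= 0, na.rm = TRUE),
            all(event %in% c(0, 1) | is.na(event)))
  if (is.null(group)) group <- rep("all", length(time))
  keep <- !(is.na(time) | is.na(event) | is.na(group))
  time <- time[keep]; event <- event[keep]; group <- as.character(group)[keep]
  if (!length(time)) stop("no usable survival records")
  if (any(table(group) < 1)) stop("empty group")
  out <- lapply(sort(unique(group)), function(g) {
    sf <- survival::survfit(survival::Surv(time[group == g],
                                           event[group == g]) ~ 1)
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, n_censor = sf$n.censor,
               survival = sf$surv)
  })
  do.call(rbind, out)
}

#' Log-rank comparison of survival between groups
#'
#' @inheritParams kmEstimate
#' @param group stratification factor with >= 2 non-empty levels
#' @return list(\code{statistic} (chi-square), \code{df} (k-1), \code{p})
#' @export
logrankTest <- function(time, event, group) {
  keep <- !(is.na(time) | is.na(event) | is.na(group))
  time <- time[keep]; event <- event[keep]
  group <- factor(as.character(group)[keep])
  if (nlevels(group) < 2) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood estimation with the Breslow tie convention. Sign
#' convention: a positive coefficient means a higher hazard, i.e.
#' correlation with worse outcome.
#'
#' @param time,event survival endpoint
#' @param covariates numeric matrix or data.frame, samples x covariates
#' @return list(\code{table} data.frame(term, estimate, se, z, p),
#'   \code{converged}, \code{n}, \code{nEvents})
#' @export
coxFit <- function(time, event, covariates) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- !(is.na(time) | is.na(event)) & stats::complete.cases(X)
  time <- time[keep]; event <- event[keep]; X <- X[keep, , drop = FALSE]
  if (sum(event) < 1) stop("no observed events")
  df <- data.frame(time = time, event = event, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow"),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)$coefficients
  converged <- all(is.finite(sm[, "se(coef)"])) &&
    all(abs(sm[, "coef"]) < 15) # runaway coefficients flag separation
  list(table = data.frame(term = colnames(X),
                          estimate = unname(sm[, "coef"]),
                          se = unname(sm[, "se(coef)"]),
                          z = unname(sm[, "z"]),
                          p = unname(sm[, "Pr(>|z|)"]), row.names = NULL),
       converged = converged, n = length(time), nEvents = sum(event))
}

#' Cox estimates for every graph edge into a survival node
#'
#' For each survival node, fits one Cox model with all of the node's graph
#' parents as simultaneous covariates: observed parents use their numeric
#' design coding, latent parents enter as regression-method factor scores
#' from the SEM stage. This makes "controlling for" semantics exact — an
#' added mediator or confounder parent changes the direct edge's z as a
#' multivariable Cox adjustment. Factor-score uncertainty is not propagated
#' (a documented approximation).
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param x a \linkS4class{Cohort}
#' @param fit the \linkS4class{SemFit} of the non-survival structure
#'   (required when a survival node has latent parents)
#' @param compiled optional precompiled structure from
#'   \code{\link{compileGraph}} (avoids recompiling)
#' @return data.frame(lhs, op, rhs, term, estimate, se, z, p, n, n_events)
#'   with one row per survival edge (k-level categorical parents contribute
#'   k-1 rows), or NULL if the graph has no survival edges
#' @export
survivalLinkEstimates <- function(graph, x, fit = NULL, compiled = NULL) {
  x <- applyDerived(graph, x)
  survNodes <- .survivalNodes(graph, x)
  if (!length(survNodes)) return(NULL)
  nd <- graph@nodes; ed <- graph@edges
  nodeVar <- structure(nd$variable, names = nd$id)
  kind <- .nodeKind(graph)
  rows <- list()
  for (sn in survNodes) {
    parents <- ed$src[ed$type == "regression" & ed$dst == sn]
    if (!length(parents)) next
    sd <- survivalData(x, nodeVar[[sn]])
    covs <- list(); rhsOf <- list()
    for (pn in parents) {
      if (kind[[pn]] == "latent") {
        if (is.null(fit))
          stop(sprintf("latent parent '%s' of '%s' needs the SEM fit", pn, sn))
        if (is.null(compiled)) compiled <- compileGraph(graph, x)
        full <- modelMatrixFor(x, unique(
          nd$variable[nd$kind == "observed" & !(nd$id %in% survNodes)]))$matrix
        sc <- factorScores(fit, full)[, pn]
        covs[[pn]] <- sc
        rhsOf[[pn]] <- pn
      } else {
        mm <- modelMatrixFor(x, nodeVar[[pn]])
        for (cc in colnames(mm$matrix)) covs[[cc]] <- mm$matrix[, cc]
        rhsOf[[pn]] <- colnames(mm$matrix)
      }
    }
    X <- do.call(cbind, covs)
    cf <- coxFit(sd$time, sd$event, X)
    tb <- cf$table
    tb$lhs <- sn; tb$op <- "~"
    rhsLookup <- rep(names(rhsOf), lengths(rhsOf))
    names(rhsLookup) <- unlist(rhsOf)
    tb$rhs <- unname(rhsLookup[tb$term])
    tb$n <- cf$n; tb$n_events <- cf$nEvents
    rows[[sn]] <- tb[, c("lhs", "op", "rhs", "term", "estimate", "se",
                         "z", "p", "n", "n_events")]
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Split a numeric variable at its median
#'
#' Values \code{<= median} take the first label, values \code{> median}
#' the second — the stratification used for high/low factor-score
#' Kaplan-Meier comparisons.
#'
#' @param values numeric vector with >= 2 distinct non-missing values
#' @param labels \code{c(low, high)}
#' @return character vector of labels (NA preserved)
#' @export
medianSplit <- function(values, labels = c("low", "high")) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) stop("median split needs >= 2 distinct values")
  md <- stats::median(v)
  out <- ifelse(values <= md, labels[1], labels[2])
  out[is.na(values)] <- NA_character_
  out
}
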
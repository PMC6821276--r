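#' Normal-theory maximum-likelihood discrepancy
#'
#' \eqn{F_{ML} = \ln|\Sigma| + tr(S \Sigma^{-1}) - \ln|S| - p}, non-negative
#' and zero exactly when the implied covariance reproduces the sample
#' covariance.
#'
#' @param sampleCov sample covariance \code{S} (positive definite)
#' @param implied model-implied covariance \code{Sigma} (positive definite)
#' @return scalar discrepancy
#' @export
mlDiscrepancy <- function(sampleCov, implied) {
  p <- nrow(sampleCov)
  stopifnot(nrow(implied) == p)
  cholS <- tryCatch(chol(sampleCov), error = function(e)
    stop("sample covariance is not positive definite"))
  cholI <- tryCatch(chol(implied), error = function(e)
    stop("implied covariance is not positive definite"))
  ldS <- 2 * sum(log(diag(cholS)))
  ldI <- 2 * sum(log(diag(cholI)))
  ldI + sum(diag(chol2inv(cholI) %*% sampleCov)) - ldS - p
}

# F_ML and its analytic gradient w.r.t. the free parameters; returns +Inf
# (and a zero gradient) off the positive-definite region so BFGS backtracks.
.fmlObjective <- function(ram, sampleCov) {
  p <- length(ram@variables)
  obs <- seq_len(ram@nObserved)
  fm <- ram@freeMap
  ldS <- determinant(sampleCov, logarithm = TRUE)$modulus[1]
  pObs <- length(obs)
  eval <- function(theta) {
    m <- .ramMatrices(ram, theta)
    ImA <- diag(p) - m$A
    B <- tryCatch(solve(ImA), error = function(e) NULL)
    if (is.null(B)) return(NULL)
    full <- B %*% m$S %*% t(B)
    Sig <- (full[obs, obs, drop = FALSE] +
            t(full[obs, obs, drop = FALSE])) / 2
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    SigInv <- chol2inv(ch)
    f <- 2 * sum(log(diag(ch))) + sum(SigInv * sampleCov) - ldS - pObs
    list(f = f, B = B, S = m$S, SigInv = SigInv)
  }
  fn <- function(theta) {
    ev <- eval(theta)
    if (is.null(ev)) return(1e12)
    ev$f
  }
  gr <- function(theta) {
    ev <- eval(theta)
    if (is.null(ev)) return(rep(0, length(theta)))
    # dF = tr(E dSigma), E = SigInv - SigInv %*% S %*% SigInv (observed block)
    E <- ev$SigInv - ev$SigInv %*% sampleCov %*% ev$SigInv
    G <- matrix(0, p, p)
    G[obs, obs] <- E                      # F^T E F over all variables
    B <- ev$B
    C <- B %*% ev$S %*% t(B)
    M1 <- t(B) %*% G %*% B                # for S-parameters
    M2 <- C %*% G %*% B                   # for A-parameters
    g <- numeric(length(theta))
    isA <- fm$matrix == "A"
    g[isA] <- 2 * M2[cbind(fm$j[isA], fm$i[isA])]
    isS <- !isA
    diagS <- isS & fm$i == fm$j
    g[diagS] <- M1[cbind(fm$i[diagS], fm$j[diagS])]
    offS <- isS & fm$i != fm$j
    g[offS] <- 2 * M1[cbind(fm$i[offS], fm$j[offS])]
    g
  }
  list(fn = fn, gr = gr)
}

#' Fit a compiled model by maximum likelihood
#'
#' Minimizes the ML discrepancy over the free parameters by BFGS with the
#' analytic gradient of \eqn{F_{ML}} (one polishing restart from the first
#' optimum). Standard errors come from the observed information: the
#' finite-difference Hessian of \eqn{F_{ML}} at the optimum scaled by
#' \eqn{2/(n-1)}; z = estimate/SE with two-sided normal p-values.
#' \eqn{\chi^2 = (n-1) F_{ML}}. The model degrees of freedom are
#' \eqn{p(p+1)/2 - q}; a negative value (non-identified model) is an error
#' before optimization.
#'
#' @param ram a \linkS4class{RAMSpec} from \code{\link{compileGraph}}
#' @param data listwise-complete samples x observed-variables matrix
#' @param maxit BFGS iteration cap
#' @param cohortName label stored on the result
#' @return a \linkS4class{SemFit}
#' @export
fitSem <- function(ram, data, maxit = 500, cohortName = "cohort") {
  obsVars <- ram@variables[seq_len(ram@nObserved)]
  stopifnot(all(obsVars %in% colnames(data)))
  data <- data[, obsVars, drop = FALSE]
  n <- nrow(data)
  pObs <- ram@nObserved
  if (n <= pObs)
    stop("need more complete samples than observed variables")
  q <- nrow(ram@freeMap)
  df <- pObs * (pObs + 1) / 2 - q
  if (df < 0)
    stop(sprintf("model is not identified: %d free parameters exceed %d moments",
                 q, pObs * (pObs + 1) / 2))
  sampleCov <- stats::cov(data)
  # scale-equivariant start values derived from the fitted data: variance
  # parameters start at half the sample variances, loadings at the sd ratio
  # to the factor's scale indicator, paths at 0.1 x the sd ratio — so a
  # compiled spec refits identically on rescaled data
  fm <- ram@freeMap
  sv <- diag(sampleCov)
  pAll <- length(ram@variables)
  effSd <- numeric(pAll)
  effSd[seq_len(pObs)] <- sqrt(sv)
  for (i in seq_len(pAll)[-seq_len(pObs)]) {
    scaleInd <- which(ram@A[seq_len(pObs), i] == 1)
    effSd[i] <- if (length(scaleInd)) sqrt(sv[scaleInd[1]]) else 1
  }
  start <- ram@start
  for (k in seq_len(nrow(fm))) {
    i <- fm$i[k]; j <- fm$j[k]
    if (fm$matrix[k] == "A") {
      isLoading <- i <= pObs && j > pObs
      start[k] <- if (isLoading) effSd[i] / effSd[j] else
        0.1 * effSd[i] / effSd[j]
    } else if (i == j) {
      start[k] <- max(0.5 * effSd[i]^2, 1e-3)
    } else start[k] <- 0
  }
  ob <- .fmlObjective(ram, sampleCov)
  # BFGS with parameter scaling, restarted from each optimum (restarts
  # reset the Hessian approximation, which tightens saturated fits and
  # rescues badly conditioned variable scalings); converged when the
  # gradient max-norm falls below 1e-6 or F stops changing (rel. 1e-10)
  opt <- list(par = start, value = ob$fn(start), convergence = 1L)
  iterations <- 0L
  # scale-invariant gradient norm: |dF/dtheta_j| * |theta_j| is unchanged
  # when a variable (hence its variance parameters) is rescaled
  gscaled <- function(par) max(abs(ob$gr(par)) * pmax(abs(par), 1e-3))
  for (round in 1:8) {
    prev <- opt$value
    o <- stats::optim(opt$par, ob$fn, ob$gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14,
                                     parscale = pmax(abs(opt$par), 1e-3)))
    iterations <- iterations + as.integer(o$counts[["function"]])
    if (o$value <= opt$value) opt <- o
    if (gscaled(opt$par) < 1e-9) break
    if (round > 1 && prev - opt$value < 1e-14) break  # stalled
  }
  # Newton polish: quadratic convergence near the optimum pushes the
  # gradient to machine precision (important for exact-fit comparisons)
  theta <- opt$par
  fval <- opt$value
  for (nw in 1:10) {
    g <- ob$gr(theta)
    if (max(abs(g)) < 1e-13) break
    H <- .fdHessian(ob$gr, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    accepted <- FALSE
    for (damp in c(1, 0.5, 0.25)) {
      cand <- theta - damp * step
      fc <- ob$fn(cand)
      if (fc <= fval) { theta <- cand; fval <- fc; accepted <- TRUE; break }
    }
    if (!accepted) break
  }
  opt$par <- theta; opt$value <- fval
  gmax <- max(abs(ob$gr(theta)))
  converged <- gscaled(theta) < 1e-6
  fml <- max(opt$value, 0) # numerically tiny negatives are exact fits
  implied <- impliedCovariance(ram, theta)

  se <- rep(NA_real_, q)
  if (converged) {
    H <- .fdHessian(ob$gr, theta)
    covTheta <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
    if (!is.null(covTheta)) {
      dg <- diag(covTheta)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  z <- theta / se
  pval <- 2 * stats::pnorm(-abs(z))
  lab <- ram@freeMap$label
  est <- data.frame(
    lhs = sub("(~~|=~|~).*$", "", lab),
    op = ifelse(grepl("~~", lab, fixed = TRUE), "~~",
                ifelse(grepl("=~", lab, fixed = TRUE), "=~", "~")),
    rhs = sub("^.*?(~~|=~|~)", "", lab),
    estimate = theta, se = se, z = z, p = pval, row.names = NULL)

  chisq <- (n - 1) * fml
  indices <- list(fml = fml, chisq = chisq, df = df, n = n,
                  converged = converged, gradMax = gmax)
  if (converged && pObs >= 2) {
    bl <- tryCatch(baselineChisq(sampleCov, n), error = function(e) NULL)
    if (!is.null(bl))
      indices <- c(indices,
                   fitIndices(chisq, df, bl$chisq, bl$df, n, sampleCov,
                              implied))
  }
  # stability of the path structure at the estimates (cyclic models)
  Ahat <- .ramMatrices(ram, theta)$A
  sr <- if (any(Ahat != 0))
    max(Mod(eigen(Ahat, only.values = TRUE)$values)) else 0
  indices$spectralRadius <- sr
  indices$stable <- sr < 1

  new("SemFit", ram = ram, theta = theta, estimates = est, indices = indices,
      sampleCov = sampleCov, impliedCov = implied, n = as.integer(n),
      converged = converged, iterations = iterations, cohort = cohortName)
}

# central-difference Hessian of F via its analytic gradient
.fdHessian <- function(gr, theta) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) {
    h <- 1e-5 * (abs(theta[j]) + 1e-2)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Independence-baseline chi-square
#'
#' The baseline (variances-only) model's discrepancy has the closed form
#' \eqn{F_b = -\ln|R|} with \eqn{R} the sample correlation matrix, so
#' \eqn{\chi^2_b = (n-1) F_b} with \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param sampleCov sample covariance (p >= 2)
#' @param n sample size
#' @return list(\code{chisq}, \code{df})
#' @export
baselineChisq <- function(sampleCov, n) {
  p <- nrow(sampleCov)
  stopifnot(p >= 2)
  R <- stats::cov2cor(sampleCov)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus[1]))
    stop("singular sample correlation matrix")
  list(chisq = (n - 1) * (-ld$modulus[1]), df = p * (p - 1) / 2)
}

#' Global fit indices
#'
#' TLI (unclipped), CFI, RMSEA and SRMR from the model and baseline
#' chi-squares:
#' \deqn{TLI = \frac{\chi^2_b/df_b - \chi^2_m/df_m}{\chi^2_b/df_b - 1}}
#' \deqn{CFI = 1 - \frac{\max(\chi^2_m - df_m, 0)}
#'   {\max(\chi^2_b - df_b,\ \chi^2_m - df_m,\ 0)}}
#' \deqn{RMSEA = \sqrt{\max(\chi^2_m - df_m, 0) / (df_m (n-1))}}
#' SRMR is the root mean square of the correlation-scale residuals
#' \eqn{(s_{ij} - \hat\sigma_{ij}) / \sqrt{s_{ii} s_{jj}}} over \eqn{i \le j}.
#' The conventional reading (with no field consensus on hard cutoffs):
#' comparative indices such as TLI should be high (> 0.9-0.95) and absolute
#' residual measures such as SRMR low (< 0.1). With zero model df the
#' ratio-based TLI and RMSEA are undefined and reported as \code{NA}.
#'
#' @param chisqM,dfM model chi-square and df
#' @param chisqB,dfB baseline chi-square and df (dfB > 0)
#' @param n sample size
#' @param sampleCov,implied sample and implied covariance (for SRMR)
#' @return list(TLI, CFI, RMSEA, SRMR)
#' @export
fitIndices <- function(chisqM, dfM, chisqB, dfB, n, sampleCov, implied) {
  stopifnot(dfB > 0)
  if (dfM > 0) {
    rB <- chisqB / dfB
    tli <- (rB - chisqM / dfM) / (rB - 1)
    rmsea <- sqrt(max(chisqM - dfM, 0) / (dfM * (n - 1)))
  } else {
    tli <- NA_real_
    rmsea <- NA_real_
  }
  denom <- max(chisqB - dfB, chisqM - dfM, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chisqM - dfM, 0) / denom
  d <- sqrt(diag(sampleCov))
  resid <- (sampleCov - implied) / outer(d, d)
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  list(TLI = tli, CFI = cfi, RMSEA = rmsea, SRMR = srmr)
}

setMethod("show", "SemFit", function(object) {
  idx <- object@indices
  cat(sprintf("SemFit (cohort '%s'): n = %d, %s\n", object@cohort, object@n,
              if (object@converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  chisq = %.4g on %d df (baseline-relative: TLI %.3f, CFI %.3f)\n",
              idx$chisq, idx$df,
              idx$TLI %||% NA_real_, idx$CFI %||% NA_real_))
  cat(sprintf("  RMSEA = %.4g, SRMR = %.4g\n",
              idx$RMSEA %||% NA_real_, idx$SRMR %||% NA_real_))
  cat(sprintf("  %d free parameters; largest |z| = %.2f\n",
              nrow(object@estimates),
              suppressWarnings(max(abs(object@estimates$z), na.rm = TRUE))))
})

#' Parameter table of a fitted model
#'
#' Long-format table (lhs, op, rhs, estimate, se, z, p) of every free
#' parameter. By design it carries no chi-square p-value — at cohort scale
#' that test tracks sample size more than misfit; judge global fit with
#' \code{\link{fitIndicesOf}}.
#'
#' @param fit a \linkS4class{SemFit}, or the list returned by
#'   \code{\link{semFit}} (whose table also contains the Cox survival links)
#' @export
parameterTable <- function(fit) {
  if (is(fit, "SemFit")) return(fit@estimates)
  if (is.list(fit) && !is.null(fit$estimates)) return(fit$estimates)
  stop("not a fitted model")
}

#' @describeIn parameterTable global fit index list
#' @export
fitIndicesOf <- function(fit) {
  if (is(fit, "SemFit")) return(fit@indices)
  if (is.list(fit) && !is.null(fit$indices)) return(fit$indices)
  stop("not a fitted model")
}

#' Fit a hypothesis graph in a cohort
#'
#' One-call pipeline: materialize derived variables, compile the
#' non-survival structure to RAM form and fit it by ML, then estimate every
#' edge into a survival node by Cox proportional hazards with all graph
#' parents of that node as simultaneous covariates (latent parents enter
#' via regression-method factor scores). The returned table merges both
#' stages, so adding a mediator parent changes a direct survival edge's z
#' exactly as multivariable Cox adjustment would.
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param x a \linkS4class{Cohort}
#' @param autoCovaryExogenous see \code{\link{compileGraph}}
#' @return list with \code{sem} (\linkS4class{SemFit} or NULL for
#'   survival-only graphs), \code{estimates} (merged parameter table),
#'   \code{survival} (Cox stage table), \code{indices}, \code{cohort}
#' @export
semFit <- function(graph, x, autoCovaryExogenous = TRUE) {
  x <- applyDerived(graph, x)
  comp <- compileGraph(graph, x, autoCovaryExogenous = autoCovaryExogenous)
  fit <- NULL
  est <- NULL
  indices <- list()
  if (!comp$survivalOnly) {
    fit <- fitSem(comp$ram, comp$data, cohortName = cohortName(x))
    est <- fit@estimates
    indices <- fit@indices
  }
  surv <- survivalLinkEstimates(graph, x, fit = fit, compiled = comp)
  if (!is.null(surv) && nrow(surv))
    est <- rbind(est, surv[, c("lhs", "op", "rhs", "estimate", "se", "z", "p")])
  list(sem = fit, estimates = est, survival = surv, indices = indices,
       cohort = cohortName(x))
}

#' Fit one graph across several cohorts
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param cohorts list of \linkS4class{Cohort} objects
#' @return list(\code{fits} per-cohort results, \code{table} long-format
#'   data.frame (cohort, lhs, op, rhs, estimate, se, z, p) for cross-cancer
#'   comparison, \code{skipped} named reasons)
#' @export
fitMultiCohort <- function(graph, cohorts) {
  fits <- list(); rows <- list(); skipped <- character()
  for (x in cohorts) {
    nm <- cohortName(x)
    res <- tryCatch(semFit(graph, x), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("cohort '%s' skipped: %s", nm, conditionMessage(res)))
      skipped[nm] <- conditionMessage(res)
      next
    }
    fits[[length(fits) + 1L]] <- res
    names(fits)[length(fits)] <- nm
    rows[[length(rows) + 1L]] <- cbind(cohort = nm, res$estimates)
  }
  list(fits = fits,
       table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
               else NULL,
       skipped = skipped)
}
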
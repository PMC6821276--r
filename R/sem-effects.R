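#' Direct, indirect and total effect of one variable on another
#'
#' Path-tracing decomposition on the fitted directed-path matrix: the total
#' effect is \eqn{((I - A)^{-1} - I)[target, source]} (the sum of all
#' directed paths, including through cycles when the structure is stable),
#' the direct effect is \eqn{A[target, source]}, and the indirect effect is
#' their difference, so direct + indirect = total exactly.
#'
#' @param ram a \linkS4class{RAMSpec}
#' @param theta free-parameter values (e.g. \code{fit@theta})
#' @param source,target variable names in \code{ram@variables}
#' @return list(\code{direct}, \code{indirect}, \code{total})
#' @export
effectDecomposition <- function(ram, theta, source, target) {
  vars <- ram@variables
  i <- match(target, vars); j <- match(source, vars)
  if (is.na(i) || is.na(j))
    stop("source/target must be modeled variables")
  A <- .ramMatrices(ram, theta)$A
  sr <- if (any(A != 0))
    max(Mod(eigen(A, only.values = TRUE)$values)) else 0
  if (sr >= 1)
    stop(sprintf("unstable cycle: spectral radius %.3f >= 1", sr))
  total <- (solve(diag(length(vars)) - A) - diag(length(vars)))[i, j]
  direct <- A[i, j]
  list(direct = direct, indirect = total - direct, total = total)
}

#' @describeIn effectDecomposition decomposition from a fitted model
#' @param fit a \linkS4class{SemFit}
#' @export
effectDecompositionOf <- function(fit, source, target)
  effectDecomposition(fit@ram, fit@theta, source, target)

#' Regression-method factor scores
#'
#' Per-sample scores for every latent factor of a converged fit:
#' \eqn{\hat\eta = C_{\eta y} \hat\Sigma_{yy}^{-1} (y - \bar y)}, where
#' \eqn{C_{\eta y}} is the model-implied latent-observed covariance block.
#' For a pure measurement model this is the familiar
#' \eqn{\Psi \Lambda^T \Sigma^{-1} (y - \bar y)}; the general form also
#' covers latents with structural parents. Scores are linear in the data
#' and have mean zero over the fitting samples.
#'
#' @param fit a converged \linkS4class{SemFit}
#' @param data samples x observed-variables matrix (defaults must supply
#'   the modeled columns; rows with missing values get NA scores)
#' @return samples x latents matrix
#' @export
factorScores <- function(fit, data) {
  if (!fit@converged) stop("factor scores require a converged fit")
  ram <- fit@ram
  pAll <- length(ram@variables)
  nObs <- ram@nObserved
  if (nObs == pAll) stop("model has no latent variables")
  obsVars <- ram@variables[seq_len(nObs)]
  latVars <- ram@variables[(nObs + 1):pAll]
  stopifnot(all(obsVars %in% colnames(data)))
  y <- as.matrix(data[, obsVars, drop = FALSE])
  m <- .ramMatrices(ram, fit@theta)
  B <- solve(diag(pAll) - m$A)
  full <- B %*% m$S %*% t(B)
  Cey <- full[(nObs + 1):pAll, seq_len(nObs), drop = FALSE]
  SigInv <- solve(full[seq_len(nObs), seq_len(nObs), drop = FALSE])
  ybar <- colMeans(y, na.rm = TRUE)
  centered <- sweep(y, 2, ybar)
  scores <- centered %*% t(Cey %*% SigInv)
  colnames(scores) <- latVars
  rownames(scores) <- rownames(data)
  scores
}
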
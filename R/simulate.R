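#' Specify a ground-truth simulation model
#'
#' Builds a \linkS4class{SimSpec}: the study conditions under which the
#' package's statistical machinery is exercised. Continuous and latent
#' nodes obey a linear structural model with Gaussian disturbances;
#' mutation nodes are Bernoulli (marginal, or logistic on parents); CNV
#' nodes are drawn marginally by quantile-thresholding a Gaussian copy
#' signal to target code frequencies; survival times are exponential with
#' a log-linear hazard in the specified parents and independent
#' uniform-horizon censoring calibrated to a target censoring fraction.
#'
#' @param nSamples cohort size
#' @param continuous character vector of continuous node ids (cohort source
#'   "mRNA" unless named otherwise via \code{sources})
#' @param latents character vector of latent node ids (simulated but not
#'   observed in the cohort)
#' @param paths data.frame(src, dst, coef) of linear effects into
#'   continuous/latent nodes; sources may also be mutation or CNV nodes
#' @param variances named disturbance variances (default 1)
#' @param mutations named prevalence vector, e.g. \code{c(TP53.Mut = 0.3)}
#' @param logistic named list: per mutation node a named coefficient vector
#'   over parents (log-odds); marginal prevalence sets the intercept
#' @param cnv named list: per CNV node, frequencies of codes -2..2 (named
#'   "-2".."2")
#' @param survival list(id, baselineHazard, logHR = named vector,
#'   censoringRate); NULL for no endpoint
#' @param sources optional named source overrides for continuous nodes
#' @return a \linkS4class{SimSpec}
#' @export
simSpec <- function(nSamples, continuous = character(), latents = character(),
                    paths = NULL, variances = NULL, mutations = NULL,
                    logistic = list(), cnv = list(), survival = NULL,
                    sources = NULL) {
  nodes <- rbind(
    if (length(continuous))
      data.frame(id = continuous, kind = "continuous",
                 source = (sources %||% character())[continuous] %|NA|% "mRNA"),
    if (length(latents))
      data.frame(id = latents, kind = "latent", source = NA_character_),
    if (length(mutations))
      data.frame(id = names(mutations), kind = "mutation",
                 source = "Mutation"),
    if (length(cnv))
      data.frame(id = names(cnv), kind = "cnv", source = "CNV"))
  if (is.null(nodes)) stop("no nodes specified")
  if (is.null(paths))
    paths <- data.frame(src = character(), dst = character(),
                        coef = numeric())
  endo <- nodes$id[nodes$kind %in% c("continuous", "latent")]
  vv <- structure(rep(1, length(endo)), names = endo)
  if (!is.null(variances)) vv[names(variances)] <- variances
  spec <- new("SimSpec", nSamples = as.integer(nSamples), nodes = nodes,
              paths = paths, variances = vv,
              prevalence = if (length(mutations)) mutations else numeric(),
              logistic = logistic, cnvFreq = cnv,
              survival = if (is.null(survival)) list() else survival)
  validObject(spec)
  spec
}

`%|NA|%` <- function(a, b) {
  if (!length(a)) return(rep(b, length.out = max(1, length(a))))
  ifelse(is.na(a), b, a)
}

#' Implied covariance of a simulation spec's continuous/latent system
#'
#' Ground truth for moment-matching checks: \eqn{(I-A)^{-1} \Psi (I-A)^{-T}}
#' over the endogenous (continuous + latent) nodes, conditioning on binary/
#' CNV parents at their realized values is ignored (i.e. this is the
#' disturbance-driven covariance given the exogenous inputs).
#'
#' @param spec a \linkS4class{SimSpec}
#' @return covariance matrix over continuous+latent nodes
#' @export
simImpliedCovariance <- function(spec) {
  endo <- spec@nodes$id[spec@nodes$kind %in% c("continuous", "latent")]
  A <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
  pp <- spec@paths[spec@paths$src %in% endo & spec@paths$dst %in% endo, ,
                   drop = FALSE]
  if (nrow(pp)) A[cbind(match(pp$dst, endo), match(pp$src, endo))] <- pp$coef
  B <- solve(diag(length(endo)) - A)
  S <- diag(spec@variances[endo], length(endo))
  out <- B %*% S %*% t(B)
  dimnames(out) <- list(endo, endo)
  out
}

#' Draw a synthetic cohort from a ground-truth model
#'
#' Fully reproducible from the seed: mutations first (marginal Bernoulli or
#' logistic on already-drawn parents), then CNV codes, then the linear
#' continuous/latent system \eqn{x = (I-A)^{-1}(\Gamma u + e)} with
#' exogenous inputs \eqn{u} (mutation/CNV parents) and Gaussian
#' disturbances, and finally the survival endpoint.
#'
#' @param spec a \linkS4class{SimSpec}
#' @param seed integer seed
#' @param name cohort name
#' @return list(\code{cohort} = \linkS4class{Cohort} of the observed nodes,
#'   \code{truth} = list(spec, latentScores, linearPredictor,
#'   eventTimes))
#' @export
simulateCohort <- function(spec, seed = 1L, name = "SIM") {
  set.seed(as.integer(seed))
  n <- spec@nSamples
  nd <- spec@nodes
  samples <- sprintf("S%04d", seq_len(n))
  vals <- list()
  # mutation nodes (ordered so logistic parents are drawn first)
  mutIds <- nd$id[nd$kind == "mutation"]
  plain <- mutIds[!mutIds %in% names(spec@logistic)]
  for (id in plain) vals[[id]] <- stats::rbinom(n, 1, spec@prevalence[[id]])
  for (id in intersect(mutIds, names(spec@logistic))) {
    co <- spec@logistic[[id]]
    miss <- setdiff(names(co), names(vals))
    if (length(miss))
      stop(sprintf("logistic parent(s) of '%s' not yet drawn: %s", id,
                   paste(miss, collapse = ", ")))
    eta <- stats::qlogis(spec@prevalence[[id]]) +
      Reduce(`+`, lapply(names(co), function(pn) co[[pn]] * vals[[pn]]))
    # recenter so the marginal prevalence is (approximately) respected
    eta <- eta - mean(eta) + stats::qlogis(spec@prevalence[[id]])
    vals[[id]] <- stats::rbinom(n, 1, stats::plogis(eta))
  }
  # CNV nodes: quantile-threshold a Gaussian copy signal to code frequencies
  for (id in names(spec@cnvFreq)) {
    fr <- spec@cnvFreq[[id]]
    fr <- fr[as.character(-2:2)]; fr[is.na(fr)] <- 0
    if (abs(sum(fr) - 1) > 1e-8) stop("CNV frequencies must sum to 1")
    zq <- stats::qnorm(cumsum(fr)[-5])
    sig <- stats::rnorm(n)
    vals[[id]] <- as.numeric(cut(sig, c(-Inf, zq, Inf), labels = FALSE)) - 3
  }
  # continuous + latent linear system
  endo <- nd$id[nd$kind %in% c("continuous", "latent")]
  if (length(endo)) {
    A <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
    pp <- spec@paths
    within <- pp$src %in% endo & pp$dst %in% endo
    if (any(within)) {
      w <- pp[within, , drop = FALSE]
      A[cbind(match(w$dst, endo), match(w$src, endo))] <- w$coef
    }
    exoIn <- matrix(0, n, length(endo), dimnames = list(NULL, endo))
    exoPaths <- pp[!within & pp$dst %in% endo, , drop = FALSE]
    for (k in seq_len(nrow(exoPaths))) {
      src <- exoPaths$src[k]
      if (is.null(vals[[src]]))
        stop(sprintf("path source '%s' is not a simulated node", src))
      exoIn[, exoPaths$dst[k]] <- exoIn[, exoPaths$dst[k]] +
        exoPaths$coef[k] * vals[[src]]
    }
    e <- sapply(endo, function(id)
      stats::rnorm(n, 0, sqrt(spec@variances[[id]])))
    if (is.null(dim(e))) e <- matrix(e, nrow = n)
    X <- t(solve(diag(length(endo)) - A, t(exoIn + e)))
    colnames(X) <- endo
    for (id in endo) vals[[id]] <- X[, id]
  }
  # survival endpoint
  truth <- list(spec = spec)
  sv <- spec@survival
  if (length(sv)) {
    lp <- rep(0, n)
    for (pn in names(sv$logHR)) {
      if (is.null(vals[[pn]]))
        stop(sprintf("survival parent '%s' is not a simulated node", pn))
      lp <- lp + sv$logHR[[pn]] * vals[[pn]]
    }
    h <- sv$baselineHazard * exp(lp)
    eventT <- stats::rexp(n, rate = h)
    cr <- sv$censoringRate %||% 0
    if (cr > 0) {
      # uniform horizon U(0, tau): solve tau so the expected censored
      # fraction matches the target rate, averaging over the hazards
      pc <- function(tau) mean((1 - exp(-h * tau)) / (h * tau)) - cr
      tau <- stats::uniroot(pc, lower = 1e-8 / sv$baselineHazard,
                            upper = 1e8 / sv$baselineHazard)$root
      cens <- stats::runif(n, 0, tau)
    } else cens <- rep(Inf, n)
    time <- pmin(eventT, cens)
    event <- as.numeric(eventT <= cens)
    truth$eventTimes <- eventT
    truth$linearPredictor <- lp
  }
  # assemble the observed cohort
  obs <- nd[nd$kind != "latent", , drop = FALSE]
  values <- do.call(rbind, lapply(obs$id, function(id) vals[[id]]))
  rownames(values) <- obs$id; colnames(values) <- samples
  info <- data.frame(
    source = obs$source,
    dtype = c(continuous = "continuous", mutation = "binary",
              cnv = "ordinal")[obs$kind])
  info$labels <- lapply(obs$kind, function(k)
    if (k == "cnv") unname(.gisticLabels) else NULL)
  event <- NULL
  if (length(sv)) {
    values <- rbind(values,
                    matrix(time, 1, dimnames = list(sv$id, samples)))
    info <- rbind(info, data.frame(source = "Survival", dtype = "survival",
                                   labels = I(list(NULL))))
    event <- matrix(NA_real_, nrow(values), n,
                    dimnames = list(rownames(values), samples))
    event[sv$id, ] <- as.numeric(eventT <= cens)
  }
  ch <- cohort(name, values, info, event)
  lat <- nd$id[nd$kind == "latent"]
  if (length(lat)) {
    truth$latentScores <- X[, lat, drop = FALSE]
    rownames(truth$latentScores) <- samples
  }
  list(cohort = ch, truth = truth)
}

#' Write the standard fixture file bundle for a simulated cohort
#'
#' Thin wrapper over \code{\link{writeCohortFiles}}: the bundle
#' (expression TSV, MAF, GISTIC TSV, clinical TSV) re-loads to an identical
#' cohort, and the same seed yields byte-identical files.
#'
#' @param x a \linkS4class{Cohort}
#' @param dir output directory
#' @return invisibly, the files written
#' @export
writeFixtureFiles <- function(x, dir) writeCohortFiles(x, dir)

#' Canned scenario: driver mutation -> proliferation factor -> survival
#'
#' The pan-cancer motif the engine is designed around: a common driver
#' mutation (prevalence 0.3, the order of TP53 mutation rates in the
#' high-burden cancers) raises a latent proliferation factor measured by
#' three expression markers (loadings 1, 0.8, 0.6), and the factor drives
#' mortality. A direct driver->survival edge can be added at fit time to
#' test mediation.
#'
#' @param n cohort size (default 500, a mid-size cancer cohort)
#' @param prevalence driver mutation prevalence
#' @param driverEffect path coefficient driver -> factor
#' @param loadings factor loadings of the three markers (first fixes the
#'   scale)
#' @param factorHR log hazard ratio of the factor on survival
#' @param driverHR direct log hazard ratio of the driver (0 = fully
#'   mediated)
#' @param censoringRate fraction censored (0.5 is typical of overall
#'   survival in these cohorts)
#' @return a \linkS4class{SimSpec}
#' @export
simSpecDriverFactor <- function(n = 500, prevalence = 0.3,
                                driverEffect = 0.5,
                                loadings = c(1, 0.8, 0.6),
                                factorHR = 0.5, driverHR = 0,
                                censoringRate = 0.5) {
  ind <- paste0(c("CCNB1", "PCNA", "MKI67"), ".RNA")
  paths <- rbind(
    data.frame(src = "Driver.Mut", dst = "CellCycle", coef = driverEffect),
    data.frame(src = "CellCycle", dst = ind, coef = loadings))
  logHR <- c(CellCycle = factorHR)
  if (driverHR != 0) logHR <- c(logHR, Driver.Mut = driverHR)
  simSpec(n, continuous = ind, latents = "CellCycle", paths = paths,
          mutations = c(Driver.Mut = prevalence),
          survival = list(id = "OS.Survival", baselineHazard = 0.001,
                          logHR = logHR, censoringRate = censoringRate))
}

#' Canned scenario: fully mediated survival effect
#'
#' A driver mutation suppresses/induces a single mediator gene which alone
#' carries the hazard — the pattern where adding the mediator to the
#' survival model abolishes the driver's direct effect.
#'
#' @param n cohort size
#' @param prevalence driver prevalence
#' @param driverEffect driver -> mediator path
#' @param mediatorHR mediator log hazard ratio
#' @param censoringRate fraction censored
#' @return a \linkS4class{SimSpec}
#' @export
simSpecMediation <- function(n = 1000, prevalence = 0.3, driverEffect = 0.8,
                             mediatorHR = 0.8, censoringRate = 0.4) {
  simSpec(n, continuous = "Mediator.RNA",
          paths = data.frame(src = "Driver.Mut", dst = "Mediator.RNA",
                             coef = driverEffect),
          mutations = c(Driver.Mut = prevalence),
          survival = list(id = "OS.Survival", baselineHazard = 0.001,
                          logHR = c(Mediator.RNA = mediatorHR),
                          censoringRate = censoringRate))
}

#' Canned scenario: confounded driver-survival correlation
#'
#' A second alteration co-occurs with the driver (logistic dependence) and
#' is independently protective; the driver itself has no effect on the
#' hazard. Unadjusted, the driver inherits a spurious survival
#' association; adjusting for the confounder attenuates it — the pattern
#' seen when a co-occurring mutation explains away a driver's apparent
#' effect.
#'
#' @param n cohort size
#' @param confounderHR protective log hazard ratio of the confounder
#' @param coOccurrence log-odds of the driver given the confounder
#' @param censoringRate fraction censored
#' @return a \linkS4class{SimSpec}
#' @export
simSpecConfounder <- function(n = 1000, confounderHR = -0.8,
                              coOccurrence = 2, censoringRate = 0.4) {
  simSpec(n,
          mutations = c(Conf.Mut = 0.3, Driver.Mut = 0.3),
          logistic = list(Driver.Mut = c(Conf.Mut = coOccurrence)),
          survival = list(id = "OS.Survival", baselineHazard = 0.001,
                          logHR = c(Conf.Mut = confounderHR),
                          censoringRate = censoringRate))
}
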
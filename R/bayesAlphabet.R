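#' Settings for the whole-genome regression Gibbs samplers
#'
#' Defaults are the conventional long chain (20,000 sweeps, 5,000 burn-in,
#' every 5th sample retained). `priorR2` is the usual variance-partition
#' heuristic: a share `priorR2` of `var(y)` is allocated a priori to the
#' markers and the rest to the residual, and prior scale parameters are
#' solved from these via the prior mode given `dfPrior` degrees of freedom.
#' The `"test"` preset (3,000 / 1,000 / thin 2) is sized for automated
#' checks and quick exploration.
#'
#' @param method one of "BRR", "BayesA", "BayesB", "BayesCpi", "BL".
#' @param nIter,burnIn,thin Gibbs chain geometry.
#' @param priorR2 prior share of variance attributed to markers, in (0,1).
#' @param dfPrior degrees of freedom of the scaled-inverse-chi-square
#'   variance priors.
#' @param piPrior Beta shape pair for the point-mass probability pi (Bayes B
#'   / Bayes Cpi). Note pi is the probability of EXCLUSION (the point mass
#'   at zero), not inclusion.
#' @param seed integer seed for the chain.
#' @param preset "full" keeps `nIter`/`burnIn`/`thin` as given; "test"
#'   overrides them with the short chain.
#' @param fixVarE,fixVarMarker optional fixed values for the residual and
#'   marker-effect variances (degenerate configs used for closed-form
#'   cross-checks).
#' @param keepChain retain the residual-variance chain for diagnostics.
#' @return list of class `WGRConfig`.
#' @export
wgrConfig <- function(method = c("BRR", "BayesA", "BayesB", "BayesCpi", "BL"),
                      nIter = 20000, burnIn = 5000, thin = 5, priorR2 = 0.5,
                      dfPrior = 5, piPrior = c(1, 1), seed = 1,
                      preset = c("full", "test"), fixVarE = NA_real_,
                      fixVarMarker = NA_real_, keepChain = FALSE) {
  method <- match.arg(method)
  preset <- match.arg(preset)
  if (preset == "test") { nIter <- 3000; burnIn <- 1000; thin <- 2 }
  if (burnIn >= nIter) stop("burnIn must be smaller than nIter")
  if (thin < 1) stop("thin must be >= 1")
  if (priorR2 <= 0 || priorR2 >= 1) stop("priorR2 must lie in (0, 1)")
  structure(list(method = method, nIter = nIter, burnIn = burnIn,
                 thin = thin, priorR2 = priorR2, dfPrior = dfPrior,
                 piPrior = piPrior, seed = seed, fixVarE = fixVarE,
                 fixVarMarker = fixVarMarker, keepChain = keepChain),
            class = "WGRConfig")
}

methodCode <- c(BRR = 1L, BayesA = 2L, BayesB = 3L, BayesCpi = 4L, BL = 5L)

#' Estimate marker effects by Bayesian whole-genome regression
#'
#' Fits `y = mu + W a + e` by single-site Gibbs sampling under one of five
#' priors on the marker effects `a`: a common normal (BRR), per-marker
#' scaled-t (Bayes A), point mass at zero mixed with a scaled-t (Bayes B)
#' or with a normal (Bayes Cpi), or a Laplace prior via the
#' exponential-mixture hierarchy (BL). The mixing probability pi of the
#' point mass is sampled with a Beta prior. The intercept has a flat prior
#' (`y` is not centered internally). Posterior means are computed from the
#' post-burn-in thinned draws.
#'
#' @param y numeric response (e.g. deregressed BLUPs); must be complete.
#' @param W lines x markers dosage matrix with marker column names; complete.
#' @param config a [wgrConfig()].
#' @return a [MarkerEffects-class].
#' @export
fitWGR <- function(y, W, config = wgrConfig()) {
  if (anyNA(y)) stop("y must not contain missing values (drop those rows)")
  if (anyNA(W)) stop("W must be complete (impute first)")
  if (length(y) != nrow(W)) stop("length(y) must equal nrow(W)")
  if (length(y) < 2) stop("need at least 2 observations")
  if (sd(y) == 0) stop("constant response: nothing to fit")
  if (is.null(colnames(W))) stop("W must carry marker column names")

  colVar <- apply(W, 2, var)
  zeroVar <- colVar <= 0
  if (any(zeroVar)) {
    warning(sum(zeroVar), " zero-variance marker(s): effects fixed at 0")
    Wfit <- W[, !zeroVar, drop = FALSE]
    colVar <- colVar[!zeroVar]
  } else Wfit <- W
  if (ncol(Wfit) == 0) stop("no polymorphic markers")

  vy <- var(y)
  R2 <- config$priorR2
  df0 <- config$dfPrior
  MSx <- sum(colVar)
  scaleE <- vy * (1 - R2) * (df0 + 2) / df0
  scaleMarker <- R2 * vy / MSx * (df0 + 2) / df0
  # BL: Gamma(shape, rate) hyperprior on lambda^2, centered so that the
  # implied marker variance sums to R2 * var(y)
  blShape <- 1.1
  lambda2Target <- 2 * (1 - R2) * MSx / R2
  blRate <- blShape / lambda2Target

  fixVarE <- !is.na(config$fixVarE)
  fixVarM <- !is.na(config$fixVarMarker)

  res <- withSeed(config$seed,
    wgr_gibbs_cpp(as.numeric(y), Wfit, methodCode[[config$method]],
                  as.integer(config$nIter), as.integer(config$burnIn),
                  as.integer(config$thin), df0, scaleMarker, df0, scaleE,
                  config$piPrior[1], config$piPrior[2],
                  fixVarE, if (fixVarE) config$fixVarE else 0,
                  fixVarM, if (fixVarM) config$fixVarMarker else 0,
                  blShape, blRate, isTRUE(config$keepChain)))

  eff <- setNames(numeric(ncol(W)), colnames(W))
  eff[colnames(Wfit)] <- res$effects
  mixture <- config$method %in% c("BayesB", "BayesCpi")
  incl <- if (mixture) {
    ip <- setNames(rep(1, ncol(W)), colnames(W))
    ip[colnames(Wfit)] <- res$inclusionProb
    ip[zeroVar] <- 0
    ip
  } else numeric(0)
  me <- new("MarkerEffects", effects = eff, method = config$method,
            varE = res$varE, varMarker = res$varMarker,
            pi = if (mixture) res$pi else NA_real_,
            inclusionProb = incl, nSamples = as.integer(res$nSamples))
  attr(me, "mu") <- res$mu
  if (isTRUE(config$keepChain)) attr(me, "chainVarE") <- res$chainVarE
  me
}

#' Compare estimated marker effects with simulated truth
#'
#' @param effects a [MarkerEffects-class].
#' @param truth a [SimTruth-class].
#' @param trait trait id in `truth`.
#' @param geno [GenotypeMatrix-class] used to form estimated breeding
#'   values (centered dosages times estimated effects).
#' @return list with `effectCor` (Pearson, estimated vs true per-marker
#'   effects) and `bvCor` (estimated vs true breeding values over the lines
#'   of `geno`).
#' @export
effectRecoveryReport <- function(effects, truth, trait, geno) {
  est <- markerEffects(effects)
  if (!trait %in% names(truth@effects)) stop("unknown trait: ", trait)
  true <- truth@effects[[trait]]
  d <- dosages(geno)
  if (!identical(length(true), ncol(d)))
    stop("truth and genotype marker sets disagree")
  if (!identical(names(est), colnames(d)))
    stop("marker sets of effects and genotypes disagree")
  Wc <- scale(d, center = TRUE, scale = FALSE)
  bvEst <- as.numeric(Wc %*% est)
  bvTrue <- truth@bv[rownames(d), trait]
  list(effectCor = safeCor(est, true), bvCor = safeCor(bvEst, bvTrue))
}
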
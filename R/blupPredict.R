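#' Precompute a kernel eigendecomposition for reuse across CV folds
#'
#' @param kernel a [Kernel-class].
#' @param tol relative eigenvalue cutoff; components with
#'   `lambda <= tol * max(lambda)` are dropped.
#' @return list with `vectors`, `values`, `lines`, `label`.
#' @export
kernelEigen <- function(kernel, tol = 1e-10) {
  ed <- eigen(kernelMatrix(kernel), symmetric = TRUE)
  keep <- ed$values > tol * max(ed$values)
  list(vectors = ed$vectors[, keep, drop = FALSE],
       values = ed$values[keep], lines = lineIds(kernel),
       label = kernel@type)
}

#' Fit a Bayesian kernel regression (gBLUP / TGRM-BLUP / multi-kernel)
#'
#' Model: `y = mu + sum_t Z_u u_t + Z_e s + e` with `u_t ~ N(0, sigma2_t
#' K_t)`. Each kernel is eigendecomposed and its random effect rotated into
#' the eigenbasis, where the Gibbs sampler updates one coordinate at a time;
#' per-kernel variances get scaled-inverse-chi-square priors (df
#' `dfPrior`, scale solved from `priorR2` split equally among kernels),
#' trial effects `s` and the intercept are fixed (flat prior). Lines in
#' `maskLines` are excluded from the likelihood but obtain GEBVs from the
#' same joint fit through the kernel rows.
#'
#' @param y numeric response per observation.
#' @param lines line id per observation; every id must be present in every
#'   kernel.
#' @param kernels named list of [Kernel-class] objects or [kernelEigen()]
#'   precomputes (all over the same line set).
#' @param trial optional trial/location factor per observation (fixed
#'   effects).
#' @param maskLines line ids whose observations are masked (prediction
#'   targets).
#' @param config a [wgrConfig()]; only the chain geometry, `priorR2`,
#'   `dfPrior`, `seed` and `fixVarE` fields are used.
#' @param fixVarG optional named numeric: per-kernel variances to hold
#'   fixed.
#' @return a [KernelModelFit-class]; `gebv` covers every line of the
#'   kernels, masked ones included.
#' @export
fitKernelModel <- function(y, lines, kernels, trial = NULL,
                           maskLines = character(0),
                           config = wgrConfig(), fixVarG = NULL) {
  if (!is.list(kernels)) kernels <- list(K = kernels)
  if (is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  eigens <- lapply(kernels, function(k)
    if (is(k, "Kernel")) kernelEigen(k) else k)
  lineSet <- eigens[[1]]$lines
  for (e in eigens) if (!identical(e$lines, lineSet))
    stop("all kernels must cover the same lines in the same order")
  if (!all(lines %in% lineSet))
    stop("response lines missing from kernels: ",
         paste(head(setdiff(lines, lineSet), 5), collapse = ", "))
  if (length(maskLines) && !all(maskLines %in% lineSet))
    stop("masked lines must be present in the kernels")
  keepObs <- !(lines %in% maskLines)
  if (sum(keepObs) < 3) stop("fewer than 3 unmasked observations")
  yObs <- y[keepObs]
  obsLines <- lines[keepObs]
  if (sd(yObs) == 0) stop("constant response among unmasked observations")

  X <- matrix(1, length(yObs), 1)
  fixNames <- "(Intercept)"
  if (!is.null(trial)) {
    f <- factor(trial[keepObs])
    if (nlevels(f) > 1) {
      Xt <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(Xt) <- paste0("trial", levels(f)[-1])
      fixNames <- c(fixNames, colnames(Xt))
      X <- cbind(X, Xt)
    }
  }

  rowIdx <- match(obsLines, lineSet)
  Blist <- lapply(eigens, function(e) e$vectors[rowIdx, , drop = FALSE])
  B <- cbind(X, do.call(cbind, Blist))
  group <- c(rep(0L, ncol(X)),
             unlist(lapply(seq_along(eigens), function(t)
               rep(t, ncol(Blist[[t]])))))
  lam <- c(rep(1, ncol(X)), unlist(lapply(eigens, `[[`, "values")))

  vy <- var(yObs)
  R2 <- config$priorR2
  df0 <- config$dfPrior
  nT <- length(eigens)
  meanDiag <- vapply(eigens, function(e)
    sum(e$values) / length(e$lines), 0)
  scaleG <- R2 * vy / (nT * pmax(meanDiag, 1e-8)) * (df0 + 2) / df0
  scaleE <- vy * (1 - R2) * (df0 + 2) / df0
  fixVarE <- !is.na(config$fixVarE)
  fixG <- rep(FALSE, nT)
  varGFix <- rep(0, nT)
  if (!is.null(fixVarG)) {
    idx <- match(names(fixVarG), names(eigens))
    if (anyNA(idx)) stop("fixVarG names must match kernel names")
    fixG[idx] <- TRUE
    varGFix[idx] <- fixVarG
  }

  res <- withSeed(config$seed,
    kernel_gibbs_cpp(as.numeric(yObs), B, as.integer(group), lam,
                     as.integer(nT), df0, scaleG, df0, scaleE,
                     as.integer(config$nIter), as.integer(config$burnIn),
                     as.integer(config$thin),
                     fixVarE, if (fixVarE) config$fixVarE else 0,
                     fixG, varGFix))

  coef <- res$coef
  fixef <- setNames(coef[seq_len(ncol(X))], fixNames)
  u <- matrix(0, length(lineSet), nT,
              dimnames = list(lineSet, names(eigens)))
  off <- ncol(X)
  for (t in seq_len(nT)) {
    m <- ncol(Blist[[t]])
    u[, t] <- eigens[[t]]$vectors %*% coef[off + seq_len(m)]
    off <- off + m
  }
  new("KernelModelFit", gebv = setNames(rowSums(u), lineSet), u = u,
      sigma2 = setNames(res$sigma2, names(eigens)), varE = res$varE,
      fixef = fixef)
}

# inverse-Wishart draw via the Wishart of the inverse scale
rinvwishart <- function(df, S) {
  solve(stats::rWishart(1, df, solve(S))[, , 1])
}

#' Multi-trait kernel BLUP with missing phenotypes
#'
#' `Y = 1 mu' + U + E` with rows of `U` matrix-normal (row covariance `K`,
#' unstructured trait covariance `SigmaG` under an inverse-Wishart prior)
#' and rows of `E` iid `N(0, SigmaE)`, also inverse-Wishart. The genetic
#' effects are sampled in the eigenbasis of `K`, where a joint
#' diagonalization of `SigmaE` and `SigmaG` makes every coordinate
#' conditionally independent. Missing cells of `Y` are imputed by data
#' augmentation each sweep; lines with no observed trait are legitimate
#' prediction targets and are never imputed into the likelihood of others
#' beyond their kernel connections.
#'
#' @param Y lines x traits numeric matrix with `NA` for unobserved cells;
#'   dimnames required.
#' @param kernel a [Kernel-class] covering all rows of `Y`.
#' @param config a [wgrConfig()] (chain geometry, dfPrior, seed).
#' @return a [MultiTraitFit-class].
#' @export
fitMultiTrait <- function(Y, kernel, config = wgrConfig()) {
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop("Y must carry line and trait dimnames")
  Tn <- ncol(Y); n <- nrow(Y)
  obs <- !is.na(Y)
  nObsTrait <- colSums(obs)
  if (any(nObsTrait < 3))
    stop("trait(s) observed for fewer than 3 lines: ",
         paste(colnames(Y)[nObsTrait < 3], collapse = ", "))
  K <- subsetKernel(kernel, rownames(Y))
  ed <- eigen(kernelMatrix(K), symmetric = TRUE)
  lamFloor <- max(ed$values) * 1e-8
  lam <- pmax(ed$values, lamFloor)
  Q <- ed$vectors

  df0 <- Tn + 2
  vars <- apply(Y, 2, var, na.rm = TRUE)
  meanDiag <- mean(diag(kernelMatrix(K)))
  S0g <- diag(pmax(vars, 1e-8) * 0.5 / meanDiag, Tn)
  S0e <- diag(pmax(vars, 1e-8) * 0.5, Tn)

  # missingness pattern groups for block imputation
  pat <- apply(obs, 1, paste, collapse = "")
  patGroups <- split(seq_len(n), pat)

  withSeed(config$seed, {
    mu <- colMeans(Y, na.rm = TRUE)
    Yc <- Y
    for (j in seq_len(Tn)) Yc[!obs[, j], j] <- mu[j]
    Ug <- matrix(0, n, Tn)
    Sg <- diag(pmax(vars, 1e-8) / (2 * meanDiag), Tn)
    Se <- diag(pmax(vars, 1e-8) / 2, Tn)

    nIter <- config$nIter; burnIn <- config$burnIn; thin <- config$thin
    postU <- matrix(0, n, Tn); postSg <- matrix(0, Tn, Tn)
    postSg2 <- matrix(0, Tn, Tn)
    postSe <- matrix(0, Tn, Tn); postMu <- numeric(Tn); nKeep <- 0

    for (it in seq_len(nIter)) {
      # 1. impute missing cells given mu, Ug, Se
      M <- sweep(Ug, 2, mu, `+`)
      for (g in patGroups) {
        o <- obs[g[1], ]
        if (all(o)) next
        mi <- which(!o); oi <- which(o)
        if (length(oi) == 0) {
          Yc[g, mi] <- M[g, mi, drop = FALSE] +
            matrix(rnorm(length(g) * length(mi)), length(g)) %*%
              chol(Se[mi, mi, drop = FALSE])
        } else {
          Soo <- Se[oi, oi, drop = FALSE]
          Smo <- Se[mi, oi, drop = FALSE]
          A <- Smo %*% solve(Soo)
          condS <- Se[mi, mi, drop = FALSE] - A %*% t(Smo)
          condS <- (condS + t(condS)) / 2
          mean <- M[g, mi, drop = FALSE] +
            (Yc[g, oi, drop = FALSE] - M[g, oi, drop = FALSE]) %*% t(A)
          Yc[g, mi] <- mean +
            matrix(rnorm(length(g) * length(mi)), length(g)) %*%
              chol(condS + diag(1e-10, length(mi)))
        }
      }
      # 2. intercepts
      R0 <- Yc - Ug
      mu <- colMeans(R0) +
        drop(rnorm(Tn) %*% chol(Se / n + diag(1e-12, Tn)))
      # 3. genetic values in the K eigenbasis with joint diagonalization
      eSe <- eigen(Se, symmetric = TRUE)
      SeIsqrt <- eSe$vectors %*% (t(eSe$vectors) / sqrt(pmax(eSe$values, 1e-12)))
      SeSqrt <- eSe$vectors %*% (t(eSe$vectors) * sqrt(pmax(eSe$values, 1e-12)))
      Sw <- SeIsqrt %*% Sg %*% SeIsqrt
      eS <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)
      V <- eS$vectors; dS <- pmax(eS$values, 1e-12)
      Yt <- crossprod(Q, sweep(Yc, 2, mu))          # n x T
      Z <- Yt %*% SeIsqrt %*% V                     # independent coords
      ld <- outer(lam, dS)                          # n x T prior variances
      pv <- ld / (1 + ld)
      Tt <- pv * Z + sqrt(pv) * matrix(rnorm(n * Tn), n)
      Gt <- Tt %*% t(SeSqrt %*% V)                  # back to trait scale
      Ug <- Q %*% Gt
      # 4. covariance components
      Sg <- rinvwishart(df0 + n, S0g + crossprod(Gt / sqrt(lam)))
      E <- Yc - sweep(Ug, 2, mu, `+`)
      Se <- rinvwishart(df0 + n, S0e + crossprod(E))
      Sg <- (Sg + t(Sg)) / 2; Se <- (Se + t(Se)) / 2

      if (it > burnIn && (it - burnIn) %% thin == 0) {
        nKeep <- nKeep + 1
        postU <- postU + Ug; postSg <- postSg + Sg
        postSg2 <- postSg2 + Sg^2
        postSe <- postSe + Se; postMu <- postMu + mu
      }
    }
    U <- postU / nKeep
    dimnames(U) <- dimnames(Y)
    Sg <- postSg / nKeep; Se <- postSe / nKeep
    dimnames(Sg) <- dimnames(Se) <- list(colnames(Y), colnames(Y))
    fit <- new("MultiTraitFit", U = U, SigmaG = Sg, SigmaE = Se,
               mu = setNames(postMu / nKeep, colnames(Y)))
    # posterior sd of the genetic covariance entries, for calibration checks
    attr(fit, "SigmaG.sd") <- sqrt(pmax(postSg2 / nKeep - Sg^2, 0))
    fit
  })
}

#' Extract genomic estimated breeding values from a fit
#'
#' @param fit a [KernelModelFit-class] or [MultiTraitFit-class].
#' @param lines line ids to extract (must be present in the fit).
#' @param trait focal-trait column for multi-trait fits.
#' @return named numeric GEBV vector.
#' @export
predictGEBV <- function(fit, lines, trait = NULL) {
  if (is(fit, "KernelModelFit")) {
    missing <- setdiff(lines, names(fit@gebv))
    if (length(missing)) stop("unknown line(s): ",
                              paste(head(missing, 5), collapse = ", "))
    fit@gebv[lines]
  } else if (is(fit, "MultiTraitFit")) {
    if (is.null(trait)) trait <- colnames(fit@U)[ncol(fit@U)]
    missing <- setdiff(lines, rownames(fit@U))
    if (length(missing)) stop("unknown line(s): ",
                              paste(head(missing, 5), collapse = ", "))
    setNames(fit@U[lines, trait], lines)
  } else stop("unsupported fit object")
}
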
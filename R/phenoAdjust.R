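#' Fit the augmented-design mixed model by EM-REML
#'
#' Model for plot-level records of one trait in one trial:
#' `y = mu + beta * covariate + check + entry + block + batch + e`,
#' where `check` is a fixed effect for each replicated check variety,
#' unreplicated entries enter an iid random entry term (assumed unrelated
#' at this stage), and `block` and `batch` are iid random effects. Variance
#' components are estimated by EM-REML on the dense mixed-model equations
#' with periodic Aitken extrapolation; entry BLUPs and their prediction
#' error variances come from the inverse coefficient matrix at the
#' converged components.
#'
#' @param records long-format phenotype data.frame with columns line_id,
#'   trait, trial, block, batch, is_check, covariate, value.
#' @param trait,trial optional subset selectors; the model covers a single
#'   trait and trial.
#' @param includeCovariate logical; `NULL` (default) includes the covariate
#'   whenever it varies across records.
#' @param maxIter,tol EM iteration cap and relative-change tolerance.
#' @param fixedVarcomp optional named vector (entry, block, batch,
#'   residual); when supplied REML is skipped and BLUPs/PEVs are computed
#'   at these components.
#' @param computeLogLik track the REML log-likelihood path (adds an O(n^3)
#'   step per iteration; default on for n <= 800).
#' @return an [AugmentedModelFit-class].
#' @export
fitAugmentedModel <- function(records, trait = NULL, trial = NULL,
                              includeCovariate = NULL, maxIter = 500,
                              tol = 1e-8, fixedVarcomp = NULL,
                              computeLogLik = NULL) {
  req <- c("line_id", "trait", "trial", "block", "batch", "is_check", "value")
  if (!all(req %in% names(records)))
    stop("records must contain columns: ", paste(req, collapse = ", "))
  if (!is.null(trait)) records <- records[records$trait == trait, ]
  if (!is.null(trial)) records <- records[records$trial == trial, ]
  if (nrow(records) == 0) stop("no records after subsetting")
  if (length(unique(records$trait)) > 1)
    stop("records span multiple traits; supply `trait`")
  if (length(unique(records$trial)) > 1)
    stop("records span multiple trials; fit one trial at a time")
  if (!any(records$is_check))
    stop("augmented-design model needs at least one replicated check")

  y <- records$value
  n <- length(y)
  if (is.null(computeLogLik)) computeLogLik <- n <= 800

  hasCov <- "covariate" %in% names(records) &&
    sd(records$covariate) > 0
  useCov <- if (is.null(includeCovariate)) hasCov else includeCovariate

  checks <- sort(unique(records$line_id[records$is_check]))
  entries <- sort(unique(records$line_id[!records$is_check]))

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (useCov) X <- cbind(X, covariate = records$covariate)
  for (ck in checks) X <- cbind(X, as.numeric(records$line_id == ck))
  colnames(X)[(ncol(X) - length(checks) + 1):ncol(X)] <- checks
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) # drop aliased columns (e.g. a check in every plot)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  makeZ <- function(f) {
    f <- factor(f)
    Z <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Z
  }
  Zg <- if (length(entries) > 0) {
    Ze <- matrix(0, n, length(entries), dimnames = list(NULL, entries))
    idx <- match(records$line_id, entries)
    ok <- !is.na(idx)
    Ze[cbind(which(ok), idx[ok])] <- 1
    Ze
  } else matrix(0, n, 0)
  Zb <- makeZ(records$block)
  Zt <- makeZ(records$batch)
  if (ncol(Zb) > 1 && ncol(Zb) == ncol(Zt) &&
      all(apply(Zb == 1, 1, which) == apply(Zt == 1, 1, which)))
    warning("block and batch are confounded (identical partitions); ",
            "their variances are not separable")

  Zs <- list(entry = Zg, block = Zb, batch = Zt)
  q <- vapply(Zs, ncol, 0L)
  p <- ncol(X)
  W <- cbind(X, do.call(cbind, Zs))
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  ridx <- split(p + seq_len(sum(q)), rep(names(Zs), q)) # columns per component

  vy <- var(y)
  theta <- c(entry = vy / 2, block = vy / 10, batch = vy / 10,
             residual = vy / 2)
  if (!is.null(fixedVarcomp)) {
    theta <- fixedVarcomp[c("entry", "block", "batch", "residual")]
    maxIter <- 0
  }
  floorV <- vy * 1e-12 + 1e-300

  solveMME <- function(theta) {
    C <- WtW
    for (k in names(Zs)) {
      if (q[[k]] == 0) next
      lam <- theta[["residual"]] / max(theta[[k]], floorV)
      dd <- ridx[[k]]
      C[cbind(dd, dd)] <- C[cbind(dd, dd)] + lam
    }
    Cinv <- solve(C)
    list(sol = Cinv %*% Wty, Cinv = Cinv)
  }

  remlLogLik <- function(theta) {
    V <- diag(theta[["residual"]], n)
    for (k in names(Zs)) if (q[[k]] > 0)
      V <- V + theta[[k]] * tcrossprod(Zs[[k]])
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] +
              sum(r * (Vi %*% r)))
  }

  llPath <- numeric(0)
  hist <- list()
  converged <- is.null(fixedVarcomp) == FALSE
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    mme <- solveMME(theta)
    sol <- mme$sol
    new <- theta
    for (k in names(Zs)) {
      if (q[[k]] == 0) { new[[k]] <- 0; next }
      dd <- ridx[[k]]
      uk <- sol[dd]
      trC <- sum(diag(mme$Cinv)[dd])
      new[[k]] <- max((sum(uk^2) + theta[["residual"]] * trC) / q[[k]], floorV)
    }
    new[["residual"]] <- max((yty - sum(sol * Wty)) / (n - p), floorV)
    if (computeLogLik) llPath <- c(llPath, remlLogLik(new))
    # components collapsing to the boundary are excluded from the
    # convergence criterion (EM approaches zero geometrically); a stalled
    # likelihood is also accepted as converged
    active <- pmax(new, theta) > 1e-4 * vy
    rel <- if (any(active))
      max(abs(new[active] - theta[active]) / (abs(theta[active]) + 1e-12))
    else 0
    if (computeLogLik && length(llPath) >= 2 &&
        abs(diff(tail(llPath, 2))) < 1e-8 * (1 + abs(tail(llPath, 1))))
      rel <- 0
    theta <- new
    hist <- c(hist, list(theta))
    if (rel < tol) { converged <- TRUE; break }
    # Aitken extrapolation on the component vector every 5th sweep
    if (iter %% 5 == 0 && length(hist) >= 3) {
      h <- hist[(length(hist) - 2):length(hist)]
      r <- (h[[3]] - h[[2]]) / (h[[2]] - h[[1]] + 1e-300)
      ok <- is.finite(r) & abs(r) < 1
      acc <- h[[3]]
      acc[ok] <- h[[2]][ok] + (h[[3]][ok] - h[[2]][ok]) / (1 - r[ok])
      if (all(acc > 0)) {
        if (computeLogLik) {
          if (remlLogLik(acc) >= llPath[length(llPath)]) theta <- acc
        } else theta <- acc
      }
    }
  }
  if (!converged && is.null(fixedVarcomp)) {
    cond <- simpleError(paste0("EM-REML did not converge in ", maxIter,
                               " iterations"))
    attr(cond, "logLikPath") <- llPath
    stop(cond)
  }

  mme <- solveMME(theta)
  sol <- drop(mme$sol)
  fixef <- setNames(sol[seq_len(p)], colnames(X))
  dd <- ridx[["entry"]]
  blup <- if (length(dd)) setNames(sol[dd], entries) else
    setNames(numeric(0), character(0))
  pev <- if (length(dd))
    setNames(theta[["residual"]] * diag(mme$Cinv)[dd], entries) else
      setNames(numeric(0), character(0))

  new("AugmentedModelFit", fixef = fixef, varcomp = theta, blup = blup,
      pev = pev,
      convergence = list(iterations = iter, logLik = llPath,
                         converged = converged || !is.null(fixedVarcomp)))
}

#' Deregress entry BLUPs
#'
#' Removes the shrinkage of a BLUP before it is used as a response in
#' marker-effect estimation: `g* = g / (1 - PEV / varG)`, i.e. the BLUP
#' divided by its reliability. Entries whose reliability falls at or below
#' `reliabilityFloor` (including any with `PEV >= varG`) are excluded and
#' listed rather than allowed to blow up the ratio.
#'
#' @param fit an [AugmentedModelFit-class].
#' @param reliabilityFloor exclusion threshold for `1 - PEV/varG`.
#' @return a [DeregressedValues-class].
#' @export
deregress <- function(fit, reliabilityFloor = 0.1) {
  varG <- fit@varcomp[["entry"]]
  if (varG <= 0) stop("entry variance component must be positive")
  rel <- 1 - fit@pev / varG
  bad <- rel <= reliabilityFloor
  reason <- ifelse(fit@pev >= varG, "PEV >= varG", "low reliability")
  table <- data.frame(line_id = names(fit@blup)[!bad],
                      value = fit@blup[!bad] / rel[!bad],
                      reliability = rel[!bad], stringsAsFactors = FALSE,
                      row.names = NULL)
  excluded <- data.frame(line_id = names(fit@blup)[bad],
                         reason = reason[bad], stringsAsFactors = FALSE,
                         row.names = NULL)
  new("DeregressedValues", table = table, excluded = excluded)
}

#' Heritabilities and genetic/phenotypic correlations from a multi-trait fit
#'
#' @param fit a [MultiTraitFit-class].
#' @return list with `h2` (per trait, genetic / (genetic + residual)
#'   variance), `genomicCor` and `phenotypicCor` matrices.
#' @export
extractGeneticParams <- function(fit) {
  Sg <- fit@SigmaG; Se <- fit@SigmaE
  for (S in list(Sg, Se))
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("covariance estimate is not positive semi-definite")
  h2 <- diag(Sg) / (diag(Sg) + diag(Se))
  list(h2 = setNames(h2, colnames(fit@U)),
       genomicCor = stats::cov2cor(Sg),
       phenotypicCor = stats::cov2cor(Sg + Se))
}
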
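# Shared fixtures and independent oracles for the test suite.

# iid inbred dosage matrix (no LD), values in {0, 2}
makeInbredGeno <- function(n, P, maf = c(0.1, 0.5), seed = 1) {
  withr::with_seed(seed, {
    p <- runif(P, maf[1], maf[2])
    d <- matrix(2 * rbinom(n * P, 1, rep(p, each = n)), n, P)
    # guarantee polymorphism so kernel builders need no extra filtering
    for (j in which(apply(d, 2, sd) == 0)) {
      i <- sample(n, 1)
      d[i, j] <- 2 - d[i, j]
    }
    dimnames(d) <- list(sprintf("L%04d", seq_len(n)),
                        sprintf("M%04d", seq_len(P)))
    GenotypeMatrix(d)
  })
}

# GLS route to BLUPs of the augmented model: independent of the MME solve
# used by fitAugmentedModel. u_hat = varG * Zg' Vinv (y - X betaHat).
glsBlup <- function(y, X, Zg, Zb, Zt, vc) {
  n <- length(y)
  V <- diag(vc[["residual"]], n) +
    vc[["entry"]] * tcrossprod(Zg) +
    vc[["block"]] * tcrossprod(Zb) +
    vc[["batch"]] * tcrossprod(Zt)
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  drop(vc[["entry"]] * crossprod(Zg, Vi %*% r))
}

# exact joint posterior mean of (mu, a) for BRR with fixed variances:
# the Bayesian ridge normal equations
ridgePosteriorMean <- function(y, W, lambda) {
  A <- cbind(1, W)
  C <- crossprod(A)
  diag(C)[-1] <- diag(C)[-1] + lambda
  drop(solve(C, crossprod(A, y)))[-1]
}

# dense-covariance Gibbs sampler for the single-kernel model: the slow
# reference implementation against which the eigenbasis sampler is checked.
# Priors replicate fitKernelModel's (df, scales from priorR2).
denseKernelGibbs <- function(y, K, nIter, burnIn, thin, df = 5, R2 = 0.5,
                             seed = 1) {
  set.seed(seed)
  n <- length(y)
  vy <- var(y)
  meanDiag <- mean(diag(K))
  scaleG <- R2 * vy / meanDiag * (df + 2) / df
  scaleE <- vy * (1 - R2) * (df + 2) / df
  Ki <- solve(K + diag(1e-8, n))
  varG <- scaleG; varE <- scaleE
  mu <- mean(y); u <- rep(0, n)
  acc <- rep(0, n); kept <- 0
  for (it in seq_len(nIter)) {
    mu <- rnorm(1, mean(y - u), sqrt(varE / n))
    Prec <- diag(n) / varE + Ki / varG
    ch <- chol(Prec)
    m <- backsolve(ch, forwardsolve(t(ch), (y - mu) / varE))
    u <- m + backsolve(ch, rnorm(n))
    varG <- as.numeric((crossprod(u, Ki %*% u) + df * scaleG) /
                         rchisq(1, n + df))
    varE <- (sum((y - mu - u)^2) + df * scaleE) / rchisq(1, n + df)
    if (it > burnIn && (it - burnIn) %% thin == 0) {
      acc <- acc + u; kept <- kept + 1
    }
  }
  setNames(acc / kept, names(y))
}

# tiny deterministic CVReport built from given run-mean accuracies
makeReport <- function(accA, accB, a = "A", b = "B") {
  runs <- seq_along(accA)
  results <- rbind(
    data.frame(run = runs, fold = 1, method = a, trial = NA_character_,
               r = accA),
    data.frame(run = runs, fold = 1, method = b, trial = NA_character_,
               r = accB))
  runMeans <- rbind(
    data.frame(run = runs, method = a, accuracy = accA),
    data.frame(run = runs, method = b, accuracy = accB))
  new("CVReport", results = results, runMeans = runMeans,
      methods = c(a, b), nRuns = length(runs))
}
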
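identityKernel <- function(n) {
  K <- diag(n)
  dimnames(K) <- list(sprintf("L%03d", 1:n), sprintf("L%03d", 1:n))
  new("Kernel", K = K, type = "GRM", bending = 0)
}

test_that("identity-kernel GEBVs match the closed-form shrinkage solution", {
  n <- 40
  y <- withr::with_seed(1, rnorm(n, 2, 1.2))
  names(y) <- sprintf("L%03d", 1:n)
  varG <- 0.8; varE <- 0.6
  fit <- fitKernelModel(y, names(y), identityKernel(n),
                        config = wgrConfig(nIter = 12000, burnIn = 3000,
                                           thin = 3, seed = 2,
                                           fixVarE = varE),
                        fixVarG = c(K = varG))
  # joint posterior mean of (mu, u) solves the ridge-like normal equations
  lam <- varE / varG
  A <- cbind(1, diag(n))
  C <- crossprod(A); diag(C)[-1] <- diag(C)[-1] + lam
  sol <- drop(solve(C, crossprod(A, y)))
  expect_lt(max(abs(gebv(fit)[names(y)] - sol[-1])), 0.05)
  # shrinkage factor visible relative to centered observations
  k <- varG / (varG + varE)
  expect_equal(unname(gebv(fit)[names(y)]),
               unname(k * (y - mean(y))), tolerance = 0.15)
})

test_that("duplicated kernels split signal but preserve total GEBVs", {
  geno <- makeInbredGeno(60, 150, seed = 3)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 150, type = "GRM", bending = 0)
  u <- withr::with_seed(4, as.numeric(M@M %*% rnorm(150, 0, 0.1)))
  y <- u + withr::with_seed(5, rnorm(60, 0, 0.4))
  names(y) <- lineIds(geno)
  cfg <- wgrConfig(nIter = 4000, burnIn = 1500, thin = 2, seed = 6)
  f1 <- fitKernelModel(y, names(y), list(G = K), config = cfg)
  f2 <- fitKernelModel(y, names(y), list(G1 = K, G2 = K), config = cfg)
  expect_gt(cor(gebv(f1)[names(y)], gebv(f2)[names(y)]), 0.98)
  # total is the sum over kernels by construction
  expect_equal(unname(gebv(f2)), unname(rowSums(f2@u)))
})

test_that("near-zero residual variance interpolates training data", {
  n <- 30
  y <- withr::with_seed(7, rnorm(n))
  names(y) <- sprintf("L%03d", 1:n)
  fit <- fitKernelModel(y, names(y), identityKernel(n),
                        config = wgrConfig(nIter = 3000, burnIn = 1000,
                                           thin = 2, seed = 8,
                                           fixVarE = 1e-4))
  expect_gt(cor(gebv(fit)[names(y)], y), 0.999)
})

test_that("observation order does not change the fit materially", {
  geno <- makeInbredGeno(50, 100, seed = 9)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 100, type = "GRM", bending = 0)
  y <- withr::with_seed(10, as.numeric(M@M %*% rnorm(100, 0, 0.1)) +
                          rnorm(50, 0, 0.3))
  names(y) <- lineIds(geno)
  perm <- withr::with_seed(11, sample(50))
  cfg <- wgrConfig(nIter = 3000, burnIn = 1000, thin = 2, seed = 12)
  f1 <- fitKernelModel(y, names(y), list(G = K), config = cfg)
  f2 <- fitKernelModel(y[perm], names(y)[perm], list(G = K), config = cfg)
  expect_gt(cor(gebv(f1)[names(y)], gebv(f2)[names(y)]), 0.999)
})

test_that("trial effects absorb trial-level shifts without moving GEBVs", {
  geno <- makeInbredGeno(40, 80, seed = 13)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 80, type = "GRM", bending = 0)
  u <- withr::with_seed(14, as.numeric(M@M %*% rnorm(80, 0, 0.12)))
  lines <- rep(lineIds(geno), 2)
  trial <- rep(c("T1", "T2"), each = 40)
  y <- u[match(lines, lineIds(geno))] +
    withr::with_seed(15, rnorm(80, 0, 0.3))
  cfg <- wgrConfig(nIter = 3000, burnIn = 1000, thin = 2, seed = 16)
  f1 <- fitKernelModel(y, lines, list(G = K), trial = trial, config = cfg)
  yShift <- y + ifelse(trial == "T2", 5, 0)
  f2 <- fitKernelModel(yShift, lines, list(G = K), trial = trial,
                       config = cfg)
  expect_gt(cor(gebv(f1)[lineIds(geno)], gebv(f2)[lineIds(geno)]), 0.99)
  expect_equal(f2@fixef[["trialT2"]] - f1@fixef[["trialT2"]], 5,
               tolerance = 0.3)
})

test_that("masked lines obtain GEBVs from the joint fit", {
  geno <- makeInbredGeno(80, 200, seed = 17)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 200, type = "GRM", bending = 0)
  u <- withr::with_seed(18, as.numeric(M@M %*% rnorm(200, 0, 0.1)))
  y <- u + withr::with_seed(19, rnorm(80, 0, 0.4))
  names(y) <- lineIds(geno)
  mask <- lineIds(geno)[1:16]
  fit <- fitKernelModel(y, names(y), list(G = K), maskLines = mask,
                        config = wgrConfig(preset = "test", seed = 20))
  expect_true(all(is.finite(predictGEBV(fit, mask))))
  expect_gt(cor(predictGEBV(fit, mask), u[1:16]), 0.3)
  expect_error(predictGEBV(fit, "unknown-line"), "unknown")
})

test_that("single-trait multi-trait fit collapses to the kernel model", {
  geno <- makeInbredGeno(60, 150, seed = 21)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 150 + diag(1e-6, 60),
           type = "GRM", bending = 0)
  dimnames(K@K) <- list(lineIds(geno), lineIds(geno))
  u <- withr::with_seed(22, as.numeric(M@M %*% rnorm(150, 0, 0.1)))
  y <- u + withr::with_seed(23, rnorm(60, 0, 0.4))
  names(y) <- lineIds(geno)
  cfg <- wgrConfig(nIter = 5000, burnIn = 2000, thin = 2, seed = 24)
  f1 <- fitKernelModel(y, names(y), list(G = K), config = cfg)
  Y <- matrix(y, ncol = 1, dimnames = list(names(y), "t"))
  f2 <- fitMultiTrait(Y, K, cfg)
  expect_gt(cor(gebv(f1)[names(y)], f2@U[names(y), "t"]), 0.99)
})

test_that("uncorrelated traits give a near-zero genetic covariance", {
  geno <- makeInbredGeno(80, 200, seed = 25)
  M <- centerScale(geno)
  K <- new("Kernel", K = tcrossprod(M@M) / 200 + diag(1e-6, 80),
           type = "GRM", bending = 0)
  dimnames(K@K) <- list(lineIds(geno), lineIds(geno))
  withr::with_seed(26, {
    u1 <- as.numeric(M@M %*% rnorm(200, 0, 0.1))
    u2 <- as.numeric(M@M[, 200:1] %*% rnorm(200, 0, 0.1))
    Y <- cbind(t1 = u1 + rnorm(80, 0, 0.3), t2 = u2 + rnorm(80, 0, 0.3))
  })
  rownames(Y) <- lineIds(geno)
  fit <- fitMultiTrait(Y, K, wgrConfig(nIter = 4000, burnIn = 1500,
                                       thin = 2, seed = 27))
  sd12 <- attr(fit, "SigmaG.sd")[1, 2]
  expect_lt(abs(fit@SigmaG[1, 2]), 2.5 * sd12)
})

test_that("a correlated helper trait improves focal predictions", {
  wins <- 0
  for (r in 1:10) {
    geno <- makeInbredGeno(90, 150, seed = 500 + r)
    M <- centerScale(geno)
    K <- new("Kernel", K = tcrossprod(M@M) / 150 + diag(1e-6, 90),
             type = "GRM", bending = 0)
    dimnames(K@K) <- list(lineIds(geno), lineIds(geno))
    withr::with_seed(600 + r, {
      a <- rnorm(150, 0, 0.1)
      u1 <- as.numeric(M@M %*% a)
      u2 <- as.numeric(M@M %*% (0.9 * a + sqrt(1 - 0.81) *
                                  rnorm(150, 0, 0.1)))
      yF <- u1 + rnorm(90, 0, 0.5)   # focal, low information
      yH <- u2 + rnorm(90, 0, 0.2)   # helper, well measured
    })
    test <- lineIds(geno)[1:20]
    Y <- cbind(helper = yH, focal = yF)
    rownames(Y) <- lineIds(geno)
    Y[test, "focal"] <- NA
    cfg <- wgrConfig(nIter = 2500, burnIn = 800, thin = 2, seed = 700 + r)
    mt <- fitMultiTrait(Y, K, cfg)
    yMasked <- setNames(yF, lineIds(geno))
    st <- fitKernelModel(yMasked, names(yMasked), list(G = K),
                         maskLines = test, config = cfg)
    accMT <- cor(mt@U[test, "focal"], u1[1:20])
    accST <- cor(predictGEBV(st, test), u1[1:20])
    if (accMT > accST) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("trait observed for too few lines errors", {
  Y <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("L%03d", 1:10), c("a", "b")))
  Y[1:8, 2] <- NA
  expect_error(fitMultiTrait(Y, identityKernel(10), wgrConfig(preset = "test")),
               "fewer than 3")
})
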
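makeRecords <- function(nEntries = 60, nBlocks = 6, h2 = 0.5, seed = 1,
                        blockVarShare = 0.2, batchVarShare = 0.2,
                        covariateBeta = 0.4) {
  bv <- withr::with_seed(seed, rnorm(nEntries, 0, 2))
  names(bv) <- sprintf("E%03d", seq_len(nEntries))
  list(bv = bv,
       rec = applyFieldDesign(bv, nBlocks = nBlocks, nChecks = 2,
                              batchSize = 15, blockVarShare = blockVarShare,
                              batchVarShare = batchVarShare,
                              trialVarShare = 0, covariateBeta = covariateBeta,
                              h2 = h2, seed = seed + 1))
}

test_that("BLUPs at fixed components match the GLS oracle to 1e-8", {
  x <- makeRecords(nEntries = 6, nBlocks = 2, seed = 3)
  vc <- c(entry = 2, block = 0.5, batch = 0.4, residual = 1)
  fit <- fitAugmentedModel(x$rec, fixedVarcomp = vc)

  rec <- x$rec
  entries <- sort(unique(rec$line_id[!rec$is_check]))
  checks <- sort(unique(rec$line_id[rec$is_check]))
  X <- cbind(1, rec$covariate,
             vapply(checks, function(ck) as.numeric(rec$line_id == ck),
                    numeric(nrow(rec))))
  Zg <- vapply(entries, function(e) as.numeric(rec$line_id == e),
               numeric(nrow(rec)))
  Zb <- vapply(sort(unique(rec$block)), function(b)
    as.numeric(rec$block == b), numeric(nrow(rec)))
  Zt <- vapply(sort(unique(rec$batch)), function(b)
    as.numeric(rec$batch == b), numeric(nrow(rec)))
  oracle <- glsBlup(rec$value, X, Zg, Zb, Zt, vc)
  expect_equal(unname(fit@blup[entries]), unname(oracle), tolerance = 1e-8)
})

test_that("EM-REML converges with a non-decreasing likelihood path", {
  x <- makeRecords(nEntries = 80, nBlocks = 8, h2 = 0.6, seed = 11)
  fit <- fitAugmentedModel(x$rec)
  expect_true(fit@convergence$converged)
  ll <- fit@convergence$logLik
  expect_true(all(diff(ll) > -1e-6))
  expect_true(all(fit@varcomp >= 0))
  # covariate slope recovered to within sampling noise (SE ~ 0.3 here)
  expect_lt(abs(fit@fixef[["covariate"]] - 0.4), 1)
})

test_that("EM-REML agrees with lme4 on components and BLUPs", {
  skip_if_not_installed("lme4")
  x <- makeRecords(nEntries = 70, nBlocks = 7, seed = 21)
  rec <- x$rec
  fit <- fitAugmentedModel(rec)

  rec$new <- as.numeric(!rec$is_check)
  rec$checkF <- factor(ifelse(rec$is_check, rec$line_id, "entry"))
  lfit <- lme4::lmer(
    value ~ 1 + covariate + checkF + (0 + new | line_id) +
      (1 | block) + (1 | batch),
    data = rec, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lfit))
  vEntry <- vc$vcov[vc$grp == "line_id"]
  vBlock <- vc$vcov[vc$grp == "block"]
  vRes <- vc$vcov[vc$grp == "Residual"]
  expect_equal(fit@varcomp[["entry"]], vEntry, tolerance = 0.02)
  expect_equal(fit@varcomp[["block"]], vBlock, tolerance = 0.05)
  expect_equal(fit@varcomp[["residual"]], vRes, tolerance = 0.02)

  re <- lme4::ranef(lfit)$line_id
  entries <- names(fit@blup)
  expect_gt(cor(fit@blup, re[entries, "new"]), 0.999)
})

test_that("EM-REML recovers the generating entry variance", {
  # no block/batch variance, replicated entries: the generating genetic
  # variance is the oracle
  ratios <- vapply(1:5, function(r) {
    bv <- withr::with_seed(300 + r, setNames(rnorm(100, 0, 2),
                                             sprintf("E%03d", 1:100)))
    rec <- applyFieldDesign(bv, nTrials = 2, nBlocks = 8, nChecks = 2,
                            blockVarShare = 0, batchVarShare = 0,
                            trialVarShare = 0, covariateBeta = 0, h2 = 0.5,
                            seed = 400 + r)
    rec$block <- paste(rec$trial, rec$block)
    rec$batch <- paste(rec$trial, rec$batch)
    rec$trial <- "T01"
    fit <- fitAugmentedModel(rec, includeCovariate = FALSE)
    fit@varcomp[["entry"]] / var(bv)
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("degenerate designs are handled", {
  x <- makeRecords(nEntries = 10, nBlocks = 2, seed = 31)
  rec <- x$rec[x$rec$is_check & x$rec$line_id == "CHK01", ]
  fit <- fitAugmentedModel(rec, fixedVarcomp = c(entry = 1, block = 0.5,
                                                 batch = 0.5, residual = 1))
  expect_length(fit@blup, 0)
  expect_error(fitAugmentedModel(x$rec[!x$rec$is_check, ]), "check")
})

test_that("deregression follows g / (1 - PEV/varG) with exclusions", {
  fit <- new("AugmentedModelFit",
             fixef = c("(Intercept)" = 0),
             varcomp = c(entry = 0.8, block = 0, batch = 0, residual = 1),
             blup = c(a = 0.5, b = -0.3, c = 0.2, d = 0.1),
             pev = c(a = 0.2, b = 0, c = 0.4, d = 0.85),
             convergence = list(iterations = 1, logLik = numeric(0),
                                converged = TRUE))
  dv <- deregress(fit, reliabilityFloor = 0.1)
  tab <- dv@table
  # worked value: 0.5 / (1 - 0.2/0.8) = 0.6667
  expect_equal(tab$value[tab$line_id == "a"], 0.6667, tolerance = 1e-4)
  # PEV = 0 keeps the BLUP untouched
  expect_equal(tab$value[tab$line_id == "b"], -0.3)
  # PEV = varG/2 doubles it
  expect_equal(tab$value[tab$line_id == "c"], 0.4)
  # PEV >= floor boundary: reliability 1 - 0.85/0.8 < 0 -> excluded
  expect_true("d" %in% dv@excluded$line_id)
  # deregression only inflates
  expect_true(all(abs(tab$value) >= abs(fit@blup[tab$line_id]) - 1e-12))
})

test_that("deregression is scale-equivariant through the full fit", {
  x <- makeRecords(nEntries = 30, nBlocks = 4, seed = 41)
  rec2 <- x$rec
  rec2$value <- rec2$value * 3
  d1 <- deregress(fitAugmentedModel(x$rec))
  d2 <- deregress(fitAugmentedModel(rec2))
  common <- intersect(d1@table$line_id, d2@table$line_id)
  # stopping criteria are not exactly scale-free, so allow convergence-level
  # differences
  expect_equal(d2@table$value[match(common, d2@table$line_id)],
               3 * d1@table$value[match(common, d1@table$line_id)],
               tolerance = 5e-3)
})

test_that("genetic parameters are read off a multi-trait fit", {
  Sg <- matrix(c(0.6, 0.3, 0.3, 0.5), 2, 2)
  Se <- matrix(c(0.4, 0, 0, 0.5), 2, 2)
  fit <- new("MultiTraitFit",
             U = matrix(0, 4, 2, dimnames = list(letters[1:4], c("A", "B"))),
             SigmaG = Sg, SigmaE = Se, mu = c(A = 0, B = 0))
  p <- extractGeneticParams(fit)
  expect_equal(unname(p$h2), c(0.6, 0.5))
  expect_equal(p$genomicCor[1, 2], 0.3 / sqrt(0.6 * 0.5))
  expect_equal(p$phenotypicCor[1, 2], 0.3 / sqrt(1.0 * 1.0))

  diagFit <- fit
  diagFit@SigmaG <- diag(c(0.6, 0.5))
  expect_equal(extractGeneticParams(diagFit)$genomicCor[1, 2], 0)
})
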
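test_that("inbred coding and seed reproducibility hold", {
  cfg <- simConfig(nLinesDiscovery = 40, nLinesElite = 30, nOverlap = 5,
                   nMarkers = 60, nLdBlocks = 12, nFoundersPerBlock = 4,
                   residualHetRate = 0, seed = 11)
  sim <- simulateGenotypes(cfg)
  d <- dosages(sim$geno)
  expect_true(all(d %in% c(0, 2)))
  expect_length(intersect(sim$discovery, sim$elite), 5)
  sim2 <- simulateGenotypes(cfg)
  expect_identical(dosages(sim2$geno), d)

  cfgHet <- simConfig(nLinesDiscovery = 100, nLinesElite = 30, nOverlap = 0,
                      nMarkers = 200, nLdBlocks = 40, residualHetRate = 0.05,
                      seed = 3)
  dh <- dosages(simulateGenotypes(cfgHet)$geno)
  expect_gt(mean(dh == 1), 0.03)
  expect_lt(mean(dh == 1), 0.07)

  expect_error(simulateGenotypes(
    simConfig(nFoundersPerBlock = 1, nMarkers = 10, nLdBlocks = 2)),
    "polymorphism")
  expect_error(simConfig(nOverlap = 50, nLinesDiscovery = 40,
                         nLinesElite = 45), "nOverlap")
})

test_that("LD structure follows the founder-mosaic blocks", {
  # one marker per block: independence
  cfg <- simConfig(nLinesDiscovery = 400, nLinesElite = 10, nOverlap = 0,
                   nMarkers = 40, nLdBlocks = 40, nFoundersPerBlock = 8,
                   residualHetRate = 0, seed = 5)
  d <- dosages(simulateGenotypes(cfg)$geno)
  d <- d[, apply(d, 2, sd) > 0]
  cm <- abs(cor(d))
  expect_lt(mean(cm[upper.tri(cm)]), 3 / sqrt(nrow(d)))

  # two founders: all polymorphic markers within a block perfectly correlated
  cfg2 <- simConfig(nLinesDiscovery = 60, nLinesElite = 10, nOverlap = 0,
                    nMarkers = 12, nLdBlocks = 2, nFoundersPerBlock = 2,
                    residualHetRate = 0, seed = 7)
  sim2 <- simulateGenotypes(cfg2)
  d2 <- dosages(sim2$geno)[, sim2$blocks == 1, drop = FALSE]
  d2 <- d2[, apply(d2, 2, sd) > 0, drop = FALSE]
  if (ncol(d2) > 1) {
    cm2 <- abs(cor(d2))
    expect_true(all(abs(cm2 - 1) < 1e-12))
  }
})

test_that("divergent block creates a discovery-common, elite-rare marker", {
  cfg <- simConfig(nLinesDiscovery = 200, nLinesElite = 150, nOverlap = 0,
                   nMarkers = 100, nLdBlocks = 20, nFoundersPerBlock = 8,
                   divergentBlock = 3, residualHetRate = 0, seed = 13)
  sim <- simulateGenotypes(cfg)
  mk <- markerIds(sim$geno)[sim$founders[[3]]$markers[1]]
  d <- dosages(sim$geno)
  mafD <- tgrm:::markerMaf(d[sim$discovery, mk, drop = FALSE])
  mafE <- tgrm:::markerMaf(d[sim$elite, mk, drop = FALSE])
  expect_gt(mafD, 0.25)
  expect_lt(mafE, 0.05)
})

test_that("endophenotype architectures produce the declared correlations", {
  # analytic oracle: shared fraction x effect correlation = 0.8 * 50/100
  nRep <- 20
  cors <- vapply(seq_len(nRep), function(r) {
    geno <- makeInbredGeno(300, 1000, maf = c(0.2, 0.5), seed = 100 + r)
    shared <- 1:50
    archs <- list(
      traitArchitecture("A", 100, "gaussian", 0.6,
                        qtlIndices = c(shared, 101:150)),
      traitArchitecture("B", 100, "gaussian", 0.6,
                        qtlIndices = c(shared, 201:250),
                        sharedQtlMap = list(list(other = "A",
                                                 indices = shared,
                                                 rho = 0.8))))
    truth <- simulateEndophenotypes(geno, archs, seed = 200 + r)
    cor(truth@bv[, "A"], truth@bv[, "B"])
  }, 0)
  se <- sd(cors) / sqrt(nRep)
  expect_lt(abs(mean(cors) - 0.4), 3 * se + 0.02)

  # sharing all QTL at rho = 1 gives genetic correlation 1
  geno <- makeInbredGeno(100, 200, seed = 9)
  archs <- list(
    traitArchitecture("A", 30, "gaussian", 0.5, qtlIndices = 1:30),
    traitArchitecture("B", 30, "gaussian", 0.5, qtlIndices = 1:30,
                      sharedQtlMap = list(list(other = "A", indices = 1:30,
                                               rho = 1))))
  truth <- simulateEndophenotypes(geno, archs, seed = 2)
  expect_equal(cor(truth@bv[, "A"], truth@bv[, "B"]), 1, tolerance = 1e-10)

  # zero QTL -> zero breeding values
  t0 <- simulateEndophenotypes(geno,
                               list(traitArchitecture("Z", 0, "gaussian", 0.5)),
                               seed = 3)
  expect_true(all(t0@bv == 0))

  # shared map referencing markers not causal in the partner errors
  expect_error(simulateEndophenotypes(geno, list(
    traitArchitecture("A", 10, "gaussian", 0.5, qtlIndices = 1:10),
    traitArchitecture("B", 10, "gaussian", 0.5, qtlIndices = 11:20,
                      sharedQtlMap = list(list(other = "A", indices = 50:55,
                                               rho = 0.5)))),
    seed = 1), "causal")
})

test_that("focal trait composes endophenotype genetic values", {
  geno <- makeInbredGeno(200, 600, seed = 21)
  archs <- list(
    traitArchitecture("A", 50, "gaussian", 0.5, qtlIndices = 1:50),
    traitArchitecture("B", 50, "gaussian", 0.5, qtlIndices = 101:150),
    traitArchitecture("C", 50, "gaussian", 0.5, qtlIndices = 201:250))
  truth <- simulateEndophenotypes(geno, archs, seed = 4)

  # single weight 1, no extra polygenic term: focal equals that trait
  t1 <- simulateFocalTrait(truth, c(0, 1, 0), 0, 0.5, seed = 5)
  expect_equal(unname(t1@bv[, "focal"]), unname(t1@bv[, "B"]))

  # all-zero weights, no extra share: zero genetic variance
  t0 <- simulateFocalTrait(truth, c(0, 0, 0), 0, 0.5, seed = 6)
  expect_equal(var(t0@bv[, "focal"]), 0)

  # equal weights on 3 near-independent equal-variance endophenotypes:
  # brute-force variance close to the sum of the three variances
  tS <- simulateFocalTrait(truth, c(1, 1, 1), 0, 0.5, seed = 7)
  vSum <- sum(apply(truth@bv, 2, var))
  expect_lt(abs(var(tS@bv[, "focal"]) / vSum - 1), 0.15)

  expect_error(simulateFocalTrait(truth, c(1, 1, 1), 0, 1.5), "h2")
})

test_that("field design conserves entries and realizes the target h2", {
  bv <- setNames(rnorm(80, 0, 2), sprintf("L%03d", 1:80))
  rec <- applyFieldDesign(bv, nBlocks = 8, nChecks = 2, h2 = 0.6, seed = 3)
  entries <- rec[!rec$is_check, ]
  expect_setequal(entries$line_id, names(bv))
  expect_equal(nrow(entries), 80)                  # once per trial
  expect_equal(sum(rec$is_check), 8 * 2)           # every check in every block

  # degenerate: no nuisance variance and h2 = 1 recovers y = mu + g exactly
  rec0 <- applyFieldDesign(bv, nBlocks = 4, nChecks = 1, blockVarShare = 0,
                           batchVarShare = 0, trialVarShare = 0,
                           covariateBeta = 0, h2 = 1, mu = 5, seed = 4)
  ent0 <- rec0[!rec0$is_check, ]
  expect_equal(ent0$value, unname(5 + bv[ent0$line_id]), tolerance = 1e-12)

  # single check with zero residual: its records differ only by block
  rec1 <- applyFieldDesign(bv, nBlocks = 6, nChecks = 1, batchVarShare = 0,
                           trialVarShare = 0, covariateBeta = 0, h2 = 1,
                           seed = 5)
  chk <- rec1[rec1$is_check, ]
  expect_equal(length(unique(chk$value)), length(unique(chk$block)))

  expect_error(applyFieldDesign(bv, nBlocks = 2, nChecks = 1,
                                plotsPerBlock = 10), "more entries")

  # realized entry-mean heritability: variance bookkeeping over replicates
  h2s <- vapply(1:50, function(r) {
    g <- rnorm(500)
    rec <- applyFieldDesign(setNames(g, sprintf("E%03d", 1:500)),
                            nBlocks = 10, nChecks = 1, blockVarShare = 0,
                            batchVarShare = 0, trialVarShare = 0,
                            covariateBeta = 0, h2 = 0.6, seed = 1000 + r)
    ent <- rec[!rec$is_check, ]
    var(g) / var(ent$value)
  }, 0)
  expect_gt(mean(h2s), 0.55)
  expect_lt(mean(h2s), 0.65)
})
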
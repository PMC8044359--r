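#' Reference two-panel simulation study
#'
#' Runs the package's compact reference experiment end to end: simulate a
#' 400-line discovery panel and a 250-line elite panel (12 overlap lines,
#' 2,000 markers) with three endophenotype architectures —
#' an oligogenic high-heritability trait (20 QTL, h2 = 0.7), a polygenic
#' low-heritability trait (2,000 QTL, h2 = 0.38), and a trait with one
#' large-effect QTL (about 40% of genetic variance) that is common in the
#' discovery panel but below the 0.05 MAF bound in the elite panel, on a
#' fully polygenic background (h2 = 0.65) — plus a focal trait composed of
#' the three (weights 0.5/0.3/0.2, 20% extra polygenic share, h2 = 0.4).
#' Marker effects are estimated in the discovery panel, trait-specific
#' kernels built on the elite panel, and repeated five-fold
#' cross-validation compares TGRM-BLUP against gBLUP per endophenotype and
#' multi-kernel TGRM-BLUP against gBLUP and multi-trait gBLUP for the
#' focal trait (overlap lines forced into training).
#'
#' @param seed global seed; every stage derives its stream from it.
#' @param nRuns resampling runs (default 10).
#' @param k folds per run.
#' @param effectIter,effectBurn,effectThin chain for marker-effect
#'   estimation.
#' @param cvIter,cvBurn,cvThin chain for the kernel/multi-trait models
#'   fitted inside the cross-validation loops.
#' @param verbose print stage progress.
#' @return list with per-comparison win proportions, mean accuracies and
#'   percent improvements, plus the underlying [CVReport-class] objects.
#' @export
benchmarkTwoPanel <- function(seed = 1, nRuns = 10, k = 5,
                              effectIter = 3000, effectBurn = 1000,
                              effectThin = 2, cvIter = 1000, cvBurn = 400,
                              cvThin = 2, verbose = FALSE) {
  ss <- function(off) seedStream(seed, off)
  say <- function(...) if (verbose) message(...)

  say("simulating two panels")
  sc <- simConfig(nLinesDiscovery = 400, nLinesElite = 250, nOverlap = 12,
                  nMarkers = 2000, nLdBlocks = 400, nFoundersPerBlock = 8,
                  driftSd = 1, divergentBlock = 1, seed = ss(11))
  sim <- simulateGenotypes(sc)
  dAll <- dosages(sim$geno)
  disc <- sim$discovery; elite <- sim$elite
  ov <- intersect(disc, elite)
  divIdx <- sim$founders[[1]]$markers[1]
  divMarker <- markerIds(sim$geno)[divIdx]

  qcPanel <- function(lines) {
    g <- GenotypeMatrix(dAll[lines, , drop = FALSE])
    g <- imputeMean(runQC(g)$geno)
    maf <- markerMaf(dosages(g))
    GenotypeMatrix(dosages(g)[, maf >= 0.05, drop = FALSE])
  }
  gD <- qcPanel(disc)
  gE <- qcPanel(elite)

  say("building trait architectures")
  truth <- simulateEndophenotypes(sim, list(
    traitArchitecture("oligo", 20, "scaled_t", 0.7),
    traitArchitecture("poly", 2000, "gaussian", 0.38)), seed = ss(12))
  bvDrift <- withSeed(ss(13), {
    Wc <- scale(dAll, center = TRUE, scale = FALSE)
    e <- numeric(ncol(dAll))
    e[-divIdx] <- rnorm(ncol(dAll) - 1)
    bg <- as.numeric(Wc %*% e)
    # size the divergent QTL at ~40% of discovery genetic variance
    e[divIdx] <- sqrt(0.67 * var(bg[match(disc, rownames(dAll))]) /
                        var(Wc[match(disc, rownames(dAll)), divIdx]))
    as.numeric(Wc %*% e)
  })
  bv <- scale(cbind(oligo = truth@bv[, "oligo"], poly = truth@bv[, "poly"],
                    drift = bvDrift))
  rownames(bv) <- rownames(dAll)
  focal <- withSeed(ss(14), {
    base <- as.numeric(bv %*% c(0.5, 0.3, 0.2))
    Wc <- scale(dAll, center = TRUE, scale = FALSE)
    px <- as.numeric(Wc %*% rnorm(ncol(dAll)))
    setNames(base + px * sqrt(0.25 * var(base) / var(px)), rownames(dAll))
  })
  h2s <- c(oligo = 0.7, poly = 0.38, drift = 0.65, focal = 0.4)
  endoIds <- c("oligo", "poly", "drift")

  mkResp <- function(lines, trait, off) {
    g <- if (trait == "focal") focal[lines] else bv[lines, trait]
    withSeed(ss(off), setNames(
      g + rnorm(length(g), 0, sqrt(var(g) * (1 - h2s[[trait]]) / h2s[[trait]])),
      lines))
  }
  respD <- list(oligo = mkResp(disc, "oligo", 31),
                poly = mkResp(disc, "poly", 32),
                drift = mkResp(disc, "drift", 33))
  respE <- list(oligo = mkResp(elite, "oligo", 35),
                poly = mkResp(elite, "poly", 36),
                drift = mkResp(elite, "drift", 37),
                focal = mkResp(elite, "focal", 38))

  say("estimating marker effects")
  WD <- dosages(gD)[disc, , drop = FALSE]
  wgrCfg <- function(m, off) wgrConfig(m, nIter = effectIter,
                                       burnIn = effectBurn,
                                       thin = effectThin, seed = ss(off))
  effs <- list(oligo.BayesB = fitWGR(respD$oligo, WD, wgrCfg("BayesB", 41)),
               oligo.BayesCpi = fitWGR(respD$oligo, WD,
                                       wgrCfg("BayesCpi", 42)),
               poly.BayesB = fitWGR(respD$poly, WD, wgrCfg("BayesB", 43)),
               drift.BayesB = fitWGR(respD$drift, WD, wgrCfg("BayesB", 44)))

  say("building kernels")
  ME <- centerScale(gE)
  eigTGRM <- lapply(effs, function(e)
    kernelEigen(buildTGRM(ME, tgrmWeights(e))))
  eigGRM <- kernelEigen(buildGRMVanRaden(gE))

  cvCfg <- wgrConfig(nIter = cvIter, burnIn = cvBurn, thin = cvThin)
  factory <- function(y, eigs, off) {
    cnt <- new.env(); cnt$i <- 0
    function(testLines) {
      cnt$i <- cnt$i + 1
      cfg <- cvCfg; cfg$seed <- ss(off * 1000 + cnt$i)
      fit <- fitKernelModel(y, names(y), eigs, maskLines = testLines,
                            config = cfg)
      predictGEBV(fit, testLines)
    }
  }

  say("cross-validating endophenotypes")
  endoCmp <- list(); endoReports <- list()
  methodSets <- list(oligo = c("BayesB", "BayesCpi"), poly = "BayesB",
                     drift = "BayesB")
  for (ti in seq_along(endoIds)) {
    tr <- endoIds[ti]
    y <- respE[[tr]]
    resp <- data.frame(line_id = names(y), value = as.numeric(y))
    plans <- makeFoldPlan(names(y), k = k, nRuns = nRuns, seed = ss(50 + ti))
    methods <- list(gBLUP = factory(y, list(G = eigGRM), 60 + 10 * ti))
    for (m in methodSets[[tr]])
      methods[[paste0("TGRM_", m)]] <-
        factory(y, eigTGRM[paste0(tr, ".", m)], 61 + 10 * ti + match(
          m, methodSets[[tr]]))
    rp <- runCV(plans, methods, resp)
    endoReports[[tr]] <- rp
    for (m in methodSets[[tr]])
      endoCmp[[paste(tr, m)]] <- compareMethods(rp, paste0("TGRM_", m),
                                                "gBLUP")
  }

  say("cross-validating the focal trait")
  yF <- respE$focal
  mtLines <- c(disc[1:120], elite)
  grmMT <- buildGRMVanRaden(qcPanel(mtLines))
  dSub <- c(disc[1:120], ov)
  Y0 <- matrix(NA_real_, length(mtLines), 4,
               dimnames = list(mtLines, c(endoIds, "focal")))
  for (tr in endoIds) Y0[dSub, tr] <- respD[[tr]][dSub]
  Y0[elite, "focal"] <- yF[elite]
  cntMT <- new.env(); cntMT$i <- 0
  mtFactory <- function(testLines) {
    cntMT$i <- cntMT$i + 1
    Y <- Y0
    Y[intersect(testLines, rownames(Y)), "focal"] <- NA
    cfg <- cvCfg; cfg$seed <- ss(90000 + cntMT$i)
    fit <- fitMultiTrait(Y, grmMT, cfg)
    predictGEBV(fit, testLines, trait = "focal")
  }
  respF <- data.frame(line_id = names(yF), value = as.numeric(yF))
  plansF <- makeFoldPlan(names(yF), k = k, nRuns = nRuns, forcedTrain = ov,
                         seed = ss(55))
  repF <- runCV(plansF,
                list(gBLUP = factory(yF, list(G = eigGRM), 70),
                     MK_TGRM = factory(yF, eigTGRM[paste0(endoIds,
                                                          ".BayesB")], 71),
                     MT_gBLUP = mtFactory),
                respF)
  cmpFG <- compareMethods(repF, "MK_TGRM", "gBLUP")
  cmpFM <- compareMethods(repF, "MK_TGRM", "MT_gBLUP")

  list(
    winOligoBayesB = endoCmp[["oligo BayesB"]]$winProportion,
    winOligoBayesCpi = endoCmp[["oligo BayesCpi"]]$winProportion,
    winPolyBayesB = endoCmp[["poly BayesB"]]$winProportion,
    winDriftBayesB = endoCmp[["drift BayesB"]]$winProportion,
    winFocalVsGblup = cmpFG$winProportion,
    winFocalVsMT = cmpFM$winProportion,
    pctFocalVsGblup = cmpFG$pctImprovement,
    pctFocalVsMT = cmpFM$pctImprovement,
    accFocalMK = cmpFG$meanA,
    accFocalGblup = cmpFG$meanB,
    accFocalMT = cmpFM$meanB,
    accOligoTGRM = endoCmp[["oligo BayesB"]]$meanA,
    accOligoGblup = endoCmp[["oligo BayesB"]]$meanB,
    accPolyTGRM = endoCmp[["poly BayesB"]]$meanA,
    accPolyGblup = endoCmp[["poly BayesB"]]$meanB,
    accDriftTGRM = endoCmp[["drift BayesB"]]$meanA,
    accDriftGblup = endoCmp[["drift BayesB"]]$meanB,
    divMarkerInElite = divMarker %in% markerIds(gE),
    endoReports = endoReports, focalReport = repF)
}
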
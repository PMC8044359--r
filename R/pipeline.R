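#' Default end-to-end pipeline configuration
#'
#' Builds the configuration for the full two-panel experiment: simulate
#' discovery and elite panels, QC, augmented-model adjustment and
#' deregression, marker-effect estimation for each endophenotype under the
#' five Bayesian priors, trait-specific kernels on the elite panel, and the
#' cross-validated model comparisons (endophenotype TGRM-BLUP vs gBLUP;
#' multi-kernel TGRM-BLUP vs gBLUP vs multi-trait gBLUP for the focal
#' trait).
#'
#' The `"test"` MCMC preset (3,000 sweeps, 1,000 burn-in, thin 2, 5 CV
#' runs) and the default panel sizes here are deliberately compact; the
#' `"full"` preset restores the conventional long chain (20,000 / 5,000 /
#' thin 5, 50 runs).
#'
#' @param outDir output directory for all stage artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @param preset "test" or "full".
#' @return nested configuration list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(outDir = tempfile("tgrm"), seed = 1,
                                  preset = c("test", "full")) {
  preset <- match.arg(preset)
  mcmc <- if (preset == "test")
    list(nIter = 3000, burnIn = 1000, thin = 2) else
    list(nIter = 20000, burnIn = 5000, thin = 5)
  structure(list(
    seed = seed, outDir = outDir, preset = preset,
    sim = list(nLinesDiscovery = 150, nLinesElite = 120, nOverlap = 10,
               nMarkers = 600, nLdBlocks = 120, nFoundersPerBlock = 6,
               mafMin = 0.02, driftSd = 1, residualHetRate = 0.005,
               divergentBlock = NA),
    traits = list(
      endophenotypes = list(
        list(traitId = "E1", nQtl = 20, effectDistribution = "scaled_t",
             h2 = 0.7),
        list(traitId = "E2", nQtl = 60, effectDistribution = "scaled_t",
             h2 = 0.55),
        list(traitId = "E3", nQtl = 300, effectDistribution = "gaussian",
             h2 = 0.4)),
      focal = list(weights = c(0.5, 0.3, 0.2), extraPolygenicShare = 0.2,
                   h2 = 0.4)),
    design = list(nBlocks = 10, nChecks = 2, batchSize = 25,
                  blockVarShare = 0.1, batchVarShare = 0.05,
                  trialVarShare = 0.05, covariateBeta = 0.3,
                  nTrialsElite = 3),
    qc = list(markerMafMin = 0.02, markerMissingMax = 0.6,
              markerHetMax = 0.1, indivMissingMax = 0.7, indivHetMax = 0.1,
              analysisMafMin = 0.05),
    mcmc = mcmc,
    methods = c("BRR", "BayesA", "BayesB", "BayesCpi", "BL"),
    cv = list(k = 5, nRuns = if (preset == "test") 5 else 50,
              threshold = 0.9, reliabilityFloor = 0.1)),
    class = "PipelineConfig")
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a pipeline configuration (YAML)
#'
#' Values absent from the file fall back to [defaultPipelineConfig()]
#' defaults for the file's preset.
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(outDir = raw$outDir %||% tempfile("tgrm"),
                               seed = raw$seed %||% 1,
                               preset = raw$preset %||% "test")
  mergeConfig(cfg, raw)
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

artifactPath <- function(config, name) file.path(config$outDir, name)

requireArtifact <- function(config, name, stage) {
  p <- artifactPath(config, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': rerun stage '", stage, "' first")
  p
}

# timestamp-free so that reruns with one config are byte-identical
logLine <- function(config, ...) {
  cat(paste0(...), "\n", file = artifactPath(config, "log.txt"),
      append = TRUE, sep = "")
}

#' Pipeline stage: simulate both panels, traits and field phenotypes
#'
#' @param config a `PipelineConfig`.
#' @return invisibly, the simulated objects.
#' @export
stageSimulate <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  s <- config$sim
  sc <- simConfig(nLinesDiscovery = s$nLinesDiscovery,
                  nLinesElite = s$nLinesElite, nOverlap = s$nOverlap,
                  nMarkers = s$nMarkers, nLdBlocks = s$nLdBlocks,
                  nFoundersPerBlock = s$nFoundersPerBlock,
                  mafMin = s$mafMin, driftSd = s$driftSd,
                  residualHetRate = s$residualHetRate,
                  divergentBlock = if (is.null(s$divergentBlock) ||
                                       is.na(s$divergentBlock))
                    NA_real_ else s$divergentBlock,
                  seed = seedStream(config$seed, 1))
  sim <- simulateGenotypes(sc)
  archs <- lapply(config$traits$endophenotypes, function(a)
    traitArchitecture(a$traitId, a$nQtl, a$effectDistribution, a$h2,
                      sharedQtlMap = a$sharedQtlMap %||% list(),
                      qtlIndices = a$qtlIndices))
  truth <- simulateEndophenotypes(sim, archs, seed = seedStream(config$seed, 2))
  fc <- config$traits$focal
  truth <- simulateFocalTrait(truth, fc$weights, fc$extraPolygenicShare,
                              fc$h2, sim = sim,
                              seed = seedStream(config$seed, 3))
  d <- config$design
  endoIds <- vapply(archs, `[[`, "", "traitId")
  discRecs <- do.call(rbind, lapply(seq_along(endoIds), function(i) {
    applyFieldDesign(truth@bv[sim$discovery, endoIds[i]], trait = endoIds[i],
                     nTrials = 1, nBlocks = d$nBlocks, nChecks = d$nChecks,
                     batchSize = d$batchSize,
                     blockVarShare = d$blockVarShare,
                     batchVarShare = d$batchVarShare,
                     trialVarShare = d$trialVarShare,
                     covariateBeta = d$covariateBeta,
                     h2 = archs[[i]]$h2,
                     seed = seedStream(config$seed, 100 + i))
  }))
  eliteTraits <- c(endoIds, "focal")
  eliteH2 <- c(vapply(archs, `[[`, 0, "h2"), fc$h2)
  eliteRecs <- do.call(rbind, lapply(seq_along(eliteTraits), function(i) {
    applyFieldDesign(truth@bv[sim$elite, eliteTraits[i]],
                     trait = eliteTraits[i], nTrials = d$nTrialsElite,
                     nBlocks = d$nBlocks, nChecks = d$nChecks,
                     batchSize = d$batchSize,
                     blockVarShare = d$blockVarShare,
                     batchVarShare = d$batchVarShare,
                     trialVarShare = d$trialVarShare, covariateBeta = 0,
                     h2 = eliteH2[i],
                     seed = seedStream(config$seed, 200 + i))
  }))
  writeDosageCSV(sim$geno, artifactPath(config, "genotypes_union.csv"))
  writeVCF(sim$geno, artifactPath(config, "genotypes_union.vcf"))
  writeLines(sim$discovery, artifactPath(config, "discovery_lines.txt"))
  writeLines(sim$elite, artifactPath(config, "elite_lines.txt"))
  writeSimTruthJSON(truth, artifactPath(config, "truth.json"))
  writePhenotypeCSV(discRecs, artifactPath(config, "phenotypes_discovery.csv"))
  writePhenotypeCSV(eliteRecs, artifactPath(config, "phenotypes_elite.csv"))
  logLine(config, "simulate: seed=", sc@seed, " markers=", s$nMarkers,
          " discovery=", s$nLinesDiscovery, " elite=", s$nLinesElite)
  invisible(list(sim = sim, truth = truth, discovery = discRecs,
                 elite = eliteRecs))
}

qcPanel <- function(geno, lines, thresholds, analysisMaf) {
  sub <- GenotypeMatrix(dosages(geno)[lines, , drop = FALSE])
  res <- runQC(sub, thresholds)
  g <- imputeMean(res$geno)
  maf <- markerMaf(dosages(g))
  keep <- maf >= analysisMaf
  if (!any(keep)) stop("analysis MAF filter removed all markers")
  list(geno = GenotypeMatrix(dosages(g)[, keep, drop = FALSE]),
       markerReport = res$markerReport, indivReport = res$indivReport,
       analysisRemoved = colnames(dosages(g))[!keep])
}

#' Pipeline stage: genotype QC per analysis panel
#'
#' Applies the base marker/individual filters and mean imputation, then the
#' per-analysis MAF bound, separately for the discovery panel, the elite
#' panel and their union (used by the multi-trait model), reproducing the
#' different marker counts per analysis.
#'
#' @param config a `PipelineConfig`.
#' @export
stageQC <- function(config) {
  geno <- readDosageCSV(requireArtifact(config, "genotypes_union.csv",
                                        "simulate"))
  disc <- readLines(artifactPath(config, "discovery_lines.txt"))
  elite <- readLines(artifactPath(config, "elite_lines.txt"))
  q <- config$qc
  th <- qcThresholds(q$markerMafMin, q$markerMissingMax, q$markerHetMax,
                     q$indivMissingMax, q$indivHetMax)
  panels <- list(discovery = disc, elite = elite,
                 union = union(disc, elite))
  for (nm in names(panels)) {
    res <- qcPanel(geno, panels[[nm]], th, q$analysisMafMin)
    writeDosageCSV(res$geno,
                   artifactPath(config, paste0("genotypes_", nm, "_qc.csv")))
    rep <- rbind(
      if (nrow(res$markerReport))
        data.frame(id = res$markerReport$marker_id,
                   reason = res$markerReport$reason, kind = "marker"),
      if (nrow(res$indivReport))
        data.frame(id = res$indivReport$line_id,
                   reason = res$indivReport$reason, kind = "individual"),
      if (length(res$analysisRemoved))
        data.frame(id = res$analysisRemoved, reason = "analysis_maf",
                   kind = "marker"))
    if (is.null(rep))
      rep <- data.frame(id = character(0), reason = character(0),
                        kind = character(0))
    write.table(rep, artifactPath(config, paste0("qc_report_", nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    logLine(config, "qc[", nm, "]: kept ", ncol(dosages(res$geno)),
            " markers x ", nrow(dosages(res$geno)), " lines",
            " (maf>=", q$analysisMafMin, ")")
  }
  invisible(NULL)
}

#' Pipeline stage: mixed-model adjustment and deregression
#'
#' Discovery records (single trial, covariate present) are fitted per
#' endophenotype; elite records are fitted per trait and trial (no
#' covariate). Deregressed BLUPs with reliabilities are written for both.
#'
#' @param config a `PipelineConfig`.
#' @export
stageAdjust <- function(config) {
  floorRel <- config$cv$reliabilityFloor
  disc <- readPhenotypeCSV(requireArtifact(config, "phenotypes_discovery.csv",
                                           "simulate"))
  out <- list()
  for (tr in unique(disc$trait)) {
    fit <- fitAugmentedModel(disc, trait = tr)
    dv <- deregress(fit, floorRel)
    out[[tr]] <- cbind(trait = tr, dv@table)
    logLine(config, "adjust[discovery ", tr, "]: varG=",
            signif(fit@varcomp[["entry"]], 4), " iters=",
            fit@convergence$iterations)
  }
  dd <- do.call(rbind, out)
  write.table(dd[, c("line_id", "trait", "value", "reliability")],
              artifactPath(config, "deregressed_discovery.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  elite <- readPhenotypeCSV(requireArtifact(config, "phenotypes_elite.csv",
                                            "simulate"))
  out <- list()
  for (tr in unique(elite$trait)) for (trl in unique(elite$trial)) {
    fit <- fitAugmentedModel(elite, trait = tr, trial = trl,
                             includeCovariate = FALSE)
    dv <- deregress(fit, floorRel)
    if (nrow(dv@table) == 0) {
      warning("no reliable entries for ", tr, " in ", trl, "; trial skipped")
      next
    }
    out[[paste(tr, trl)]] <- cbind(trait = tr, trial = trl, dv@table)
  }
  de <- do.call(rbind, out)
  write.table(de[, c("line_id", "trait", "trial", "value", "reliability")],
              artifactPath(config, "deregressed_elite.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Pipeline stage: marker effects for every endophenotype and method
#'
#' @param config a `PipelineConfig`.
#' @export
stageEffects <- function(config) {
  geno <- readDosageCSV(requireArtifact(config, "genotypes_discovery_qc.csv",
                                        "qc"))
  dd <- read.delim(requireArtifact(config, "deregressed_discovery.tsv",
                                   "adjust"))
  W <- dosages(geno)
  for (tr in unique(dd$trait)) {
    sub <- dd[dd$trait == tr & dd$line_id %in% rownames(W), ]
    for (i in seq_along(config$methods)) {
      m <- config$methods[i]
      cfg <- wgrConfig(method = m, nIter = config$mcmc$nIter,
                       burnIn = config$mcmc$burnIn, thin = config$mcmc$thin,
                       seed = seedStream(config$seed,
                                         1000 + 10 * i + match(tr, unique(dd$trait))))
      eff <- fitWGR(sub$value, W[sub$line_id, , drop = FALSE], cfg)
      writeEffectsTSV(eff, artifactPath(config,
                                        paste0("effects_", m, "_", tr, ".tsv")))
    }
    logLine(config, "effects[", tr, "]: ", length(config$methods),
            " methods, chain ", config$mcmc$nIter, "/", config$mcmc$burnIn,
            "/", config$mcmc$thin)
  }
  invisible(NULL)
}

#' Pipeline stage: kernels on the elite panel (and union GRM)
#'
#' Builds the VanRaden GRM for the elite panel and the union panel, and one
#' trait-specific kernel per endophenotype and method. Markers filtered out
#' of the elite panel receive weight zero when absent from the effect
#' table's support.
#'
#' @param config a `PipelineConfig`.
#' @export
stageKernels <- function(config) {
  elite <- readDosageCSV(requireArtifact(config, "genotypes_elite_qc.csv",
                                         "qc"))
  un <- readDosageCSV(requireArtifact(config, "genotypes_union_qc.csv", "qc"))
  M <- centerScale(elite)
  grm <- buildGRMVanRaden(elite)
  writeKernelCSV(grm, artifactPath(config, "kernel_GRM_elite.csv"))
  writeKernelCSV(buildGRMVanRaden(un),
                 artifactPath(config, "kernel_GRM_union.csv"))
  endoIds <- vapply(config$traits$endophenotypes, `[[`, "", "traitId")
  for (m in config$methods) for (tr in endoIds) {
    eff <- readEffectsTSV(requireArtifact(
      config, paste0("effects_", m, "_", tr, ".tsv"), "effects"))
    w <- tgrmWeights(eff)
    k <- buildTGRM(M, w, trait = paste0(tr, ".", m))
    writeKernelCSV(k, artifactPath(config,
                                   paste0("kernel_TGRM_", m, "_", tr, ".csv")))
  }
  logLine(config, "kernels: GRM + ", length(config$methods), "x",
          length(endoIds), " TGRMs")
  invisible(NULL)
}

kernelFactory <- function(y, lines, eigens, trial, mcmcCfg, counterEnv,
                          seedBase) {
  function(testLines) {
    counterEnv$i <- counterEnv$i + 1
    cfg <- mcmcCfg
    cfg$seed <- seedStream(seedBase, counterEnv$i)
    fit <- fitKernelModel(y, lines, eigens, trial = trial,
                          maskLines = testLines, config = cfg)
    predictGEBV(fit, testLines)
  }
}

#' Pipeline stage: cross-validated model comparisons
#'
#' (i) per endophenotype, TGRM-BLUP under every marker-effect method vs
#' gBLUP on the elite per-trial deregressed values (trial-effect model,
#' per-trial accuracies); (ii) for the focal trait, multi-kernel TGRM-BLUP
#' per method vs gBLUP vs multi-trait gBLUP on entry means, with the
#' panel-overlap lines forced into training. Writes per-fold reports, a
#' win-proportion summary table (method x trait) and the focal-trait
#' comparison summary.
#'
#' @param config a `PipelineConfig`.
#' @return invisibly, list with both [CVReport-class] objects and the
#'   summary data frames.
#' @export
stageEvaluate <- function(config) {
  de <- read.delim(requireArtifact(config, "deregressed_elite.tsv", "adjust"))
  grmElite <- readKernelCSV(requireArtifact(config, "kernel_GRM_elite.csv",
                                            "kernel"))
  endoIds <- vapply(config$traits$endophenotypes, `[[`, "", "traitId")
  mcmcCfg <- wgrConfig(nIter = config$mcmc$nIter, burnIn = config$mcmc$burnIn,
                       thin = config$mcmc$thin)
  k <- config$cv$k; nRuns <- config$cv$nRuns; thr <- config$cv$threshold

  # --- (i) endophenotype prediction: TGRM-BLUP vs gBLUP, per trial
  eliteLines <- lineIds(grmElite)
  eigGRM <- kernelEigen(grmElite)
  reports <- list(); summaryRows <- list()
  for (ti in seq_along(endoIds)) {
    tr <- endoIds[ti]
    resp <- de[de$trait == tr & de$line_id %in% eliteLines, ]
    plans <- makeFoldPlan(unique(resp$line_id), k = k, nRuns = nRuns,
                          seed = seedStream(config$seed, 2000 + ti))
    methods <- list()
    cnt <- new.env(); cnt$i <- 0
    methods[["gBLUP"]] <- kernelFactory(resp$value, resp$line_id,
                                        list(G = eigGRM), resp$trial,
                                        mcmcCfg, cnt,
                                        seedStream(config$seed, 3000 + ti))
    for (m in config$methods) {
      kern <- readKernelCSV(requireArtifact(
        config, paste0("kernel_TGRM_", m, "_", tr, ".csv"), "kernel"),
        type = paste0("TGRM:", tr))
      cntm <- new.env(); cntm$i <- 0
      methods[[paste0("TGRM_", m)]] <-
        kernelFactory(resp$value, resp$line_id,
                      list(G = kernelEigen(kern)), resp$trial, mcmcCfg,
                      cntm, seedStream(config$seed,
                                       3000 + 100 * match(m, config$methods) + ti))
    }
    rep <- runCV(plans, methods, resp, grouping = "trial")
    reports[[tr]] <- rep
    for (m in config$methods) {
      cmp <- compareMethods(rep, paste0("TGRM_", m), "gBLUP", thr)
      summaryRows[[paste(m, tr)]] <- data.frame(
        method = m, trait = tr, win_proportion = cmp$winProportion,
        significant = cmp$significant,
        pct_improvement = cmp$pctImprovement)
    }
    writeCVReportTSV(rep, artifactPath(config,
                                       paste0("cv_endo_", tr, ".tsv")))
  }
  endoSummary <- do.call(rbind, c(summaryRows, list(make.row.names = FALSE)))
  write.table(endoSummary,
              artifactPath(config, "summary_endophenotypes.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # --- (ii) focal trait: MK-TGRM-BLUP vs gBLUP vs MT-gBLUP on entry means
  focal <- de[de$trait == "focal" & de$line_id %in% eliteLines, ]
  fmean <- aggregate(value ~ line_id, data = focal, FUN = mean)
  ddisc <- read.delim(artifactPath(config, "deregressed_discovery.tsv"))
  grmUnion <- readKernelCSV(artifactPath(config, "kernel_GRM_union.csv"))
  overlap <- intersect(readLines(artifactPath(config, "discovery_lines.txt")),
                       fmean$line_id)
  plans <- makeFoldPlan(fmean$line_id, k = k, nRuns = nRuns,
                        forcedTrain = overlap,
                        seed = seedStream(config$seed, 2100))
  methods <- list()
  cnt0 <- new.env(); cnt0$i <- 0
  methods[["gBLUP"]] <- kernelFactory(fmean$value, fmean$line_id,
                                      list(G = eigGRM), NULL, mcmcCfg, cnt0,
                                      seedStream(config$seed, 4000))
  for (m in config$methods) {
    eigs <- lapply(endoIds, function(tr) kernelEigen(readKernelCSV(
      artifactPath(config, paste0("kernel_TGRM_", m, "_", tr, ".csv")),
      type = paste0("TGRM:", tr))))
    names(eigs) <- endoIds
    cntm <- new.env(); cntm$i <- 0
    methods[[paste0("MK_", m)]] <-
      kernelFactory(fmean$value, fmean$line_id, eigs, NULL, mcmcCfg, cntm,
                    seedStream(config$seed, 4000 + match(m, config$methods)))
  }
  # multi-trait gBLUP: endophenotypes from the discovery panel plus the
  # focal entry means, joined on the union GRM
  unionLines <- lineIds(grmUnion)
  traits <- c(endoIds, "focal")
  Y0 <- matrix(NA_real_, length(unionLines), length(traits),
               dimnames = list(unionLines, traits))
  for (tr in endoIds) {
    sub <- ddisc[ddisc$trait == tr & ddisc$line_id %in% unionLines, ]
    Y0[sub$line_id, tr] <- sub$value
  }
  okF <- fmean$line_id %in% unionLines
  Y0[fmean$line_id[okF], "focal"] <- fmean$value[okF]
  cntMT <- new.env(); cntMT$i <- 0
  mtSeedBase <- seedStream(config$seed, 4500)
  methods[["MT_gBLUP"]] <- function(testLines) {
    cntMT$i <- cntMT$i + 1
    Y <- Y0
    Y[intersect(testLines, rownames(Y)), "focal"] <- NA
    cfg <- mcmcCfg
    cfg$seed <- seedStream(mtSeedBase, cntMT$i)
    fit <- fitMultiTrait(Y, grmUnion, cfg)
    predictGEBV(fit, testLines, trait = "focal")
  }
  repF <- runCV(plans, methods, fmean, grouping = "none")
  writeCVReportTSV(repF, artifactPath(config, "cv_focal.tsv"))
  focalRows <- list()
  for (m in config$methods) {
    a <- paste0("MK_", m)
    cg <- compareMethods(repF, a, "gBLUP", thr)
    cm <- compareMethods(repF, a, "MT_gBLUP", thr)
    focalRows[[m]] <- data.frame(
      method = m,
      win_vs_gBLUP = cg$winProportion, pct_vs_gBLUP = cg$pctImprovement,
      sig_vs_gBLUP = cg$significant,
      win_vs_MT = cm$winProportion, pct_vs_MT = cm$pctImprovement,
      sig_vs_MT = cm$significant, mean_accuracy = cg$meanA)
  }
  focalSummary <- do.call(rbind, c(focalRows, list(make.row.names = FALSE)))
  write.table(focalSummary, artifactPath(config, "summary_focal.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  logLine(config, "evaluate: ", nRuns, " runs x ", k, " folds, threshold ",
          thr)
  invisible(list(endoReports = reports, endoSummary = endoSummary,
                 focalReport = repF, focalSummary = focalSummary))
}

#' Pipeline stage: GEBVs for the focal trait from the full elite data
#'
#' Fits the multi-kernel TGRM model (first configured method) on all elite
#' focal-trait records and writes GEBVs for every elite line.
#'
#' @param config a `PipelineConfig`.
#' @export
stagePredict <- function(config) {
  de <- read.delim(requireArtifact(config, "deregressed_elite.tsv", "adjust"))
  endoIds <- vapply(config$traits$endophenotypes, `[[`, "", "traitId")
  m <- config$methods[1]
  eigs <- lapply(endoIds, function(tr) kernelEigen(readKernelCSV(
    requireArtifact(config, paste0("kernel_TGRM_", m, "_", tr, ".csv"),
                    "kernel"), type = paste0("TGRM:", tr))))
  names(eigs) <- endoIds
  focal <- de[de$trait == "focal", ]
  fmean <- aggregate(value ~ line_id, data = focal, FUN = mean)
  keep <- fmean$line_id %in% eigs[[1]]$lines
  cfg <- wgrConfig(nIter = config$mcmc$nIter, burnIn = config$mcmc$burnIn,
                   thin = config$mcmc$thin,
                   seed = seedStream(config$seed, 5000))
  fit <- fitKernelModel(fmean$value[keep], fmean$line_id[keep], eigs,
                        config = cfg)
  writeGEBVTSV(gebv(fit), paste0("MK_", m),
               artifactPath(config, "gebv_focal.tsv"))
  invisible(fit)
}

#' Run the whole pipeline end to end
#'
#' simulate -> qc -> adjust -> effects -> kernel -> predict -> evaluate.
#' Every stage reads only artifacts in `config$outDir` and its own config
#' section, and all randomness flows from `config$seed`, so a rerun with an
#' identical config reproduces every artifact.
#'
#' @param config a `PipelineConfig` (see [defaultPipelineConfig()],
#'   [readPipelineConfig()]).
#' @return invisibly, the [stageEvaluate()] summaries.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writePipelineConfig(config, artifactPath(config, "config_used.yaml"))
  stageSimulate(config)
  stageQC(config)
  stageAdjust(config)
  stageEffects(config)
  stageKernels(config)
  stagePredict(config)
  res <- stageEvaluate(config)
  invisible(res)
}
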
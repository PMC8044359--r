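#' Configure the two-panel genotype simulator
#'
#' The simulator emulates two related inbred SNP panels: a large, diverse
#' "discovery" panel in which endophenotypes are measured and marker effects
#' estimated, and an "elite" panel in which predictions are evaluated. LD is
#' produced by a founder-mosaic model: markers are grouped into blocks and
#' each line inherits one of `nFoundersPerBlock` founder haplotypes per
#' block. The elite panel is drawn from the same founders with perturbed
#' (logit-scale Gaussian, sd `driftSd`) founder weights, producing
#' allele-frequency drift between panels; `nOverlap` lines are shared
#' verbatim.
#'
#' @param nLinesDiscovery,nLinesElite,nOverlap panel sizes, overlap included
#'   in both counts.
#' @param nMarkers,nLdBlocks,nFoundersPerBlock marker panel and LD geometry.
#' @param mafMin lower bound for founder allele frequencies (per-panel MAF is
#'   not guaranteed; QC filters handle that downstream).
#' @param driftSd logit-scale sd of the elite founder-weight perturbation.
#' @param residualHetRate probability a call is left heterozygous (dosage 1).
#' @param divergentBlock optional block index; the first marker of that block
#'   is made common (frequency 1/2) in the discovery panel but rare
#'   (< 0.05) in the elite panel, the drift failure mode in which a
#'   trait-specific kernel loses its causal marker.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nLinesDiscovery = 336, nLinesElite = 210, nOverlap = 12,
                      nMarkers = 3000, nLdBlocks = 300,
                      nFoundersPerBlock = 8, mafMin = 0.02, driftSd = 1,
                      residualHetRate = 0.005, divergentBlock = NA_real_,
                      seed = 1) {
  new("SimConfig", nLinesDiscovery = nLinesDiscovery,
      nLinesElite = nLinesElite, nOverlap = nOverlap, nMarkers = nMarkers,
      nLdBlocks = nLdBlocks, nFoundersPerBlock = nFoundersPerBlock,
      mafMin = mafMin, driftSd = driftSd,
      residualHetRate = residualHetRate, divergentBlock = divergentBlock,
      seed = seed)
}

# contiguous near-equal marker blocks
markerBlocks <- function(P, nb) {
  sizes <- rep(P %/% nb, nb) + c(rep(1, P %% nb), rep(0, nb - P %% nb))
  rep(seq_len(nb), times = sizes)
}

#' Simulate two related inbred SNP panels
#'
#' @param config a [SimConfig-class].
#' @return list with `geno` (a [GenotypeMatrix-class] over the union of both
#'   panels), `discovery`/`elite` (line-id vectors; overlap ids are in
#'   both), and `founders` (per-block founder haplotypes and the two weight
#'   vectors actually used).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nFoundersPerBlock < 2)
    stop("nFoundersPerBlock must be >= 2: a single founder gives no polymorphism")
  withSeed(config@seed, {
    P <- config@nMarkers
    K <- config@nFoundersPerBlock
    nb <- config@nLdBlocks
    blk <- markerBlocks(P, nb)
    nD <- config@nLinesDiscovery
    nOv <- config@nOverlap
    nEonly <- config@nLinesElite - nOv
    nTot <- nD + nEonly

    discIds <- sprintf("L%04d", seq_len(nD))
    eliteOnlyIds <- sprintf("E%04d", seq_len(nEonly))
    ovIds <- if (nOv > 0) discIds[(nD - nOv + 1):nD] else character(0)
    allIds <- c(discIds, eliteOnlyIds)
    eliteIds <- c(ovIds, eliteOnlyIds)

    dos <- matrix(NA_real_, nTot, P, dimnames = list(allIds, NULL))
    founders <- vector("list", nb)
    for (b in seq_len(nb)) {
      mIdx <- which(blk == b)
      m <- length(mIdx)
      q <- runif(m, config@mafMin, 1 - config@mafMin)
      Fh <- matrix(rbinom(K * m, 1, rep(q, each = K)), K, m)
      wD <- rep(1 / K, K)
      z <- rnorm(K, 0, config@driftSd)
      wE <- exp(z) / sum(exp(z))
      if (!is.na(config@divergentBlock) && b == config@divergentBlock) {
        # first marker of this block: carried by half the founders, which
        # the elite panel then almost never samples
        carrier <- seq_len(K) <= K / 2
        Fh[, 1] <- as.integer(carrier)
        # keep the carrier mass tiny: overlap lines (drawn with discovery
        # weights) already contribute carrier alleles to the elite panel
        wE <- ifelse(carrier, 0.001 / sum(carrier), 0.999 / sum(!carrier))
      }
      idxD <- sample.int(K, nD, replace = TRUE, prob = wD)
      idxE <- if (nEonly > 0)
        sample.int(K, nEonly, replace = TRUE, prob = wE) else integer(0)
      dos[, mIdx] <- 2 * Fh[c(idxD, idxE), , drop = FALSE]
      founders[[b]] <- list(haplotypes = Fh, weightsDiscovery = wD,
                            weightsElite = wE, markers = mIdx)
    }
    if (config@residualHetRate > 0) {
      het <- runif(length(dos)) < config@residualHetRate
      dos[het] <- 1
    }
    colnames(dos) <- sprintf("M%05d", seq_len(P))
    list(geno = GenotypeMatrix(dos), discovery = discIds, elite = eliteIds,
         founders = founders, blocks = blk)
  })
}

#' Describe the genetic architecture of one simulated trait
#'
#' @param traitId trait label.
#' @param nQtl number of causal markers.
#' @param effectDistribution "gaussian" (many small effects), "scaled_t"
#'   (heavy-tailed, occasional large effects) or "point_mass_mixture"
#'   (mostly zero with a few large effects).
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param sharedQtlMap list of `list(other=, indices=, rho=)` entries
#'   declaring QTL shared with another trait and the effect correlation.
#' @param qtlIndices optional explicit causal marker indices (sampled
#'   otherwise).
#' @return a validated list of class `TraitArchitecture`.
#' @export
traitArchitecture <- function(traitId, nQtl, effectDistribution = "gaussian",
                              h2 = 0.5, sharedQtlMap = list(),
                              qtlIndices = NULL) {
  effectDistribution <- match.arg(effectDistribution,
                                  c("gaussian", "scaled_t",
                                    "point_mass_mixture"))
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (nQtl < 0) stop("nQtl must be >= 0")
  structure(list(traitId = traitId, nQtl = nQtl,
                 effectDistribution = effectDistribution, h2 = h2,
                 sharedQtlMap = sharedQtlMap, qtlIndices = qtlIndices),
            class = "TraitArchitecture")
}

drawEffects <- function(n, distribution) {
  switch(distribution,
         gaussian = rnorm(n),
         scaled_t = rt(n, df = 3),
         point_mass_mixture = ifelse(runif(n) < 0.8, 0,
                                     rnorm(n, 0, sqrt(5))))
}

#' Simulate genetically correlated endophenotypes
#'
#' Draws QTL effects per trait from the declared distribution and forms true
#' breeding values as centered dosages times effects. QTL declared shared in
#' `sharedQtlMap` receive correlated effects: for correlation `rho`, the
#' second trait's effect at a shared marker is
#' `rho * a_first + sqrt(1 - rho^2) * z`.
#'
#' @param sim output of [simulateGenotypes()] (or a [GenotypeMatrix-class]).
#' @param archs list of [traitArchitecture()] objects.
#' @param seed integer seed.
#' @return a [SimTruth-class] with QTL indices, full-length effect vectors
#'   and the lines x traits breeding-value matrix.
#' @export
simulateEndophenotypes <- function(sim, archs, seed = 1) {
  geno <- if (is(sim, "GenotypeMatrix")) sim else sim$geno
  d <- dosages(geno)
  if (anyNA(d)) stop("dosage matrix must be complete (impute first)")
  P <- ncol(d)
  traitIds <- vapply(archs, `[[`, "", "traitId")
  if (anyDuplicated(traitIds)) stop("duplicated trait ids")

  # shared-map consistency: every shared index must be declared by both sides
  for (a in archs) for (s in a$sharedQtlMap) {
    if (!s$other %in% traitIds)
      stop("sharedQtlMap references unknown trait: ", s$other)
    if (any(s$indices < 1 | s$indices > P))
      stop("shared QTL indices out of marker range")
  }

  withSeed(seed, {
    qtl <- list(); eff <- list()
    for (a in archs) {
      if (any(!is.null(a$qtlIndices)) && any(a$qtlIndices > P))
        stop("qtlIndices out of marker range")
      shared <- unlist(lapply(a$sharedQtlMap, `[[`, "indices"))
      own <- a$qtlIndices %||%
        c(shared, sample(setdiff(seq_len(P), shared),
                         max(0, a$nQtl - length(shared))))
      own <- unique(as.integer(own))
      e <- numeric(P)
      e[own] <- drawEffects(length(own), a$effectDistribution)
      for (s in a$sharedQtlMap) {
        if (!s$other %in% names(eff)) next  # partner processed later
        if (!all(s$indices %in% qtl[[s$other]]))
          stop("shared QTL indices not causal in trait ", s$other)
        aOther <- eff[[s$other]][s$indices]
        sdO <- sd(aOther); if (is.na(sdO) || sdO == 0) sdO <- 1
        e[s$indices] <- s$rho * aOther +
          sqrt(1 - s$rho^2) * rnorm(length(s$indices), 0, sdO)
      }
      qtl[[a$traitId]] <- own
      eff[[a$traitId]] <- e
    }
    # the later trait of each declared pair must also declare the link
    for (a in archs) for (s in a$sharedQtlMap) {
      if (!all(s$indices %in% qtl[[a$traitId]]) ||
          !all(s$indices %in% qtl[[s$other]]))
        stop("shared QTL must be causal in both traits (",
             a$traitId, " / ", s$other, ")")
    }
    Wc <- scale(d, center = TRUE, scale = FALSE)
    bv <- vapply(traitIds, function(tr) as.numeric(Wc %*% eff[[tr]]),
                 numeric(nrow(d)))
    rownames(bv) <- rownames(d)
    new("SimTruth", qtl = qtl, effects = eff, bv = bv,
        realizedH2 = setNames(numeric(0), character(0)),
        focalWeights = numeric(0))
  })
}

#' Add a focal trait as a weighted sum of endophenotype genetic values
#'
#' The focal genetic value is `sum_t w_t bv_t` plus an independent polygenic
#' term whose variance makes up `extraPolygenicShare` of the focal genetic
#' variance. When `sim` is supplied the polygenic term is itself a
#' whole-genome marker term (small Gaussian effects at every marker);
#' otherwise it is line-level Gaussian noise.
#'
#' @param truth a [SimTruth-class] from [simulateEndophenotypes()].
#' @param weights numeric weights, one per endophenotype column of `truth`.
#' @param extraPolygenicShare share in `[0, 1)` of focal genetic variance
#'   from loci unrelated to the endophenotypes.
#' @param h2 target heritability of the focal trait, stored for the field
#'   design stage.
#' @param sim optional [simulateGenotypes()] output for a marker-based
#'   polygenic term.
#' @param traitId name of the focal trait column.
#' @param seed integer seed.
#' @return the updated [SimTruth-class] with a focal column appended to
#'   `bv` and `focalWeights` recorded.
#' @export
simulateFocalTrait <- function(truth, weights, extraPolygenicShare = 0.2,
                               h2 = 0.4, sim = NULL, traitId = "focal",
                               seed = 1) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (extraPolygenicShare < 0 || extraPolygenicShare >= 1)
    stop("extraPolygenicShare must lie in [0, 1)")
  nEndo <- ncol(truth@bv)
  if (length(weights) != nEndo)
    stop("need one weight per endophenotype (", nEndo, ")")
  withSeed(seed, {
    base <- as.numeric(truth@bv %*% weights)
    poly <- numeric(length(base))
    if (extraPolygenicShare > 0 && var(base) > 0) {
      targetVar <- extraPolygenicShare / (1 - extraPolygenicShare) * var(base)
      if (!is.null(sim)) {
        geno <- if (is(sim, "GenotypeMatrix")) sim else sim$geno
        Wc <- scale(dosages(geno), center = TRUE, scale = FALSE)
        raw <- as.numeric(Wc %*% rnorm(ncol(Wc)))
        poly <- raw * sqrt(targetVar / var(raw))
      } else {
        poly <- rnorm(length(base), 0, sqrt(targetVar))
      }
    }
    focal <- base + poly
    truth@bv <- cbind(truth@bv, focal)
    colnames(truth@bv)[ncol(truth@bv)] <- traitId
    truth@focalWeights <- weights
    truth@realizedH2[traitId] <- h2
    truth
  })
}

#' Generate plot-level phenotype records under an augmented block design
#'
#' Unreplicated entries appear once per trial; `nChecks` check varieties are
#' replicated in every block. Measurement batches are consecutive runs of
#' `batchSize` plots in field order, mimicking instrument injection order.
#' Block, batch and trial effects are Gaussian with variances expressed as
#' shares of the genetic variance; the residual variance is set from the
#' target entry-mean heritability `h2` (one plot per entry, so
#' `varE = varG (1 - h2) / h2`).
#'
#' @param bv named numeric vector of true genetic values (the entries).
#' @param trait trait label written into the records.
#' @param nTrials,nBlocks,nChecks,batchSize design geometry.
#' @param blockVarShare,batchVarShare,trialVarShare variance shares relative
#'   to `var(bv)`.
#' @param covariateBeta fixed-effect slope of the entry-level covariate
#'   (heading-date analogue); the covariate is standard normal per entry.
#'   Use 0 to omit covariate effects (the column is still emitted).
#' @param h2 target entry-mean heritability in (0, 1].
#' @param mu overall mean.
#' @param plotsPerBlock optional capacity; error if entries + checks exceed
#'   `nBlocks * plotsPerBlock`.
#' @param checkBv optional named genetic values for the checks (drawn from
#'   `N(0, var(bv))` otherwise).
#' @param seed integer seed.
#' @return a long-format data.frame: line_id, trait, trial, block, batch,
#'   is_check, covariate, value.
#' @export
applyFieldDesign <- function(bv, trait = "trait", nTrials = 1, nBlocks = 10,
                             nChecks = 2, batchSize = 20,
                             blockVarShare = 0.1, batchVarShare = 0.1,
                             trialVarShare = 0.1, covariateBeta = 0,
                             h2 = 0.5, mu = 0, plotsPerBlock = NULL,
                             checkBv = NULL, seed = 1) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  entries <- names(bv)
  if (is.null(entries)) stop("bv must be named by line id")
  nE <- length(entries)
  if (!is.null(plotsPerBlock) &&
      nE + nChecks * nBlocks > nBlocks * plotsPerBlock)
    stop("more entries than plots: ", nE, " entries do not fit ",
         nBlocks, " blocks of ", plotsPerBlock)
  varG <- if (nE > 1) var(bv) else 1
  varE <- varG * (1 - h2) / h2
  withSeed(seed, {
    if (is.null(checkBv)) {
      checkBv <- setNames(rnorm(nChecks, 0, sqrt(varG)),
                          sprintf("CHK%02d", seq_len(nChecks)))
    }
    covariate <- setNames(rnorm(nE + length(checkBv)),
                          c(entries, names(checkBv)))
    g <- c(bv, checkBv)
    out <- vector("list", nTrials)
    for (tr in seq_len(nTrials)) {
      trialEff <- rnorm(1, 0, sqrt(trialVarShare * varG))
      blockEff <- rnorm(nBlocks, 0, sqrt(blockVarShare * varG))
      entryBlock <- sample(rep(seq_len(nBlocks), length.out = nE))
      plots <- data.frame(
        line_id = c(entries, rep(names(checkBv), each = nBlocks)),
        block = c(entryBlock, rep(seq_len(nBlocks), times = length(checkBv))),
        is_check = c(rep(FALSE, nE),
                     rep(TRUE, nBlocks * length(checkBv))),
        stringsAsFactors = FALSE)
      plots <- plots[order(plots$block, plots$line_id), ]
      nPlot <- nrow(plots)
      plots$batch <- (seq_len(nPlot) - 1) %/% batchSize + 1
      nBatch <- max(plots$batch)
      batchEff <- rnorm(nBatch, 0, sqrt(batchVarShare * varG))
      e <- rnorm(nPlot, 0, sqrt(varE))
      plots$trait <- trait
      plots$trial <- sprintf("T%02d", tr)
      plots$covariate <- covariate[plots$line_id]
      plots$value <- mu + covariateBeta * plots$covariate +
        g[plots$line_id] + blockEff[plots$block] + batchEff[plots$batch] +
        trialEff + e
      out[[tr]] <- plots[, c("line_id", "trait", "trial", "block", "batch",
                             "is_check", "covariate", "value")]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
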
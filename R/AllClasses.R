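#' @import methods
#' @importFrom stats var cor sd rnorm runif rbeta rgamma rchisq rbinom rt
#'   setNames complete.cases aggregate quantile
#' @importFrom utils read.csv write.csv read.delim write.table head
#' @useDynLib tgrm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GenotypeMatrix: lines x markers allele dosages
#'
#' Container for biallelic SNP dosages coded 0/1/2 (reference-allele count on
#' fully inbred material is mostly 0 or 2). Missing calls are `NA`; imputed
#' dosages may be fractional in `[0, 2]`. Row names are line identifiers and
#' column names are marker identifiers; both are mandatory.
#'
#' @slot dosages numeric matrix, lines in rows, markers in columns.
#' @export
setClass("GenotypeMatrix", representation(dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (!is.numeric(d)) return("dosages must be a numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosages must carry line (row) and marker (column) names")
  if (anyDuplicated(rownames(d))) return("duplicated line ids")
  if (anyDuplicated(colnames(d))) return("duplicated marker ids")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("dosages must lie in [0, 2]")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (lines x markers) with dimnames.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages) {
  new("GenotypeMatrix", dosages = as.matrix(dosages))
}

#' MarkerEffects: posterior-mean marker effects from one sampler run
#'
#' @slot effects named numeric vector of posterior-mean additive effects.
#' @slot method sampler label (BRR, BayesA, BayesB, BayesCpi, BL).
#' @slot varE posterior-mean residual variance.
#' @slot varMarker posterior-mean marker-effect variance (method specific).
#' @slot pi posterior mean of the point-mass (exclusion) probability;
#'   `NA` for methods without a mixture prior.
#' @slot inclusionProb per-marker posterior inclusion probability
#'   (length 0 for non-mixture methods).
#' @slot nSamples number of retained posterior draws.
#' @export
setClass("MarkerEffects", representation(
  effects = "numeric", method = "character", varE = "numeric",
  varMarker = "numeric", pi = "numeric", inclusionProb = "numeric",
  nSamples = "integer"))

setValidity("MarkerEffects", function(object) {
  if (is.null(names(object@effects))) return("effects must be named by marker id")
  if (length(object@varE) != 1 || object@varE <= 0) return("varE must be a positive scalar")
  if (!is.na(object@pi) && (object@pi < 0 || object@pi > 1)) return("pi must lie in [0,1]")
  if (length(object@inclusionProb) &&
      length(object@inclusionProb) != length(object@effects))
    return("inclusionProb length must match effects")
  TRUE
})

#' Kernel: symmetric PSD line x line relationship matrix
#'
#' @slot K symmetric numeric matrix with line ids as dimnames.
#' @slot type "GRM" or "TGRM:<trait>".
#' @slot bending amount added to the diagonal to restore PSD (0 if none).
#' @export
setClass("Kernel", representation(K = "matrix", type = "character",
                                  bending = "numeric"))

setValidity("Kernel", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("kernel must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    return("kernel needs identical row/column line ids")
  if (max(abs(K - t(K))) > 1e-10) return("kernel must be symmetric")
  TRUE
})

#' CenteredDosages: column-centered, unit-variance dosage matrix
#'
#' @slot M centered/scaled matrix (lines x markers).
#' @slot centers,scales per-column centering and scaling constants used.
#' @export
setClass("CenteredDosages", representation(M = "matrix", centers = "numeric",
                                           scales = "numeric"))

setValidity("CenteredDosages", function(object) {
  if (max(abs(colMeans(object@M))) > 1e-8) return("columns must be centered")
  if (any(object@scales <= 0)) return("scale factors must be positive")
  TRUE
})

#' AugmentedModelFit: EM-REML fit of the augmented-design mixed model
#'
#' @slot fixef named fixed-effect estimates (intercept, covariate, checks).
#' @slot varcomp named variance components (entry, block, batch, residual).
#' @slot blup named entry BLUPs (unreplicated entries).
#' @slot pev named prediction error variances, same order as `blup`.
#' @slot convergence list with iterations, logLik path and converged flag.
#' @export
setClass("AugmentedModelFit", representation(
  fixef = "numeric", varcomp = "numeric", blup = "numeric",
  pev = "numeric", convergence = "list"))

setValidity("AugmentedModelFit", function(object) {
  if (any(object@varcomp < 0)) return("variance components must be >= 0")
  if (length(object@blup) != length(object@pev))
    return("blup and pev must align")
  TRUE
})

#' DeregressedValues: deregressed entry BLUPs with reliabilities
#'
#' @slot table data.frame with line_id, value (deregressed BLUP), reliability.
#' @slot excluded data.frame with line_id and exclusion reason.
#' @export
setClass("DeregressedValues", representation(table = "data.frame",
                                             excluded = "data.frame"))

#' KernelModelFit: Bayesian kernel-regression (gBLUP/TGRM-BLUP) fit
#'
#' @slot gebv named per-line total genomic value (sum over kernels).
#' @slot u lines x kernels matrix of per-kernel genetic values.
#' @slot sigma2 named per-kernel variance components.
#' @slot varE residual variance posterior mean.
#' @slot fixef fixed-effect posterior means (intercept, trial effects).
#' @export
setClass("KernelModelFit", representation(
  gebv = "numeric", u = "matrix", sigma2 = "numeric", varE = "numeric",
  fixef = "numeric"))

setValidity("KernelModelFit", function(object) {
  if (any(!is.finite(object@gebv))) return("GEBVs must be finite")
  if (object@varE <= 0) return("residual variance must be positive")
  TRUE
})

#' MultiTraitFit: multi-trait kernel BLUP fit with missing phenotypes
#'
#' @slot U lines x traits posterior-mean genetic values.
#' @slot SigmaG,SigmaE trait x trait genetic and residual covariance
#'   posterior means.
#' @slot mu per-trait intercepts.
#' @export
setClass("MultiTraitFit", representation(
  U = "matrix", SigmaG = "matrix", SigmaE = "matrix", mu = "numeric"))

setValidity("MultiTraitFit", function(object) {
  for (S in list(object@SigmaG, object@SigmaE)) {
    if (max(abs(S - t(S))) > 1e-8) return("covariance matrices must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return("covariance matrices must be PSD")
  }
  TRUE
})

#' CVReport: repeated cross-validation accuracies
#'
#' @slot results data.frame(run, fold, method, trial, r).
#' @slot runMeans data.frame(run, method, accuracy) after fold averaging.
#' @slot methods method labels present.
#' @slot nRuns number of resampling runs.
#' @export
setClass("CVReport", representation(results = "data.frame",
                                    runMeans = "data.frame",
                                    methods = "character", nRuns = "integer"))

setValidity("CVReport", function(object) {
  r <- object@results$r
  if (any(!is.na(r) & (r < -1 - 1e-12 | r > 1 + 1e-12)))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' SimTruth: ground truth of a simulated study
#'
#' @slot qtl named list of QTL marker indices per trait.
#' @slot effects named list of full-length true effect vectors per trait.
#' @slot bv lines x traits matrix of true breeding values.
#' @slot realizedH2 named realized narrow-sense heritabilities (filled by
#'   [applyFieldDesign()]).
#' @slot focalWeights weights of the endophenotypes in the focal trait.
#' @export
setClass("SimTruth", representation(
  qtl = "list", effects = "list", bv = "matrix", realizedH2 = "numeric",
  focalWeights = "numeric"))

#' SimConfig: parameters of the two-panel genotype simulator
#'
#' Defaults mirror the study conditions this package emulates: a 336-line
#' discovery panel and a 210-line elite panel sharing 12 lines, genotyped on
#' a dense inbred SNP panel.
#'
#' @slot nLinesDiscovery,nLinesElite,nOverlap panel sizes and overlap.
#' @slot nMarkers,nLdBlocks,nFoundersPerBlock marker panel and LD structure.
#' @slot mafMin lower bound of founder allele frequencies.
#' @slot driftSd sd of the logit-scale founder-weight perturbation that
#'   separates the elite panel from the discovery panel.
#' @slot residualHetRate probability a dosage is left heterozygous.
#' @slot divergentBlock optional LD-block index whose first marker is forced
#'   to be common in the discovery panel but rare in the elite panel.
#' @slot seed integer seed.
#' @export
setClass("SimConfig", representation(
  nLinesDiscovery = "numeric", nLinesElite = "numeric", nOverlap = "numeric",
  nMarkers = "numeric", nLdBlocks = "numeric", nFoundersPerBlock = "numeric",
  mafMin = "numeric", driftSd = "numeric", residualHetRate = "numeric",
  divergentBlock = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  counts <- c(object@nLinesDiscovery, object@nLinesElite, object@nOverlap,
              object@nMarkers, object@nLdBlocks, object@nFoundersPerBlock)
  if (any(counts < 0) || any(counts[-3] <= 0)) return("counts must be positive")
  if (object@nOverlap > min(object@nLinesDiscovery, object@nLinesElite))
    return("nOverlap must not exceed either panel size")
  if (object@mafMin <= 0 || object@mafMin >= 0.5)
    return("mafMin must lie in (0, 0.5)")
  if (object@residualHetRate < 0 || object@residualHetRate > 1)
    return("residualHetRate must be a probability")
  if (object@nLdBlocks > object@nMarkers)
    return("cannot have more LD blocks than markers")
  TRUE
})
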
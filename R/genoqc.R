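#' Quality-control thresholds for markers and individuals
#'
#' Defaults follow common SNP-panel practice for inbred material: markers
#' with allele frequency below 0.02, more than 60% missing calls or more
#' than 10% heterozygous calls are dropped; individuals missing more than
#' 70% of markers or heterozygous at more than 10% are dropped. A stricter
#' per-analysis MAF bound (0.05) is applied after extracting each study's
#' line subset, via `markerMafMin`.
#'
#' Removal uses strict inequalities ("< maf", "> missing"), so a marker
#' sitting exactly at a threshold is retained.
#'
#' @param markerMafMin,markerMissingMax,markerHetMax marker thresholds.
#' @param indivMissingMax,indivHetMax individual thresholds.
#' @return list of class `QCThresholds`.
#' @export
qcThresholds <- function(markerMafMin = 0.02, markerMissingMax = 0.6,
                         markerHetMax = 0.1, indivMissingMax = 0.7,
                         indivHetMax = 0.1) {
  v <- c(markerMafMin, markerMissingMax, markerHetMax, indivMissingMax,
         indivHetMax)
  if (any(v < 0 | v > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(markerMafMin = markerMafMin,
                 markerMissingMax = markerMissingMax,
                 markerHetMax = markerHetMax,
                 indivMissingMax = indivMissingMax,
                 indivHetMax = indivHetMax), class = "QCThresholds")
}

# allele frequency of the counted allele from non-missing calls
# (heterozygotes contribute one allele each); MAF folds at 0.5
markerMaf <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter markers on MAF, missingness and heterozygosity
#'
#' @param geno a [GenotypeMatrix-class] with dosages in \{0, 1, 2, NA\}.
#' @param thresholds a [qcThresholds()] object.
#' @return list with `geno` (filtered) and `report` (data.frame of removed
#'   markers with reason; reasons are assigned in the order
#'   maf, missing, het and partition the removals).
#' @export
filterMarkers <- function(geno, thresholds = qcThresholds()) {
  d <- dosages(geno)
  maf <- markerMaf(d)
  miss <- colMeans(is.na(d))
  het <- colMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 1 # all-missing marker: treated as failing
  maf[is.nan(maf)] <- 0
  reason <- rep(NA_character_, ncol(d))
  reason[het > thresholds$markerHetMax] <- "het"
  reason[miss > thresholds$markerMissingMax] <- "missing"
  reason[maf < thresholds$markerMafMin] <- "maf"
  keep <- is.na(reason)
  if (!any(keep))
    stop("all ", ncol(d), " markers removed (maf: ", sum(reason == "maf",
         na.rm = TRUE), ", missing: ", sum(reason == "missing", na.rm = TRUE),
         ", het: ", sum(reason == "het", na.rm = TRUE), ")")
  report <- data.frame(marker_id = colnames(d)[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  list(geno = GenotypeMatrix(d[, keep, drop = FALSE]), report = report)
}

#' Filter individuals on missingness and heterozygosity
#'
#' @inheritParams filterMarkers
#' @return list with `geno` and `report` (line_id, reason).
#' @export
filterIndividuals <- function(geno, thresholds = qcThresholds()) {
  d <- dosages(geno)
  miss <- rowMeans(is.na(d))
  het <- rowMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 1
  reason <- rep(NA_character_, nrow(d))
  reason[het > thresholds$indivHetMax] <- "het"
  reason[miss > thresholds$indivMissingMax] <- "missing"
  keep <- is.na(reason)
  if (!any(keep)) stop("all individuals removed by QC")
  report <- data.frame(line_id = rownames(d)[!keep], reason = reason[!keep],
                       stringsAsFactors = FALSE)
  list(geno = GenotypeMatrix(d[keep, , drop = FALSE]), report = report)
}

#' Run the full QC sequence: markers first, then individuals
#'
#' @inheritParams filterMarkers
#' @return list with `geno`, `markerReport`, `indivReport`.
#' @export
runQC <- function(geno, thresholds = qcThresholds()) {
  fm <- filterMarkers(geno, thresholds)
  fi <- filterIndividuals(fm$geno, thresholds)
  list(geno = fi$geno, markerReport = fm$report, indivReport = fi$report)
}

#' Replace missing dosages by the marker mean
#'
#' @param geno a [GenotypeMatrix-class].
#' @return a complete [GenotypeMatrix-class]; observed calls are untouched,
#'   so per-marker means are preserved.
#' @export
imputeMean <- function(geno) {
  d <- dosages(geno)
  if (!anyNA(d)) return(geno)
  cm <- colMeans(d, na.rm = TRUE)
  if (anyNA(cm) || any(is.nan(cm)))
    stop("marker(s) with all calls missing; filter markers first")
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- cm[idx[, 2]]
  GenotypeMatrix(d)
}
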
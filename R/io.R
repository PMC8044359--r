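# File-format adapters. Every writer/reader pair round-trips: read(write(x))
# reproduces x (up to numeric printing precision where noted).

#' Dosage CSV adapters
#'
#' Lines x markers table: first column `line_id`, remaining columns one per
#' marker (header row carries marker ids). Missing calls are empty cells.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path file path.
#' @return `readDosageCSV` returns a [GenotypeMatrix-class].
#' @export
writeDosageCSV <- function(geno, path) {
  d <- dosages(geno)
  df <- data.frame(line_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeDosageCSV
#' @export
readDosageCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line_id")
    stop("malformed dosage CSV (line 1): first column must be line_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line_id
  GenotypeMatrix(m)
}

#' Minimal VCF adapters (GT field only)
#'
#' The writer emits an unphased biallelic VCF 4.2 with genotypes mapped from
#' dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.); markers are laid out
#' on a single synthetic contig at consecutive positions, since no
#' position-aware logic is used anywhere in the package. The reader (built
#' on vcfR) accepts any GT-bearing VCF and counts alternate alleles.
#'
#' @param geno a [GenotypeMatrix-class] with integer dosages.
#' @param path file path.
#' @return `readVCF` returns a [GenotypeMatrix-class].
#' @export
writeVCF <- function(geno, path) {
  d <- dosages(geno)
  if (any(!is.na(d) & d != round(d)))
    stop("VCF output requires integer dosages (write imputed data as CSV)")
  gtMap <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt <- matrix(gtMap[d + 1], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  body <- vapply(seq_len(ncol(d)), function(j)
    paste(c("1", j, colnames(d)[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeVCF
#' @export
readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt == "0/0"] <- 0
  d[gt %in% c("0/1", "1/0")] <- 1
  d[gt == "1/1"] <- 2
  GenotypeMatrix(t(d))
}

#' Long-format phenotype CSV adapters
#'
#' Columns: line_id, trait, trial, block, batch, is_check, covariate, value.
#'
#' @param records phenotype data.frame (see [applyFieldDesign()]).
#' @param path file path.
#' @export
writePhenotypeCSV <- function(records, path) {
  cols <- c("line_id", "trait", "trial", "block", "batch", "is_check",
            "covariate", "value")
  stopifnot(all(cols %in% names(records)))
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeCSV
#' @export
readPhenotypeCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "trait", "trial", "block", "batch", "is_check",
            "covariate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed phenotype CSV (line 1): missing column(s) ",
         paste(miss, collapse = ", "))
  df$is_check <- as.logical(df$is_check)
  df
}

#' Kernel CSV adapters (square matrix with line-id header row and column)
#'
#' @param kernel a [Kernel-class].
#' @param path file path.
#' @export
writeKernelCSV <- function(kernel, path) {
  K <- kernelMatrix(kernel)
  df <- data.frame(line_id = rownames(K), K, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeKernelCSV
#' @param type kernel type tag to restore.
#' @export
readKernelCSV <- function(path, type = "GRM") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line_id")
    stop("malformed kernel CSV (line 1): first column must be line_id")
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$line_id
  K <- (K + t(K)) / 2 # symmetrize away printing round-off
  new("Kernel", K = K, type = type, bending = 0)
}

#' Marker-effects TSV adapters
#'
#' @param effects a [MarkerEffects-class].
#' @param path file path.
#' @export
writeEffectsTSV <- function(effects, path) {
  ip <- if (length(effects@inclusionProb)) effects@inclusionProb else
    rep(NA_real_, length(effects@effects))
  df <- data.frame(marker_id = names(effects@effects),
                   effect = unname(effects@effects),
                   inclusion_prob = unname(ip))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEffectsTSV
#' @param method method label to restore.
#' @param varE residual variance to restore.
#' @export
readEffectsTSV <- function(path, method = "BRR", varE = 1) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "effect") %in% names(df)))
    stop("malformed effects TSV (line 1): need marker_id and effect columns")
  new("MarkerEffects",
      effects = setNames(df$effect, df$marker_id), method = method,
      varE = varE, varMarker = NA_real_, pi = NA_real_,
      inclusionProb = if (all(is.na(df$inclusion_prob))) numeric(0) else
        setNames(df$inclusion_prob, df$marker_id),
      nSamples = NA_integer_)
}

#' GEBV TSV adapters (line_id, model, gebv)
#'
#' @param gebvs named numeric vector.
#' @param model model label.
#' @param path file path.
#' @export
writeGEBVTSV <- function(gebvs, model, path) {
  df <- data.frame(line_id = names(gebvs), model = model,
                   gebv = unname(gebvs))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGEBVTSV
#' @export
readGEBVTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "model", "gebv") %in% names(df)))
    stop("malformed GEBV TSV (line 1)")
  df
}

#' CVReport TSV adapters (run, fold, method, trial, r)
#'
#' @param report a [CVReport-class].
#' @param path file path.
#' @export
writeCVReportTSV <- function(report, path) {
  write.table(report@results, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writeCVReportTSV
#' @export
readCVReportTSV <- function(path) {
  results <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("run", "fold", "method", "trial", "r")
  if (!all(need %in% names(results))) stop("malformed CVReport TSV (line 1)")
  foldMeans <- aggregate(r ~ run + fold + method, data = results, FUN = mean)
  runMeans <- aggregate(r ~ run + method, data = foldMeans, FUN = mean)
  names(runMeans)[names(runMeans) == "r"] <- "accuracy"
  new("CVReport", results = results, runMeans = runMeans,
      methods = unique(results$method),
      nRuns = length(unique(results$run)))
}

#' Simulation-truth JSON sidecar
#'
#' @param truth a [SimTruth-class].
#' @param path file path.
#' @export
writeSimTruthJSON <- function(truth, path) {
  jsonlite::write_json(list(
    qtl = truth@qtl,
    effects = truth@effects,
    bv = list(lines = rownames(truth@bv), traits = colnames(truth@bv),
              values = unname(truth@bv)),
    realizedH2 = as.list(truth@realizedH2),
    focalWeights = truth@focalWeights), path, digits = NA,
    auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeSimTruthJSON
#' @export
readSimTruthJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bv <- as.matrix(x$bv$values)
  dimnames(bv) <- list(x$bv$lines, x$bv$traits)
  new("SimTruth", qtl = lapply(x$qtl, as.integer),
      effects = lapply(x$effects, as.numeric), bv = bv,
      realizedH2 = unlist(x$realizedH2) %||% setNames(numeric(0), character(0)),
      focalWeights = as.numeric(x$focalWeights))
}
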
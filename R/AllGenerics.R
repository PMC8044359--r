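#' Accessors for tgrm objects
#'
#' `dosages()`, `lineIds()`, `markerIds()` access a [GenotypeMatrix-class];
#' `kernelMatrix()` the matrix of a [Kernel-class]; `markerEffects()` the
#' effect vector of a [MarkerEffects-class]; `gebv()` the genomic estimated
#' breeding values of a fit.
#'
#' @param object a tgrm S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(object) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(object) standardGeneric("kernelMatrix"))
#' @rdname accessors
#' @export
setGeneric("markerEffects", function(object) standardGeneric("markerEffects"))
#' @rdname accessors
#' @export
setGeneric("gebv", function(object) standardGeneric("gebv"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(object) object@dosages)
#' @rdname accessors
#' @export
setMethod("lineIds", "GenotypeMatrix", function(object) rownames(object@dosages))
#' @rdname accessors
#' @export
setMethod("markerIds", "GenotypeMatrix", function(object) colnames(object@dosages))
#' @rdname accessors
#' @export
setMethod("lineIds", "Kernel", function(object) rownames(object@K))
#' @rdname accessors
#' @export
setMethod("kernelMatrix", "Kernel", function(object) object@K)
#' @rdname accessors
#' @export
setMethod("markerEffects", "MarkerEffects", function(object) object@effects)
#' @rdname accessors
#' @export
setMethod("markerIds", "MarkerEffects", function(object) names(object@effects))
#' @rdname accessors
#' @export
setMethod("gebv", "KernelModelFit", function(object) object@gebv)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "lines x", ncol(d), "markers\n")
  cat("  missing calls:", sum(is.na(d)),
      sprintf("(%.2f%%)\n", 100 * mean(is.na(d))))
})

setMethod("show", "MarkerEffects", function(object) {
  cat("MarkerEffects [", object@method, "]: ", length(object@effects),
      " markers, ", object@nSamples, " posterior draws\n", sep = "")
  cat(sprintf("  varE = %.4g", object@varE))
  if (!is.na(object@pi)) cat(sprintf(", pi (point mass) = %.3f", object@pi))
  cat("\n")
})

setMethod("show", "Kernel", function(object) {
  cat("Kernel [", object@type, "]: ", nrow(object@K), " lines",
      if (object@bending > 0) sprintf(", bent by %.2g", object@bending),
      "\n", sep = "")
})

setMethod("show", "AugmentedModelFit", function(object) {
  cat("AugmentedModelFit:", length(object@blup), "entry BLUPs\n")
  cat("  variance components:\n")
  print(round(object@varcomp, 5))
  cat("  converged:", object@convergence$converged, "in",
      object@convergence$iterations, "iterations\n")
})

setMethod("show", "KernelModelFit", function(object) {
  cat("KernelModelFit:", length(object@gebv), "lines,",
      ncol(object@u), "kernel(s)\n")
  cat("  sigma2:", paste(sprintf("%s=%.4g", names(object@sigma2),
                                 object@sigma2), collapse = ", "),
      sprintf(" varE=%.4g\n", object@varE))
})

setMethod("show", "MultiTraitFit", function(object) {
  cat("MultiTraitFit:", nrow(object@U), "lines x", ncol(object@U), "traits\n")
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport:", object@nRuns, "runs,",
      length(object@methods), "methods:",
      paste(object@methods, collapse = ", "), "\n")
  rm <- object@runMeans
  for (m in object@methods)
    cat(sprintf("  %-12s mean accuracy %.3f\n", m,
                mean(rm$accuracy[rm$method == m], na.rm = TRUE)))
})
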
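#' Center and scale a dosage matrix
#'
#' Each marker column is centered to mean zero and scaled to unit sample
#' variance. Zero-variance columns are an error: filter them first.
#'
#' @param geno a complete [GenotypeMatrix-class] (or numeric matrix).
#' @return a [CenteredDosages-class].
#' @export
centerScale <- function(geno) {
  d <- if (is(geno, "GenotypeMatrix")) dosages(geno) else as.matrix(geno)
  if (anyNA(d)) stop("dosages must be complete")
  sds <- apply(d, 2, sd)
  if (any(sds == 0))
    stop(sum(sds == 0), " zero-variance marker column(s); filter first")
  M <- scale(d, center = TRUE, scale = sds)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  new("CenteredDosages", M = M, centers = colMeans(d), scales = sds)
}

#' Marker weights for a trait-specific kernel
#'
#' Raw weights are the normalized squared effects `a_p^2 / sum(a^2)`, which
#' sum to one. By default they are rescaled to sum to the marker count `P`
#' so that uniform effects reproduce the unweighted kernel `M M' / P` and
#' variance components remain on the same scale across kernels; set
#' `rescale = FALSE` for the sum-to-one convention.
#'
#' Weights are invariant to rescaling all effects by a constant.
#'
#' @param effects a [MarkerEffects-class] or named numeric vector.
#' @param rescale rescale weights to sum to `P` (default TRUE).
#' @return named numeric weight vector with attribute `normalization`.
#' @export
tgrmWeights <- function(effects, rescale = TRUE) {
  a <- if (is(effects, "MarkerEffects")) markerEffects(effects) else effects
  if (is.null(names(a))) stop("effects must be named by marker id")
  ss <- sum(a^2)
  if (ss == 0) stop("all effects are zero: trait-specific kernel undefined")
  d <- a^2 / ss
  if (rescale) d <- d * length(a)
  attr(d, "normalization") <- if (rescale) "sum=P" else "sum=1"
  d
}

#' Build a trait-specific genomic relationship matrix
#'
#' `G* = M D M' / P` with `M` the centered/scaled dosages and `D` the
#' diagonal marker-weight matrix. Weights are aligned to `M`'s markers by
#' name; markers of `M` absent from the weight vector (e.g. filtered out of
#' the effect-estimation panel) receive weight zero.
#'
#' @param M a [CenteredDosages-class].
#' @param weights output of [tgrmWeights()].
#' @param trait trait label stored in the kernel type tag.
#' @param eps PSD bending tolerance (see [bendPSD()]).
#' @return a [Kernel-class] of type `TGRM:<trait>`.
#' @export
buildTGRM <- function(M, weights, trait = "trait", eps = 1e-6) {
  Mm <- M@M
  P <- ncol(Mm)
  d <- setNames(numeric(P), colnames(Mm))
  common <- intersect(names(weights), colnames(Mm))
  if (length(common) == 0) stop("no markers shared between M and weights")
  d[common] <- weights[common]
  K <- tcrossprod(Mm * rep(sqrt(d), each = nrow(Mm))) / P
  K <- (K + t(K)) / 2
  bendPSD(new("Kernel", K = K, type = paste0("TGRM:", trait), bending = 0),
          eps = eps)
}

#' VanRaden (method 2) genomic relationship matrix
#'
#' `G = (1/P) sum_p (w_p - 2 p_hat)(w_p - 2 p_hat)' / v_p` with allele
#' frequencies `p_hat` estimated from the observed dosages and `v_p` the
#' expected dosage variance at marker `p`. On fully inbred material
#' (dosages essentially 0/2) that variance is `4 p (1 - p)`, which makes
#' the diagonal average about one; `inbred = FALSE` switches to the
#' outbred Hardy-Weinberg variance `2 p (1 - p)`.
#'
#' @param geno a complete [GenotypeMatrix-class].
#' @param inbred scale markers by the inbred (default) or outbred dosage
#'   variance.
#' @param eps PSD bending tolerance.
#' @return a [Kernel-class] of type `GRM`.
#' @export
buildGRMVanRaden <- function(geno, inbred = TRUE, eps = 1e-6) {
  d <- dosages(geno)
  if (anyNA(d)) stop("dosages must be complete")
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) (p in {0,1}); filter first")
  Wc <- sweep(d, 2, 2 * p)
  v <- if (inbred) 4 * p * (1 - p) else 2 * p * (1 - p)
  Wc <- sweep(Wc, 2, sqrt(v), "/")
  K <- tcrossprod(Wc) / ncol(d)
  K <- (K + t(K)) / 2
  bendPSD(new("Kernel", K = K, type = "GRM", bending = 0), eps = eps)
}

#' Bend a kernel to positive semi-definiteness
#'
#' If the smallest eigenvalue is materially negative (below `-tol`),
#' `(eps - minEig)` is added to the diagonal; the amount is recorded in the
#' `bending` slot. Eigenvalues within `-tol` of zero are ordinary
#' floating-point noise and are left untouched.
#'
#' @param kernel a [Kernel-class].
#' @param eps smallest admissible eigenvalue after bending.
#' @param tol negativity below which bending kicks in.
#' @return the (possibly) bent [Kernel-class].
#' @export
bendPSD <- function(kernel, eps = 1e-6, tol = 1e-8) {
  ev <- eigen(kernel@K, symmetric = TRUE, only.values = TRUE)$values
  minEig <- min(ev)
  if (minEig < -tol) {
    add <- eps - minEig
    K <- kernel@K + diag(add, nrow(kernel@K))
    dimnames(K) <- dimnames(kernel@K)
    kernel@K <- K
    kernel@bending <- kernel@bending + add
  }
  kernel
}

#' Subset a kernel to a set of lines
#'
#' @param kernel a [Kernel-class].
#' @param lines line ids to keep, in the requested order.
#' @return the subset [Kernel-class].
#' @export
subsetKernel <- function(kernel, lines) {
  missing <- setdiff(lines, lineIds(kernel))
  if (length(missing))
    stop("lines absent from kernel: ", paste(head(missing, 5), collapse = ", "))
  new("Kernel", K = kernel@K[lines, lines, drop = FALSE],
      type = kernel@type, bending = kernel@bending)
}
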
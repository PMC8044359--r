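test_that("centerScale produces exact zero-mean unit-variance columns", {
  g <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 0, 0, 2, 2, 0, 1, 1, 0,
                               0, 2, 2, 0, 2, 0, 1, 2), 5, 4,
                             dimnames = list(letters[1:5],
                                             sprintf("M%d", 1:4))))
  M <- centerScale(g)
  expect_lt(max(abs(colMeans(M@M))), 1e-12)
  expect_equal(unname(apply(M@M, 2, var)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(M@M[, 1] * M@scales[1] + M@centers[1]),
               unname(dosages(g)[, 1]))

  # the (0,1,2) column maps to (-1,0,1): sample sd is exactly 1
  g3 <- GenotypeMatrix(matrix(c(0, 1, 2), 3, 1,
                              dimnames = list(letters[1:3], "M1")))
  expect_equal(unname(centerScale(g3)@M[, 1]), c(-1, 0, 1))

  mono <- GenotypeMatrix(matrix(2, 3, 1,
                                dimnames = list(letters[1:3], "M1")))
  expect_error(centerScale(mono), "zero-variance")
})

test_that("TGRM weights follow the squared-effect rule", {
  a <- setNames(c(1, 2, 3), c("A", "B", "C"))
  w <- tgrmWeights(a, rescale = FALSE)
  expect_equal(as.vector(w), c(1, 4, 9) / 14)
  w3 <- tgrmWeights(a)
  expect_equal(as.vector(w3), 3 * c(1, 4, 9) / 14)
  expect_equal(sum(w3), 3)

  # uniform effects give uniform unit weights after rescaling
  expect_equal(as.vector(tgrmWeights(setNames(rep(0.3, 5), letters[1:5]))),
               rep(1, 5))
  # a single nonzero effect takes all the weight
  wS <- tgrmWeights(setNames(c(0, 0, 2, 0), letters[1:4]))
  expect_equal(as.vector(wS), c(0, 0, 4, 0))
  # weights are scale-free in the effects
  expect_equal(tgrmWeights(a * 17.3), tgrmWeights(a))
  expect_error(tgrmWeights(setNames(numeric(3), letters[1:3])), "zero")
})

test_that("TGRM equals the hand-computed triple product", {
  d <- matrix(c(0, 2, 2, 0, 0, 0, 2, 2, 2, 2, 0, 0), 4, 3,
              dimnames = list(letters[1:4], c("M1", "M2", "M3")))
  M <- centerScale(GenotypeMatrix(d))
  w <- tgrmWeights(setNames(c(1, 1, 1), colnames(d)))
  K <- buildTGRM(M, w)
  expect_lt(max(abs(kernelMatrix(K) - tcrossprod(M@M) / 3)), 1e-12)

  wgt <- tgrmWeights(setNames(c(2, 1, 0.5), colnames(d)))
  K2 <- buildTGRM(M, wgt)
  oracle <- M@M %*% diag(wgt) %*% t(M@M) / 3
  expect_lt(max(abs(kernelMatrix(K2) - oracle)), 1e-12)

  # single-marker weight: rank one
  K1 <- buildTGRM(M, setNames(c(0, 3, 0), colnames(d)))
  expect_lte(qr(kernelMatrix(K1))$rank, 1)

  # markers missing from the weight vector get weight zero
  K0 <- buildTGRM(M, setNames(2, "M2"))
  expect_equal(kernelMatrix(K0), kernelMatrix(K1) * 2 / 3, tolerance = 1e-10)
})

test_that("uniform-weight TGRM is invariant to effect rescaling", {
  geno <- makeInbredGeno(30, 50, seed = 3)
  M <- centerScale(geno)
  a <- withr::with_seed(4, rnorm(50))
  names(a) <- markerIds(geno)
  K1 <- buildTGRM(M, tgrmWeights(a))
  K2 <- buildTGRM(M, tgrmWeights(a * -5))
  expect_equal(kernelMatrix(K1), kernelMatrix(K2), tolerance = 1e-12)
})

test_that("VanRaden method-2 GRM matches its formula", {
  # single marker, dosages (0,2), p = 0.5
  g <- GenotypeMatrix(matrix(c(0, 2), 2, 1,
                             dimnames = list(c("a", "b"), "M1")))
  K <- kernelMatrix(buildGRMVanRaden(g))
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  # duplicated lines: off-diagonal equals both diagonals
  geno <- makeInbredGeno(30, 80, seed = 6)
  d <- dosages(geno)
  d[2, ] <- d[1, ]
  d <- d[, apply(d, 2, sd) > 0, drop = FALSE]
  K2 <- kernelMatrix(buildGRMVanRaden(GenotypeMatrix(d)))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  expect_equal(K2[1, 2], K2[2, 2], tolerance = 1e-12)

  # inbred panel at many markers: mean diagonal near 1
  gBig <- makeInbredGeno(60, 1000, maf = c(0.3, 0.5), seed = 7)
  expect_lt(abs(mean(diag(kernelMatrix(buildGRMVanRaden(gBig)))) - 1), 0.1)

  mono <- GenotypeMatrix(matrix(c(2, 2, 0, 2), 2, 2,
                                dimnames = list(c("a", "b"), c("M1", "M2"))))
  expect_error(buildGRMVanRaden(mono), "monomorphic")
})

test_that("bending restores PSD and leaves PSD kernels alone", {
  I3 <- diag(3)
  dimnames(I3) <- list(letters[1:3], letters[1:3])
  id <- new("Kernel", K = I3, type = "GRM", bending = 0)
  expect_identical(kernelMatrix(bendPSD(id)), kernelMatrix(id))

  v <- c(1, -0.5, 0.2)
  r1 <- tcrossprod(v)
  dimnames(r1) <- list(letters[1:3], letters[1:3])
  rank1 <- new("Kernel", K = r1, type = "GRM", bending = 0)
  expect_equal(bendPSD(rank1)@bending, 0)

  Kneg <- diag(c(1, 1, -0.01))
  dimnames(Kneg) <- list(letters[1:3], letters[1:3])
  bent <- bendPSD(new("Kernel", K = Kneg, type = "GRM", bending = 0),
                  eps = 1e-6)
  ev <- eigen(kernelMatrix(bent), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1e-6, tolerance = 1e-9)
})

test_that("kernels align with line order and permute consistently", {
  geno <- makeInbredGeno(25, 60, seed = 9)
  K <- buildGRMVanRaden(geno)
  expect_identical(lineIds(K), lineIds(geno))
  perm <- withr::with_seed(10, sample(lineIds(K)))
  Ksub <- subsetKernel(K, perm)
  expect_equal(kernelMatrix(Ksub), kernelMatrix(K)[perm, perm])
  expect_error(subsetKernel(K, c(perm[1], "nope")), "absent")
})

test_that("trace of the uniform TGRM is near the line count", {
  geno <- makeInbredGeno(40, 400, seed = 12)
  M <- centerScale(geno)
  K <- buildTGRM(M, tgrmWeights(setNames(rep(1, 400), markerIds(geno))))
  expect_lt(abs(mean(diag(kernelMatrix(K))) - 1), 1 / sqrt(400) + 0.05)
})
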
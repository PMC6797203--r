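## Independent restricted-likelihood evaluation used as a grid-search
## oracle: direct dense-matrix REML criterion at a given variance ratio.
remlLoglikDirect <- function(delta, yv, Xmat, Kmat) {
  n <- length(yv); p <- ncol(Xmat)
  V <- Kmat + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(Xmat) %*% Vi %*% Xmat
  beta <- solve(XtViX, t(Xmat) %*% Vi %*% yv)
  r <- yv - Xmat %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  as.numeric(-0.5 * ((n - p) * log(rss) + determinant(V)$modulus +
    determinant(XtViX)$modulus))
}

test_that("spectral REML matches a dense grid search of the restricted likelihood", {
  G <- imputeMissing(randomGeno(20L, 80L, seed = 30L))
  Km <- kinship(vanRadenKinship(G))
  m <- genotypeCodes(G)
  y <- withr::with_seed(31L, {
    u <- drop(t(chol(Km + 1e-8 * diag(20))) %*% rnorm(20)) # N(0, K) draw
    setNames(2 + u + rnorm(20, 0, 0.5), rownames(m))
  })
  Xf <- cbind(intercept = rep(1, 20))
  fit <- solveGblupReml(y, Xf, Km)
  deltaHat <- fit@varComp["sigmaE2"] / fit@varComp["sigmaU2"]
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 10000L))
  ll <- vapply(grid, remlLoglikDirect, 0, yv = y, Xmat = Xf, Kmat = Km)
  deltaGrid <- grid[which.max(ll)]
  expect_lt(abs(deltaHat - deltaGrid) / deltaGrid, 1e-3)
  ## the solver's optimum is at least as good as the best grid point
  expect_gte(remlLoglikDirect(deltaHat, y, Xf, Km) + 1e-9, max(ll))
})

test_that("a purely fixed-effect response yields near-zero genetic variance", {
  n <- 30L
  Xf <- cbind(1, rep(c(0, 1), length.out = n))
  y <- drop(Xf %*% c(2, 3))
  fit <- solveGblupReml(y, Xf, diag(n))
  expect_lt(fit@varComp["sigmaU2"] / max(fit@varComp["sigmaE2"], 1e-12), 1e-4)
  expect_lt(max(abs(fit@u)), 1e-6)
  expect_equal(unname(fit@beta), c(2, 3), tolerance = 1e-6)
  expect_error(solveGblupReml(y, cbind(Xf, Xf[, 2]), diag(n)),
    "rank-deficient")
})

test_that("kernel GBLUP equals marker-effect ridge regression (rrBLUP duality)", {
  G <- imputeMissing(randomGeno(40L, 120L, seed = 32L))
  m <- genotypeCodes(G)
  KK <- vanRadenKinship(G)
  y <- withr::with_seed(33L, {
    eff <- rnorm(120, 0, 0.1)
    setNames(drop(m %*% eff) + rnorm(40, 0, 0.5), rownames(m))
  })
  Xf <- cbind(intercept = rep(1, 40))
  fit <- solveGblupReml(y, Xf, kinship(KK))
  ## matched-penalty ridge on the centered marker matrix W: with
  ## K = WW'/c and marker-effect variance sigmaU2/c, the penalty is
  ## lambda = sigmaE2 * c / sigmaU2
  W <- sweep(m, 2, centeringOffsets(KK))
  cc <- KK@denom
  lambda <- fit@varComp["sigmaE2"] * cc / fit@varComp["sigmaU2"]
  e <- y - drop(Xf %*% fit@beta)
  a <- solve(crossprod(W) + lambda * diag(ncol(W)), crossprod(W, e))
  expect_equal(unname(fit@u), unname(drop(W %*% a)), tolerance = 1e-8)
})

test_that("Gibbs posterior means agree with REML BLUPs on a single kernel", {
  ## pedigree-structured genotypes give K real relatedness structure, so
  ## the (sigmaU2, sigmaE2) split is identifiable and REML and posterior
  ## means are comparable
  G <- imputeMissing(simulateCross(tinyMap(nChrom = 5L, m = 12L),
    smallScheme(nBc1f3 = 120L), seed = 34L))
  Km <- kinship(vanRadenKinship(G))
  n <- nrow(kinship(vanRadenKinship(G)))
  y <- withr::with_seed(35L, {
    u <- drop(t(chol(Km + 1e-8 * diag(n))) %*% rnorm(n, 0, 0.7))
    setNames(5 + u + rnorm(n, 0, 0.6), rownames(genotypeCodes(G)))
  })
  Xf <- cbind(intercept = rep(1, n))
  reml <- solveGblupReml(y, Xf, Km)
  gibbs <- solveBayesGibbs(y, Xf, list(g = list(Z = diag(n), K = Km)),
    ChainConfig(nIter = 6000L, burnIn = 1000L, thin = 5L, seed = 36L))
  dif <- abs(gibbs@details$uk[[1L]] - unname(reml@u))
  expect_lt(mean(dif), 3 * mean(gibbs@details$mcse[[1L]]) + 0.02 * sd(y))
  expect_gt(cor(gibbs@details$uk[[1L]], unname(reml@u)), 0.98)
  ## two chains with different seeds agree within combined MC error
  gibbs2 <- solveBayesGibbs(y, Xf, list(g = list(Z = diag(n), K = Km)),
    ChainConfig(nIter = 6000L, burnIn = 1000L, thin = 5L, seed = 37L))
  comb <- sqrt(gibbs@details$mcse[[1L]]^2 + gibbs2@details$mcse[[1L]]^2)
  frac <- mean(abs(gibbs@details$uk[[1L]] - gibbs2@details$uk[[1L]]) <=
    3 * comb + 0.01 * sd(y))
  expect_gt(frac, 0.95)
})

test_that("a constant response drives the genetic variance to its floor", {
  n <- 30L
  y <- setNames(rep(4, n), sprintf("L%d", seq_len(n)))
  Xf <- cbind(intercept = rep(1, n))
  fit <- solveBayesGibbs(y, Xf, list(g = list(Z = diag(n), K = diag(n))),
    ChainConfig(nIter = 2000L, burnIn = 500L, seed = 38L))
  expect_lt(max(abs(fit@fitted - 4)), 0.05)
  expect_lt(fit@varComp[["g"]], 1e-4)
})

test_that("fixed-design construction removes the fixed SNPs from the marker set", {
  G <- randomGeno(30L, 20L, seed = 40L)
  ids <- markerIDs(G)[c(3, 7, 11, 15)]
  fd <- buildFixedDesign(G, ids)
  expect_equal(ncol(fd$Xf), 5L)
  expect_equal(ncol(genotypeCodes(fd$reduced)), 16L)
  expect_false(any(ids %in% markerIDs(fd$reduced)))
  expect_equal(fd$Xf[, 1L], setNames(rep(1, 30), familyIDs(G)),
    ignore_attr = TRUE)
  expect_error(buildFixedDesign(G, rep(ids[1], 2)), "duplicate")
  expect_error(buildFixedDesign(G, "chr9_99"), "unknown")
  ## empty list: intercept-only covariates, marker set unchanged
  fd0 <- buildFixedDesign(G, character())
  expect_equal(ncol(fd0$Xf), 1L)
  expect_identical(markerIDs(fd0$reduced), markerIDs(G))
})

test_that("GXE interaction components vanish when environments are identical", {
  set <- simTrainingSet(nLines = 100L, markersPerChrom = 10L, gxeSd = 0,
    targetH2 = 0.85, seed = 50L, nEnvs = 2L)
  ## duplicate one environment's family means exactly
  r <- phenoRecords(set$pheno)
  r <- r[r$env == "E1", ]
  r2 <- r; r2$env <- "E2"
  phDup <- PhenotypeTable(rbind(r, r2))
  spec <- GsModelSpec("GXE", environments = c("E1", "E2"))
  fit <- fitEnvironmentModel(spec, phDup, set$G,
    ChainConfig(nIter = 3000L, burnIn = 1000L, seed = 51L))
  vc <- fit@varComp
  expect_lt(vc[["sigmaU12"]], 0.15 * vc[["sigmaU02"]])
  expect_lt(vc[["sigmaU22"]], 0.15 * vc[["sigmaU02"]])
  ## AE fit on the same data predicts nearly the same values
  fitAE <- fitEnvironmentModel(GsModelSpec("AE",
    environments = c("E1", "E2")), phDup, set$G,
    ChainConfig(nIter = 3000L, burnIn = 1000L, seed = 52L))
  expect_gt(cor(fit@fitted, fitAE@fitted), 0.98)
})

test_that("fitting planted large-effect SNPs as fixed reduces the genetic variance", {
  set <- simTrainingSet(nLines = 120L, markersPerChrom = 12L,
    qtlEffects = c(1.5, 1.2), gxeSd = 0.1, targetH2 = 0.8, seed = 60L)
  spec0 <- GsModelSpec("SE", environments = "E1")
  specF <- GsModelSpec("SE", fixedSnps = set$qtlIDs, environments = "E1")
  fit0 <- fitEnvironmentModel(spec0, set$pheno, set$G, solver = "reml")
  fitF <- fitEnvironmentModel(specF, set$pheno, set$G, solver = "reml")
  expect_lt(fitF@varComp[["sigmaU2"]], fit0@varComp[["sigmaU2"]])
})

test_that("predictions are invariant to marker order and to monomorphic markers", {
  G <- imputeMissing(randomGeno(40L, 60L, seed = 70L))
  y <- withr::with_seed(71L, setNames(
    drop(genotypeCodes(G) %*% rnorm(60, 0, 0.2)) + rnorm(40, 0, 0.4),
    familyIDs(G)))
  Xf <- cbind(intercept = rep(1, 40))
  f1 <- solveGblupReml(y, Xf, kinship(vanRadenKinship(G)))
  perm <- withr::with_seed(72L, sample(60L))
  f2 <- solveGblupReml(y, Xf, kinship(vanRadenKinship(
    subsetGenotypes(G, j = perm))))
  expect_equal(f1@fitted, f2@fitted, tolerance = 1e-6)
  ## a monomorphic marker does not change the kinship (it adds zero to W
  ## and zero to the denominator) and is rejected when it is all there is
  codes <- cbind(genotypeCodes(G), chr9_5 = rep(1, 40))
  f3 <- solveGblupReml(y, Xf,
    kinship(vanRadenKinship(GenotypeMatrix(codes, imputed = TRUE))))
  expect_equal(f1@fitted, f3@fitted, tolerance = 1e-6)
})
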
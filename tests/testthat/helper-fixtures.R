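## Shared fixture builders. Everything is generated in code; no stored data.

## small genome map: nChrom chromosomes, m markers each
tinyMap <- function(nChrom = 2L, m = 20L, lengthM = 1.8, lengthBp = 1e7) {
  defaultGenomeMap(nChrom = nChrom, lengthM = lengthM, lengthBp = lengthBp,
    markersPerChrom = m)
}

## crossing scheme small enough for fast tests (bulk size must stay >= 10)
smallScheme <- function(nBc1f3 = 100L, nFam = 12L, nSelf = 2L) {
  CrossingScheme(nBc1f2Families = nFam, nSelfedPerFamily = nSelf,
    nBc1f3 = nBc1f3, pollenBulkSize = 10L)
}

## iid genotype matrix with BC1F3 class frequencies (no linkage; fast)
randomGeno <- function(n, m, seed = 1L, probs = c(0.65625, 0.1875, 0.15625)) {
  withr::with_seed(seed, {
    codes <- matrix(sample(c(1, 0, -1), n * m, replace = TRUE, prob = probs),
      n, m)
    rownames(codes) <- sprintf("L%03d", seq_len(n))
    colnames(codes) <- sprintf("chr%d_%d", rep(1:10, length.out = m),
      10000L + seq_len(m))
    GenotypeMatrix(codes)
  })
}

## pedigree-simulated population plus an additive trait and its BLUEs
simTrainingSet <- function(nLines = 120L, markersPerChrom = 20L,
                           qtlEffects = c(1.2, 0.8), gxeSd = 0.2,
                           targetH2 = 0.7, seed = 11L, nEnvs = 4L,
                           nReps = 2L) {
  map <- tinyMap(nChrom = 10L, m = markersPerChrom)
  G <- simulateCross(map, smallScheme(nBc1f3 = nLines), seed = seed)
  nm <- ncol(genotypeCodes(G))
  qtlIdx <- withr::with_seed(seed + 1L,
    sample(seq_len(nm), length(qtlEffects)))
  arch <- TraitArchitecture(
    qtl = data.frame(marker = qtlIdx, effect = qtlEffects),
    envMeans = setNames(70 + seq_len(nEnvs), sprintf("E%d", seq_len(nEnvs))),
    gxeSd = gxeSd, repSd = 0.2, targetH2 = targetH2)
  pheno <- simulateTrait(G, arch, nEnvs = nEnvs, nReps = nReps,
    seed = seed + 2L)
  Gi <- imputeMissing(G)
  blueFit <- fitBlueModel(pheno)
  list(G = Gi, pheno = pheno, blue = blueFit, qtlIdx = qtlIdx,
    qtlIDs = markerIDs(G)[qtlIdx], arch = arch, map = map)
}

## balanced multi-environment phenotype data with known variance components
balancedPheno <- function(nFam = 100L, nEnv = 4L, nRep = 2L, sigmaG2 = 4,
                          sigmaGE2 = 1, sigmaRep2 = 0.25, sigmaE2 = 1,
                          mu = 50, seed = 5L) {
  withr::with_seed(seed, {
    g <- rnorm(nFam, 0, sqrt(sigmaG2))
    e <- rnorm(nEnv, 0, 1)
    ge <- matrix(rnorm(nFam * nEnv, 0, sqrt(sigmaGE2)), nFam, nEnv)
    rp <- matrix(rnorm(nEnv * nRep, 0, sqrt(sigmaRep2)), nEnv, nRep)
    rec <- expand.grid(i = seq_len(nFam), j = seq_len(nEnv),
      m = seq_len(nRep))
    rec$value <- mu + g[rec$i] + e[rec$j] + ge[cbind(rec$i, rec$j)] +
      rp[cbind(rec$j, rec$m)] + rnorm(nrow(rec), 0, sqrt(sigmaE2))
    PhenotypeTable(data.frame(family = sprintf("F%03d", rec$i),
      env = sprintf("E%d", rec$j), rep = as.character(rec$m),
      value = rec$value))
  })
}

## method-of-moments variance components from balanced-data mean squares,
## the expected-mean-squares oracle for REML on balanced designs
emsComponents <- function(pheno) {
  r <- phenoRecords(pheno)
  nFam <- length(unique(r$family)); nEnv <- length(unique(r$env))
  nRep <- length(unique(r$rep))
  ybar <- mean(r$value)
  mFam <- tapply(r$value, r$family, mean)
  mEnv <- tapply(r$value, r$env, mean)
  mFE <- tapply(r$value, list(r$family, r$env), mean)
  mER <- tapply(r$value, list(r$env, r$rep), mean)
  msFam <- nRep * nEnv * sum((mFam - ybar)^2) / (nFam - 1)
  ge <- sweep(sweep(mFE, 1, mFam), 2, mEnv) + ybar
  msGE <- nRep * sum(ge^2) / ((nFam - 1) * (nEnv - 1))
  er <- sweep(mER, 1, mEnv)
  msRep <- nFam * sum(er^2) / (nEnv * (nRep - 1))
  fit <- r$value - mFE[cbind(r$family, r$env)] - mER[cbind(r$env, r$rep)] +
    mEnv[r$env]
  msErr <- sum(fit^2) / ((nFam - 1) * nEnv * (nRep - 1))
  c(sigmaG2 = (msFam - msGE) / (nRep * nEnv),
    sigmaGE2 = (msGE - msErr) / nRep,
    sigmaRep2 = (msRep - msErr) / nFam,
    sigmaE2 = msErr)
}

## brute-force VanRaden K, coded independently of the package internals
bruteKinship <- function(M) {
  p <- colMeans(M + 1) / 2
  P <- matrix(2 * (p - 0.5), nrow(M), ncol(M), byrow = TRUE)
  W <- M - P
  (W %*% t(W)) / (2 * sum(p * (1 - p)))
}
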
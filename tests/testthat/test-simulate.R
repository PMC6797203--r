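test_that("zero genetic length gives non-recombinant chromosomes", {
  map <- tinyMap(nChrom = 1L, m = 15L, lengthM = 0)
  G <- simulateCross(map, smallScheme(nBc1f3 = 60L), seed = 3L)
  codes <- genotypeCodes(G)
  perPlantClasses <- apply(codes, 1L, function(r) length(unique(r)))
  expect_true(all(perPlantClasses == 1L))
  expect_true(all(codes %in% c(-1, 0, 1)))
})

test_that("BC1F3 genotype-class proportions match the pedigree expectation", {
  ## Mendelian brute force over the pedigree: donor allele frequency 1/4 in
  ## BC1F1 gametes, random union at the intermating step (classes
  ## 9/16, 6/16, 1/16), one selfing halves heterozygosity ->
  ## (recurrent, het, donor) = (0.65625, 0.1875, 0.15625)
  map <- tinyMap(nChrom = 10L, m = 30L)
  G <- simulateCross(map, CrossingScheme(), seed = 42L)
  expect_equal(nrow(genotypeCodes(G)), 481L)
  cm <- genotypeComposition(G)$mean
  expect_lt(abs(cm["recurrent"] - 0.65625), 0.03)
  expect_lt(abs(cm["het"] - 0.1875), 0.02)
  expect_lt(abs(cm["donor"] - 0.15625), 0.02)
  ## the observed field-population values fall inside the same band
  expect_lt(abs(cm["recurrent"] - 0.654), 0.035)
  expect_lt(abs(cm["het"] - 0.186), 0.025)
  expect_lt(abs(cm["donor"] - 0.160), 0.025)
})

test_that("class proportions pass a chi-square GOF at large n and het halves per selfing", {
  ## large population, many independent families: counts at one marker per
  ## chromosome against the (10.5, 3, 2.5)/16 expectation
  map <- tinyMap(nChrom = 10L, m = 2L)
  scheme <- CrossingScheme(nBc1f2Families = 2500L, nSelfedPerFamily = 2L,
    nBc1f3 = 10000L, pollenBulkSize = 10L)
  G <- simulateCross(map, scheme, seed = 9L)
  codes <- genotypeCodes(G)[, seq(1, 20, by = 2)]  # first marker per chrom
  obs <- c(sum(codes == 1), sum(codes == 0), sum(codes == -1))
  gof <- suppressWarnings(stats::chisq.test(obs,
    p = c(10.5, 3, 2.5) / 16))
  expect_gt(gof$p.value, 0.01)
  ## heterozygosity: BC1F2 expectation 6/16; one selfing halves it
  expect_lt(abs(mean(codes == 0) - 0.5 * 6 / 16), 3 * 0.005)
})

test_that("adjacent-marker genotype correlation decays with genetic distance", {
  map <- tinyMap(nChrom = 1L, m = 40L, lengthM = 1.8)
  G <- simulateCross(map, CrossingScheme(nBc1f2Families = 40L,
    nBc1f3 = 400L), seed = 17L)
  codes <- genotypeCodes(G)
  corNear <- mean(sapply(1:30, function(j) cor(codes[, j], codes[, j + 1])))
  corFar <- mean(sapply(1:10, function(j) cor(codes[, j], codes[, j + 30])))
  expect_gt(corNear, corFar)
  expect_gt(corNear, 0.8)
  ## identical position (distance 0) is the self-correlation limit
  expect_equal(cor(codes[, 1], codes[, 1]), 1)
})

test_that("simulateCross is deterministic in the seed and validates the map", {
  map <- tinyMap(nChrom = 2L, m = 10L)
  g1 <- simulateCross(map, smallScheme(nBc1f3 = 40L), seed = 5L)
  g2 <- simulateCross(map, smallScheme(nBc1f3 = 40L), seed = 5L)
  g3 <- simulateCross(map, smallScheme(nBc1f3 = 40L), seed = 6L)
  expect_identical(genotypeCodes(g1), genotypeCodes(g2))
  expect_false(identical(genotypeCodes(g1), genotypeCodes(g3)))
  expect_error(GenomeMap(data.frame(id = "1", lengthM = 1, lengthBp = 1e6),
    list("1" = numeric(0))), "no markers")
})

test_that("genotypeComposition counts classes row-wise over observed markers", {
  codes <- rbind(L1 = c(1, 1, 1, 1), L2 = c(-1, 0, 1, 1))
  colnames(codes) <- sprintf("chr1_%d", 1:4)
  G <- GenotypeMatrix(codes)
  comp <- genotypeComposition(G)$perPlant
  expect_equal(unname(comp["L1", ]), c(1, 0, 0))
  expect_equal(unname(comp["L2", ]), c(0.5, 0.25, 0.25))
  ## proportions over non-missing markers sum to 1 even with missing calls
  codes[1, 2] <- NA
  compNA <- genotypeComposition(GenotypeMatrix(codes))$perPlant
  expect_equal(unname(rowSums(compNA)), c(1, 1))
})

test_that("injectMissingness hits the target rate and keeps rate 0 exact", {
  G <- randomGeno(100L, 100L, seed = 2L)
  expect_identical(genotypeCodes(injectMissingness(G, 0)), genotypeCodes(G))
  Gm <- injectMissingness(G, 0.5, seed = 8L)
  frac <- mean(is.na(genotypeCodes(Gm)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_error(injectMissingness(G, 1), "rate")
  ## determinism
  expect_identical(genotypeCodes(injectMissingness(G, 0.3, seed = 4L)),
    genotypeCodes(injectMissingness(G, 0.3, seed = 4L)))
})

test_that("simulateTrait degenerates to environment means without noise", {
  G <- randomGeno(20L, 10L, seed = 3L)
  arch <- TraitArchitecture(qtl = data.frame(marker = 1L, effect = 0),
    envMeans = c(A = 10, B = 20), gxeSd = 0, repSd = 0, residSd = 0)
  ph <- simulateTrait(G, arch, nEnvs = 2L, nReps = 2L, seed = 1L)
  r <- phenoRecords(ph)
  expect_equal(r$value, ifelse(r$env == "A", 10, 20))
  expect_error(simulateTrait(G, TraitArchitecture(
    qtl = data.frame(marker = 99L, effect = 1), envMeans = c(A = 0)),
    nEnvs = 1L, seed = 1L), "out of range")
})

test_that("trait simulation recovers its own variance components", {
  ## REML decomposition of simulated data returns the planted components
  ## (20% relative band at 200 families x 4 envs x 2 reps)
  G <- randomGeno(200L, 60L, seed = 21L)
  qtlIdx <- 1:8
  effects <- rep(c(0.7, -0.5), 4)
  arch <- TraitArchitecture(
    qtl = data.frame(marker = qtlIdx, effect = effects),
    envMeans = c(E1 = 70, E2 = 71, E3 = 66, E4 = 69),
    gxeSd = 0.3, repSd = 0.2, residSd = 1)
  ph <- simulateTrait(G, arch, nEnvs = 4L, nReps = 2L, seed = 31L)
  vc <- varianceComponents(estimateVarianceComponents(ph))
  ## noise-free twin (same seed, same QTL deviation draws) gives the
  ## realized genetic and interaction surfaces exactly
  arch0 <- TraitArchitecture(qtl = arch@qtl, envMeans = arch@envMeans,
    gxeSd = 0.3, repSd = 0, residSd = 0)
  y0 <- phenoRecords(simulateTrait(G, arch0, nEnvs = 4L, nReps = 1L,
    seed = 31L))
  surf <- tapply(y0$value, list(y0$family, y0$env), mean)
  plantedVg <- var(rowMeans(surf))
  inter <- sweep(sweep(surf, 1, rowMeans(surf)), 2, colMeans(surf)) +
    mean(surf)
  plantedVge <- sum(inter^2) / ((nrow(surf) - 1) * (ncol(surf) - 1))
  expect_lt(abs(vc["sigmaG2"] - plantedVg) / plantedVg, 0.2)
  expect_lt(abs(vc["sigmaE2"] - 1) / 1, 0.2)
  expect_lt(abs(vc["sigmaGE2"] - plantedVge) / plantedVge, 0.35)
})

test_that("targetH2 calibration lands near the requested heritability", {
  G <- randomGeno(200L, 60L, seed = 22L)
  arch <- TraitArchitecture(
    qtl = data.frame(marker = 1:6, effect = c(1, 0.8, 0.6, -0.7, 0.5, 0.4)),
    envMeans = c(E1 = 70, E2 = 71, E3 = 66, E4 = 69),
    gxeSd = 0.15, repSd = 0.2, targetH2 = 0.64)
  ph <- simulateTrait(G, arch, nEnvs = 4L, nReps = 2L, seed = 33L)
  vc <- estimateVarianceComponents(ph)
  h2 <- broadSenseHeritability(vc, Ne = 4L, r = 2L)
  expect_lt(abs(h2 - 0.64), 0.05)
})
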
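## Run configuration (YAML) and the end-to-end pipeline:
## phenotype summary -> BLUEs/H2 -> QC/imputation -> kinship -> GWAS ->
## top-SNP PVE -> fixed-SNP choice -> single- and multi-environment CV.

runConfigDefaults <- function() list(
  phenotypes = NULL, genotypes = NULL,
  simulate = FALSE, nLines = 200L, markersPerChrom = 50L, nChrom = 10L,
  trait = "trait",
  environments = NULL, envPair = NULL,
  maxMissing = 0.05,
  topSnps = 50L, maxFixedSnps = 4L, chooseFixed = FALSE,
  fixedSnps = NULL,
  model = "GXE", cvScheme = "CV2", folds = 5L, repeats = 10L,
  chainIter = 1500L, chainBurnIn = 500L, chainThin = 5L,
  seed = 1L, outDir = "gsfix_out")

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; referenced files must exist.
#'
#' @param path YAML file.
#' @return Named list of settings merged over the defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- runConfigDefaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defs
  out[names(cfg)] <- cfg
  for (key in c("phenotypes", "genotypes")) {
    if (!is.null(out[[key]]) && !file.exists(out[[key]]))
      stop(sprintf("config %s: file not found: %s", key, out[[key]]))
  }
  if (!is.numeric(out$seed) || out$seed != round(out$seed))
    stop("seed must be an integer")
  out
}

logStage <- function(log, stage, t0, ...) {
  entry <- c(list(stage = stage, seconds = round(as.numeric(
    difftime(Sys.time(), t0, units = "secs")), 2)), list(...))
  c(log, list(entry))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writes per-stage artifacts (CSV/TSV) and a
#' JSON summary to the output directory, and logs stage timings and every
#' seed. With \code{simulate = TRUE} (or no input files) the data are
#' generated by the built-in breeding-scheme and trait simulators.
#'
#' @param config a list from \code{\link{readRunConfig}}, or a path to a
#'   YAML file.
#' @return Invisibly, a list with the main stage results and the summary.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- runConfigDefaults()
  cfg[names(config)] <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  t0 <- Sys.time()
  seed <- as.integer(cfg$seed)

  ## stage: data
  if (cfg$simulate || is.null(cfg$genotypes)) {
    map <- defaultGenomeMap(nChrom = cfg$nChrom,
      markersPerChrom = cfg$markersPerChrom)
    scheme <- CrossingScheme(nBc1f3 = cfg$nLines,
      nBc1f2Families = max(12L, round(cfg$nLines / 11)))
    G <- simulateCross(map, scheme, seed = deriveSeed(seed, 1L))
    nm <- ncol(genotypeCodes(G))
    qtlIdx <- withSeed(deriveSeed(seed, 2L), sample(nm, 4L))
    arch <- TraitArchitecture(
      qtl = data.frame(marker = qtlIdx, effect = c(1.2, 0.9, 0.7, 0.6)),
      envMeans = c(E1 = 73, E2 = 72.7, E3 = 63.6, E4 = 70.1),
      gxeSd = 0.25, repSd = 0.3, targetH2 = 0.64)
    pheno <- simulateTrait(G, arch, nEnvs = 4L, nReps = 2L,
      seed = deriveSeed(seed, 3L))
    writeGenotypes(G, file.path(cfg$outDir, "genotypes.tsv"))
    writePhenotypes(pheno, file.path(cfg$outDir, "phenotypes.csv"))
  } else {
    G <- readGenotypes(cfg$genotypes)
    pheno <- readPhenotypes(cfg$phenotypes)
  }
  log <- logStage(log, "data", t0, seed = seed,
    nLines = nrow(genotypeCodes(G)), nMarkers = ncol(genotypeCodes(G)))

  ## stage: phenotype summary + BLUEs + H2
  t0 <- Sys.time()
  summ <- summarizePhenotypes(pheno)
  blueFit <- fitBlueModel(pheno)
  vc <- estimateVarianceComponents(pheno)
  ne <- length(unique(phenoRecords(pheno)$env))
  nr <- length(unique(phenoRecords(pheno)$rep))
  h2 <- broadSenseHeritability(vc, Ne = ne, r = nr)
  write.csv(summ, file.path(cfg$outDir, "phenotype_summary.csv"),
    row.names = FALSE)
  write.csv(data.frame(family = names(blues(blueFit)),
    blue = unname(blues(blueFit))),
    file.path(cfg$outDir, "blues.csv"), row.names = FALSE)
  log <- logStage(log, "blue", t0, h2 = h2)

  ## stage: QC + imputation + kinship
  t0 <- Sys.time()
  nmIn <- ncol(genotypeCodes(G))
  parents <- rbind(rep(1, nmIn), rep(-1, nmIn))  # fully polymorphic parents
  Gf <- filterMarkers(G, parents, maxMissing = cfg$maxMissing)
  Gi <- imputeMissing(Gf)
  K <- vanRadenKinship(Gi)
  log <- logStage(log, "qc", t0, markersIn = nmIn,
    markersOut = ncol(genotypeCodes(Gi)))

  ## stage: GWAS + PVE
  t0 <- Sys.time()
  scan <- gwasScan(blueFit, Gi, K)
  nTop <- min(cfg$topSnps, ncol(genotypeCodes(Gi)) - 1L,
    length(blues(blueFit)) - 2L)
  top <- selectTopSnps(scan, n = nTop)
  pve <- pveMultipleRegression(blueFit, Gi, top)
  write.table(resultTable(scan), file.path(cfg$outDir, "gwas.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(resultTable(pve), file.path(cfg$outDir, "pve.csv"),
    row.names = FALSE)
  log <- logStage(log, "gwas", t0, topSnp = top[1L])

  ## stage: fixed-SNP choice (optional) + single-environment CV
  t0 <- Sys.time()
  scheme1 <- CvScheme("SINGLE", k = cfg$folds, nRepeats = cfg$repeats,
    seed = deriveSeed(seed, 4L))
  if (isTRUE(cfg$chooseFixed)) {
    sel <- chooseNFixedSnps(blueFit, Gi, top, maxN = cfg$maxFixedSnps,
      scheme = scheme1)
    fixedSnps <- head(top, sel$nStar)
    write.csv(sel$tTable, file.path(cfg$outDir, "fixed_snp_ttests.csv"),
      row.names = FALSE)
  } else if (!is.null(cfg$fixedSnps)) {
    fixedSnps <- cfg$fixedSnps
  } else {
    fixedSnps <- head(top, cfg$maxFixedSnps)
  }
  cvBase <- runCvSingle(blueFit, Gi, character(), scheme1)
  cvFixed <- runCvSingle(blueFit, Gi, fixedSnps, scheme1)
  log <- logStage(log, "cv_single", t0, cvSeed = scheme1@seed,
    paNoFixed = meanPa(cvBase), paFixed = meanPa(cvFixed),
    nFixed = length(fixedSnps))

  ## stage: multi-environment CV on one environment pair
  t0 <- Sys.time()
  envs <- sort(unique(phenoRecords(pheno)$env))
  pair <- if (!is.null(cfg$envPair)) cfg$envPair else envs[1:2]
  chain <- ChainConfig(nIter = cfg$chainIter, burnIn = cfg$chainBurnIn,
    thin = cfg$chainThin, seed = deriveSeed(seed, 5L))
  schemeM <- CvScheme(cfg$cvScheme, k = cfg$folds,
    nRepeats = max(1L, cfg$repeats %/% 5L), seed = deriveSeed(seed, 6L))
  cvMulti <- runCvMulti(pheno, Gi, modelType = cfg$model,
    fixedSnps = fixedSnps, scheme = schemeM, environments = pair,
    chain = chain)
  write.csv(paTable(cvMulti), file.path(cfg$outDir, "cv_multi.csv"),
    row.names = FALSE)
  log <- logStage(log, "cv_multi", t0, pair = paste(pair, collapse = "_"),
    meanPa = meanPa(cvMulti))

  summary <- list(
    phenotypeSummary = summ,
    heritability = h2,
    varianceComponents = as.list(varianceComponents(vc)),
    topSnps = top,
    pve = resultTable(pve),
    fixedSnps = fixedSnps,
    paSingle = list(noFixed = meanPa(cvBase), fixed = meanPa(cvFixed)),
    paMulti = as.list(meanPa(cvMulti, by = "env")),
    stages = log,
    config = cfg)
  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
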
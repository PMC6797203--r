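## Constructors and accessors. Slot access outside the package should go
## through these.

#' Construct a genome map
#'
#' @param chromosomes data.frame with columns id, lengthM, lengthBp.
#' @param markers named list of marker bp positions per chromosome.
#' @return A \linkS4class{GenomeMap}.
#' @export
GenomeMap <- function(chromosomes, markers) {
  chromosomes$id <- as.character(chromosomes$id)
  new("GenomeMap", chromosomes = chromosomes,
    markers = markers[chromosomes$id])
}

#' Default genome map for the simulator
#'
#' Ten chromosomes of equal genetic and physical length with evenly spaced
#' markers, the desk-scale stand-in for a dense maize SNP map.
#'
#' @param nChrom number of chromosomes.
#' @param lengthM genetic length per chromosome (Morgans).
#' @param lengthBp physical length per chromosome (bp).
#' @param markersPerChrom markers per chromosome, evenly spaced.
#' @return A \linkS4class{GenomeMap}.
#' @export
defaultGenomeMap <- function(nChrom = 10L, lengthM = 1.8, lengthBp = 2e8,
                             markersPerChrom = 100L) {
  ids <- as.character(seq_len(nChrom))
  pos <- round(seq(lengthBp / (markersPerChrom + 1), lengthBp,
    length.out = markersPerChrom))
  GenomeMap(
    data.frame(id = ids, lengthM = lengthM, lengthBp = lengthBp),
    setNames(rep(list(pos), nChrom), ids))
}

#' Construct a crossing scheme
#'
#' Defaults mirror the study population: 43 bulk-BC1F2 families, 3 selfed
#' plants per family, 481 genotyped BC1F3 plants, pollen bulks of >= 10
#' BC1F1 plants.
#'
#' @param recurrent,donor parent labels.
#' @param nBc1f2Families,nSelfedPerFamily,nBc1f3,pollenBulkSize scheme sizes.
#' @return A \linkS4class{CrossingScheme}.
#' @export
CrossingScheme <- function(recurrent = "PH4CV", donor = "Zheng58",
                           nBc1f2Families = 43L, nSelfedPerFamily = 3L,
                           nBc1f3 = 481L, pollenBulkSize = 10L) {
  new("CrossingScheme", recurrent = recurrent, donor = donor,
    nBc1f2Families = as.integer(nBc1f2Families),
    nSelfedPerFamily = as.integer(nSelfedPerFamily),
    nBc1f3 = as.integer(nBc1f3),
    pollenBulkSize = as.integer(pollenBulkSize))
}

#' Construct a trait architecture
#'
#' @param qtl data.frame with columns marker (index) and effect.
#' @param envMeans named per-environment intercepts.
#' @param gxeSd per-QTL sd of environment-specific effect deviations.
#' @param repSd replicate-effect sd.
#' @param residSd residual sd (overridden when targetH2 is set).
#' @param targetH2 optional entry-mean heritability to calibrate residSd to.
#' @return A \linkS4class{TraitArchitecture}.
#' @export
TraitArchitecture <- function(qtl, envMeans, gxeSd = 0, repSd = 0,
                              residSd = 1, targetH2 = NA_real_) {
  new("TraitArchitecture", qtl = qtl, envMeans = envMeans,
    gxeSd = as.numeric(gxeSd), repSd = as.numeric(repSd),
    residSd = as.numeric(residSd), targetH2 = as.numeric(targetH2))
}

#' Construct a genotype matrix
#'
#' @param codes numeric matrix with family rownames and "chrN_pos" marker
#'   colnames; entries -1/0/1/NA (or fractional when \code{imputed}).
#' @param family optional BC1F2 family label per row.
#' @param imputed whether the codes are imputation output.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(codes, family = rep("", nrow(codes)),
                           imputed = FALSE) {
  new("GenotypeMatrix", codes = codes,
    markers = parseMarkerIDs(colnames(codes)),
    family = family, imputed = imputed)
}

#' Parse "chrN_pos" marker identifiers
#'
#' @param ids character vector of marker IDs.
#' @return data.frame (rownames = ids) with columns chr and pos (1-based bp).
#' @export
parseMarkerIDs <- function(ids) {
  m <- regmatches(ids, regexec("^[Cc]hr([0-9A-Za-z]+)_([0-9]+)$", ids))
  bad <- lengths(m) != 3
  if (any(bad))
    stop("malformed marker ID(s): ", paste(head(ids[bad], 5), collapse = ", "))
  out <- data.frame(
    chr = vapply(m, `[`, "", 2L),
    pos = as.numeric(vapply(m, `[`, "", 3L)),
    row.names = ids, stringsAsFactors = FALSE)
  out
}

#' Construct a phenotype table
#'
#' @param records data.frame with columns family, env, rep, value.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
PhenotypeTable <- function(records) {
  records$family <- as.character(records$family)
  records$env <- as.character(records$env)
  records$rep <- as.character(records$rep)
  records$value <- as.numeric(records$value)
  new("PhenotypeTable", records = records[, c("family", "env", "rep", "value")])
}

#' Construct Gibbs chain settings
#'
#' Defaults follow the full-fidelity runs (20000 iterations, 5000 burn-in);
#' cross-validation at desk scale typically shortens the chain.
#'
#' @param nIter,burnIn,thin,seed chain settings.
#' @param priorDf,r2 scaled-inverse-chi-squared prior df and the share of
#'   response variance placed, at the prior mode, on the genetic kernels.
#' @return A \linkS4class{ChainConfig}.
#' @export
ChainConfig <- function(nIter = 20000L, burnIn = 5000L, thin = 5L,
                        seed = 1L, priorDf = 5, r2 = 0.5) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
    thin = as.integer(thin), seed = as.integer(seed),
    priorDf = as.numeric(priorDf), r2 = as.numeric(r2))
}

#' Construct a GS model specification
#'
#' @param modelType "SE", "AE" or "GXE".
#' @param fixedSnps marker IDs fitted as fixed effects.
#' @param environments environment labels.
#' @return A \linkS4class{GsModelSpec}.
#' @export
GsModelSpec <- function(modelType, fixedSnps = character(),
                        environments = character()) {
  new("GsModelSpec", modelType = modelType, fixedSnps = fixedSnps,
    environments = environments)
}

#' Construct a cross-validation scheme
#'
#' @param kind "SINGLE", "CV1" or "CV2".
#' @param k number of folds.
#' @param nRepeats number of repeats.
#' @param seed master seed.
#' @return A \linkS4class{CvScheme}.
#' @export
CvScheme <- function(kind = "SINGLE", k = 5L, nRepeats = 100L, seed = 1L) {
  new("CvScheme", kind = kind, k = as.integer(k),
    nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

## ---- accessors ----

#' Genotype codes matrix
#' @param x a GenotypeMatrix.
#' @return numeric matrix of codes.
#' @export
genotypeCodes <- function(x) x@codes

#' Family IDs of a genotype matrix or phenotype table
#' @param x a GenotypeMatrix or PhenotypeTable.
#' @return character vector of family IDs.
#' @export
familyIDs <- function(x) {
  if (is(x, "GenotypeMatrix")) rownames(x@codes)
  else if (is(x, "PhenotypeTable")) unique(x@records$family)
  else stop("no familyIDs method for ", class(x))
}

#' Marker IDs
#' @param x a GenotypeMatrix or KinshipMatrix.
#' @return character vector of marker IDs.
#' @export
markerIDs <- function(x) {
  if (is(x, "GenotypeMatrix")) colnames(x@codes)
  else if (is(x, "KinshipMatrix")) x@markerIDs
  else stop("no markerIDs method for ", class(x))
}

#' Marker chromosome/position table
#' @param x a GenotypeMatrix.
#' @return data.frame with columns chr, pos.
#' @export
markerInfo <- function(x) x@markers

#' Phenotype records
#' @param x a PhenotypeTable.
#' @return long-format data.frame.
#' @export
phenoRecords <- function(x) x@records

#' Relationship matrix values
#' @param x a KinshipMatrix.
#' @return numeric matrix K.
#' @export
kinship <- function(x) x@K

#' Marker centering offsets 2(p - 0.5) of a kinship matrix
#' @param x a KinshipMatrix.
#' @return numeric vector, one offset per marker.
#' @export
centeringOffsets <- function(x) 2 * (x@p - 0.5)

#' BLUEs per family
#' @param x a BlueResult.
#' @return named numeric vector.
#' @export
blues <- function(x) x@blues

#' GWAS result table
#' @param x a GwasResult or PveTable.
#' @return data.frame of per-marker statistics.
#' @export
resultTable <- function(x) x@table

#' Variance components as a named vector
#' @param x a VarianceComponents or GsFit.
#' @return named numeric vector.
#' @export
varianceComponents <- function(x) {
  if (is(x, "VarianceComponents"))
    c(sigmaG2 = x@sigmaG2, sigmaGE2 = x@sigmaGE2,
      sigmaRep2 = x@sigmaRep2, sigmaE2 = x@sigmaE2)
  else if (is(x, "GsFit")) x@varComp
  else stop("no varianceComponents method for ", class(x))
}

#' Genetic values of a fitted GS model
#' @param x a GsFit.
#' @return named numeric vector of line genetic values (main effects).
#' @export
geneticValues <- function(x) x@u

#' Fixed-effect estimates of a fitted GS model
#' @param x a GsFit.
#' @return named numeric vector.
#' @export
fixedEffects <- function(x) x@beta

#' Per-repeat prediction accuracies
#' @param x a CvResult.
#' @return data.frame with columns repeat., env, pa.
#' @export
paTable <- function(x) x@pa

#' Mean prediction accuracy
#' @param x a CvResult.
#' @param by "overall" or "env".
#' @return numeric mean PA (named by environment when \code{by = "env"}).
#' @export
meanPa <- function(x, by = c("overall", "env")) {
  by <- match.arg(by)
  if (by == "overall") mean(x@pa$pa)
  else tapply(x@pa$pa, x@pa$env, mean)
}

#' Subset a genotype matrix
#'
#' @param x a GenotypeMatrix.
#' @param i family IDs or indices (default all).
#' @param j marker IDs or indices (default all).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
subsetGenotypes <- function(x, i = NULL, j = NULL) {
  m <- x@codes
  if (is.null(i)) i <- seq_len(nrow(m))
  if (is.null(j)) j <- seq_len(ncol(m))
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, colnames(m))
  if (anyNA(i) || anyNA(j)) stop("unknown family or marker ID in subset")
  new("GenotypeMatrix", codes = m[i, j, drop = FALSE],
    markers = x@markers[j, , drop = FALSE],
    family = x@family[i], imputed = x@imputed)
}

## seed derivation: one master integer spawns per-repeat / per-draw seeds by
## a fixed counter scheme, so any single repeat is re-runnable in isolation.

#' Derive a stream seed from a master seed
#'
#' Deterministic counter scheme: \code{(master * 48271 + stream) mod (2^31 - 1)},
#' mapped away from 0.
#'
#' @param master master integer seed.
#' @param stream stream counter (repeat or draw index).
#' @return integer seed.
#' @export
deriveSeed <- function(master, stream) {
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 + as.numeric(stream)
  s <- s %% 2147483647
  as.integer(s + (s == 0))
}

## evaluate code under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
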
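#' @import methods
#' @importFrom stats anova aov coef cor lm model.matrix na.omit optimize pf
#'   predict pt quantile rbinom rchisq rnorm rpois runif sd setNames t.test var
#' @importFrom utils read.table write.table write.csv head
NULL

## Central S4 containers. Genotypes are coded on the {-1, 0, +1} scale of a
## biparental backcross population: +1 = homozygous recurrent parent (PH4CV),
## 0 = heterozygote, -1 = homozygous donor parent (Zheng58). Missing = NA.

#' Genetic map of a simulated genome
#'
#' Chromosome lengths (genetic, in Morgans; physical, in bp) plus marker
#' positions (bp) per chromosome. Genetic positions of markers are obtained by
#' linear bp-to-cM interpolation along each chromosome.
#'
#' @slot chromosomes data.frame with columns \code{id}, \code{lengthM}
#'   (Morgans) and \code{lengthBp} (bp).
#' @slot markers named list (one element per chromosome id) of strictly
#'   increasing marker positions in bp.
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(chromosomes = "data.frame", markers = "list"))

setValidity("GenomeMap", function(object) {
  ch <- object@chromosomes
  if (!all(c("id", "lengthM", "lengthBp") %in% names(ch)))
    return("chromosomes needs columns id, lengthM, lengthBp")
  if (any(ch$lengthM < 0) || any(ch$lengthBp <= 0))
    return("chromosome lengths must be positive (genetic length may be 0)")
  if (!identical(sort(names(object@markers)), sort(as.character(ch$id))))
    return("markers list must be named by chromosome id")
  for (id in names(object@markers)) {
    pos <- object@markers[[id]]
    if (length(pos) < 1) return(sprintf("chromosome %s has no markers", id))
    if (any(diff(pos) <= 0))
      return(sprintf("marker positions on %s not strictly increasing", id))
    if (any(pos < 1) || any(pos > ch$lengthBp[ch$id == id]))
      return(sprintf("marker positions on %s outside [1, lengthBp]", id))
  }
  TRUE
})

#' Backcross-self crossing scheme
#'
#' Parameters of the breeding scheme: F1 (donor x recurrent) backcrossed to
#' the recurrent parent, BC1F1 plants intermated with bulked pollen to give
#' bulk-BC1F2 families, plants selfed once to produce the genotyped BC1F3
#' generation.
#'
#' @slot recurrent,donor parent labels.
#' @slot nBc1f2Families number of bulk-BC1F2 families (BC1F1 mother plants).
#' @slot nSelfedPerFamily BC1F2 plants selfed per family.
#' @slot nBc1f3 number of BC1F3 plants genotyped.
#' @slot pollenBulkSize number of BC1F1 plants contributing to each pollen
#'   bulk (mother excluded).
#' @exportClass CrossingScheme
setClass("CrossingScheme",
  representation(recurrent = "character", donor = "character",
    nBc1f2Families = "integer", nSelfedPerFamily = "integer",
    nBc1f3 = "integer", pollenBulkSize = "integer"))

setValidity("CrossingScheme", function(object) {
  counts <- c(object@nBc1f2Families, object@nSelfedPerFamily, object@nBc1f3,
    object@pollenBulkSize)
  if (any(counts < 1L)) return("all counts must be >= 1")
  if (object@pollenBulkSize < 10L)
    return("pollenBulkSize must be >= 10 (bulked pollen from at least ten plants)")
  if (object@pollenBulkSize >= object@nBc1f2Families)
    return("pollenBulkSize must be smaller than the number of BC1F1 plants minus the mother")
  TRUE
})

#' Additive trait architecture for the phenotype simulator
#'
#' @slot qtl data.frame with columns \code{marker} (marker index into the
#'   genotype matrix) and \code{effect} (additive effect in trait units per
#'   coded allele unit).
#' @slot envMeans per-environment intercepts (named numeric).
#' @slot gxeSd per-QTL standard deviation of environment-specific effect
#'   deviations (recycled to the number of QTL).
#' @slot repSd standard deviation of the replicate-within-environment effect.
#' @slot residSd residual standard deviation; ignored when \code{targetH2}
#'   is set.
#' @slot targetH2 optional entry-mean heritability target; when finite, the
#'   residual standard deviation is solved from the heritability formula
#'   given the realized genetic and interaction variances.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(qtl = "data.frame", envMeans = "numeric", gxeSd = "numeric",
    repSd = "numeric", residSd = "numeric", targetH2 = "numeric"))

setValidity("TraitArchitecture", function(object) {
  if (!all(c("marker", "effect") %in% names(object@qtl)))
    return("qtl needs columns marker, effect")
  if (any(c(object@gxeSd, object@repSd, object@residSd) < 0))
    return("standard deviations must be >= 0")
  h2 <- object@targetH2
  if (is.finite(h2) && (h2 <= 0 || h2 >= 1))
    return("targetH2 must lie in (0, 1)")
  TRUE
})

#' Families-by-markers genotype matrix
#'
#' @slot codes numeric matrix, rows = families/plants, columns = markers.
#'   Raw matrices contain -1/0/+1/NA; imputed matrices contain values in
#'   [-1, 1] with no NA.
#' @slot markers data.frame (rownames = marker IDs) with columns \code{chr}
#'   and \code{pos} (1-based bp), parsed from "chrN_pos" IDs.
#' @slot family BC1F2 family assignment per plant ("" when unknown).
#' @slot imputed logical, whether missing codes were replaced by expected
#'   values.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(codes = "matrix", markers = "data.frame",
    family = "character", imputed = "logical"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@codes
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("codes must have row (family) and column (marker) names")
  if (anyDuplicated(colnames(m))) return("marker IDs must be unique")
  if (anyDuplicated(rownames(m))) return("family IDs must be unique")
  if (nrow(object@markers) != ncol(m))
    return("markers table does not match number of columns")
  if (!identical(rownames(object@markers), colnames(m)))
    return("markers table rownames must equal marker IDs")
  if (length(object@family) != nrow(m))
    return("family vector must have one entry per row")
  vals <- m[!is.na(m)]
  if (object@imputed) {
    if (anyNA(m)) return("imputed matrix may not contain NA")
    if (length(vals) && (min(vals) < -1 || max(vals) > 1))
      return("imputed codes must lie in [-1, 1]")
  } else if (length(vals) && !all(vals %in% c(-1, 0, 1))) {
    return("non-missing codes must be -1, 0 or 1")
  }
  TRUE
})

#' Long-format multi-environment phenotype table
#'
#' @slot records data.frame with columns \code{family}, \code{env},
#'   \code{rep}, \code{value} (replicate nested in environment).
#' @exportClass PhenotypeTable
setClass("PhenotypeTable", representation(records = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  r <- object@records
  if (!all(c("family", "env", "rep", "value") %in% names(r)))
    return("records needs columns family, env, rep, value")
  if (!is.numeric(r$value)) return("value must be numeric")
  if (any(!is.finite(r$value))) return("values must be finite")
  key <- paste(r$family, r$env, r$rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key), , drop = FALSE][1, ]
    return(sprintf("duplicate (family, env, rep) key: (%s, %s, %s)",
      d$family, d$env, d$rep))
  }
  TRUE
})

#' VanRaden genomic relationship matrix
#'
#' K = WW' / (2 * sum_j p_j q_j), where W = M - P, P's j-th column is
#' 2(p_j - 0.5), and p_j is the frequency of the +1-coded allele.
#'
#' @slot K symmetric n x n relationship matrix.
#' @slot p per-marker frequency of the +1 allele.
#' @slot denom scaling denominator 2 * sum_j p_j q_j.
#' @slot markerIDs markers the matrix was computed from.
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(K = "matrix", p = "numeric", denom = "numeric",
    markerIDs = "character"))

setValidity("KinshipMatrix", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (max(abs(K - t(K))) > 1e-8) return("K must be symmetric")
  if (object@denom <= 0) return("denominator must be > 0")
  TRUE
})

#' Variance components of the multi-environment phenotype model
#'
#' @slot sigmaG2 genotype variance.
#' @slot sigmaGE2 genotype-by-environment variance.
#' @slot sigmaRep2 replicate-within-environment variance.
#' @slot sigmaE2 residual variance.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigmaG2 = "numeric", sigmaGE2 = "numeric",
    sigmaRep2 = "numeric", sigmaE2 = "numeric"))

setValidity("VarianceComponents", function(object) {
  if (any(c(object@sigmaG2, object@sigmaGE2, object@sigmaRep2,
    object@sigmaE2) < 0)) return("variance components must be >= 0")
  TRUE
})

#' Best linear unbiased estimates of family means
#'
#' @slot blues named numeric, one BLUE (mu + g_i) per family.
#' @slot mu overall mean.
#' @slot logLik restricted log-likelihood of the fit.
#' @slot dropped families removed as non-identifiable (no observations).
#' @exportClass BlueResult
setClass("BlueResult",
  representation(blues = "numeric", mu = "numeric", logLik = "numeric",
    dropped = "character"))

#' Mixed-model GWAS scan result
#'
#' @slot table data.frame with one row per tested marker: \code{marker},
#'   \code{chr}, \code{pos}, \code{effect}, \code{se}, \code{p},
#'   \code{neglog10p}.
#' @slot varU,varE background (null-model) variance components reused for
#'   every marker test (P3D).
#' @exportClass GwasResult
setClass("GwasResult",
  representation(table = "data.frame", varU = "numeric", varE = "numeric"))

#' Sequential sum-of-squares PVE decomposition
#'
#' @slot table data.frame: \code{marker}, \code{ssReg} (Type-I sequential
#'   SS in fit order), \code{pve} (fraction of the denominator).
#' @slot ssTol denominator sum of squares.
#' @slot denominator "total" (corrected total SS of the response) or
#'   "model" (regression SS of the full model).
#' @slot droppedAliased markers dropped for collinearity.
#' @exportClass PveTable
setClass("PveTable",
  representation(table = "data.frame", ssTol = "numeric",
    denominator = "character", droppedAliased = "character"))

#' Gibbs sampler chain settings
#'
#' @slot nIter total iterations (default 20000).
#' @slot burnIn discarded initial iterations (default 5000).
#' @slot thin thinning interval (default 5).
#' @slot seed RNG seed.
#' @slot priorDf degrees of freedom of the scaled-inverse-chi-squared
#'   variance priors.
#' @slot r2 proportion of response variance assigned, at the prior mode, to
#'   the genetic side (split equally over kernels); the rest to the residual.
#' @exportClass ChainConfig
setClass("ChainConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
    seed = "integer", priorDf = "numeric", r2 = "numeric"))

setValidity("ChainConfig", function(object) {
  if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@r2 <= 0 || object@r2 >= 1) return("r2 must lie in (0,1)")
  TRUE
})

#' Specification of a genomic-selection model
#'
#' @slot modelType "SE" (single environment), "AE" (across-environment, one
#'   shared marker-effect vector) or "GXE" (shared main effect plus
#'   environment-specific deviations).
#' @slot fixedSnps marker IDs fitted as fixed effects (possibly none).
#' @slot environments environment labels entering the model.
#' @exportClass GsModelSpec
setClass("GsModelSpec",
  representation(modelType = "character", fixedSnps = "character",
    environments = "character"))

setValidity("GsModelSpec", function(object) {
  if (!object@modelType %in% c("SE", "AE", "GXE"))
    return("modelType must be SE, AE or GXE")
  if (anyDuplicated(object@fixedSnps)) return("duplicate fixed SNP IDs")
  if (object@modelType != "SE" && length(object@environments) < 2)
    return("AE/GXE require >= 2 environments")
  if (object@modelType == "SE" && length(object@environments) != 1)
    return("SE requires exactly 1 environment")
  TRUE
})

#' Fitted genomic-selection model
#'
#' @slot beta named fixed-effect estimates (per-environment intercepts and
#'   fixed-SNP effects).
#' @slot u genetic values: main effects per line; for GXE fits the
#'   environment-specific deviations are in \code{details$uEnv}.
#' @slot varComp named variance components (>= 0).
#' @slot fitted fitted values at the observed design rows.
#' @slot method "reml" or "gibbs".
#' @slot details solver internals (eigenvectors, BLUP weights, chain
#'   settings) used by the predictors.
#' @exportClass GsFit
setClass("GsFit",
  representation(beta = "numeric", u = "numeric", varComp = "numeric",
    fitted = "numeric", method = "character", details = "list"))

#' Cross-validation scheme
#'
#' @slot kind "SINGLE" (repeated k-fold on one response), "CV1" (whole lines
#'   masked in every environment) or "CV2" (line-by-environment cells
#'   masked, each masked line keeps its record elsewhere).
#' @slot k number of folds (default 5).
#' @slot nRepeats number of repeats (default 100).
#' @slot seed master seed; per-repeat seeds are derived from it.
#' @exportClass CvScheme
setClass("CvScheme",
  representation(kind = "character", k = "integer", nRepeats = "integer",
    seed = "integer"))

setValidity("CvScheme", function(object) {
  if (!object@kind %in% c("SINGLE", "CV1", "CV2"))
    return("kind must be SINGLE, CV1 or CV2")
  if (object@k < 2L) return("k must be >= 2")
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  TRUE
})

#' Cross-validation result
#'
#' @slot pa data.frame with columns \code{repeat.}, \code{env} ("" for
#'   single-response CV) and \code{pa} (Pearson correlation of predicted vs
#'   observed over the pooled validation records of that repeat).
#' @slot meta model, fixed SNPs, scheme and seed metadata.
#' @exportClass CvResult
setClass("CvResult", representation(pa = "data.frame", meta = "list"))

setValidity("CvResult", function(object) {
  if (!all(c("repeat.", "env", "pa") %in% names(object@pa)))
    return("pa needs columns repeat., env, pa")
  ok <- is.na(object@pa$pa) | abs(object@pa$pa) <= 1 + 1e-12
  if (!all(ok)) return("prediction accuracies must lie in [-1, 1]")
  TRUE
})

## ---- show methods ----

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d chromosomes, %d markers, %.2f M total\n",
    nrow(object@chromosomes), sum(lengths(object@markers)),
    sum(object@chromosomes$lengthM)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d families x %d markers (%s; %.2f%% missing)\n",
    nrow(object@codes), ncol(object@codes),
    if (object@imputed) "imputed" else "raw codes -1/0/1",
    100 * mean(is.na(object@codes))))
})

setMethod("show", "PhenotypeTable", function(object) {
  r <- object@records
  cat(sprintf(
    "PhenotypeTable: %d records, %d families, %d environments (%s)\n",
    nrow(r), length(unique(r$family)), length(unique(r$env)),
    paste(sort(unique(r$env)), collapse = ", ")))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d x %d from %d markers (2*sum(pq) = %.3f)\n",
    nrow(object@K), ncol(object@K), length(object@markerIDs), object@denom))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigmaG2=%.4g sigmaGE2=%.4g sigmaRep2=%.4g sigmaE2=%.4g\n",
    object@sigmaG2, object@sigmaGE2, object@sigmaRep2, object@sigmaE2))
})

setMethod("show", "BlueResult", function(object) {
  cat(sprintf("BlueResult: %d families, overall mean %.3f\n",
    length(object@blues), object@mu))
})

setMethod("show", "GwasResult", function(object) {
  best <- object@table[which.min(object@table$p), , drop = FALSE]
  cat(sprintf(
    "GwasResult: %d markers; varU=%.4g varE=%.4g; top: %s (p=%.3g)\n",
    nrow(object@table), object@varU, object@varE, best$marker[1], best$p[1]))
})

setMethod("show", "GsFit", function(object) {
  cat(sprintf("GsFit (%s): %d fixed effects, %d genetic values; varComp: %s\n",
    object@method, length(object@beta), length(object@u),
    paste(sprintf("%s=%.4g", names(object@varComp), object@varComp),
      collapse = " ")))
})

setMethod("show", "CvResult", function(object) {
  agg <- tapply(object@pa$pa, object@pa$env, mean)
  cat(sprintf("CvResult: %d repeats; mean PA: %s\n",
    max(object@pa$repeat.),
    paste(sprintf("%s%.4f", ifelse(names(agg) == "", "", paste0(names(agg), "=")),
      agg), collapse = " ")))
})
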
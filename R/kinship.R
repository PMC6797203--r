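## Marker QC, expected-value imputation and the VanRaden genomic
## relationship matrix.

#' Filter markers by parental data and missing rate
#'
#' Removes markers (i) missing in either parent, (ii) non-polymorphic
#' between the parents, and (iii) with a missing rate strictly greater than
#' \code{maxMissing} in the population.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param parentGenotypes 2 x m matrix (rows = the two parents) aligned to
#'   \code{markerIDs(G)}, codes -1/0/1/NA.
#' @param maxMissing maximum tolerated missing rate (markers at exactly the
#'   threshold are kept).
#' @return Filtered \linkS4class{GenotypeMatrix}.
#' @export
filterMarkers <- function(G, parentGenotypes, maxMissing = 0.05) {
  m <- genotypeCodes(G)
  if (ncol(parentGenotypes) != ncol(m))
    stop("parent genotypes not aligned to markers")
  parentOk <- !is.na(parentGenotypes[1L, ]) & !is.na(parentGenotypes[2L, ])
  poly <- parentOk & (parentGenotypes[1L, ] != parentGenotypes[2L, ])
  missRate <- colMeans(is.na(m))
  keep <- poly & (missRate <= maxMissing)
  if (!any(keep)) stop("all markers removed by filtering")
  subsetGenotypes(G, j = which(keep))
}

#' Impute missing genotype calls with marker expected values
#'
#' Each missing call is replaced by the expected code under the observed
#' genotype frequencies of its marker, i.e. the observed column mean
#' \code{E[g] = p*(+1) + h*0 + q*(-1)}; the output may be non-integer.
#'
#' @param G a \linkS4class{GenotypeMatrix} in which every marker has at
#'   least one observed call.
#' @return An imputed \linkS4class{GenotypeMatrix} (no missing values).
#' @export
imputeMissing <- function(G) {
  m <- genotypeCodes(G)
  if (!anyNA(m))
    return(new("GenotypeMatrix", codes = m, markers = G@markers,
      family = G@family, imputed = TRUE))
  mu <- colMeans(m, na.rm = TRUE)
  if (anyNA(mu)) stop("marker(s) with no observed genotype: ",
    paste(head(colnames(m)[is.na(mu)], 5), collapse = ", "))
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2L]]
  new("GenotypeMatrix", codes = m, markers = G@markers, family = G@family,
    imputed = TRUE)
}

#' VanRaden genomic relationship matrix
#'
#' \code{K = WW' / (2 * sum_j p_j q_j)} with \code{W = M - P}; column j of
#' P is \code{2(p_j - 0.5)}, where \code{p_j} is the sample frequency of
#' the +1-coded allele (computed from the imputed matrix).
#'
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param exclude marker IDs to leave out (e.g. SNPs moved to the fixed
#'   part of a GS model).
#' @return A \linkS4class{KinshipMatrix}.
#' @export
vanRadenKinship <- function(G, exclude = character()) {
  m <- genotypeCodes(G)
  if (anyNA(m)) stop("genotypes must be imputed before computing kinship")
  if (length(exclude)) {
    miss <- setdiff(exclude, colnames(m))
    if (length(miss)) stop("unknown marker ID(s) in exclude: ",
      paste(head(miss, 5), collapse = ", "))
    m <- m[, !colnames(m) %in% exclude, drop = FALSE]
  }
  if (ncol(m) == 0) stop("no markers left after exclusion")
  p <- colMeans(m + 1) / 2
  q <- 1 - p
  denom <- 2 * sum(p * q)
  if (denom <= 0)
    stop("all markers monomorphic: VanRaden denominator 2*sum(pq) is zero")
  W <- sweep(m, 2L, 2 * (p - 0.5))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  new("KinshipMatrix", K = K, p = p, denom = denom, markerIDs = colnames(m))
}
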
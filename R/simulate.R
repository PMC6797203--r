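## Breeding-scheme and trait simulator.
##
## Pedigree emulated: F1 (donor x recurrent) -> backcross to the recurrent
## parent (BC1F1) -> each BC1F1 mother pollinated with bulked pollen from
## >= 10 other BC1F1 plants (bulk-BC1F2 families) -> plants selfed once ->
## genotyped BC1F3 generation. Meiosis is Haldane: crossover count is
## Poisson(genetic length in Morgans), breakpoints uniform, no interference.
##
## Haplotypes carry 1 for the recurrent-parent (PH4CV) allele and 0 for the
## donor (Zheng58) allele; a genotype code is hap1 + hap2 - 1, giving the
## -1/0/+1 convention used throughout.

## genetic positions (Morgans) of markers on one chromosome, by linear
## bp <-> cM interpolation
markerMorgans <- function(posBp, lengthBp, lengthM) {
  posBp / lengthBp * lengthM
}

## one meiotic gamete from a pair of haplotypes (0/1 vectors) given marker
## genetic positions gpos (Morgans) and chromosome genetic length L
meiosisGamete <- function(h1, h2, gpos, L) {
  ncx <- rpois(1L, L)
  start <- sample.int(2L, 1L)
  if (ncx == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  breaks <- sort(runif(ncx, 0, L))
  seg <- findInterval(gpos, breaks)  # 0..ncx segments
  useFirst <- (seg + start) %% 2L == 1L
  ifelse(useFirst, h1, h2)
}

## whole-genome gamete: individual is a list (per chromosome) of 2-row
## haplotype matrices; returns a list of haplotype vectors
genomeGamete <- function(ind, geno) {
  lapply(seq_along(ind), function(ci) {
    meiosisGamete(ind[[ci]][1L, ], ind[[ci]][2L, ], geno$gpos[[ci]],
      geno$L[ci])
  })
}

uniteGametes <- function(g1, g2) {
  lapply(seq_along(g1), function(ci) rbind(g1[[ci]], g2[[ci]]))
}

#' Simulate BC1F3 genotypes through the backcross-self scheme
#'
#' Runs gamete-level simulation of the pedigree F1 -> BC1F1 (backcross to
#' the recurrent parent) -> bulk-pollen intermated BC1F2 -> one selfing,
#' and returns the genotypes of the BC1F3 plants at the map's markers.
#' BC1F3 plants are allocated round-robin over the BC1F2 ears (families x
#' selfed plants per family).
#'
#' @param map a \linkS4class{GenomeMap}.
#' @param scheme a \linkS4class{CrossingScheme}.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A \linkS4class{GenotypeMatrix} with one row per BC1F3 plant and
#'   the BC1F2 family of each plant recorded.
#' @export
simulateCross <- function(map, scheme, seed = 1L) {
  validObject(map); validObject(scheme)
  ch <- map@chromosomes
  geno <- list(
    L = ch$lengthM,
    gpos = lapply(seq_len(nrow(ch)), function(ci)
      markerMorgans(map@markers[[ch$id[ci]]], ch$lengthBp[ci], ch$lengthM[ci])))
  nmark <- lengths(map@markers)
  if (any(nmark == 0)) stop("chromosome with zero markers")

  withSeed(seed, {
    ## founders: F1 heterozygous everywhere; recurrent parent fixed for 1
    f1 <- lapply(nmark, function(m) rbind(rep(1, m), rep(0, m)))
    recGamete <- lapply(nmark, function(m) rep(1, m))

    nFam <- scheme@nBc1f2Families
    bc1f1 <- lapply(seq_len(nFam), function(i)
      uniteGametes(genomeGamete(f1, geno), recGamete))

    ## bulk-BC1F2: egg from the mother, pollen from a per-family bulk of
    ## other BC1F1 plants (selfing excluded)
    nSelf <- scheme@nSelfedPerFamily
    bc1f2 <- vector("list", nFam * nSelf)
    fam2 <- character(nFam * nSelf)
    idx <- 0L
    for (f in seq_len(nFam)) {
      bulk <- sample(setdiff(seq_len(nFam), f), scheme@pollenBulkSize)
      for (s in seq_len(nSelf)) {
        idx <- idx + 1L
        donor <- bulk[sample.int(length(bulk), 1L)]
        bc1f2[[idx]] <- uniteGametes(
          genomeGamete(bc1f1[[f]], geno),
          genomeGamete(bc1f1[[donor]], geno))
        fam2[idx] <- sprintf("F%02d_E%d", f, s)
      }
    }

    ## BC1F3: one selfing of a BC1F2 ear parent, ears used round-robin
    n3 <- scheme@nBc1f3
    earOf <- rep(seq_along(bc1f2), length.out = n3)
    codes <- matrix(NA_real_, n3, sum(nmark))
    for (i in seq_len(n3)) {
      par <- bc1f2[[earOf[i]]]
      plant <- uniteGametes(genomeGamete(par, geno), genomeGamete(par, geno))
      codes[i, ] <- unlist(lapply(plant, function(h) h[1L, ] + h[2L, ] - 1))
    }
    rownames(codes) <- sprintf("L%03d", seq_len(n3))
    colnames(codes) <- unlist(lapply(seq_len(nrow(ch)), function(ci)
      sprintf("chr%s_%d", ch$id[ci], map@markers[[ch$id[ci]]])))
    GenotypeMatrix(codes, family = fam2[earOf])
  })
}

#' Per-plant and mean genotype-class composition
#'
#' Proportions of recurrent-parent homozygous (+1), heterozygous (0) and
#' donor homozygous (-1) markers per plant, over non-missing markers.
#'
#' @param G a \linkS4class{GenotypeMatrix} (raw codes).
#' @return list with \code{perPlant} (n x 3 matrix, columns recurrent/het/
#'   donor) and \code{mean} (column means).
#' @export
genotypeComposition <- function(G) {
  m <- genotypeCodes(G)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty genotype matrix")
  nObs <- rowSums(!is.na(m))
  if (any(nObs == 0)) stop("row(s) with all markers missing")
  perPlant <- cbind(
    recurrent = rowSums(m == 1, na.rm = TRUE) / nObs,
    het = rowSums(m == 0, na.rm = TRUE) / nObs,
    donor = rowSums(m == -1, na.rm = TRUE) / nObs)
  rownames(perPlant) <- rownames(m)
  list(perPlant = perPlant, mean = colMeans(perPlant))
}

#' Set genotype calls missing at random
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param rate per-entry independent missingness probability in [0, 1).
#' @param seed integer RNG seed.
#' @return A \linkS4class{GenotypeMatrix} with injected NA calls.
#' @export
injectMissingness <- function(G, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(G)
  m <- genotypeCodes(G)
  withSeed(seed, {
    m[runif(length(m)) < rate] <- NA_real_
  })
  new("GenotypeMatrix", codes = m, markers = G@markers, family = G@family,
    imputed = FALSE)
}

#' Simulate multi-environment replicated phenotypes
#'
#' Generates \code{y_ijm = mu_j + sum_q a_q g_iq + sum_q d_qj g_iq +
#' delta_(j)m + e_ijm} with per-(QTL, environment) deviations
#' \code{d_qj ~ N(0, gxeSd_q^2)} held fixed across replicates,
#' replicate-within-environment effects \code{delta ~ N(0, repSd^2)} and
#' residuals \code{e ~ N(0, residSd^2)}. When the architecture sets
#' \code{targetH2}, the residual sd is solved from the entry-mean
#' heritability formula given the realized genetic and interaction
#' variances.
#'
#' @param G a \linkS4class{GenotypeMatrix} (BC1F3 parents; heterozygotes
#'   contribute zero additive value under the -1/0/+1 coding).
#' @param arch a \linkS4class{TraitArchitecture}.
#' @param nEnvs number of environments (uses the first \code{nEnvs} entries
#'   of \code{envMeans}, recycled if needed).
#' @param nReps replicates per environment.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
simulateTrait <- function(G, arch, nEnvs = length(arch@envMeans),
                          nReps = 2L, seed = 1L) {
  validObject(arch)
  if (nEnvs < 1 || nReps < 1) stop("nEnvs and nReps must be >= 1")
  m <- genotypeCodes(G)
  if (anyNA(m)) stop("genotypes must be complete (impute first)")
  qtl <- arch@qtl
  if (nrow(qtl) && (min(qtl$marker) < 1 || max(qtl$marker) > ncol(m)))
    stop("QTL marker index out of range")
  envMeans <- rep_len(arch@envMeans, nEnvs)
  envs <- names(arch@envMeans)
  if (is.null(envs)) envs <- sprintf("E%d", seq_len(nEnvs))
  envs <- rep_len(envs, nEnvs)
  fam <- rownames(m)
  n <- nrow(m)
  nq <- nrow(qtl)
  gq <- if (nq) m[, qtl$marker, drop = FALSE] else matrix(0, n, 0)
  gxeSd <- if (nq) rep_len(arch@gxeSd, nq) else numeric(0)

  withSeed(seed, {
    gval <- if (nq) drop(gq %*% qtl$effect) else rep(0, n)
    ## per-(QTL, env) deviations, fixed across replicates
    inter <- matrix(0, n, nEnvs)
    if (nq) {
      d <- matrix(rnorm(nq * nEnvs, 0, gxeSd), nq, nEnvs)
      inter <- gq %*% d
    }
    residSd <- arch@residSd
    if (is.finite(arch@targetH2)) {
      vg <- var(gval)
      if (vg <= 0) stop("targetH2 calibration needs nonzero genetic variance")
      ## two-way interaction variance of the realized deviations
      tt <- inter
      tij <- tt - rowMeans(tt)
      tij <- sweep(tij, 2, colMeans(tij))
      vge <- sum(tij^2) / max(1, (n - 1) * (nEnvs - 1))
      h2 <- arch@targetH2
      ve <- nReps * nEnvs * (vg / h2 - vg - vge / nEnvs)
      if (ve <= 0)
        stop("targetH2 unattainable given interaction variance; lower gxeSd or targetH2")
      residSd <- sqrt(ve)
    }
    repEff <- matrix(rnorm(nEnvs * nReps, 0, arch@repSd), nEnvs, nReps)
    rec <- expand.grid(family = fam, envIdx = seq_len(nEnvs),
      rep = seq_len(nReps), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE)
    i <- match(rec$family, fam)
    y <- envMeans[rec$envIdx] + gval[i] + inter[cbind(i, rec$envIdx)] +
      repEff[cbind(rec$envIdx, rec$rep)] +
      rnorm(nrow(rec), 0, residSd)
    PhenotypeTable(data.frame(family = rec$family, env = envs[rec$envIdx],
      rep = as.character(rec$rep), value = y))
  })
}
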
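## Multi-environment genomic-selection models.
##
## SE:  y_i = 1 mu_i + X beta_i + e_i, one environment at a time.
## AE:  stacked environments, one shared marker-effect vector (equivalently
##      one genetic kernel shared across environment blocks).
## GXE: shared main effect beta0 plus environment-specific deviations
##      beta_i (equivalently a shared kernel plus per-environment block
##      kernels), giving sigmaU0^2 and per-environment sigmaU1^2, sigmaU2^2.
## All three are fitted through kernels K = VanRaden GRM; large-effect SNPs
## optionally enter the fixed part and are excluded from the GRM.

## per-environment response vectors (family means across replicates)
envResponses <- function(pheno, environments) {
  r <- phenoRecords(pheno)
  out <- lapply(environments, function(ev) {
    s <- r[r$env == ev, , drop = FALSE]
    if (nrow(s) == 0) stop("no records for environment ", ev)
    tapply(s$value, s$family, mean)
  })
  names(out) <- environments
  out
}

## assemble stacked design for AE/GXE over the family intersection
stackedDesign <- function(yList, G, fixedSnps, standardize) {
  fams <- Reduce(intersect, lapply(yList, names))
  if (length(fams) == 0) stop("no family is phenotyped in every environment")
  fams <- intersect(familyIDs(G), fams)
  Gsub <- subsetGenotypes(G, i = fams)
  fd <- buildFixedDesign(Gsub, fixedSnps)
  K <- kinship(vanRadenKinship(fd$reduced))
  nf <- length(fams); ne <- length(yList)
  y <- unlist(lapply(yList, function(v) {
    v <- v[fams]
    if (standardize) as.numeric(scale(v)) else as.numeric(v)
  }))
  envCol <- rep(seq_len(ne), each = nf)
  ## one intercept per environment, then the fixed-SNP columns (shared)
  Xint <- matrix(0, nf * ne, ne)
  Xint[cbind(seq_len(nf * ne), envCol)] <- 1
  colnames(Xint) <- paste0("mu_", names(yList))
  Xsnp <- fd$Xf[, -1L, drop = FALSE][rep(seq_len(nf), ne), , drop = FALSE]
  Xf <- cbind(Xint, Xsnp)
  Zline <- matrix(0, nf * ne, nf)
  Zline[cbind(seq_len(nf * ne), rep(seq_len(nf), ne))] <- 1
  rownames(K) <- colnames(K) <- fams
  list(fams = fams, y = y, Xf = Xf, K = K, envCol = envCol, nf = nf,
    ne = ne, Zline = Zline)
}

#' Fit a single- or multi-environment GS model
#'
#' SE fits GBLUP within one environment; AE stacks the environments with
#' per-environment intercepts and one shared genetic kernel; GXE adds
#' per-environment interaction kernels (block-diagonal marker designs),
#' yielding a main genetic variance and per-environment interaction
#' variances. Responses may be standardized to mean 0 / sd 1 per
#' environment before fitting, which is the convention used for full-data
#' variance decomposition.
#'
#' @param spec a \linkS4class{GsModelSpec}.
#' @param pheno a \linkS4class{PhenotypeTable} (family means per
#'   environment are used as responses).
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param chain a \linkS4class{ChainConfig} for the Gibbs solver.
#' @param solver "gibbs" (default for AE/GXE) or "reml" (SE and AE only,
#'   deterministic spectral REML).
#' @param standardize scale each environment's response to mean 0, sd 1
#'   (default TRUE, the full-data variance-decomposition convention).
#' @return A \linkS4class{GsFit}. For GXE, \code{details$uEnv} holds the
#'   per-environment interaction deviations.
#' @export
fitEnvironmentModel <- function(spec, pheno, G, chain = ChainConfig(),
                                solver = c("gibbs", "reml"),
                                standardize = TRUE) {
  validObject(spec)
  solver <- match.arg(solver)
  yList <- envResponses(pheno, spec@environments)

  if (spec@modelType == "SE") {
    v <- yList[[1L]]
    fams <- intersect(familyIDs(G), names(v))
    Gsub <- subsetGenotypes(G, i = fams)
    y <- v[fams]
    if (standardize) y <- setNames(as.numeric(scale(y)), fams)
    fd <- buildFixedDesign(Gsub, spec@fixedSnps)
    Km <- kinship(vanRadenKinship(fd$reduced))
    rownames(Km) <- colnames(Km) <- fams
    if (solver == "reml") return(solveGblupReml(y, fd$Xf, Km))
    fit <- solveBayesGibbs(y, fd$Xf,
      list(sigmaU02 = list(Z = diag(length(y)), K = Km)), chain)
    return(fit)
  }

  sd0 <- stackedDesign(yList, G, spec@fixedSnps, standardize)
  if (spec@modelType == "AE") {
    if (solver == "reml") {
      Kobs <- sd0$Zline %*% sd0$K %*% t(sd0$Zline)
      fit <- solveGblupReml(sd0$y, sd0$Xf, Kobs)
      ## recover per-line main effects from the observation-level BLUPs
      uLine <- drop(sd0$K %*% t(sd0$Zline) %*% fit@details$alpha) *
        fit@varComp["sigmaU2"]
      fit@u <- setNames(uLine, sd0$fams)
      fit@varComp <- c(sigmaU02 = unname(fit@varComp["sigmaU2"]),
        sigmaE2 = unname(fit@varComp["sigmaE2"]))
      fit@details$fams <- sd0$fams
      return(fit)
    }
    fit <- solveBayesGibbs(sd0$y, sd0$Xf,
      list(sigmaU02 = list(Z = sd0$Zline, K = sd0$K)), chain)
    fit@u <- setNames(fit@details$uk[[1L]], sd0$fams)
    fit@details$fams <- sd0$fams
    return(fit)
  }

  ## GXE: shared kernel + one block kernel per environment
  if (solver == "reml")
    stop("GXE has multiple variance components; use the gibbs solver")
  kernels <- list(sigmaU02 = list(Z = sd0$Zline, K = sd0$K))
  for (j in seq_len(sd0$ne)) {
    Zj <- sd0$Zline * (sd0$envCol == j)
    kernels[[paste0("sigmaU", j, "2")]] <- list(Z = Zj, K = sd0$K)
  }
  fit <- solveBayesGibbs(sd0$y, sd0$Xf, kernels, chain)
  fit@u <- setNames(fit@details$uk[[1L]], sd0$fams)
  names(fit@details$uk) <- names(kernels)
  fit@details$uEnv <- lapply(fit@details$uk[-1L], function(u)
    setNames(u, sd0$fams))
  fit@details$fams <- sd0$fams
  fit
}
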
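## Cross-validation machinery: repeated five-fold CV on BLUEs, CV1/CV2
## multi-environment schemes, sequential fixed-SNP selection, the
## random-SNP null and the MAS baseline.
##
## Seed policy: the scheme's master seed derives one seed per repeat (and
## per draw) through deriveSeed(), so any repeat is re-runnable alone.
## Genotypes are known for every line, so the relationship matrix is built
## once from all lines and only phenotypes are masked.

#' Prediction accuracy (Pearson correlation)
#'
#' @param predicted,observed equal-length numeric vectors (>= 3 values,
#'   both with nonzero variance).
#' @return Sample Pearson correlation.
#' @export
pearsonPa <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop("prediction accuracy undefined: zero variance")
  cor(predicted, observed)
}

## exact k-fold partition of n lines
foldAssignment <- function(n, k) {
  if (floor(n / k) < 2) stop("fold with fewer than 2 lines")
  sample(rep(seq_len(k), length.out = n))
}

#' Repeated k-fold cross-validation of single-response GBLUP
#'
#' Per repeat: a seeded random k-fold partition; the model is trained on
#' k-1 folds and predicts the held-out fold; pooled validation predictions
#' are correlated with the observed values once per repeat.
#'
#' @param blues a \linkS4class{BlueResult} or named numeric response.
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param fixedSnps marker IDs fitted as fixed effects (excluded from the
#'   relationship matrix).
#' @param scheme a \linkS4class{CvScheme} of kind "SINGLE".
#' @param solver "reml" (deterministic, default) or "gibbs".
#' @param chain \linkS4class{ChainConfig} when \code{solver = "gibbs"}.
#' @return A \linkS4class{CvResult}.
#' @export
runCvSingle <- function(blues, G, fixedSnps = character(),
                        scheme = CvScheme("SINGLE"),
                        solver = c("reml", "gibbs"),
                        chain = ChainConfig(nIter = 1500L, burnIn = 500L)) {
  solver <- match.arg(solver)
  if (scheme@kind != "SINGLE") stop("scheme kind must be SINGLE")
  y <- if (is(blues, "BlueResult")) blues(blues) else blues
  fams <- intersect(familyIDs(G), names(y))
  y <- y[fams]
  Gsub <- subsetGenotypes(G, i = fams)
  fd <- buildFixedDesign(Gsub, fixedSnps)
  Km <- kinship(vanRadenKinship(fd$reduced))
  n <- length(y)
  pa <- numeric(scheme@nRepeats)
  for (r in seq_len(scheme@nRepeats)) {
    folds <- withSeed(deriveSeed(scheme@seed, r), foldAssignment(n, scheme@k))
    pred <- rep(NA_real_, n)
    for (f in seq_len(scheme@k)) {
      te <- which(folds == f); tr <- which(folds != f)
      if (solver == "reml") {
        fit <- solveGblupReml(y[tr], fd$Xf[tr, , drop = FALSE],
          Km[tr, tr, drop = FALSE])
        pred[te] <- predictGblup(fit, Km[te, tr, drop = FALSE],
          fd$Xf[te, , drop = FALSE])
      } else {
        Z <- diag(n)[tr, , drop = FALSE]
        ch <- ChainConfig(chain@nIter, chain@burnIn, chain@thin,
          deriveSeed(deriveSeed(scheme@seed, r), 1000L + f),
          chain@priorDf, chain@r2)
        fit <- solveBayesGibbs(y[tr], fd$Xf[tr, , drop = FALSE],
          list(g = list(Z = Z, K = Km)), ch)
        pred[te] <- drop(fd$Xf[te, , drop = FALSE] %*% fit@beta) +
          fit@details$uk[[1L]][te]
      }
    }
    pa[r] <- pearsonPa(pred, y)
  }
  new("CvResult",
    pa = data.frame(repeat. = seq_len(scheme@nRepeats), env = "", pa = pa),
    meta = list(model = "GBLUP", fixedSnps = fixedSnps, scheme = "SINGLE",
      k = scheme@k, seed = scheme@seed, solver = solver))
}

#' Choose how many top SNPs to fit as fixed effects
#'
#' For n = 1..maxN, compares the per-repeat prediction accuracies when
#' fitting the top n SNPs against the top n-1 SNPs by a two-tailed Welch
#' t-test (repeats paired through shared fold seeds). The chosen n* is the
#' largest n such that every step up to n is significant at \code{alpha}
#' and the next step is not.
#'
#' @param blues response (see \code{\link{runCvSingle}}).
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param rankedSnps marker IDs in GWAS rank order.
#' @param maxN largest number of fixed SNPs to consider.
#' @param scheme a \linkS4class{CvScheme} of kind "SINGLE".
#' @param alpha significance level (default 0.05).
#' @param solver passed to \code{\link{runCvSingle}}.
#' @return list with \code{nStar}, \code{tTable} (one row per step:
#'   meanPa, t, p, significant) and \code{paByN} (per-repeat PA vectors for
#'   n = 0..maxN).
#' @export
chooseNFixedSnps <- function(blues, G, rankedSnps, maxN, scheme,
                             alpha = 0.05, solver = "reml") {
  if (maxN > length(rankedSnps)) stop("maxN exceeds the ranked SNP list")
  paByN <- vector("list", maxN + 1L)
  paByN[[1L]] <- paTable(runCvSingle(blues, G, character(), scheme,
    solver = solver))$pa
  rows <- list()
  nStar <- 0L
  for (n in seq_len(maxN)) {
    paByN[[n + 1L]] <- paTable(runCvSingle(blues, G, rankedSnps[seq_len(n)],
      scheme, solver = solver))$pa
    tt <- t.test(paByN[[n + 1L]], paByN[[n]], var.equal = FALSE)
    sig <- tt$p.value < alpha && mean(paByN[[n + 1L]]) > mean(paByN[[n]])
    rows[[n]] <- data.frame(n = n, meanPa = mean(paByN[[n + 1L]]),
      t = unname(tt$statistic), p = tt$p.value, significant = sig)
    if (nStar == n - 1L && sig) nStar <- n
  }
  list(nStar = nStar, tTable = do.call(rbind, rows),
    paByN = setNames(paByN, paste0("n", 0:maxN)))
}

#' Null distribution of PA under randomly chosen fixed SNPs
#'
#' Each draw samples \code{nFixed} markers uniformly without replacement,
#' runs the full repeated-CV with them as fixed effects, and records the
#' mean PA. Fold partitions are shared across draws (same scheme seed), so
#' draws differ only in the fixed-SNP set.
#'
#' @param blues response.
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param nFixed number of random SNPs per draw (default 4).
#' @param nDraws number of draws (default 200).
#' @param scheme a \linkS4class{CvScheme} of kind "SINGLE".
#' @param solver passed to \code{\link{runCvSingle}}.
#' @return numeric vector of mean PAs, one per draw.
#' @export
randomSnpNull <- function(blues, G, nFixed = 4L, nDraws = 200L,
                          scheme = CvScheme("SINGLE"), solver = "reml") {
  if (nDraws < 1) stop("nDraws must be >= 1")
  ids <- markerIDs(G)
  if (nFixed >= length(ids)) stop("nFixed must be smaller than the marker count")
  vapply(seq_len(nDraws), function(dr) {
    snps <- withSeed(deriveSeed(scheme@seed, 1000000L + dr),
      sample(ids, nFixed))
    meanPa(runCvSingle(blues, G, snps, scheme, solver = solver))
  }, 0)
}

#' Multi-environment cross-validation (CV1 / CV2)
#'
#' Works on a pair (or more) of environments restricted to the families
#' phenotyped in all of them. CV1 masks fold lines in every environment
#' (untested lines); CV2 masks line-by-environment cells with a
#' deterministic alternation inside each fold, so every masked line keeps
#' its record in the other environment and masked-cell counts stay
#' balanced. PA is computed per validation environment over that
#' environment's masked records, pooled within a repeat.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param modelType "AE" or "GXE".
#' @param fixedSnps marker IDs fitted as fixed effects.
#' @param scheme a \linkS4class{CvScheme} of kind "CV1" or "CV2".
#' @param environments the environment labels to use (>= 2).
#' @param chain \linkS4class{ChainConfig} for the Gibbs solver.
#' @param solver "gibbs" (default; required for GXE) or "reml" (AE only).
#' @return A \linkS4class{CvResult} with one PA per repeat x environment.
#' @export
runCvMulti <- function(pheno, G, modelType = c("AE", "GXE"),
                       fixedSnps = character(), scheme, environments,
                       chain = ChainConfig(nIter = 1500L, burnIn = 500L),
                       solver = c("gibbs", "reml")) {
  modelType <- match.arg(modelType)
  solver <- match.arg(solver)
  if (!scheme@kind %in% c("CV1", "CV2"))
    stop("scheme kind must be CV1 or CV2")
  if (length(environments) < 2) stop("need >= 2 environments")
  if (solver == "reml" && modelType == "GXE")
    stop("GXE requires the gibbs solver")
  yList <- envResponses(pheno, environments)
  sd0 <- stackedDesign(yList, G, fixedSnps, standardize = FALSE)
  nf <- sd0$nf; ne <- sd0$ne
  ymat <- matrix(sd0$y, nf, ne)  # columns in environment order

  out <- vector("list", scheme@nRepeats)
  for (r in seq_len(scheme@nRepeats)) {
    folds <- withSeed(deriveSeed(scheme@seed, r), foldAssignment(nf, scheme@k))
    predMat <- matrix(NA_real_, nf, ne)
    for (f in seq_len(scheme@k)) {
      inFold <- which(folds == f)
      cellMask <- matrix(FALSE, nf, ne)
      if (scheme@kind == "CV1") {
        cellMask[inFold, ] <- TRUE
      } else {
        ## alternate the masked environment within the fold (and rotate the
        ## starting environment across folds) to balance cell counts
        for (s in seq_along(inFold))
          cellMask[inFold[s], ((s + f) %% ne) + 1L] <- TRUE
      }
      obs <- which(!cellMask)
      yTr <- sd0$y[obs]
      XfTr <- sd0$Xf[obs, , drop = FALSE]
      kernels <- list(sigmaU02 = list(Z = sd0$Zline[obs, , drop = FALSE],
        K = sd0$K))
      if (modelType == "GXE") {
        for (j in seq_len(ne)) {
          Zj <- (sd0$Zline * (sd0$envCol == j))[obs, , drop = FALSE]
          kernels[[paste0("sigmaU", j, "2")]] <- list(Z = Zj, K = sd0$K)
        }
      }
      if (solver == "reml") {
        Kobs <- kernels[[1L]]$Z %*% sd0$K %*% t(kernels[[1L]]$Z)
        fit <- solveGblupReml(yTr, XfTr, Kobs)
        uLine <- fit@varComp["sigmaU2"] *
          drop(sd0$K %*% t(kernels[[1L]]$Z) %*% fit@details$alpha)
        uEnv <- NULL
        beta <- fit@beta
      } else {
        ch <- ChainConfig(chain@nIter, chain@burnIn, chain@thin,
          deriveSeed(deriveSeed(scheme@seed, r), 1000L + f),
          chain@priorDf, chain@r2)
        fit <- solveBayesGibbs(yTr, XfTr, kernels, ch)
        uLine <- fit@details$uk[[1L]]
        uEnv <- if (modelType == "GXE") fit@details$uk[-1L] else NULL
        beta <- fit@beta
      }
      for (j in seq_len(ne)) {
        lines <- which(cellMask[, j])
        if (!length(lines)) next
        XfTe <- sd0$Xf[(j - 1L) * nf + lines, , drop = FALSE]
        pr <- drop(XfTe %*% beta) + uLine[lines]
        if (!is.null(uEnv)) pr <- pr + uEnv[[j]][lines]
        predMat[lines, j] <- pr
      }
    }
    out[[r]] <- do.call(rbind, lapply(seq_len(ne), function(j) {
      keep <- !is.na(predMat[, j])
      data.frame(repeat. = r, env = environments[j],
        pa = pearsonPa(predMat[keep, j], ymat[keep, j]))
    }))
  }
  new("CvResult", pa = do.call(rbind, out),
    meta = list(model = modelType, fixedSnps = fixedSnps,
      scheme = scheme@kind, k = scheme@k, seed = scheme@seed,
      environments = environments, solver = solver))
}

#' Marker-assisted-selection baseline by repeated CV
#'
#' Ordinary least squares of the response on the selected SNP genotypes in
#' the training folds, linear prediction on the validation folds, PA pooled
#' per repeat as in \code{\link{runCvSingle}}.
#'
#' @param blues response.
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param snps marker IDs used as predictors (>= 1).
#' @param scheme a \linkS4class{CvScheme} of kind "SINGLE".
#' @return A \linkS4class{CvResult}.
#' @export
masPredictCv <- function(blues, G, snps, scheme = CvScheme("SINGLE")) {
  if (length(snps) < 1) stop("need at least one SNP")
  y <- if (is(blues, "BlueResult")) blues(blues) else blues
  fams <- intersect(familyIDs(G), names(y))
  y <- y[fams]
  X <- cbind(1, genotypeCodes(G)[fams, snps, drop = FALSE])
  n <- length(y)
  pa <- numeric(scheme@nRepeats)
  warnedAlias <- FALSE
  for (r in seq_len(scheme@nRepeats)) {
    folds <- withSeed(deriveSeed(scheme@seed, r), foldAssignment(n, scheme@k))
    pred <- rep(NA_real_, n)
    for (f in seq_len(scheme@k)) {
      te <- folds == f; tr <- !te
      cf <- qr.coef(qr(X[tr, , drop = FALSE]), y[tr])
      if (anyNA(cf)) {
        if (!warnedAlias) {
          warning("aliased SNP column(s) dropped in MAS regression")
          warnedAlias <- TRUE
        }
        cf[is.na(cf)] <- 0
      }
      pred[te] <- drop(X[te, , drop = FALSE] %*% cf)
    }
    pa[r] <- pearsonPa(pred, y)
  }
  new("CvResult",
    pa = data.frame(repeat. = seq_len(scheme@nRepeats), env = "", pa = pa),
    meta = list(model = "MAS", snps = snps, scheme = "SINGLE",
      seed = scheme@seed))
}
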
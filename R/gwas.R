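## Mixed-model GWAS on BLUEs with a VanRaden kinship background, top-SNP
## selection and sequential-regression PVE decomposition.

#' Mixed-model GWAS scan (P3D)
#'
#' Fits the null model \code{y* = 1 mu + g + e}, \code{g ~ N(0, K sigmaU2)},
#' once by spectral REML, then tests each marker as a fixed effect by
#' generalized least squares in the eigenrotated space with the null
#' variance components held fixed (P3D). Wald p-values use a t reference
#' with \code{n - 2} degrees of freedom. Exact per-marker REML is available
#' behind \code{perMarkerReml}.
#'
#' @param blues a \linkS4class{BlueResult} (or named numeric response).
#' @param G an imputed \linkS4class{GenotypeMatrix} aligned to the response
#'   families.
#' @param K a \linkS4class{KinshipMatrix} over the same families.
#' @param perMarkerReml re-estimate variance components for every marker
#'   (slow; default FALSE).
#' @param varComp optional list(varU=, varE=) overriding the null-model
#'   estimates (e.g. \code{varU = 0} reduces every test to ordinary least
#'   squares).
#' @return A \linkS4class{GwasResult}.
#' @export
gwasScan <- function(blues, G, K, perMarkerReml = FALSE, varComp = NULL) {
  y <- if (is(blues, "BlueResult")) blues(blues) else blues
  m <- genotypeCodes(G)
  if (anyNA(m)) stop("genotypes must be imputed before GWAS")
  if (is.null(names(y)) || !all(names(y) %in% rownames(m)))
    stop("response names must match genotype family IDs")
  m <- m[names(y), , drop = FALSE]
  Km <- kinship(K)
  if (!identical(dim(Km), c(length(y), length(y))))
    stop("kinship dimension does not match response")
  n <- length(y)
  eg <- eigen(Km, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("K is not positive semi-definite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ones <- matrix(1, n, 1)

  if (is.null(varComp)) {
    nullFit <- spectralRemlCore(y, ones, U, d)
    varU <- nullFit$sigmaU2
    varE <- nullFit$sigmaE2
  } else {
    varU <- varComp$varU
    varE <- varComp$varE
  }

  yr <- drop(crossprod(U, y))
  onesR <- drop(crossprod(U, rep(1, n)))
  mr <- crossprod(U, m)

  testMarker <- function(j, wi) {
    x <- mr[, j]
    X <- cbind(onesR, x)
    XtWX <- crossprod(X, X * wi)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(c(NA_real_, NA_real_, 1))
    XtWy <- crossprod(X, yr * wi)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yr - X %*% beta
    s2 <- sum(r^2 * wi) / (n - 2L)
    covb <- chol2inv(ch) * s2
    se <- sqrt(covb[2L, 2L])
    if (!is.finite(se) || se == 0) return(c(beta[2L], se, 1))
    tval <- beta[2L] / se
    c(beta[2L], se, 2 * pt(-abs(tval), df = n - 2L))
  }

  nm <- ncol(m)
  out <- matrix(NA_real_, nm, 3L)
  if (perMarkerReml) {
    for (j in seq_len(nm)) {
      fitJ <- spectralRemlCore(y, cbind(1, m[, j]), U, d)
      out[j, ] <- testMarker(j, 1 / (fitJ$sigmaU2 * d + fitJ$sigmaE2))
    }
  } else {
    wi <- 1 / (varU * d + varE)
    for (j in seq_len(nm)) out[j, ] <- testMarker(j, wi)
  }

  info <- markerInfo(G)
  tab <- data.frame(marker = colnames(m), chr = info$chr, pos = info$pos,
    effect = out[, 1L], se = out[, 2L], p = pmin(pmax(out[, 3L], 1e-300), 1),
    stringsAsFactors = FALSE)
  tab$neglog10p <- -log10(tab$p)
  new("GwasResult", table = tab, varU = varU, varE = varE)
}

#' Select the top-ranked SNPs of a GWAS scan
#'
#' Markers in descending \code{-log10(p)} order; ties broken
#' deterministically by (chromosome, position).
#'
#' @param res a \linkS4class{GwasResult}.
#' @param n number of markers to return (default 50).
#' @return Character vector of marker IDs in rank order.
#' @export
selectTopSnps <- function(res, n = 50L) {
  tab <- resultTable(res)
  if (n > nrow(tab)) stop("n exceeds the number of tested markers")
  chrNum <- suppressWarnings(as.numeric(tab$chr))
  chrKey <- if (anyNA(chrNum)) rank(tab$chr, ties.method = "min") else chrNum
  ord <- order(tab$p, chrKey, tab$pos)
  tab$marker[ord][seq_len(n)]
}

#' Sequential (Type-I) PVE decomposition over selected SNPs
#'
#' Fits one multiple linear regression of the response on all selected SNPs
#' in the given order; each SNP's regression sum of squares is its
#' sequential (Type-I) SS, and its PVE is that SS divided by the total
#' corrected SS of the response (default) or by the model SS.
#'
#' @param blues a \linkS4class{BlueResult} (or named numeric response).
#' @param G an imputed \linkS4class{GenotypeMatrix}.
#' @param snps ordered marker IDs to fit.
#' @param denominator "total" (corrected total SS; PVEs are fractions of
#'   phenotypic variance) or "model" (regression SS of the full model).
#' @return A \linkS4class{PveTable} with PVE as a fraction.
#' @export
pveMultipleRegression <- function(blues, G, snps,
                                  denominator = c("total", "model")) {
  denominator <- match.arg(denominator)
  y <- if (is(blues, "BlueResult")) blues(blues) else blues
  m <- genotypeCodes(G)
  miss <- setdiff(snps, colnames(m))
  if (length(miss)) stop("unknown marker ID(s): ",
    paste(head(miss, 5), collapse = ", "))
  if (length(snps) >= length(y))
    stop("need fewer selected SNPs than families")
  X <- m[names(y), snps, drop = FALSE]
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  droppedAliased <- character()
  cf <- coef(fit)[-1L]
  if (anyNA(cf)) {
    droppedAliased <- snps[is.na(cf)]
    warning("dropping aliased marker(s): ",
      paste(droppedAliased, collapse = ", "))
    snps <- setdiff(snps, droppedAliased)
    dat <- data.frame(y = y, m[names(y), snps, drop = FALSE],
      check.names = FALSE)
    fit <- lm(y ~ ., data = dat)
  }
  an <- suppressWarnings(anova(fit))  # F-tests unused; only the Type-I SS
  ss <- an[seq_along(snps), "Sum Sq"]
  ssTol <- if (denominator == "total") sum((y - mean(y))^2) else sum(ss)
  new("PveTable",
    table = data.frame(marker = snps, ssReg = ss, pve = ss / ssTol,
      stringsAsFactors = FALSE),
    ssTol = ssTol, denominator = denominator,
    droppedAliased = droppedAliased)
}
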
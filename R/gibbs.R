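## Bayesian multi-kernel solver. Model:
##   y = Xf beta + sum_k Z_k u_k + e,  u_k ~ N(0, K_k sigma_k^2),
##   e ~ N(0, I sigmaE^2),
## with scaled-inverse-chi-squared priors on every variance and a flat prior
## on beta. Each kernel is eigendecomposed once (u_k = Gamma_k v_k with
## independent v_i ~ N(0, lambda_i sigma_k^2)), so the per-iteration kernel
## update is a joint Gaussian draw in the eigencoefficient space. Linear
## kernels make this exactly equivalent to the marker-effect formulation.

#' Build the fixed-covariate design for large-effect SNPs
#'
#' Returns the covariate matrix [1 | selected SNP genotype columns] and the
#' genotype matrix with those SNPs removed, so the relationship matrix used
#' downstream is built without them.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param fixedSnps marker IDs to move to the fixed part (possibly empty).
#' @return list with \code{Xf} (n x (1 + length(fixedSnps))) and
#'   \code{reduced} (\linkS4class{GenotypeMatrix} without the SNPs).
#' @export
buildFixedDesign <- function(G, fixedSnps = character()) {
  m <- genotypeCodes(G)
  if (anyDuplicated(fixedSnps)) stop("duplicate fixed SNP ID")
  miss <- setdiff(fixedSnps, colnames(m))
  if (length(miss)) stop("unknown fixed SNP ID(s): ",
    paste(miss, collapse = ", "))
  Xf <- cbind(intercept = rep(1, nrow(m)),
    m[, fixedSnps, drop = FALSE])
  reduced <- if (length(fixedSnps))
    subsetGenotypes(G, j = which(!colnames(m) %in% fixedSnps)) else G
  list(Xf = Xf, reduced = reduced)
}

## eigendecompose a PSD kernel, truncating numerically null dimensions
kernelEigen <- function(K, tol = 1e-8) {
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values), 1))
    stop("kernel is not positive semi-definite")
  keep <- eg$values > tol * max(eg$values)
  list(G = eg$vectors[, keep, drop = FALSE], lambda = eg$values[keep])
}

#' Gibbs sampler for the Gaussian multi-kernel model
#'
#' @param y response vector over the observed records.
#' @param Xf fixed-covariate matrix (include intercepts), full rank.
#' @param kernels list of kernels, each \code{list(Z = incidence matrix
#'   (n_obs x q), K = q x q PSD covariance)}; genetic values are returned
#'   for all q support lines, including those without observations.
#' @param chain a \linkS4class{ChainConfig}.
#' @return A \linkS4class{GsFit} with posterior means; \code{details$uk} is
#'   the list of per-kernel genetic-value vectors, \code{details$mcse} their
#'   Monte-Carlo standard errors, \code{details$samples} the thinned
#'   variance-component draws.
#' @export
solveBayesGibbs <- function(y, Xf, kernels, chain = ChainConfig()) {
  validObject(chain)
  n <- length(y)
  if (nrow(Xf) != n) stop("Xf rows must match length(y)")
  p <- ncol(Xf)
  nk <- length(kernels)
  vy <- var(y)
  if (vy == 0) vy <- 1e-8

  eig <- lapply(kernels, function(k) {
    if (nrow(k$Z) != n) stop("kernel incidence rows must match length(y)")
    e <- kernelEigen(k$K)
    B <- k$Z %*% e$G
    A <- crossprod(B)
    diagA <- max(abs(A - diag(diag(A), nrow(A)))) < 1e-10
    list(G = e$G, lambda = e$lambda, B = B, A = A, diagA = diagA)
  })
  ## prior scales: mode of scaled-inv-chi2(df, S) is df*S/(df+2); put r2 of
  ## the response variance on the kernels (split evenly, scaled by the mean
  ## diagonal of each Z K Z') and 1 - r2 on the residual
  df0 <- chain@priorDf
  meanDiag <- vapply(seq_len(nk), function(k) {
    B <- eig[[k]]$B
    mean(drop(B^2 %*% eig[[k]]$lambda))
  }, 0)
  Sk <- (chain@r2 * vy / nk) * (df0 + 2) / df0 / pmax(meanDiag, 1e-12)
  Se <- ((1 - chain@r2) * vy) * (df0 + 2) / df0

  XtX <- crossprod(Xf)
  chX <- tryCatch(chol(XtX), error = function(e)
    stop("Xf is rank-deficient"))
  XtXi <- chol2inv(chX)
  chXi <- chol(XtXi)

  nIter <- chain@nIter; burnIn <- chain@burnIn; thin <- chain@thin
  keepIdx <- seq(burnIn + thin, nIter, by = thin)
  nKeep <- length(keepIdx)

  withSeed(chain@seed, {
    beta <- drop(XtXi %*% crossprod(Xf, y))
    v <- lapply(eig, function(e) rep(0, length(e$lambda)))
    s2k <- rep(vy * chain@r2 / max(nk, 1), nk)
    s2e <- vy * (1 - chain@r2)
    Bv <- lapply(eig, function(e) rep(0, n))

    sumBeta <- rep(0, p); sumU <- lapply(eig, function(e) rep(0, nrow(e$G)))
    sumU2 <- lapply(eig, function(e) rep(0, nrow(e$G)))
    sumFit <- rep(0, n)
    varSamples <- matrix(NA_real_, nKeep, nk + 1L)
    kept <- 0L

    for (it in seq_len(nIter)) {
      ## beta | rest
      e0 <- y - Reduce(`+`, Bv, rep(0, n))
      betaHat <- drop(XtXi %*% crossprod(Xf, e0))
      beta <- betaHat + sqrt(s2e) * drop(t(chXi) %*% rnorm(p))
      resid <- e0 - drop(Xf %*% beta)

      ## kernels | rest
      for (k in seq_len(nk)) {
        ek <- resid + Bv[[k]]
        E <- eig[[k]]
        rhs <- drop(crossprod(E$B, ek)) / s2e
        if (E$diagA) {
          prec <- diag(E$A) / s2e + 1 / (E$lambda * s2k[k])
          mu <- rhs / prec
          v[[k]] <- mu + rnorm(length(mu)) / sqrt(prec)
        } else {
          P <- E$A / s2e
          diag(P) <- diag(P) + 1 / (E$lambda * s2k[k])
          chP <- chol(P)
          mu <- backsolve(chP, forwardsolve(t(chP), rhs))
          v[[k]] <- drop(mu + backsolve(chP, rnorm(length(mu))))
        }
        newBv <- drop(E$B %*% v[[k]])
        resid <- ek - newBv
        Bv[[k]] <- newBv
        ## sigma_k^2 | v
        ssv <- sum(v[[k]]^2 / E$lambda)
        s2k[k] <- (df0 * Sk[k] + ssv) / rchisq(1L, df0 + length(v[[k]]))
      }

      ## sigmaE^2 | rest
      s2e <- (df0 * Se + sum(resid^2)) / rchisq(1L, df0 + n)
      if (!is.finite(s2e) || s2e > 1e8 * vy || any(!is.finite(s2k)))
        stop(sprintf("Gibbs sampler diverged at iteration %d (s2e=%g)",
          it, s2e))

      if (it > burnIn && (it - burnIn) %% thin == 0L) {
        kept <- kept + 1L
        sumBeta <- sumBeta + beta
        for (k in seq_len(nk)) {
          uk <- drop(eig[[k]]$G %*% v[[k]])
          sumU[[k]] <- sumU[[k]] + uk
          sumU2[[k]] <- sumU2[[k]] + uk^2
        }
        sumFit <- sumFit + drop(Xf %*% beta) + Reduce(`+`, Bv, rep(0, n))
        varSamples[kept, ] <- c(s2k, s2e)
      }
    }

    betaMean <- setNames(sumBeta / kept, colnames(Xf))
    ukMean <- lapply(sumU, function(s) s / kept)
    mcse <- lapply(seq_len(nk), function(k) {
      sqrt(pmax(sumU2[[k]] / kept - ukMean[[k]]^2, 0) / kept)
    })
    vc <- colMeans(varSamples[seq_len(kept), , drop = FALSE])
    kn <- names(kernels)
    if (is.null(kn) || any(kn == ""))
      kn <- sprintf("sigmaU%d2", seq_len(nk) - 1L)
    names(vc) <- c(kn, "sigmaE2")
    u0 <- if (nk) ukMean[[1L]] else numeric(0)
    if (nk && !is.null(rownames(kernels[[1L]]$K)))
      names(u0) <- rownames(kernels[[1L]]$K)
    new("GsFit", beta = betaMean, u = u0, varComp = vc,
      fitted = sumFit / kept, method = "gibbs",
      details = list(uk = ukMean, mcse = mcse,
        samples = varSamples[seq_len(kept), , drop = FALSE],
        chain = chain))
  })
}
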
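## Spectral REML for the single-kernel mixed model
##   y = X b + u + e,  u ~ N(0, K sigmaU2),  e ~ N(0, I sigmaE2).
## Eigendecomposing K reduces the restricted likelihood to a 1-D profile in
## delta = sigmaE2 / sigmaU2, optimized deterministically on log(delta).
## This is the computational core shared by the GWAS null model and GBLUP.

## restricted log-likelihood profile at delta (up to an additive constant)
remlProfile <- function(delta, yr, Xr, d) {
  w <- d + delta                       # eigenvalues of K + delta I
  wi <- 1 / w
  XtWX <- crossprod(Xr, Xr * wi)
  XtWy <- crossprod(Xr, yr * wi)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yr - Xr %*% beta
  rss <- max(sum(r^2 * wi), 1e-300)  # guard exact-fit degeneracy
  n <- length(yr); p <- ncol(Xr)
  -0.5 * ((n - p) * log(rss) + sum(log(w)) + 2 * sum(log(diag(ch))))
}

## full spectral REML solve; K given as eigen decomposition (U, d)
spectralRemlCore <- function(y, X, U, d, logDeltaRange = c(-12, 12)) {
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  opt <- optimize(function(ld) remlProfile(exp(ld), yr, Xr, d),
    interval = logDeltaRange, maximum = TRUE, tol = 1e-9)
  delta <- exp(opt$maximum)
  w <- d + delta
  wi <- 1 / w
  XtWX <- crossprod(Xr, Xr * wi)
  beta <- solve(XtWX, crossprod(Xr, yr * wi))
  r <- yr - Xr %*% beta
  n <- length(y); p <- ncol(X)
  sigmaU2 <- sum(r^2 * wi) / (n - p)
  sigmaE2 <- sigmaU2 * delta
  ## alpha = V^{-1}(y - X beta) with V = sigmaU2 K + sigmaE2 I
  alphaRot <- drop(r) * wi / sigmaU2
  alpha <- drop(U %*% alphaRot)
  u <- sigmaU2 * drop(U %*% (d * alphaRot))
  list(beta = drop(beta), delta = delta, sigmaU2 = sigmaU2,
    sigmaE2 = sigmaE2, alpha = alpha, u = u, logLik = opt$objective,
    U = U, d = d, wi = wi)
}

#' Solve single-kernel GBLUP by spectral REML
#'
#' Deterministic REML for \code{y = Xf b + u + e} with
#' \code{u ~ N(0, K sigmaU2)}: one-dimensional optimization of the
#' restricted likelihood in \code{delta = sigmaE2/sigmaU2} on the
#' eigendecomposition of K, GLS for the fixed effects and BLUP for the
#' genetic values.
#'
#' @param y response, one value per line (names used for the output).
#' @param Xf full-rank fixed-covariate matrix (include the intercept).
#' @param K a \linkS4class{KinshipMatrix} or plain PSD matrix over the same
#'   lines.
#' @return A \linkS4class{GsFit}; \code{details} carries the BLUP weights
#'   \code{alpha = V^{-1}(y - Xf b)} so that genetic values of unphenotyped
#'   lines are \code{sigmaU2 * K[new, train] alpha}.
#' @export
solveGblupReml <- function(y, Xf, K) {
  Km <- if (is(K, "KinshipMatrix")) kinship(K) else K
  n <- length(y)
  if (nrow(Km) != n || nrow(Xf) != n) stop("dimension mismatch")
  if (qr(Xf)$rank < ncol(Xf)) stop("Xf is rank-deficient")
  eg <- eigen(Km, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("K is not positive semi-definite")
  d <- pmax(eg$values, 0)
  sol <- spectralRemlCore(y, Xf, eg$vectors, d)
  beta <- setNames(sol$beta, colnames(Xf))
  u <- setNames(sol$u, names(y))
  fitted <- drop(Xf %*% sol$beta) + sol$u
  new("GsFit", beta = beta, u = u,
    varComp = c(sigmaU2 = sol$sigmaU2, sigmaE2 = sol$sigmaE2),
    fitted = fitted, method = "reml",
    details = list(alpha = sol$alpha, delta = sol$delta,
      logLik = sol$logLik))
}

#' Predict genetic values of new lines from a REML GBLUP fit
#'
#' @param fit a \linkS4class{GsFit} from \code{\link{solveGblupReml}}.
#' @param Kcross relationship matrix block K[new, train].
#' @param XfNew fixed-covariate rows of the new lines.
#' @return Predicted response \code{XfNew b + sigmaU2 Kcross alpha}.
#' @export
predictGblup <- function(fit, Kcross, XfNew) {
  drop(XfNew %*% fit@beta) +
    fit@varComp["sigmaU2"] * drop(Kcross %*% fit@details$alpha)
}
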
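## Multi-environment phenotype analysis: BLUEs, variance components and
## entry-mean heritability. The model is
##   y_ijm = mu + g_i + e_j + ge_ij + delta_(j)m + eps_ijm
## with replicate nested in environment. BLUEs treat genotype as fixed;
## heritability treats every term as random. Fitting is REML through lme4.

phenoFrame <- function(pheno) {
  r <- phenoRecords(pheno)
  data.frame(
    family = factor(r$family),
    env = factor(r$env),
    envRep = factor(paste(r$env, r$rep, sep = ":")),
    value = r$value)
}

quietLmer <- function(formula, data) {
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
        check.conv.grad = lme4::.makeCC("ignore", tol = 1e-3),
        optimizer = "bobyqa", optCtrl = list(rhoend = 1e-13)))))
}

#' Fit the BLUE model (genotype fixed)
#'
#' Fits \code{value ~ 0 + family + (1|env) + (1|family:env) + (1|env:rep)}
#' by REML and reports per-family BLUEs on the observation scale
#' (\code{mu + g_i}), which are invariant to the fixed-effect
#' parameterization. Families with zero observations are dropped with a
#' warning.
#'
#' @param pheno a \linkS4class{PhenotypeTable} with >= 2 environments and
#'   >= 2 families.
#' @return A \linkS4class{BlueResult}.
#' @export
fitBlueModel <- function(pheno) {
  d <- phenoFrame(pheno)
  if (nlevels(d$env) < 2) stop("need >= 2 environments")
  if (nlevels(d$family) < 2) stop("need >= 2 families")
  counts <- table(d$family)
  dropped <- names(counts)[counts == 0]
  if (length(dropped)) {
    warning("dropping families with no observations: ",
      paste(dropped, collapse = ", "))
    d <- droplevels(d[!d$family %in% dropped, ])
  }
  fit <- quietLmer(value ~ 0 + family + (1 | env) + (1 | family:env) +
    (1 | envRep), d)
  b <- lme4::fixef(fit)
  names(b) <- sub("^family", "", names(b))
  new("BlueResult", blues = b[levels(d$family)], mu = mean(b),
    logLik = as.numeric(stats::logLik(fit)), dropped = dropped)
}

#' Estimate variance components (all effects random)
#'
#' Same model as \code{\link{fitBlueModel}} with genotype random; REML
#' estimates with lme4's boundary handling (components pinned at 0).
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @return A \linkS4class{VarianceComponents}.
#' @export
estimateVarianceComponents <- function(pheno) {
  d <- phenoFrame(pheno)
  if (nlevels(d$env) < 2) stop("need >= 2 environments")
  if (var(d$value) == 0)
    return(new("VarianceComponents", sigmaG2 = 0, sigmaGE2 = 0,
      sigmaRep2 = 0, sigmaE2 = 0))
  fit <- quietLmer(value ~ 1 + (1 | family) + (1 | env) + (1 | family:env) +
    (1 | envRep), d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  new("VarianceComponents",
    sigmaG2 = pick("family"), sigmaGE2 = pick("family:env"),
    sigmaRep2 = pick("envRep"), sigmaE2 = pick("Residual"))
}

#' Entry-mean broad-sense heritability
#'
#' \code{H2 = sigmaG2 / (sigmaG2 + sigmaGE2/Ne + sigmaE2/(r*Ne))}, the
#' fraction of variance among family means attributable to genotype for a
#' trial with \code{Ne} environments and \code{r} replicates.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @param Ne number of environments.
#' @param r replicates per environment.
#' @return Heritability in [0, 1].
#' @export
broadSenseHeritability <- function(vc, Ne, r) {
  if (Ne < 1 || r < 1) stop("Ne and r must be >= 1")
  denom <- vc@sigmaG2 + vc@sigmaGE2 / Ne + vc@sigmaE2 / (r * Ne)
  if (denom == 0) stop("heritability undefined: all variance components are zero")
  vc@sigmaG2 / denom
}

#' Per-environment phenotype summary
#'
#' One row per environment: number of families with at least one
#' observation, mean, sd, range and coefficient of variation (100*sd/mean)
#' of the raw observations.
#'
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @return data.frame with columns env, n, mean, sd, min, max, cv.
#' @export
summarizePhenotypes <- function(pheno) {
  r <- phenoRecords(pheno)
  if (nrow(r) == 0) stop("empty phenotype table")
  out <- do.call(rbind, lapply(split(r, r$env), function(e) {
    s <- sd(e$value)
    if (is.na(s)) s <- 0
    data.frame(env = e$env[1], n = length(unique(e$family)),
      mean = mean(e$value), sd = s, min = min(e$value), max = max(e$value),
      cv = if (mean(e$value) == 0) NA_real_ else 100 * s / mean(e$value))
  }))
  rownames(out) <- NULL
  out[order(out$env), ]
}
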
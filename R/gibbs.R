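## Gibbs sampling front end, posterior summaries, accuracies and the
## derived depression statistics.

.asCsc <- function(M) {
  M <- as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  list(p = M@p, i = M@i, x = M@x)
}

#' Fit the bivariate additive + inbreeding-load model by Gibbs sampling
#'
#' Samples the model `y = X theta + Z u + K i + e` with
#' `(u, i) ~ N(0, V (x) H)`, `h ~ N(0, I sigma_h2)`,
#' `p ~ N(0, I sigma_p2)` and flat priors on fixed effects and variance
#' components (implemented as the limiting conjugate full conditionals;
#' the inverse-Wishart degrees of freedom for V are `q - 3 + dfAdjust`
#' with `dfAdjust = 0` by default).  Scalar effects are updated single
#' site; each animal's `(u_j, i_j)` pair is sampled as a joint 2-block
#' using the sparse `H^-1` structure.
#'
#' @param design a `loadDesign` from [assembleDesign()].
#' @param relInv sparse inverse relationship matrix over all animals:
#'   [aInverse()] for a pedigree model or [hInverse()] for single step.
#' @param nIter,burnIn,thin chain settings (defaults 50000 / 10000 / 10).
#' @param seed RNG seed (recommended for reproducibility).
#' @param startV starting V as c(sigma_u2, sigma_ui, sigma_i2); default
#'   scaled from the phenotypic variance.
#' @param startScalars starting c(sigma_h2, sigma_p2, sigma_e2).
#' @param fixedVariances optional list `V`, `sh2`, `sp2`, `se2`; when
#'   given, variances are held fixed (posterior means of the location
#'   effects then solve Henderson's mixed-model equations).
#' @param keepEffects store thinned chains of u and i (memory permitting).
#' @param dfAdjust documented adjustment to the inverse-Wishart degrees
#'   of freedom (default 0).
#' @return a [LoadModelFit-class].
#' @export
fitLoadModel <- function(design, relInv, nIter = 50000, burnIn = 10000, thin = 10,
                         seed = NULL, startV = NULL, startScalars = NULL,
                         fixedVariances = NULL, keepEffects = FALSE, dfAdjust = 0) {
  stopifnot(inherits(design, "loadDesign"))
  if (!is.null(seed)) set.seed(seed)
  q <- design$q
  if (!all(dim(relInv) == c(q, q))) stop("relInv must be q x q over all animals")
  vy <- var(design$y)
  if (is.null(startV)) startV <- c(vy / 4, 0, vy / 2)
  if (is.null(startScalars)) startScalars <- c(vy / 4, vy / 4, vy / 2)
  updateVar <- is.null(fixedVariances)
  if (!updateVar) {
    V <- fixedVariances$V
    startV <- c(V[1, 1], V[1, 2], V[2, 2])
    startScalars <- c(fixedVariances$sh2 %||% 1, fixedVariances$sp2 %||% 1,
      fixedVariances$se2)
  }
  if (startV[1] <= 0 || startV[3] <= 0 || startV[1] * startV[3] - startV[2]^2 <= 0) {
    stop("starting V must be positive definite")
  }
  Kc <- .asCsc(design$K)
  Hc <- .asCsc(relInv)
  hysIdx <- design$hysIdx %||% integer(design$n)
  peIdx <- design$peIdx %||% integer(design$n)
  res <- .gibbs_load_core(
    design$y, design$X, design$zIdx,
    hysIdx, design$nHys %||% 0L, peIdx, design$nPe %||% 0L,
    Kc$p, Kc$i, Kc$x, Hc$p, Hc$i, Hc$x, q,
    as.integer(nIter), as.integer(burnIn), as.integer(thin),
    startV, startScalars[1], startScalars[2], startScalars[3],
    updateVar, keepEffects, dfAdjust)
  samples <- res$samples
  colnames(samples) <- c("sigma_u2", "sigma_ui", "sigma_i2",
    "sigma_h2", "sigma_p2", "sigma_e2", design$coefNames)
  effects <- data.frame(
    id = design$ids,
    uMean = res$uMean, uPSD = res$uPSD,
    iMean = res$iMean, iPSD = res$iPSD,
    stringsAsFactors = FALSE
  )
  new("LoadModelFit",
    samples = samples, effects = effects,
    effectSamples = if (keepEffects) list(u = res$uSamples, i = res$iSamples) else list(),
    mcmc = list(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed,
      nSaved = res$nSaved, dfAdjust = dfAdjust, updateVar = updateVar),
    model = list(trait = design$spec$trait, spec = design$spec,
      n = design$n, q = design$q,
      nHys = design$nHys %||% 0L, nPe = design$nPe %||% 0L))
}

#' Thinned posterior samples
#' @param fit a [LoadModelFit-class]
#' @export
posteriorSamples <- function(fit) fit@samples

#' Per-animal posterior summaries of u and i
#' @param fit a [LoadModelFit-class]
#' @export
effectSummary <- function(fit) fit@effects

#' Highest posterior density interval
#'
#' Shortest interval containing `prob` posterior mass (empirical, from
#' the sorted sample).
#'
#' @param x numeric sample.
#' @param prob coverage (default 0.95).
#' @return numeric c(lower, upper).
#' @export
hpdInterval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[(m + 1L):n] - x[1L:(n - m)]
  j <- which.min(w)
  c(x[j], x[j + m])
}

#' Posterior summaries of variance components and derived parameters
#'
#' Posterior mean, posterior SD and HPD95 for each variance component,
#' the inbreeding-depression regression d (and age coefficient when
#' present), and the derived genetic correlation between additive and
#' load effects.
#'
#' @param fit a [LoadModelFit-class]
#' @return data.frame with rows per parameter.
#' @export
varianceSummary <- function(fit) {
  S <- fit@samples
  keep <- c("sigma_u2", "sigma_ui", "sigma_i2",
    if ((fit@model$nHys %||% 3L) > 2) "sigma_h2",
    if ((fit@model$nPe %||% 0L) > 2) "sigma_p2",
    "sigma_e2", intersect(c("d", "c"), colnames(S)))
  M <- cbind(S[, keep, drop = FALSE],
    corr_ui = S[, "sigma_ui"] / sqrt(S[, "sigma_u2"] * S[, "sigma_i2"]))
  out <- do.call(rbind, lapply(colnames(M), function(p) {
    h <- hpdInterval(M[, p])
    data.frame(parameter = p, mean = mean(M[, p]), psd = sd(M[, p]),
      hpd95Lower = h[1], hpd95Upper = h[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

setMethod("show", "LoadModelFit", function(object) {
  cat("LoadModelFit:", object@model$n, "records,", object@model$q, "animals;",
    object@mcmc$nSaved, "saved samples",
    sprintf("(%d iterations, %d burn-in, thin %d)\n",
      object@mcmc$nIter, object@mcmc$burnIn, object@mcmc$thin))
  vs <- varianceSummary(object)
  print(vs, digits = 4)
  invisible(object)
})

#' Prediction accuracy from the posterior standard deviation
#'
#' `acc = sqrt(1 - PSD^2 / (H_jj sigma2))`, clamped to 0 when the
#' argument is negative (clamping is reported via a warning).  Always in
#' [0, 1].
#'
#' @param psd posterior standard deviation(s) of the effect.
#' @param hjj diagonal element(s) of the H matrix.
#' @param sigma2 posterior-mean variance of the effect (> 0).
#' @return numeric accuracy vector.
#' @export
accuracy <- function(psd, hjj, sigma2) {
  stopifnot(all(sigma2 > 0), all(hjj > 0))
  arg <- 1 - psd^2 / (hjj * sigma2)
  nneg <- sum(arg < 0)
  if (nneg > 0) warning(nneg, " accuracies clamped to 0")
  sqrt(pmax(arg, 0))
}

#' Per-animal accuracies for a fitted load model
#'
#' @param fit a [LoadModelFit-class]
#' @param hDiag diagonal of H per animal (see [hDiagonal()]).
#' @return data.frame `id`, `accU`, `accI`.
#' @export
fitAccuracy <- function(fit, hDiag) {
  S <- fit@samples
  su2 <- mean(S[, "sigma_u2"]); si2 <- mean(S[, "sigma_i2"])
  data.frame(
    id = fit@effects$id,
    accU = accuracy(fit@effects$uPSD, hDiag, su2),
    accI = accuracy(fit@effects$iPSD, hDiag, si2),
    stringsAsFactors = FALSE
  )
}

#' Inbreeding depression as a percentage of the trait mean and SD
#'
#' D%-M = 100 |d| / mean and D%-SD = 100 |d| / SD, applied to the
#' posterior mean of d; the posterior SD of d transforms with the same
#' scale factors.
#'
#' @param dMean posterior mean of the depression regression d (trait
#'   units at F = 1).
#' @param dPSD posterior SD of d.
#' @param traitMean,traitSD phenotypic mean and SD (> 0).
#' @return data.frame `DpctM`, `DpctM_PSD`, `DpctSD`, `DpctSD_PSD`.
#' @export
depressionSummary <- function(dMean, dPSD, traitMean, traitSD) {
  stopifnot(all(traitMean > 0), all(traitSD > 0))
  data.frame(
    DpctM = 100 * abs(dMean) / traitMean,
    DpctM_PSD = 100 * dPSD / traitMean,
    DpctSD = 100 * abs(dMean) / traitSD,
    DpctSD_PSD = 100 * dPSD / traitSD
  )
}

#' Ratio of inbreeding-load variance to phenotypic variance
#'
#' `F^2 sigma_i2 / (sigma_u2 + sigma_h2 + sigma_p2 + sigma_e2)` for an
#' assumed inbreeding coefficient F.  Vectorized, so it can be applied
#' per MCMC sample (the posterior of the ratio) or to posterior means.
#'
#' @param si2,su2,sh2,sp2,se2 variance components (vectors allowed).
#' @param F scenario inbreeding coefficient (default 0.10).
#' @param includeEnv include sigma_h2 and sigma_p2 in the phenotypic
#'   variance denominator (default TRUE).
#' @export
loadVarianceRatio <- function(si2, su2, sh2 = 0, sp2 = 0, se2, F = 0.10,
                              includeEnv = TRUE) {
  denom <- su2 + se2 + if (includeEnv) sh2 + sp2 else 0
  F^2 * si2 / denom
}

#' Heritability from variance components
#'
#' `sigma_u2 / (sigma_u2 + sigma_h2 + sigma_p2 + sigma_e2)`; vectorized.
#'
#' @inheritParams loadVarianceRatio
#' @export
heritability <- function(su2, sh2 = 0, sp2 = 0, se2, includeEnv = TRUE) {
  denom <- su2 + se2 + if (includeEnv) sh2 + sp2 else 0
  su2 / denom
}
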
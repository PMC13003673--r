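# Shared model fixtures: a small simulated fit and the direct
# mixed-model-equation oracle used to validate the Gibbs sampler.

smallFit <- function(seedPed = 7, seedPhe = 8, nIter = 15000, burnIn = 3000,
                     thin = 5, seedChain = 1, fixedVariances = NULL,
                     keepEffects = FALSE, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- simConfig(nFounders = 12, nGenerations = 3, nMatings = 6,
      closeMatingFraction = 0.4, nHys = 4)
  }
  ped <- simulatePedigree(cfg, seed = seedPed)
  pt <- partialInbreeding(ped)
  sim <- simulatePhenotypes(ped, pt, cfg, seed = seedPhe)
  des <- assembleDesign(sim$records, modelSpec(trait = "value", fixed = "sex"), ped, pt)
  fit <- fitLoadModel(des, aInverse(ped), nIter = nIter, burnIn = burnIn,
    thin = thin, seed = seedChain, fixedVariances = fixedVariances,
    keepEffects = keepEffects)
  list(ped = ped, pt = pt, sim = sim, des = des, fit = fit)
}

# Direct solution of Henderson's mixed-model equations at fixed variances.
# Coefficient order: fixed columns, HYS levels, u (all animals), i.
solveMME <- function(des, Ainv, V, sh2, se2) {
  X <- Matrix::Matrix(des$X, sparse = TRUE)
  W <- Matrix::sparseMatrix(i = seq_len(des$n), j = des$hysIdx,
    dims = c(des$n, des$nHys))
  Z <- Matrix::sparseMatrix(i = seq_len(des$n), j = des$zIdx,
    dims = c(des$n, des$q))
  M <- cbind(X, W, Z, des$K)
  lam <- c(rep(0, ncol(des$X)), rep(1 / sh2, des$nHys))
  Vi <- solve(V)
  Pr <- Matrix::bdiag(Matrix::Diagonal(x = lam),
    rbind(cbind(Vi[1, 1] * Ainv, Vi[1, 2] * Ainv),
          cbind(Vi[2, 1] * Ainv, Vi[2, 2] * Ainv)))
  C <- Matrix::crossprod(M) / se2 + Pr
  as.numeric(Matrix::solve(C, Matrix::crossprod(M, des$y) / se2))
}
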
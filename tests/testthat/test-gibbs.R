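# Checks the sampler against closed-form and direct-solve oracles; the
# small simulated fit and the MME oracle live in helper-model.R.

test_that("fixed-variance posterior means solve Henderson's equations", {
  V <- matrix(c(9.27, -11.03, -11.03, 57.97), 2, 2)
  out <- smallFit(nIter = 24000, burnIn = 4000, thin = 5,
    fixedVariances = list(V = V, sh2 = 7.89, se2 = 29.49), keepEffects = TRUE)
  des <- out$des
  sol <- solveMME(des, aInverse(out$ped), V, 7.89, 29.49)
  p <- ncol(des$X) + des$nHys; q <- des$q
  uhat <- sol[p + seq_len(q)]
  ihat <- sol[p + q + seq_len(q)]
  eff <- effectSummary(out$fit)
  seU <- apply(out$fit@effectSamples$u, 2, batchSE)
  seI <- apply(out$fit@effectSamples$i, 2, batchSE)
  expect_lt(max(abs(eff$uMean - uhat) / pmax(seU, 1e-8)), 3.5)
  expect_lt(max(abs(eff$iMean - ihat) / pmax(seI, 1e-8)), 3.5)
  # fixed scalar effects too (d is among them)
  S <- posteriorSamples(out$fit)
  dcol <- match("d", colnames(S))
  expect_lt(abs(mean(S[, "d"]) - sol[match("d", des$coefNames)]) /
    batchSE(S[, "d"]), 3.5)
})

test_that("degenerate known-mean model reproduces the analytic scaled inverse chi-square", {
  set.seed(3)
  n <- 40
  y <- rnorm(n, 0, 2)
  des <- structure(list(
    y = y, X = matrix(numeric(0), n, 0),
    zIdx = rep(1L, n), hysIdx = integer(n), nHys = 0L,
    peIdx = integer(n), nPe = 0L,
    K = Matrix::sparseMatrix(i = integer(0), j = integer(0),
      x = numeric(0), dims = c(n, 0)), f = numeric(n),
    coefNames = character(0), n = n, q = 0L, ids = character(0),
    spec = modelSpec()), class = "loadDesign")
  fit <- fitLoadModel(des, Matrix::Matrix(matrix(numeric(0), 0, 0), sparse = TRUE),
    nIter = 30000, burnIn = 1000, thin = 3, seed = 4, startV = c(1, 0, 1))
  draws <- posteriorSamples(fit)[, "sigma_e2"]
  # flat prior => sigma_e2 | y  =  SSE / chisq(n - 2)
  sse <- sum(y^2)
  ks <- suppressWarnings(stats::ks.test(sse / draws, "pchisq", df = n - 2))
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(draws) - sse / (n - 4)) / sd(draws) * sqrt(length(draws)), 5)
})

test_that("no inbreeding means no information pathway to sigma_ui", {
  cfg <- simConfig(nFounders = 12, nGenerations = 2, nMatings = 6,
    closeMatingFraction = 0, nHys = 4)
  out <- smallFit(cfg = cfg, nIter = 12000, burnIn = 2000)
  expect_equal(sum(abs(out$des$K)), 0)   # no inbred animals at fraction 0
  S <- posteriorSamples(out$fit)
  z <- abs(mean(S[, "sigma_ui"])) / batchSE(S[, "sigma_ui"])
  expect_lt(z, 4)
})

test_that("chains are reproducible bit for bit under the same seed", {
  a <- smallFit(nIter = 4000, burnIn = 1000, seedChain = 5)
  b <- smallFit(nIter = 4000, burnIn = 1000, seedChain = 5)
  expect_identical(posteriorSamples(a$fit), posteriorSamples(b$fit))
  c2 <- smallFit(nIter = 4000, burnIn = 1000, seedChain = 6)
  expect_false(identical(posteriorSamples(a$fit), posteriorSamples(c2$fit)))
})

test_that("accuracy formula: edge cases exact, output clamped to [0, 1]", {
  expect_equal(accuracy(0, 1, 4), 1)
  expect_equal(accuracy(2, 1, 4), 0)                       # PSD^2 = H_jj sigma2
  expect_equal(accuracy(sqrt(0.51), 1, 1), 0.7)
  expect_warning(a <- accuracy(3, 1, 4), "clamped")
  expect_equal(a, 0)
  psd <- runif(50, 0, 3)
  acc <- suppressWarnings(accuracy(psd, rep(1.2, 50), 2.5))
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("accuracy grows with records per animal", {
  cfg1 <- simConfig(nFounders = 12, nGenerations = 3, nMatings = 8,
    closeMatingFraction = 0.3, nHys = 4, recordsPerAnimal = 1)
  cfg5 <- simConfig(nFounders = 12, nGenerations = 3, nMatings = 8,
    closeMatingFraction = 0.3, nHys = 4, recordsPerAnimal = 5)
  V <- matrix(c(9.27, -11.03, -11.03, 57.97), 2, 2)
  fv <- list(V = V, sh2 = 7.89, se2 = 29.49)
  o1 <- smallFit(cfg = cfg1, nIter = 8000, burnIn = 2000, fixedVariances = fv)
  o5 <- smallFit(cfg = cfg5, nIter = 8000, burnIn = 2000, fixedVariances = fv)
  hd1 <- hDiagonal(o1$ped); hd5 <- hDiagonal(o5$ped)
  rec1 <- unique(o1$des$zIdx); rec5 <- unique(o5$des$zIdx)
  a1 <- mean(accuracy(effectSummary(o1$fit)$uPSD[rec1], hd1[rec1], V[1, 1]))
  a5 <- mean(accuracy(effectSummary(o5$fit)$uPSD[rec5], hd5[rec5], V[1, 1]))
  expect_gt(a5, a1)
})

test_that("depression and ratio transforms are plain arithmetic", {
  expect_equal(depressionSummary(0, 0, 10, 2)$DpctM, 0)
  d <- depressionSummary(-2, 0.5, 50, 10)
  expect_equal(d$DpctM, 4)
  expect_equal(d$DpctM_PSD, 1)
  expect_equal(d$DpctSD, 20)
  expect_equal(loadVarianceRatio(si2 = 100, su2 = 300, sh2 = 300, sp2 = 0,
    se2 = 300, F = 1), 1 / 9)
  expect_equal(loadVarianceRatio(si2 = 57.97, su2 = 9.27, se2 = 29.49, F = 0), 0)
  expect_equal(heritability(su2 = 25, sh2 = 25, se2 = 50), 0.25)
})
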
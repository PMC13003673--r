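test_that("pedigree simulation: determinism, close-mating control, forced inbreeding", {
  cfg <- simConfig(nFounders = 16, nGenerations = 3, nMatings = 8,
    closeMatingFraction = 0.5)
  p1 <- simulatePedigree(cfg, seed = 3)
  p2 <- simulatePedigree(cfg, seed = 3)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- simulatePedigree(cfg, seed = 4)
  expect_false(identical(as.data.frame(p1), as.data.frame(p3)))

  # close-mating fraction 0 over 2 generations: all F = 0
  cfg0 <- simConfig(nFounders = 16, nGenerations = 2, nMatings = 8,
    closeMatingFraction = 0)
  expect_equal(max(inbreeding(simulatePedigree(cfg0, seed = 5))), 0)

  # fraction 1 with full-sib matings: generation-2 offspring have F = 0.25
  cfg1 <- simConfig(nFounders = 16, nGenerations = 2, nMatings = 8,
    closeMatingFraction = 1, closeMatingType = "full-sib")
  ped1 <- simulatePedigree(cfg1, seed = 6)
  expect_equal(max(inbreeding(ped1)), 0.25)
  expect_gt(sum(inbreeding(ped1) == 0.25), 0)

  # parent-offspring matings also produce F = 0.25
  cfgp <- simConfig(nFounders = 16, nGenerations = 2, nMatings = 8,
    closeMatingFraction = 1, closeMatingType = "parent-offspring")
  expect_equal(max(inbreeding(simulatePedigree(cfgp, seed = 7))), 0.25)

  # any positive fraction with >= 2 generations guarantees an inbred animal
  cfg2 <- simConfig(nFounders = 16, nGenerations = 2, nMatings = 8,
    closeMatingFraction = 0.05)
  expect_gt(sum(inbreeding(simulatePedigree(cfg2, seed = 8)) > 0), 0)
})

test_that("gene-dropped genotypes: Hardy-Weinberg founders, monomorphic stays, realized inbreeding", {
  # founder-only pedigree: genotype frequencies match binomial sampling
  nf <- 400
  pedF <- pedigree(sprintf("f%03d", 1:nf), rep("0", nf), rep("0", nf))
  cfg <- simConfig(nFounders = nf, nSnp = 60)
  g <- simulateGenotypes(pedF, cfg, seed = 9)
  phat <- colMeans(g$geno) / 2
  se <- sqrt(g$trueFreq * (1 - g$trueFreq) / (2 * nf))
  expect_lt(max(abs(phat - g$trueFreq) / se), 4.5)
  # Hardy-Weinberg heterozygosity
  hobs <- colMeans(g$geno == 1)
  hexp <- 2 * g$trueFreq * (1 - g$trueFreq)
  expect_lt(max(abs(hobs - hexp) / sqrt(hexp * (1 - hexp) / nf)), 4.5)

  # monomorphic founders stay monomorphic everywhere
  cfgM <- simConfig(nFounders = 10, nGenerations = 2, nMatings = 5, nSnp = 5,
    founderFreqRange = c(1, 1))
  pedM <- simulatePedigree(cfgM, seed = 10)
  gM <- simulateGenotypes(pedM, cfgM, seed = 11)
  expect_true(all(gM$geno == 2))

  # full-sib offspring cohort: excess homozygosity ~ F = 0.25
  cfgS <- simConfig(nFounders = 60, nGenerations = 2, nMatings = 30,
    closeMatingFraction = 1, closeMatingType = "full-sib", nSnp = 800)
  pedS <- simulatePedigree(cfgS, seed = 12)
  gS <- simulateGenotypes(pedS, cfgS, seed = 13)
  coh <- which(inbreeding(pedS) == 0.25)
  expect_gt(length(coh), 20)
  het <- rowMeans(gS$geno[coh, ] == 1)
  hexp2 <- mean(2 * gS$trueFreq * (1 - gS$trueFreq))
  Freal <- 1 - mean(het) / hexp2
  expect_lt(abs(Freal - 0.25), 0.05)

  # missingness injection for QC testing
  cfgNA <- simConfig(nFounders = 20, nGenerations = 1, nMatings = 5, nSnp = 50,
    missingRate = 0.2)
  pedNA <- simulatePedigree(cfgNA, seed = 14)
  gNA <- simulateGenotypes(pedNA, cfgNA, seed = 15)
  expect_gt(mean(is.na(gNA$geno)), 0.1)
})

test_that("phenotypes follow the generating equation exactly in the noiseless limit", {
  cfg0 <- simConfig(nFounders = 12, nGenerations = 3, nMatings = 6,
    closeMatingFraction = 0.5,
    V = matrix(c(1e-12, 0, 0, 1e-12), 2), sh2 = 1e-12, se2 = 1e-12,
    d = 0, sexEffect = 0)
  ped <- simulatePedigree(cfg0, seed = 16)
  pt <- partialInbreeding(ped)
  sim <- simulatePhenotypes(ped, pt, cfg0, seed = 17)
  expect_lt(max(abs(sim$records$value - cfg0$mu)), 1e-4)

  # d = -10 and a single F = 0.25 contrast: record sits 2.5 below baseline
  cfgD <- simConfig(nFounders = 12, nGenerations = 2, nMatings = 6,
    closeMatingFraction = 1, closeMatingType = "full-sib",
    V = matrix(c(1e-12, 0, 0, 1e-12), 2), sh2 = 1e-12, se2 = 1e-12,
    d = -10, sexEffect = 0)
  pedD <- simulatePedigree(cfgD, seed = 18)
  simD <- simulatePhenotypes(pedD, partialInbreeding(pedD), cfgD, seed = 19)
  fD <- inbreeding(pedD)[simD$records$animal]
  expect_equal(simD$records$value, unname(cfg0$mu - 10 * fD), tolerance = 1e-4)

  # moment check: var(y) over non-inbred singletons ~ su2 + sh2 + se2
  nf <- 6000
  pedB <- pedigree(c(sprintf("m%04d", 1:(nf / 2)), sprintf("f%04d", 1:(nf / 2)),
    sprintf("o%04d", 1:(nf / 2))),
    c(rep("0", nf), sprintf("m%04d", 1:(nf / 2))),
    c(rep("0", nf), sprintf("f%04d", 1:(nf / 2))),
    sex = c(rep("M", nf / 2), rep("F", nf / 2), rep(c("M", "F"), nf / 4)))
  cfgB <- simConfig(sexEffect = 0, d = 0, nHys = 2000)
  simB <- simulatePhenotypes(pedB, partialInbreeding(pedB), cfgB, seed = 20)
  vy <- var(simB$records$value)
  expected <- cfgB$V[1, 1] + cfgB$sh2 + cfgB$se2
  expect_lt(abs(vy - expected) / expected, 0.05)
})

test_that("genetic effects reproduce V over founder draws", {
  nf <- 10000
  pedF <- pedigree(sprintf("f%05d", 1:nf), rep("0", nf), rep("0", nf))
  V <- matrix(c(9.27, -11.03, -11.03, 57.97), 2, 2)
  set.seed(21)
  gen <- inbredload:::.simulateGeneticEffects(pedF, V)
  expect_lt(abs(var(gen$u) - V[1, 1]) / V[1, 1], 0.05)
  expect_lt(abs(var(gen$i) - V[2, 2]) / V[2, 2], 0.05)
  expect_lt(abs(cor(gen$u, gen$i) - V[1, 2] / sqrt(V[1, 1] * V[2, 2])), 0.05)
})
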
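test_that("non-inbred pedigrees give an empty partial table", {
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  pt <- partialInbreeding(ped)
  expect_equal(nrow(partialTriplets(pt)), 0)
  expect_equal(length(partialMatrix(pt)@x), 0)
})

test_that("full-sib mating splits inbreeding equally between the grandparents", {
  pt <- partialTriplets(partialInbreeding(fullSibPed()))
  expect_equal(nrow(pt), 2)
  expect_setequal(pt$ancestor, c("G1", "G2"))
  expect_equal(pt$partial_F, c(0.125, 0.125))
})

test_that("sire x daughter mating attributes all inbreeding to the sire", {
  pt <- partialTriplets(partialInbreeding(sireDaughterPed()))
  expect_equal(nrow(pt), 1)
  expect_identical(pt$ancestor, "S")
  expect_equal(pt$partial_F, 0.25)
})

test_that("conservation: partial coefficients sum to Meuwissen-Luo F", {
  for (s in 1:6) {
    n <- c(60, 120, 200, 300, 400, 500)[s]
    ped <- randomPed(n, nf = 10, seed = 20 + s)
    pt <- partialInbreeding(ped)
    expect_lt(max(abs(Matrix::rowSums(partialMatrix(pt)) - unname(inbreeding(ped)))), 1e-10)
    expect_true(all(partialMatrix(pt)@x >= 0))
  }
})

test_that("locality: only common ancestors of both parents carry coefficients", {
  for (s in 1:3) {
    ped <- randomPed(100, nf = 8, seed = 40 + s)
    Tm <- as(partialMatrix(partialInbreeding(ped)), "TsparseMatrix")
    anc <- inbredload:::.ancestorSets(sireIndex(ped), damIndex(ped))
    for (k in seq_along(Tm@x)) {
      x <- Tm@i[k] + 1L; j <- Tm@j[k] + 1L
      s1 <- sireIndex(ped)[x]; d1 <- damIndex(ped)[x]
      expect_true(j %in% c(anc[[s1]], s1))
      expect_true(j %in% c(anc[[d1]], d1))
    }
  }
})

test_that("gene-dropping oracle agrees with the exact decomposition", {
  # founders never autozygous
  gd0 <- geneDropInbreeding(pedigree(c("A", "B"), c("0", "0"), c("0", "0")),
    nRep = 100, seed = 1)
  expect_equal(sum(gd0$estimate), 0)

  # known truth on the full-sib example
  ped <- fullSibPed()
  gd <- geneDropInbreeding(ped, nRep = 5e4, seed = 2)
  x <- which(animalIds(ped) == "X")
  for (g in c("G1", "G2")) {
    j <- which(animalIds(ped) == g)
    expect_lt(abs(gd$estimate[x, j] - 0.125), 3 * max(gd$se[x, j], 1e-4))
  }

  # random pedigrees: per-coefficient agreement and per-animal F sums
  for (s in 1:4) {
    ped <- randomPed(30, nf = 6, seed = 50 + s)
    pt <- as.matrix(partialMatrix(partialInbreeding(ped)))
    gd <- geneDropInbreeding(ped, nRep = 2e4, seed = 60 + s)
    sel <- pt > 0 | gd$estimate > 0
    z <- abs(gd$estimate[sel] - pt[sel]) / pmax(gd$se[sel], 1e-4)
    expect_lt(max(z), 4)    # a few hundred simultaneous comparisons
    sums <- rowSums(gd$estimate)
    seF <- sqrt(rowSums(gd$se^2))
    expect_true(all(abs(sums - unname(inbreeding(ped))) <= 3 * pmax(seF, 1e-4)))
  }
})

test_that("K = T(I - P): founder rows pass through, parental rows subtract halves", {
  # non-inbred records give a zero matrix
  ped0 <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  K0 <- buildK(partialInbreeding(ped0), parentMatrix(ped0), c(3L, 3L))
  expect_equal(sum(abs(K0)), 0)
  expect_equal(dim(K0), c(2L, 3L))

  # grandparents are founders: the record row has 0.125 at each
  ped <- fullSibPed()
  K <- buildK(partialInbreeding(ped), parentMatrix(ped),
    which(animalIds(ped) == "X"))
  expect_equal(K[1, "G1"], 0.125)
  expect_equal(K[1, "G2"], 0.125)
  expect_equal(sum(abs(K)), 0.25)

  # G1 with known parents U, V: the row gains -0.0625 at U and V
  pedg <- fullSibPedGrand()
  Kg <- buildK(partialInbreeding(pedg), parentMatrix(pedg),
    which(animalIds(pedg) == "X"))
  expect_equal(Kg[1, "G1"], 0.125)
  expect_equal(Kg[1, "G2"], 0.125)
  expect_equal(Kg[1, "U"], -0.0625)
  expect_equal(Kg[1, "V"], -0.0625)

  expect_error(buildK(partialInbreeding(ped), parentMatrix(pedg), 1L), "dimension")
})

test_that("ancestor summary tallies nonzero columns and global coefficient stats", {
  ped0 <- pedigree(c("A", "B"), c("0", "0"), c("0", "0"))
  s0 <- ancestorSummary(partialInbreeding(ped0), ped0)
  expect_equal(nrow(s0$ancestors), 0)
  expect_equal(s0$coefficients$n, 0)

  ped <- fullSibPed()
  s1 <- ancestorSummary(partialInbreeding(ped), ped)
  expect_setequal(s1$ancestors$id, c("G1", "G2"))
  expect_equal(s1$ancestors$nIndividuals, c(1L, 1L))

  ped2 <- randomPed(150, nf = 10, seed = 77)
  pt <- partialInbreeding(ped2)
  s2 <- ancestorSummary(pt, ped2)
  Tm <- as(partialMatrix(pt), "TsparseMatrix")
  tal <- table(Tm@j + 1L)
  expect_equal(sum(s2$ancestors$nIndividuals), length(Tm@x))
  expect_equal(s2$ancestors$nIndividuals,
    as.integer(tal[match(match(s2$ancestors$id, animalIds(ped2)), as.integer(names(tal)))]))
  expect_equal(s2$coefficients$n, length(Tm@x))
  expect_equal(s2$coefficients$fracBelow001, mean(Tm@x < 0.001))
})
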
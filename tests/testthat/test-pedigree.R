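test_that("pedigree sorting assigns parent-first indices and is permutation invariant", {
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  expect_identical(animalIds(ped), c("A", "B", "C"))

  perms <- list(c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  an <- c("A", "B", "C"); si <- c("0", "0", "A"); da <- c("0", "0", "B")
  for (p in perms) {
    ped2 <- pedigree(an[p], si[p], da[p])
    expect_identical(animalIds(ped2), animalIds(ped))
  }

  # sorting is a pure permutation: record content preserved
  df <- as.data.frame(pedigree(c("X", "M", "F"), c("M", "0", "0"), c("F", "0", "0"),
    birthYear = c(2002, 2000, 2001), sex = c("M", "M", "F")))
  expect_setequal(df$animal, c("X", "M", "F"))
  expect_identical(df$sire[df$animal == "X"], "M")
  expect_identical(df$dam[df$animal == "X"], "F")
})

test_that("invalid pedigrees are rejected with informative errors", {
  expect_error(pedigree(c("A", "A"), c("0", "0"), c("0", "0")), "duplicated")
  expect_error(pedigree(c("C", "A"), c("A", "C"), c("B", "0")), "not present|cycle")
  # C's parent A lists C as its own sire: a two-node cycle
  expect_error(pedigree(c("C", "A", "B"), c("A", "C", "0"), c("B", "0", "0")), "cycle")
  expect_error(pedigree("A", "A", "0"), "cycle")
  expect_error(pedigree(c("A", "B"), c("0", "Z"), c("0", "0")), "Z")
})

test_that("Meuwissen-Luo inbreeding reproduces textbook identities", {
  expect_equal(unname(inbreeding(pedigree(c("A", "B"), c("0", "0"), c("0", "0")))),
    c(0, 0))
  ped <- fullSibPed()
  expect_equal(inbreeding(ped)[["X"]], 0.25)
  expect_equal(inbreeding(sireDaughterPed())[["X"]], 0.25)
  # animals with an unknown parent have F = 0
  ped3 <- pedigree(c("A", "B", "C"), c("0", "A", "A"), c("0", "0", "0"))
  expect_equal(unname(inbreeding(ped3)), c(0, 0, 0))
})

test_that("diag(A) - 1 equals Meuwissen-Luo F on random pedigrees", {
  for (s in 1:4) {
    ped <- randomPed(500, nf = 12, seed = s)
    A <- tabularOracle(sireIndex(ped), damIndex(ped))
    expect_lt(max(abs(diag(A) - 1 - unname(inbreeding(ped)))), 1e-12)
  }
})

test_that("parent matrix P has 0.5 at parent links, row sums in {0, .5, 1}, strictly lower triangular", {
  ped <- pedigree(c("A", "B", "C", "D"), c("0", "0", "A", "A"), c("0", "0", "B", "0"))
  P <- parentMatrix(ped)
  expect_equal(unname(Matrix::diag(P)), rep(0, 4))
  expect_true(all(P[lower.tri(P, diag = TRUE) == FALSE] == 0))  # upper strictly zero
  rs <- unname(Matrix::rowSums(P))
  expect_equal(rs, c(0, 0, 1, 0.5))
  expect_equal(P["C", "A"], 0.5)
  expect_equal(P["C", "B"], 0.5)

  ped2 <- randomPed(120, seed = 9)
  P2 <- parentMatrix(ped2)
  expect_true(all(abs(Matrix::rowSums(P2) * 2 - round(Matrix::rowSums(P2) * 2)) == 0))
  expect_true(all(Matrix::rowSums(P2) <= 1))
  expect_true(Matrix::isTriangular(P2, upper = FALSE))
})

test_that("A-inverse follows Henderson's rules and inverts tabular A", {
  # unrelated non-inbred trio -> identity
  trio <- pedigree(c("A", "B", "C"), rep("0", 3), rep("0", 3))
  expect_equal(as.matrix(aInverse(trio)), diag(3), ignore_attr = TRUE)

  # founder + offspring with one known parent: invert tabular A numerically
  ped1 <- pedigree(c("A", "B"), c("0", "A"), c("0", "0"))
  A1 <- tabularOracle(sireIndex(ped1), damIndex(ped1))
  expect_equal(as.matrix(aInverse(ped1)), solve(A1), ignore_attr = TRUE, tolerance = 1e-10)

  for (s in 1:4) {
    ped <- randomPed(if (s < 3) 50 else 200, nf = 8, seed = 10 + s)
    A <- tabularOracle(sireIndex(ped), damIndex(ped))
    I <- as.matrix(aInverse(ped) %*% A)
    expect_lt(max(abs(I - diag(nrow(A)))), 1e-8)
  }
})

test_that("relationship submatrix matches the tabular oracle on arbitrary subsets", {
  expect_equal(relationshipMatrix(pedigree("A", "0", "0"), "A"),
    matrix(1, 1, 1, dimnames = list("A", "A")))
  # parent and offspring with the other parent unknown
  ped1 <- pedigree(c("A", "B"), c("0", "A"), c("0", "0"))
  expect_equal(unname(relationshipMatrix(ped1, c("A", "B"))[1, 2]), 0.5)
  # full-sib pair
  ped <- fullSibPed()
  A <- relationshipMatrix(ped, c("S", "D"))
  expect_equal(unname(A[1, 2]), 0.5)
  expect_equal(unname(Matrix::diag(A)), c(1, 1))
  expect_error(relationshipMatrix(ped, "nope"), "unknown")

  ped2 <- randomPed(80, seed = 3)
  ids <- animalIds(ped2)[c(5, 40, 77, 63)]
  Afull <- tabularOracle(sireIndex(ped2), damIndex(ped2))
  expect_equal(unname(relationshipMatrix(ped2, ids)),
    unname(Afull[c(5, 40, 77, 63), c(5, 40, 77, 63)]), tolerance = 1e-12)
})

test_that("pedigree statistics report bins and depth", {
  ped <- fullSibPed()
  st <- pedStats(ped)
  expect_equal(st$n, 5)
  expect_equal(st$nInbred, 1)
  expect_equal(sum(st$bins$n), 5)
  expect_equal(st$bins$n[st$bins$bin == "0.2-0.25"], 1)  # F = 0.25 in (0.20, 0.25]
  dp <- pedigreeDepth(ped)
  expect_equal(unname(dp$generations[animalIds(ped) == "X"]), 2)
  expect_equal(min(dp$generations), 0)
})

test_that("pedigree CSV round trip", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(animal = c("X", "M", "F"), sire = c("M", "0", ""),
    dam = c("F", "0", "0"), birth_year = c(2002, 2000, 2000),
    sex = c("male", "M", "F")), f, row.names = FALSE)
  ped <- readPedigree(f)
  expect_equal(nAnimals(ped), 3)
  expect_identical(animalIds(ped)[3], "X")
  unlink(f)
})
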
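# Small fixture pedigrees and independent oracles used across tests.

# Full-sib mating: S and D are full sibs out of founders G1 x G2; X = S x D.
fullSibPed <- function() {
  pedigree(c("G1", "G2", "S", "D", "X"),
           c("0", "0", "G1", "G1", "S"),
           c("0", "0", "G2", "G2", "D"))
}

# As above but G1 has known founder parents U and V.
fullSibPedGrand <- function() {
  pedigree(c("U", "V", "G1", "G2", "S", "D", "X"),
           c("0", "0", "U", "0", "G1", "G1", "S"),
           c("0", "0", "V", "0", "G2", "G2", "D"))
}

# Sire x daughter: D = S x U (U unrelated founder); X = S x D.
sireDaughterPed <- function() {
  pedigree(c("S", "U", "D", "X"),
           c("0", "0", "S", "S"),
           c("0", "0", "U", "D"))
}

# Random sorted pedigree: first nf founders, then each animal draws two
# distinct earlier parents.  Produces plenty of inbreeding.
randomPed <- function(n, nf = 10, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(0L, n)
  for (x in (nf + 1L):n) {
    sire[x] <- sample.int(x - 1L, 1L)
    repeat {
      dam[x] <- sample.int(x - 1L, 1L)
      if (dam[x] != sire[x]) break
    }
  }
  pedigree(sprintf("id%03d", 1:n), ifelse(sire == 0L, "0", sprintf("id%03d", sire)),
           ifelse(dam == 0L, "0", sprintf("id%03d", dam)))
}

# Independent tabular-method oracle for A (plain R, quadratic loop),
# written directly from the recurrence a_xy = (a_{sx,y} + a_{dx,y})/2,
# a_xx = 1 + a_{sx,dx}/2.
tabularOracle <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (x in seq_len(n)) {
    s <- sire[x]; d <- dam[x]
    if (x > 1) {
      for (y in seq_len(x - 1)) {
        v <- 0
        if (s > 0) v <- v + 0.5 * A[s, y]
        if (d > 0) v <- v + 0.5 * A[d, y]
        A[x, y] <- A[y, x] <- v
      }
    }
    A[x, x] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

# Batch-means Monte Carlo standard error of a chain mean.
batchSE <- function(v, nBatch = 30) {
  m <- length(v) %/% nBatch
  mb <- colMeans(matrix(v[seq_len(nBatch * m)], m))
  sd(mb) / sqrt(nBatch)
}
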
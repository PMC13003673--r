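## Synthetic data with exactly the statistical structure of the load
## model: multi-generation pedigrees with close matings, gene-dropped
## biallelic genotypes, and phenotypes drawn from
## y = f d + t c + X b + W h + Z u + K i + (L p) + e with
## (u, i) ~ N(0, V (x) A).

#' Simulation configuration
#'
#' Defaults mirror a desk-scale beef-cattle design: the variance preset
#' follows the magnitudes reported for birth weight in the Rubia Gallega
#' population (sigma_u2 9.27, sigma_ui -11.03, sigma_i2 57.97,
#' sigma_h2 7.89, sigma_e2 29.49, d -1.20 on the F = 1 scale, phenotypic
#' mean 42.65), and the pedigree design (40 founders, 6 discrete
#' generations, 25 matings of 2 offspring per generation, close-mating
#' fraction 0.30) produces a mean inbreeding coefficient near the 0.04
#' reported for that population.
#'
#' @param nFounders,nGenerations,nMatings,offspringPerMating pedigree
#'   design (founders split evenly by sex; discrete generations).
#' @param closeMatingFraction fraction of matings between close
#'   relatives.
#' @param closeMatingType type of close mating: "full-sib",
#'   "parent-offspring" (a female mated back to her own sire, the
#'   pattern produced by heavy use of popular sires) or "mixed"
#'   (default, an even mixture).
#' @param nSnp,nChrom,founderFreqRange genotype design; founder allele
#'   frequencies are drawn uniformly from the range.
#' @param missingRate genotype missingness injected for QC testing.
#' @param genotypedFraction fraction of animals genotyped.
#' @param V 2x2 genetic (co)variance matrix of (u, i).
#' @param sh2,sp2,se2 HYS, permanent-environment and residual variances.
#' @param d,cAge inbreeding-depression and age regression coefficients.
#' @param mu,sexEffect overall mean and additive effect of male sex.
#' @param nHys number of herd-year-season levels.
#' @param recordsPerAnimal records per phenotyped animal (> 1 implies a
#'   repeated-records design with a permanent environmental effect).
#' @return a `simConfig` list.
#' @export
simConfig <- function(nFounders = 40, nGenerations = 6, nMatings = 25,
                      offspringPerMating = 2, closeMatingFraction = 0.30,
                      closeMatingType = c("mixed", "full-sib", "parent-offspring"),
                      nSnp = 500, nChrom = 5, founderFreqRange = c(0.1, 0.9),
                      missingRate = 0, genotypedFraction = 1,
                      V = matrix(c(9.27, -11.03, -11.03, 57.97), 2, 2),
                      sh2 = 7.89, sp2 = 0, se2 = 29.49,
                      d = -1.20, cAge = 0, mu = 42.65, sexEffect = 2,
                      nHys = 20, recordsPerAnimal = 1) {
  closeMatingType <- match.arg(closeMatingType)
  stopifnot(V[1, 1] > 0, V[2, 2] > 0, V[1, 1] * V[2, 2] - V[1, 2]^2 > 0,
    closeMatingFraction >= 0, closeMatingFraction <= 1,
    missingRate >= 0, missingRate < 1)
  structure(as.list(environment()), class = "simConfig")
}

#' Simulate a multi-generation pedigree with close matings
#'
#' Discrete generations of females; each mating is, with probability
#' `closeMatingFraction`, a close mating -- a full-sib pair from the
#' previous generation, or a female mated back to her own sire (the
#' pattern created by the heavy use of popular sires, which concentrates
#' partial inbreeding on single ancestors) -- and otherwise a mating
#' between members of different sibships.  When the fraction is positive
#' and there are at least two generations, at least one close mating is
#' forced, so the pedigree contains inbred animals.
#'
#' @param cfg a [simConfig()].
#' @param seed RNG seed.
#' @return a [Pedigree-class].
#' @export
simulatePedigree <- function(cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- cfg$nFounders
  animal <- paste0("F", seq_len(nf))
  sire <- dam <- rep("0", nf)
  sex <- rep(c("M", "F"), length.out = nf)
  year <- rep(2000L, nf)
  sireOf <- setNames(rep(NA_character_, nf), animal)
  damOf <- setNames(rep(NA_character_, nf), animal)
  prevIds <- animal; prevSex <- sex
  counter <- nf
  pFullSib <- switch(cfg$closeMatingType, "full-sib" = 1, "parent-offspring" = 0, 0.5)
  for (g in seq_len(cfg$nGenerations)) {
    males <- prevIds[prevSex == "M"]
    females <- prevIds[prevSex == "F"]
    if (!length(males) || !length(females)) break
    sibKey <- paste(sireOf[prevIds], damOf[prevIds], sep = "|")
    nm <- cfg$nMatings
    close <- runif(nm) < cfg$closeMatingFraction
    if (cfg$closeMatingFraction > 0 && !any(close)) close[1L] <- TRUE
    newA <- newS <- newD <- newX <- character(0)
    for (k in seq_len(nm)) {
      pair <- NULL
      if (close[k]) {
        wantSib <- runif(1) < pFullSib
        if (!wantSib) {
          # mate a female back to her own (possibly older) sire
          dtr <- females[!is.na(sireOf[females])]
          if (length(dtr)) {
            dchoice <- if (length(dtr) > 1) sample(dtr, 1L) else dtr
            pair <- c(sireOf[[dchoice]], dchoice)
          }
        }
        if (is.null(pair)) {
          # full-sib pair: a previous-generation sibship with both sexes
          ok <- which(!is.na(sireOf[prevIds]))
          if (length(ok)) {
            tab <- split(ok, sibKey[ok])
            tab <- tab[vapply(tab, function(ix) any(prevSex[ix] == "M") &&
              any(prevSex[ix] == "F"), logical(1))]
            if (length(tab)) {
              ix <- tab[[sample.int(length(tab), 1L)]]
              pair <- c(sample(prevIds[ix][prevSex[ix] == "M"], 1L),
                        sample(prevIds[ix][prevSex[ix] == "F"], 1L))
            }
          }
        }
        if (is.null(pair)) {
          # sire x daughter fallback when no sibship is available
          dtr <- females[!is.na(sireOf[females])]
          if (length(dtr)) {
            dchoice <- if (length(dtr) > 1) sample(dtr, 1L) else dtr
            pair <- c(sireOf[[dchoice]], dchoice)
          }
        }
      }
      if (is.null(pair)) {
        s <- if (length(males) > 1) sample(males, 1L) else males
        # avoid accidental full- and half-sib pairs in "unrelated" matings
        shareS <- !is.na(sireOf[females]) & !is.na(sireOf[[s]]) &
          sireOf[females] == sireOf[[s]]
        shareD <- !is.na(damOf[females]) & !is.na(damOf[[s]]) &
          damOf[females] == damOf[[s]]
        cand <- females[!shareS & !shareD]
        if (!length(cand)) cand <- females
        pair <- c(s, if (length(cand) > 1) sample(cand, 1L) else cand)
      }
      for (o in seq_len(cfg$offspringPerMating)) {
        counter <- counter + 1L
        id <- paste0("A", counter)
        newA <- c(newA, id)
        newS <- c(newS, pair[1L]); newD <- c(newD, pair[2L])
        newX <- c(newX, if (o %% 2L == 1L) "M" else "F")
        sireOf[id] <- pair[1L]; damOf[id] <- pair[2L]
      }
    }
    animal <- c(animal, newA); sire <- c(sire, newS); dam <- c(dam, newD)
    sex <- c(sex, newX); year <- c(year, rep(2000L + g, length(newA)))
    prevIds <- newA; prevSex <- newX
  }
  pedigree(animal, sire, dam, birthYear = year, sex = sex)
}

#' Simulate gene-dropped biallelic genotypes
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies
#' (uniform over `founderFreqRange`); descendants inherit one allele per
#' SNP from each parent (unlinked gene dropping).  Optional missingness
#' is injected for QC testing.
#'
#' @param ped a [Pedigree-class].
#' @param cfg a [simConfig()].
#' @param seed RNG seed.
#' @return list: `geno` (matrix with NA for missing), `map`, `trueFreq`
#'   (founder frequencies), `genotypedIds`.
#' @export
simulateGenotypes <- function(ped, cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nAnimals(ped)
  m <- cfg$nSnp
  p <- runif(m, cfg$founderFreqRange[1], cfg$founderFreqRange[2])
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (x in seq_len(n)) {
    s <- ped@sire[x]; d <- ped@dam[x]
    h1[x, ] <- if (s > 0L) {
      pick <- runif(m) < 0.5
      ifelse(pick, h1[s, ], h2[s, ])
    } else rbinom(m, 1L, p)
    h2[x, ] <- if (d > 0L) {
      pick <- runif(m) < 0.5
      ifelse(pick, h1[d, ], h2[d, ])
    } else rbinom(m, 1L, p)
  }
  geno <- h1 + h2
  storage.mode(geno) <- "double"
  if (cfg$missingRate > 0) geno[runif(length(geno)) < cfg$missingRate] <- NA_real_
  rownames(geno) <- ped@id
  colnames(geno) <- paste0("snp", seq_len(m))
  perChrom <- ceiling(m / cfg$nChrom)
  map <- data.frame(
    snp = colnames(geno),
    chrom = rep(seq_len(cfg$nChrom), each = perChrom)[seq_len(m)],
    pos = as.integer(((seq_len(m) - 1L) %% perChrom + 1L) * 50000L),
    stringsAsFactors = FALSE
  )
  ng <- round(cfg$genotypedFraction * n)
  genotypedIds <- if (ng >= n) ped@id else sort(sample(ped@id, ng))
  list(geno = geno, map = map, trueFreq = p, genotypedIds = genotypedIds)
}

## (u, i) ~ N(0, V (x) A) by the pedigree recursion: each animal's pair
## is the parent average plus a bivariate Mendelian sampling deviate
## with covariance msv_x * V.
.simulateGeneticEffects <- function(ped, V) {
  n <- nAnimals(ped)
  L <- t(chol(V))
  u <- numeric(n); iv <- numeric(n)
  for (x in seq_len(n)) {
    s <- ped@sire[x]; d <- ped@dam[x]
    pa <- c(0, 0)
    if (s > 0L) pa <- pa + 0.5 * c(u[s], iv[s])
    if (d > 0L) pa <- pa + 0.5 * c(u[d], iv[d])
    ms <- sqrt(ped@msv[x]) * as.numeric(L %*% rnorm(2))
    u[x] <- pa[1] + ms[1]
    iv[x] <- pa[2] + ms[2]
  }
  list(u = u, i = iv)
}

#' Simulate phenotypes under the load model
#'
#' Draws `(u, i) ~ N(0, V (x) A)` by the pedigree Cholesky recursion,
#' HYS (and optional permanent-environment) effects from their scalar
#' variances, and assembles records exactly as
#' `y = mu + sex + f d + t c + h + u + K i + p + e`, where K = T(I - P)
#' links each record to the loads of the ancestors responsible for its
#' animal's inbreeding.  Records are generated for all non-founders.
#'
#' @param ped a [Pedigree-class].
#' @param partial a [PartialInbreeding-class] for the same pedigree.
#' @param cfg a [simConfig()].
#' @param spec a [modelSpec()]; defaults to the base model with sex.
#' @param seed RNG seed.
#' @return list: `records` (data.frame `animal`, `value`, `sex`, `hys`,
#'   `age`) and `truth` (u, i, h, e and the generating parameters).
#' @export
simulatePhenotypes <- function(ped, partial, cfg = simConfig(),
                               spec = modelSpec(trait = "value", fixed = "sex"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nAnimals(ped)
  gen <- .simulateGeneticEffects(ped, cfg$V)
  h <- rnorm(cfg$nHys, 0, sqrt(cfg$sh2))
  recAnimals <- rep(which(ped@sire > 0L | ped@dam > 0L),
    each = max(1L, cfg$recordsPerAnimal))
  if (!length(recAnimals)) stop("no non-founder animals to record")
  nr <- length(recAnimals)
  hys <- sample.int(cfg$nHys, nr, replace = TRUE)
  age <- round(rnorm(nr, 212, 19))
  sexv <- ped@sex[recAnimals]
  sexv[is.na(sexv)] <- "F"
  f <- ped@inbreeding[recAnimals]
  K <- buildK(partial, parentMatrix(ped), recAnimals)
  pe <- if (cfg$recordsPerAnimal > 1 && cfg$sp2 > 0) {
    rnorm(n, 0, sqrt(cfg$sp2))
  } else numeric(n)
  e <- rnorm(nr, 0, sqrt(cfg$se2))
  y <- cfg$mu + ifelse(sexv == "M", cfg$sexEffect, 0) + f * cfg$d +
    (if (isTRUE(spec$ageCovariate)) (age - mean(age)) * cfg$cAge else 0) +
    h[hys] + gen$u[recAnimals] + as.numeric(K %*% gen$i) +
    pe[recAnimals] + e
  records <- data.frame(
    animal = ped@id[recAnimals], value = y, sex = sexv, hys = hys, age = age,
    stringsAsFactors = FALSE
  )
  list(records = records,
    truth = list(u = gen$u, i = gen$i, h = h, e = e, pe = pe,
      V = cfg$V, sh2 = cfg$sh2, sp2 = cfg$sp2, se2 = cfg$se2,
      d = cfg$d, cAge = cfg$cAge, mu = cfg$mu, sexEffect = cfg$sexEffect))
}

#' Reference simulation design for load-model recovery studies
#'
#' The frozen study conditions used by the package's parameter-recovery
#' checks: the birth-weight-magnitude variance preset combined with a
#' deliberately informative breeding design -- heavy use of popular
#' sires (parent-offspring close matings at fraction 0.85) over seven
#' generations, with repeated records -- so that the inbreeding-load
#' variance and its genetic correlation with the additive effect are
#' identifiable at desk scale (about 1,300 animals and 5,000 records,
#' mean F near 0.28).
#'
#' @return a [simConfig()] list.
#' @export
recoveryDesign <- function() {
  simConfig(nFounders = 40, nGenerations = 7, nMatings = 60,
    offspringPerMating = 3, closeMatingFraction = 0.85,
    closeMatingType = "parent-offspring", recordsPerAnimal = 4)
}
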
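## Genotype QC, VanRaden G and the single-step H-inverse.

#' Read genotype and map files
#'
#' Genotype file: CSV with a header of SNP names and rows
#' `animal,g1,...,gm`; genotypes coded 0/1/2, missing as `5` or `NA`.
#' Map file: CSV with columns `snp`, `chrom`, `pos`.
#'
#' @param genoFile,mapFile paths.
#' @return list with `geno` (matrix, NA for missing), `map` (data.frame).
#' @export
readGenotypes <- function(genoFile, mapFile) {
  df <- read.csv(genoFile, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  geno <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(geno) <- "double"
  geno[geno == 5] <- NA_real_
  rownames(geno) <- ids
  map <- read.csv(mapFile, stringsAsFactors = FALSE)
  need <- c("snp", "chrom", "pos")
  if (!all(need %in% names(map))) stop("map file must have columns: ", paste(need, collapse = ", "))
  if (!all(colnames(geno) %in% map$snp)) stop("map does not cover all SNP columns")
  map <- map[match(colnames(geno), map$snp), , drop = FALSE]
  list(geno = geno, map = map)
}

#' Genotype quality control
#'
#' Applies filters in order: autosome only, SNP call rate >= `callRate`,
#' MAF filter with strict exclusion (a SNP with MAF exactly equal to
#' `maf` is retained).  Remaining missing genotypes are imputed to twice
#' the allele frequency (which preserves column means) and frequencies
#' are recomputed after imputation.  Deterministic and idempotent.
#'
#' @param geno matrix of allele counts with NA (or 5) for missing.
#' @param map data.frame `snp`, `chrom`, `pos` covering the columns.
#' @param callRate minimum SNP call rate (default 0.95).
#' @param maf exclusion threshold: SNPs with MAF < `maf` are removed
#'   (default 0.05).
#' @param autosomes chromosome labels treated as autosomal; by default
#'   any chromosome whose label is a number.
#' @param freq optional known allele frequencies (per input SNP); by
#'   default estimated from the observed genotypes.
#' @return a [GenotypeData-class] with a QC report in `qcReport()`.
#' @export
qcGenotypes <- function(geno, map, callRate = 0.95, maf = 0.05,
                        autosomes = NULL, freq = NULL) {
  if (is.list(geno) && !is.matrix(geno)) { map <- geno$map; geno <- geno$geno }
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno))
  geno[geno == 5] <- NA_real_
  m0 <- ncol(geno)
  if (is.null(autosomes)) {
    keepAuto <- !is.na(suppressWarnings(as.numeric(as.character(map$chrom))))
  } else {
    keepAuto <- map$chrom %in% autosomes
  }
  nAuto <- sum(!keepAuto)
  geno <- geno[, keepAuto, drop = FALSE]
  map <- map[keepAuto, , drop = FALSE]
  if (!is.null(freq)) freq <- freq[keepAuto]

  cr <- colMeans(!is.na(geno))
  keepCR <- cr >= callRate
  nCR <- sum(!keepCR)
  geno <- geno[, keepCR, drop = FALSE]
  map <- map[keepCR, , drop = FALSE]
  if (!is.null(freq)) freq <- freq[keepCR]

  p <- if (is.null(freq)) colMeans(geno, na.rm = TRUE) / 2 else freq
  mafv <- pmin(p, 1 - p)
  keepMAF <- mafv >= maf            # strict "< maf" exclusion
  nMAF <- sum(!keepMAF)
  geno <- geno[, keepMAF, drop = FALSE]
  map <- map[keepMAF, , drop = FALSE]
  p <- p[keepMAF]
  if (!ncol(geno)) stop("all SNPs removed by quality control")

  miss <- is.na(geno)
  if (any(miss)) {
    imp <- matrix(rep(2 * p, each = nrow(geno)), nrow(geno))
    geno[miss] <- imp[miss]
  }
  if (is.null(freq)) p <- colMeans(geno) / 2   # recompute after imputation

  rownames(map) <- NULL
  new("GenotypeData",
    geno = geno, id = rownames(geno), map = map, freq = as.numeric(p),
    qc = list(input = m0, removedNonAutosomal = nAuto, removedCallRate = nCR,
      removedMAF = nMAF, retained = ncol(geno), nAnimals = nrow(geno),
      imputed = sum(miss)))
}

#' @describeIn qcGenotypes QC report accessor
#' @param x a [GenotypeData-class]
#' @export
qcReport <- function(x) x@qc

#' Allele frequencies of a GenotypeData object
#' @param x a [GenotypeData-class]
#' @export
alleleFreq <- function(x) setNames(x@freq, x@map$snp)

#' Marker map of a GenotypeData object
#' @param x a [GenotypeData-class]
#' @export
markerMap <- function(x) x@map

#' Centered gene-content matrix W_g
#'
#' Allele counts minus twice the allele frequency per SNP; columns have
#' zero mean when frequencies are estimated from the data.
#' @param x a [GenotypeData-class]
#' @export
centeredGenotypes <- function(x) sweep(x@geno, 2L, 2 * x@freq, "-")

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@geno), "animals x", ncol(object@geno), "SNPs",
      sprintf("(QC removed %d non-autosomal, %d call-rate, %d MAF)\n",
        object@qc$removedNonAutosomal %||% 0L, object@qc$removedCallRate %||% 0L,
        object@qc$removedMAF %||% 0L))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' VanRaden genomic relationship matrix
#'
#' `G = W_g W_g' / sum_j 2 p_j (1 - p_j)` with W_g the centered gene
#' contents.  Rows of G sum to zero when the frequencies are estimated
#' from the genotyped sample (centering removes the column means).
#'
#' @param x a [GenotypeData-class], or a genotype matrix.
#' @param freq allele frequencies if `x` is a bare matrix.
#' @return dense symmetric G with animal dimnames.
#' @export
vanRadenG <- function(x, freq = NULL) {
  if (is(x, "GenotypeData")) { geno <- x@geno; freq <- x@freq } else geno <- x
  if (is.null(freq)) freq <- colMeans(geno) / 2
  k <- sum(2 * freq * (1 - freq))
  if (k <= 0) stop("zero VanRaden denominator: all markers are monomorphic")
  W <- sweep(geno, 2L, 2 * freq, "-")
  G <- tcrossprod(W) / k
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

#' Single-step H-inverse
#'
#' Combines the pedigree A-inverse with genomic information on the
#' genotyped subset: `H^-1 = A^-1 + [0 0; 0 Gs^-1 - A22^-1]` on the
#' genotyped indices, where `Gs = (1 - blend) G + blend A22` (default
#' blend 0.05, standard single-step practice) optionally rescaled so
#' that its mean diagonal and mean off-diagonal match A22 (`tune`).
#'
#' @param Ainv sparse A-inverse over all animals ([aInverse()]).
#' @param A22 pedigree relationship block of the genotyped animals.
#' @param G genomic relationship matrix (same order as A22).
#' @param genoIdx integer internal indices of the genotyped animals.
#' @param blend weight on A22 in the blended Gs (default 0.05).
#' @param tune logical; rescale Gs to match A22 means (default FALSE).
#' @return sparse symmetric H-inverse.
#' @export
hInverse <- function(Ainv, A22, G, genoIdx, blend = 0.05, tune = FALSE) {
  n <- nrow(Ainv)
  genoIdx <- as.integer(genoIdx)
  if (!length(genoIdx)) return(Ainv)
  if (any(genoIdx < 1L | genoIdx > n)) stop("genotyped indices outside pedigree")
  m <- length(genoIdx)
  if (!all(dim(G) == m) || !all(dim(A22) == m)) stop("A22 and G must match the genotyped set")
  Gs <- (1 - blend) * G + blend * A22
  if (tune) {
    mdA <- mean(diag(A22)); moA <- (sum(A22) - sum(diag(A22))) / (m * (m - 1))
    mdG <- mean(diag(Gs)); moG <- (sum(Gs) - sum(diag(Gs))) / (m * (m - 1))
    b <- (mdA - moA) / (mdG - moG)
    a <- mdA - b * mdG
    Gs <- a + b * Gs
  }
  Gsi <- tryCatch(solve(Gs), error = function(e) {
    stop("blended genomic matrix is singular; increase the blend weight")
  })
  A22i <- solve(A22)
  blockDelta <- Gsi - A22i
  Delta <- sparseMatrix(
    i = rep(genoIdx, times = m), j = rep(genoIdx, each = m),
    x = as.numeric(blockDelta), dims = c(n, n), dimnames = dimnames(Ainv))
  Ainv + Delta
}

#' Approximate diagonal of the single-step H matrix
#'
#' `1 + F` for non-genotyped animals and the diagonal of the blended
#' genomic matrix for genotyped ones; an approximation adequate for the
#' accuracy formula at desk scale.
#'
#' @param ped a [Pedigree-class]
#' @param G genomic relationship matrix of the genotyped animals (optional).
#' @param genoIdx internal indices of genotyped animals.
#' @param blend blend weight used when building H-inverse.
#' @return numeric vector of H diagonal values per animal.
#' @export
hDiagonal <- function(ped, G = NULL, genoIdx = integer(0), blend = 0.05) {
  dH <- 1 + ped@inbreeding
  if (!is.null(G) && length(genoIdx)) {
    A22 <- relationshipMatrix(ped, genoIdx)
    dH[genoIdx] <- diag((1 - blend) * G + blend * A22)
  }
  setNames(dH, ped@id)
}
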
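## Mendelian decomposition of inbreeding into per-ancestor partial
## coefficients, the gene-dropping validation oracle, K = T(I - P), and
## ancestor-contribution summaries.

## Ancestor index sets (including self) per animal, as a list of sorted
## integer vectors.  Desk-scale O(n * ancestors).
.ancestorSets <- function(sire, dam) {
  n <- length(sire)
  anc <- vector("list", n)
  for (x in seq_len(n)) {
    s <- sire[x]; d <- dam[x]
    as <- if (s > 0L) c(anc[[s]], s) else integer(0)
    ad <- if (d > 0L) c(anc[[d]], d) else integer(0)
    anc[[x]] <- sort.int(unique(c(as, ad)))
  }
  anc
}

#' Mendelian decomposition of inbreeding into partial coefficients
#'
#' Splits each animal's inbreeding coefficient F_x into per-ancestor
#' parts F_x^(j): the probability that the two alleles of x are identical
#' by descent with the shared copy created by ancestor j's Mendelian
#' sampling.  For each candidate ancestor (a common ancestor of the
#' parents of at least one inbred animal) a partial-kinship tabular
#' recursion is propagated through the descendant pedigree; the
#' coefficient of x for ancestor j is the partial coancestry of x's
#' parents.  The decomposition is exact: for every animal,
#' `sum_j F_x^(j) = F_x` to numerical precision, and it agrees with the
#' [geneDropInbreeding()] Monte Carlo oracle.
#'
#' All positive coefficients are stored without truncation so that the
#' conservation identity holds exactly.
#'
#' @param ped a [Pedigree-class]
#' @return a [PartialInbreeding-class] object.
#' @examples
#' ped <- pedigree(c("G1","G2","S","D","X"), c(0,0,"G1","G1","S"),
#'                 c(0,0,"G2","G2","D"))
#' partialTriplets(partialInbreeding(ped))
#' @export
partialInbreeding <- function(ped) {
  n <- nAnimals(ped)
  Fv <- ped@inbreeding
  inbred <- which(Fv > 0)
  if (!length(inbred)) {
    Tm <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
      dims = c(n, n), dimnames = list(ped@id, ped@id))
    return(new("PartialInbreeding", T = Tm, id = ped@id))
  }
  anc <- .ancestorSets(ped@sire, ped@dam)
  cand <- sort.int(unique(unlist(lapply(inbred, function(x) {
    s <- ped@sire[x]; d <- ped@dam[x]
    intersect(c(anc[[s]], s), c(anc[[d]], d))   # ancestors-or-self of each parent
  }))))
  tri <- .partial_inbreeding_cpp(ped@sire, ped@dam, as.integer(cand), as.integer(inbred))
  Tm <- sparseMatrix(i = tri$i, j = tri$j, x = tri$x, dims = c(n, n),
    dimnames = list(ped@id, ped@id))
  rs <- Matrix::rowSums(Tm)
  if (max(abs(rs - Fv)) > 1e-8) {
    stop("internal error: partial coefficients do not sum to inbreeding coefficients")
  }
  new("PartialInbreeding", T = Tm, id = ped@id)
}

#' Sparse matrix of partial inbreeding coefficients
#' @param x a [PartialInbreeding-class]
#' @return `dgCMatrix` T with T[x, j] = F_x^(j).
#' @export
partialMatrix <- function(x) x@T

#' Partial coefficients as (individual, ancestor, F) triplets
#'
#' @param x a [PartialInbreeding-class]
#' @param labels return animal labels (default) or internal indices.
#' @return data.frame `individual`, `ancestor`, `partial_F`, sorted by
#'   individual then ancestor.
#' @export
partialTriplets <- function(x, labels = TRUE) {
  Tm <- as(x@T, "TsparseMatrix")
  ord <- order(Tm@i, Tm@j)
  i <- Tm@i[ord] + 1L
  j <- Tm@j[ord] + 1L
  data.frame(
    individual = if (labels) x@id[i] else i,
    ancestor = if (labels) x@id[j] else j,
    partial_F = Tm@x[ord],
    stringsAsFactors = FALSE
  )
}

setMethod("show", "PartialInbreeding", function(object) {
  nz <- length(object@T@x)
  cat("PartialInbreeding:", nz, "partial coefficients,",
      length(unique(as(object@T, "TsparseMatrix")@j)), "ancestors,",
      sum(Matrix::rowSums(object@T) > 0), "inbred individuals\n")
  invisible(object)
})

#' Gene-dropping Monte Carlo estimate of partial inbreeding
#'
#' Drops uniquely labelled allele copies through the pedigree.  In each
#' replicate an animal is autozygous when its two allele-copy lineages
#' share a node, and the event is attributed to the individual containing
#' the first shared node.  Event frequencies estimate the partial
#' inbreeding coefficients; their sum per animal estimates F.
#'
#' @param ped a [Pedigree-class]
#' @param nRep number of replicates (>= 1).
#' @param seed optional RNG seed.
#' @return list with `estimate` and `se` (dense animal x ancestor
#'   matrices, binomial standard errors) and `nRep`.
#' @seealso [partialInbreeding()] for the exact decomposition.
#' @export
geneDropInbreeding <- function(ped, nRep = 1e5, seed = NULL) {
  stopifnot(nRep >= 1)
  if (!is.null(seed)) set.seed(seed)
  inbred <- which(ped@inbreeding > 0)
  counts <- .gene_drop_cpp(ped@sire, ped@dam, as.integer(inbred), as.integer(nRep))
  est <- counts / nRep
  se <- sqrt(est * (1 - est) / nRep)
  dimnames(est) <- dimnames(se) <- list(ped@id, ped@id)
  list(estimate = est, se = se, nRep = nRep)
}

#' Assemble the load incidence matrix K = T(I - P)
#'
#' Maps record rows to ancestral inbreeding loads: `K = R T (I - P)`
#' where R is the record-to-animal incidence, T the partial inbreeding
#' coefficients and P the parent matrix.  Rows of non-inbred animals are
#' all zero and are retained (record/row alignment is preserved).
#'
#' @param partial a [PartialInbreeding-class]
#' @param P parent matrix from [parentMatrix()]
#' @param recordAnimals integer internal indices (or labels) mapping each
#'   record row to its animal.
#' @return sparse matrix (records x animals).
#' @export
buildK <- function(partial, P, recordAnimals) {
  n <- nrow(partial@T)
  if (!all(dim(P) == c(n, n))) stop("dimension mismatch between T and P")
  idx <- if (is.character(recordAnimals)) match(recordAnimals, partial@id) else as.integer(recordAnimals)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n)) stop("record animals outside pedigree")
  (partial@T %*% (Diagonal(n) - P))[idx, , drop = FALSE]
}

#' Ancestor contribution summary
#'
#' Per-ancestor counts of individuals whose inbreeding they contribute
#' to, aggregated by birth-year cohort, plus global statistics on the
#' partial coefficients (count, fraction below 0.001, fraction above
#' 0.01, coefficients per inbred individual).
#'
#' @param partial a [PartialInbreeding-class]
#' @param ped the matching [Pedigree-class]
#' @param genotypedIds optional character vector marking genotyped animals.
#' @param yearBreaks optional numeric cut points for the cohort table;
#'   default: five-year bins across the observed range.
#' @return list with data.frames `ancestors` (id, nIndividuals,
#'   birthYear, genotyped) and `cohorts`, and a list `coefficients` of
#'   global statistics.
#' @export
ancestorSummary <- function(partial, ped, genotypedIds = NULL, yearBreaks = NULL) {
  Tm <- as(partial@T, "TsparseMatrix")
  if (!length(Tm@x)) {
    return(list(
      ancestors = data.frame(id = character(0), nIndividuals = integer(0),
        birthYear = integer(0), genotyped = logical(0)),
      cohorts = data.frame(),
      coefficients = list(n = 0L, fracBelow001 = NA_real_, fracAbove01 = NA_real_,
        meanPerInbred = NA_real_, sdPerInbred = NA_real_)
    ))
  }
  jj <- Tm@j + 1L
  cnt <- table(factor(jj, levels = sort(unique(jj))))
  aidx <- as.integer(names(cnt))
  ancestors <- data.frame(
    id = ped@id[aidx],
    nIndividuals = as.integer(cnt),
    birthYear = ped@birthYear[aidx],
    genotyped = if (is.null(genotypedIds)) FALSE else ped@id[aidx] %in% genotypedIds,
    stringsAsFactors = FALSE
  )
  cohorts <- data.frame()
  if (any(!is.na(ancestors$birthYear))) {
    yr <- ancestors$birthYear
    if (is.null(yearBreaks)) {
      rng <- range(yr, na.rm = TRUE)
      yearBreaks <- seq(5 * floor(rng[1] / 5), 5 * ceiling((rng[2] + 1) / 5), by = 5)
    }
    grp <- cut(yr, breaks = yearBreaks, include.lowest = TRUE, right = TRUE)
    keep <- !is.na(grp)
    if (any(keep)) {
      cohorts <- do.call(rbind, lapply(levels(droplevels(grp[keep])), function(g) {
        sel <- which(grp == g)
        data.frame(cohort = g, nAncestors = length(sel),
          pctGenotyped = 100 * mean(ancestors$genotyped[sel]),
          meanIndividuals = mean(ancestors$nIndividuals[sel]),
          sdIndividuals = if (length(sel) > 1) sd(ancestors$nIndividuals[sel]) else 0,
          stringsAsFactors = FALSE)
      }))
    }
  }
  perInbred <- table(Tm@i)
  list(
    ancestors = ancestors,
    cohorts = cohorts,
    coefficients = list(
      n = length(Tm@x),
      fracBelow001 = mean(Tm@x < 0.001),
      fracAbove01 = mean(Tm@x > 0.01),
      meanPerInbred = mean(perInbred),
      sdPerInbred = if (length(perInbred) > 1) sd(perInbred) else 0
    )
  )
}
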
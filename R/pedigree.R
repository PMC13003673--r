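## Pedigree construction, sorting, inbreeding and relationship structures.

.UNKNOWN_CODES <- c("", "0", "NA", ".", "-")

#' Build a sorted Pedigree from animal/sire/dam labels
#'
#' Resolves parent labels, topologically sorts the pedigree (parents before
#' offspring) and computes inbreeding coefficients by the Meuwissen-Luo
#' algorithm.  Unknown parents may be coded as `0`, `NA`, `"-"`, `"."` or
#' an empty string.  Animals are ordered so that every parent precedes its
#' offspring; within a sorting batch, ties are broken by birth year (NA
#' last) and then by animal label, so the ordering is invariant to row
#' permutations of the input.
#'
#' @param animal,sire,dam character (or coercible) label vectors.
#' @param birthYear optional integer vector.
#' @param sex optional vector; values starting with "m"/"M" are sires,
#'   "f"/"F"/"h"/"H" dams, anything else NA.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
#' inbreeding(ped)
#' @export
pedigree <- function(animal, sire, dam, birthYear = NULL, sex = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n <- length(animal)
  if (length(sire) != n || length(dam) != n) {
    stop("animal, sire and dam must have equal length")
  }
  if (anyDuplicated(animal)) {
    stop("duplicated animal ids: ", paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  sire[is.na(sire) | sire %in% .UNKNOWN_CODES] <- NA_character_
  dam[is.na(dam) | dam %in% .UNKNOWN_CODES] <- NA_character_
  sidx <- match(sire, animal)
  didx <- match(dam, animal)
  badS <- !is.na(sire) & is.na(sidx)
  badD <- !is.na(dam) & is.na(didx)
  if (any(badS | badD)) {
    off <- unique(c(sire[badS], dam[badD]))
    stop("parent labels not present as animals: ", paste(off, collapse = ", "))
  }
  if (any(sire == animal, na.rm = TRUE) || any(dam == animal, na.rm = TRUE)) {
    bad <- animal[which(sire == animal | dam == animal)][1L]
    stop("pedigree cycle detected involving animal '", bad, "'")
  }
  sidx[is.na(sidx)] <- 0L
  didx[is.na(didx)] <- 0L

  by <- if (is.null(birthYear)) rep(NA_integer_, n) else as.integer(birthYear)
  sx <- if (is.null(sex)) rep(NA_character_, n) else {
    s1 <- toupper(substr(as.character(sex), 1L, 1L))
    ifelse(s1 == "M", "M", ifelse(s1 %in% c("F", "H"), "F", NA_character_))
  }

  ord <- .topoSort(sidx, didx, by, animal)
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  news <- ifelse(sidx == 0L, 0L, rnk[pmax(sidx, 1L)])[ord]
  newd <- ifelse(didx == 0L, 0L, rnk[pmax(didx, 1L)])[ord]

  Fv <- .meuwissenLuo(news, newd)
  obj <- new("Pedigree",
    id = animal[ord], sire = as.integer(news), dam = as.integer(newd),
    birthYear = by[ord], sex = sx[ord],
    inbreeding = Fv, msv = .mendelianVariance(news, newd, Fv)
  )
  validObject(obj)
  obj
}

## Batch topological sort; within-batch order by (birthYear, label).
.topoSort <- function(sidx, didx, by, labels) {
  n <- length(sidx)
  placed <- logical(n)
  out <- integer(0)
  byKey <- ifelse(is.na(by), .Machine$integer.max, by)
  while (length(out) < n) {
    rem <- which(!placed)
    ok <- rem[(sidx[rem] == 0L | placed[pmax(sidx[rem], 1L)]) &
              (didx[rem] == 0L | placed[pmax(didx[rem], 1L)])]
    if (!length(ok)) {
      stop("pedigree cycle detected involving animal '", labels[rem[1L]], "'")
    }
    ok <- ok[order(byKey[ok], labels[ok])]
    out <- c(out, ok)
    placed[ok] <- TRUE
  }
  out
}

## Meuwissen & Luo (1992) inbreeding; parents must precede offspring.
## Uses the F = -1 sentinel for unknown parents so that the Mendelian
## sampling term D is 1 for founders and 0.75 - 0.25 F with one parent.
.meuwissenLuo <- function(sire, dam, check = TRUE) {
  n <- length(sire)
  if (check && (any(sire >= seq_len(n)) || any(dam >= seq_len(n)))) {
    stop("pedigree must be topologically sorted before computing inbreeding")
  }
  Fs <- numeric(n + 1L)   # Fs[1] is the unknown-parent sentinel
  Fs[1L] <- -1
  D <- numeric(n)
  L <- numeric(n)
  for (x in seq_len(n)) {
    s <- sire[x]; d <- dam[x]
    D[x] <- 0.5 - 0.25 * (Fs[s + 1L] + Fs[d + 1L])
    if (s == 0L || d == 0L) {
      Fs[x + 1L] <- 0
      next
    }
    # accumulate a_xx = sum_j L_j^2 D_j over ancestors of x
    L[x] <- 1
    stack <- x
    axx <- 0
    while (length(stack)) {
      j <- max(stack)
      stack <- stack[stack != j]
      lj <- L[j]
      axx <- axx + lj * lj * D[j]
      js <- sire[j]; jd <- dam[j]
      if (js > 0L) { if (L[js] == 0) stack <- c(stack, js); L[js] <- L[js] + 0.5 * lj }
      if (jd > 0L) { if (L[jd] == 0) stack <- c(stack, jd); L[jd] <- L[jd] + 0.5 * lj }
      L[j] <- 0
    }
    Fs[x + 1L] <- axx - 1
  }
  Fs[-1L]
}

.mendelianVariance <- function(sire, dam, Fv) {
  fS <- ifelse(sire == 0L, -1, Fv[pmax(sire, 1L)])
  fD <- ifelse(dam == 0L, -1, Fv[pmax(dam, 1L)])
  0.5 - 0.25 * (fS + fD)
}

#' Read a pedigree CSV file
#'
#' Expects columns `animal`, `sire`, `dam` and optionally `birth_year`
#' (or `birthYear`) and `sex`.  Missing parents may be coded `0` or empty.
#'
#' @param file path to a CSV file.
#' @return a [Pedigree-class] object (sorted, with inbreeding computed).
#' @export
readPedigree <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  by <- if ("birth_year" %in% names(df)) df$birth_year else df[["birthYear"]]
  pedigree(df$animal, df$sire, df$dam, birthYear = by, sex = df[["sex"]])
}

## ---- accessors -------------------------------------------------------

#' @describeIn Pedigree-class number of animals
#' @param x,object a `Pedigree`
#' @export
nAnimals <- function(x) length(x@id)

#' Animal labels in sorted order
#' @param x a [Pedigree-class] or [GenotypeData-class] object
#' @export
animalIds <- function(x) x@id

#' Inbreeding coefficients (Meuwissen-Luo)
#' @param x a [Pedigree-class]
#' @return numeric vector of F, one per animal in sorted order.
#' @export
inbreeding <- function(x) setNames(x@inbreeding, x@id)

#' Sire and dam internal indices (0 = unknown)
#' @param x a [Pedigree-class]
#' @export
sireIndex <- function(x) x@sire

#' @rdname sireIndex
#' @export
damIndex <- function(x) x@dam

#' Mendelian sampling variance scalings
#' @param x a [Pedigree-class]
#' @export
mendelianVariance <- function(x) setNames(x@msv, x@id)

#' @export
as.data.frame.Pedigree <- function(x, ...) {
  data.frame(
    animal = x@id,
    sire = ifelse(x@sire == 0L, NA_character_, x@id[pmax(x@sire, 1L)]),
    dam = ifelse(x@dam == 0L, NA_character_, x@id[pmax(x@dam, 1L)]),
    birth_year = x@birthYear,
    sex = x@sex,
    F = x@inbreeding,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  Fv <- object@inbreeding
  cat("Pedigree with", n, "animals\n")
  cat(sprintf("  known sire: %.1f%%, known dam: %.1f%%\n",
    100 * mean(object@sire > 0L), 100 * mean(object@dam > 0L)))
  cat(sprintf("  inbred animals: %d (mean F among inbred: %.4f)\n",
    sum(Fv > 0), if (any(Fv > 0)) mean(Fv[Fv > 0]) else 0))
  invisible(object)
})

## ---- relationship structures ----------------------------------------

#' Parent incidence matrix P
#'
#' Sparse matrix with 0.5 at each (animal, known parent) entry and zeros
#' elsewhere (zero diagonal); strictly lower triangular in sorted order.
#' Row sums are 0, 0.5 or 1 according to the number of known parents.
#'
#' @param ped a [Pedigree-class]
#' @return a sparse `dgCMatrix` of dimension n x n.
#' @export
parentMatrix <- function(ped) {
  n <- nAnimals(ped)
  i <- c(which(ped@sire > 0L), which(ped@dam > 0L))
  j <- c(ped@sire[ped@sire > 0L], ped@dam[ped@dam > 0L])
  sparseMatrix(i = i, j = j, x = rep(0.5, length(i)), dims = c(n, n),
    dimnames = list(ped@id, ped@id))
}

#' Inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: each animal contributes
#' alpha = 1/msv blocks linking itself and its known parents, where msv is
#' the Mendelian sampling variance scaling.
#'
#' @param ped a [Pedigree-class]
#' @return sparse symmetric `dgCMatrix` A^-1.
#' @export
aInverse <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire; d <- ped@dam
  alpha <- 1 / ped@msv
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  x <- seq_len(n)
  add(x, x, alpha)
  hs <- s > 0L
  add(x[hs], s[hs], -alpha[hs] / 2); add(s[hs], x[hs], -alpha[hs] / 2)
  add(s[hs], s[hs], alpha[hs] / 4)
  hd <- d > 0L
  add(x[hd], d[hd], -alpha[hd] / 2); add(d[hd], x[hd], -alpha[hd] / 2)
  add(d[hd], d[hd], alpha[hd] / 4)
  hb <- hs & hd
  add(s[hb], d[hb], alpha[hb] / 4); add(d[hb], s[hb], alpha[hb] / 4)
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
    dimnames = list(ped@id, ped@id))
}

## Tabular relationship matrix over a set of internal indices; prunes to
## the ancestors of `idx` first.  Dense, for desk-scale submatrices.
.tabularA <- function(ped, idx) {
  n <- nAnimals(ped)
  keep <- logical(n)
  keep[idx] <- TRUE
  for (x in rev(seq_len(n))) {    # mark all ancestors
    if (keep[x]) {
      if (ped@sire[x] > 0L) keep[ped@sire[x]] <- TRUE
      if (ped@dam[x] > 0L) keep[ped@dam[x]] <- TRUE
    }
  }
  sub <- which(keep)
  m <- length(sub)
  rnk <- integer(n); rnk[sub] <- seq_len(m)
  s <- ifelse(ped@sire[sub] > 0L, rnk[pmax(ped@sire[sub], 1L)], 0L)
  d <- ifelse(ped@dam[sub] > 0L, rnk[pmax(ped@dam[sub], 1L)], 0L)
  A <- matrix(0, m, m)
  for (x in seq_len(m)) {
    sx <- s[x]; dx <- d[x]
    if (x > 1L) {
      y <- seq_len(x - 1L)
      ax <- numeric(x - 1L)
      if (sx > 0L) ax <- ax + 0.5 * A[sx, y]
      if (dx > 0L) ax <- ax + 0.5 * A[dx, y]
      A[x, y] <- ax
      A[y, x] <- ax
    }
    A[x, x] <- 1 + if (sx > 0L && dx > 0L) 0.5 * A[sx, dx] else 0
  }
  dimnames(A) <- list(ped@id[sub], ped@id[sub])
  A[rnk[idx], rnk[idx], drop = FALSE]
}

#' Numerator relationship submatrix (tabular method)
#'
#' Exact A restricted to the given animals, computed by the tabular method
#' on the ancestor-pruned pedigree (used for the A22 block of genotyped
#' animals in single-step evaluations).
#'
#' @param ped a [Pedigree-class]
#' @param ids character labels (or integer internal indices) of animals.
#' @return dense symmetric matrix with dimnames.
#' @export
relationshipMatrix <- function(ped, ids) {
  idx <- if (is.character(ids)) match(ids, ped@id) else as.integer(ids)
  if (anyNA(idx) || any(idx < 1L) || any(idx > nAnimals(ped))) {
    stop("unknown animal ids: ",
      paste(if (is.character(ids)) ids[is.na(idx)] else idx[is.na(idx) | idx < 1], collapse = ", "))
  }
  .tabularA(ped, idx)
}

## ---- summaries -------------------------------------------------------

#' Pedigree summary statistics with inbreeding-coefficient bins
#'
#' Counts animals, parent knowledge, mean and SD of inbreeding (overall
#' and among inbred animals), and tabulates F into the bins
#' 0, (0, 0.05], (0.05, 0.10], ..., (0.35, 0.40], > 0.4.
#'
#' @param ped a [Pedigree-class]
#' @return list with elements `n`, `pctKnownSire`, `pctKnownDam`,
#'   `nInbred`, `meanF`, `sdF`, `meanFInbred`, `sdFInbred` and a
#'   data.frame `bins`.
#' @export
pedStats <- function(ped) {
  Fv <- ped@inbreeding
  edges <- c(seq(0, 0.40, by = 0.05), Inf)
  labs <- c("0", paste0(head(edges, -2), "-", edges[2:(length(edges) - 1)]), "> 0.4")
  counts <- c(sum(Fv == 0),
    vapply(seq_len(length(edges) - 1L), function(k) {
      sum(Fv > edges[k] & Fv <= edges[k + 1L])
    }, integer(1)))
  inb <- Fv[Fv > 0]
  list(
    n = nAnimals(ped),
    pctKnownSire = 100 * mean(ped@sire > 0L),
    pctKnownDam = 100 * mean(ped@dam > 0L),
    nInbred = length(inb),
    meanF = mean(Fv), sdF = sd(Fv),
    meanFInbred = if (length(inb)) mean(inb) else 0,
    sdFInbred = if (length(inb) > 1) sd(inb) else 0,
    bins = data.frame(bin = labs, n = counts)
  )
}

#' Approximate pedigree depth in generations
#'
#' Generation count per animal: founders are generation 0, otherwise
#' 1 + max(parent generations).  This is a simple upper-path statistic;
#' pedigree-depth measures differ between packages, so treat the mean as
#' approximate.
#'
#' @param ped a [Pedigree-class]
#' @return list with `generations` (per animal), `mean` and `sd`.
#' @export
pedigreeDepth <- function(ped) {
  n <- nAnimals(ped)
  g <- numeric(n)
  for (x in seq_len(n)) {
    gs <- if (ped@sire[x] > 0L) g[ped@sire[x]] else -1
    gd <- if (ped@dam[x] > 0L) g[ped@dam[x]] else -1
    g[x] <- 1 + max(gs, gd)
  }
  list(generations = setNames(g, ped@id), mean = mean(g), sd = sd(g))
}
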
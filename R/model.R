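## Record filtering, model specification and design assembly for the
## bivariate additive + inbreeding-load animal model.

#' Remove phenotypic outliers beyond 3 standard deviations
#'
#' Single pass: removes records with |y - mean| > `k` * SD, both moments
#' computed on the input set.
#'
#' @param records data.frame of records.
#' @param valueCol name of the trait column (default "value").
#' @param k SD multiplier (default 3).
#' @return filtered data.frame; the number removed is in
#'   `attr(, "nRemoved")`.
#' @export
filterOutliers <- function(records, valueCol = "value", k = 3) {
  y <- records[[valueCol]]
  if (length(y) < 2) stop("need at least two records to compute an SD")
  m <- mean(y); s <- sd(y)
  keep <- if (s == 0) rep(TRUE, length(y)) else abs(y - m) <= k * s
  out <- records[keep, , drop = FALSE]
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Specify the trait model
#'
#' Three variants of the animal model are supported: the base model
#' (intercept, fixed factors, inbreeding covariate d, HYS, additive and
#' load effects), the base model plus a centered age-at-recording
#' covariate c, and the base model plus a permanent environmental effect
#' for repeated records.
#'
#' @param trait trait name (the records column holding phenotypes).
#' @param fixed character vector of fixed-effect factor columns.
#' @param ageCovariate include the age covariate (requires an `age`
#'   column in the records).
#' @param permanentEnv include a permanent environmental effect
#'   (requires repeated records per animal).
#' @return a `loadModelSpec` list.
#' @export
modelSpec <- function(trait = "value", fixed = character(0),
                      ageCovariate = FALSE, permanentEnv = FALSE) {
  structure(list(trait = trait, fixed = fixed,
    ageCovariate = ageCovariate, permanentEnv = permanentEnv),
    class = "loadModelSpec")
}

#' Assemble the design for the load model
#'
#' Builds y, the inbreeding covariate f (pedigree F of each record's
#' animal), the dense scalar-effect design (intercept, fixed-factor
#' contrasts, f, centered age), HYS and permanent-environment indicator
#' columns with their prior codes, the record-to-animal map, and
#' K = R T (I - P).
#'
#' @param records data.frame with columns `animal`, the trait column,
#'   `hys`, the fixed-factor columns, and `age` if the spec asks for it.
#' @param spec a [modelSpec()].
#' @param ped a [Pedigree-class].
#' @param partial a [PartialInbreeding-class] for the same pedigree.
#' @return a `loadDesign` list: `y`, `X` (dense fixed columns), `zIdx`,
#'   `hysIdx`/`nHys`, `peIdx`/`nPe`, `K`, `f`, `coefNames`, `n`, `q`,
#'   `spec`.
#' @export
assembleDesign <- function(records, spec, ped, partial) {
  stopifnot(inherits(spec, "loadModelSpec"))
  idx <- match(as.character(records$animal), ped@id)
  if (anyNA(idx)) {
    stop("record animals absent from pedigree: ",
      paste(unique(records$animal[is.na(idx)]), collapse = ", "))
  }
  y <- as.numeric(records[[spec$trait]])
  n <- length(y)
  f <- ped@inbreeding[idx]

  cols <- list(`(Intercept)` = rep(1, n))
  for (fx in spec$fixed) {
    fac <- factor(records[[fx]])
    if (nlevels(fac) > 1) {
      mm <- model.matrix(~fac)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(fx, levels(fac)[-1L])
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
  }
  cols[["d"]] <- f
  if (isTRUE(spec$ageCovariate)) {
    if (is.null(records$age)) stop("age covariate requested but records have no 'age' column")
    cols[["c"]] <- records$age - mean(records$age)
  }
  X <- do.call(cbind, cols)

  if (!is.null(records$hys)) {
    hf <- factor(records$hys)
    hysIdx <- as.integer(hf)
    nHys <- nlevels(hf)
    hysLevels <- levels(hf)
  } else {
    hysIdx <- integer(n); nHys <- 0L; hysLevels <- character(0)
  }
  if (isTRUE(spec$permanentEnv)) {
    if (!any(duplicated(idx))) {
      stop("permanent environmental effect requires repeated records per animal")
    }
    pf <- factor(idx)
    peIdx <- as.integer(pf)
    nPe <- nlevels(pf)
  } else {
    peIdx <- integer(n); nPe <- 0L
  }
  K <- buildK(partial, parentMatrix(ped), idx)

  structure(list(
    y = y, X = X, zIdx = as.integer(idx),
    hysIdx = hysIdx, nHys = nHys, hysLevels = hysLevels,
    peIdx = peIdx, nPe = nPe,
    K = K, f = f, coefNames = colnames(X), n = n, q = nAnimals(ped),
    ids = ped@id, spec = spec
  ), class = "loadDesign")
}
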
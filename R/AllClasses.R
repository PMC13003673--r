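#' Pedigree: a topologically sorted pedigree with inbreeding coefficients
#'
#' Animals are stored in topological order (every parent precedes its
#' offspring); `sire`/`dam` are 1-based internal indices into the sorted
#' order, with 0 coding an unknown parent.  Inbreeding coefficients are
#' computed with the Meuwissen-Luo algorithm at construction time, and
#' `msv` holds the Mendelian sampling variance scaling of each animal
#' (1 for founders, 0.75 - 0.25 F_s with one known parent,
#' 0.5 - 0.25 (F_s + F_d) with both).
#'
#' @slot id character vector of animal labels (sorted order).
#' @slot sire,dam integer internal indices of the parents (0 = unknown).
#' @slot birthYear integer birth years (NA allowed).
#' @slot sex character, "M", "F" or NA.
#' @slot inbreeding numeric inbreeding coefficients F in [0, 1).
#' @slot msv numeric Mendelian sampling variance scalings.
#'
#' @seealso [pedigree()], [readPedigree()], [inbreeding()], [aInverse()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    birthYear = "integer",
    sex = "character",
    inbreeding = "numeric",
    msv = "numeric"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msgs <- character(0)
  for (s in c("sire", "dam", "birthYear", "sex", "inbreeding", "msv")) {
    if (length(slot(object, s)) != n) {
      msgs <- c(msgs, sprintf("slot '%s' must have length %d", s, n))
    }
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(object@id)) msgs <- c(msgs, "duplicated animal ids")
  bad <- object@sire < 0L | object@sire > n | object@dam < 0L | object@dam > n
  if (any(bad)) msgs <- c(msgs, "parent indices out of range")
  idx <- seq_len(n)
  if (any(object@sire >= idx) || any(object@dam >= idx)) {
    msgs <- c(msgs, "pedigree is not topologically sorted (a parent index >= offspring index)")
  }
  if (any(object@inbreeding < 0 | object@inbreeding >= 1)) {
    msgs <- c(msgs, "inbreeding coefficients must lie in [0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' PartialInbreeding: per-ancestor decomposition of inbreeding coefficients
#'
#' Sparse matrix T with T[x, j] = F_x^(j), the part of animal x's
#' inbreeding attributable to the Mendelian sampling of ancestor j.
#' Row sums over ancestors reproduce the Meuwissen-Luo inbreeding
#' coefficient of each animal (the conservation identity).
#'
#' @slot T a `dgCMatrix` (animals x animals, columns = ancestors).
#' @slot id character animal labels matching the pedigree order.
#'
#' @seealso [partialInbreeding()], [partialTriplets()], [buildK()]
#' @importClassesFrom Matrix sparseMatrix dgCMatrix
#' @exportClass PartialInbreeding
setClass("PartialInbreeding",
  representation(T = "sparseMatrix", id = "character")
)

setValidity("PartialInbreeding", function(object) {
  if (nrow(object@T) != ncol(object@T)) return("T must be square (animals x animals)")
  if (length(object@id) != nrow(object@T)) return("id length must match T")
  if (any(object@T@x < 0)) return("partial inbreeding coefficients must be nonnegative")
  TRUE
})

#' GenotypeData: quality-controlled SNP genotypes with map and frequencies
#'
#' Allele counts after QC (autosome, call-rate and MAF filters) with
#' missing genotypes imputed to twice the allele frequency, the marker
#' map, post-QC allele frequencies, and a QC report.
#'
#' @slot geno numeric matrix (animals x SNPs) of allele counts after
#'   imputation; column names are SNP ids.
#' @slot id character animal labels (rows of `geno`).
#' @slot map data.frame with columns `snp`, `chrom`, `pos` for retained SNPs.
#' @slot freq numeric allele frequencies per retained SNP.
#' @slot qc list: counts removed per filter and final dimensions.
#'
#' @seealso [qcGenotypes()], [vanRadenG()], [centeredGenotypes()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(
    geno = "matrix",
    id = "character",
    map = "data.frame",
    freq = "numeric",
    qc = "list"
  )
)

setValidity("GenotypeData", function(object) {
  msgs <- character(0)
  if (length(object@id) != nrow(object@geno)) msgs <- c(msgs, "id length must match rows of geno")
  if (nrow(object@map) != ncol(object@geno)) msgs <- c(msgs, "map rows must match columns of geno")
  if (length(object@freq) != ncol(object@geno)) msgs <- c(msgs, "freq length must match columns of geno")
  if (length(object@freq) && any(object@freq <= 0 | object@freq >= 1)) {
    msgs <- c(msgs, "allele frequencies must lie strictly in (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' LoadModelFit: posterior output of the bivariate load model
#'
#' Holds thinned Gibbs samples of the variance components and regression
#' coefficients, posterior means and standard deviations of the additive
#' (`u`) and inbreeding-load (`i`) effects per animal, and chain metadata.
#'
#' @slot samples numeric matrix, one row per saved iteration; columns
#'   `sigma_u2`, `sigma_ui`, `sigma_i2`, `sigma_h2`, `sigma_p2`,
#'   `sigma_e2` followed by the location coefficients (intercept, fixed
#'   levels, `d`, `c`, HYS and permanent-environment levels).
#' @slot effects data.frame per animal: `id`, `uMean`, `uPSD`, `iMean`, `iPSD`.
#' @slot effectSamples list with optional thinned chains of `u` and `i`.
#' @slot mcmc list of chain settings (iterations, burn-in, thinning, seed).
#' @slot model list describing the fitted design (trait, terms, sizes).
#'
#' @seealso [fitLoadModel()], [varianceSummary()], [fitAccuracy()]
#' @exportClass LoadModelFit
setClass("LoadModelFit",
  representation(
    samples = "matrix",
    effects = "data.frame",
    effectSamples = "list",
    mcmc = "list",
    model = "list"
  )
)
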
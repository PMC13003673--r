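## Pipeline orchestration: decompose -> relationship matrices -> fit ->
## back-solve, with CSV reports and a reproducibility manifest.

.stageSeed <- function(root, stage) {
  (as.integer(root) + 1000L * match(stage,
    c("pedigree", "genotypes", "phenotypes", "fit", "backsolve"))) %% 2147483647L
}

#' Accuracy grouping by animal category
#'
#' Groups animals for accuracy reporting: "old_sires" (males in the
#' oldest third of birth years with offspring), "current_sires" and
#' "current_dams" (parents in the more recent cohorts) and "candidates"
#' (animals of the youngest cohort without offspring).
#'
#' @param ped a [Pedigree-class]
#' @return character vector of group labels per animal (NA when a group
#'   does not apply).
#' @export
animalGroups <- function(ped) {
  n <- nAnimals(ped)
  isParent <- logical(n)
  isParent[ped@sire[ped@sire > 0L]] <- TRUE
  isParent[ped@dam[ped@dam > 0L]] <- TRUE
  yr <- ped@birthYear
  yr[is.na(yr)] <- min(yr, na.rm = TRUE)
  qs <- quantile(yr, c(1 / 3, 2 / 3), names = FALSE, type = 1)
  grp <- rep(NA_character_, n)
  grp[isParent & yr <= qs[1] & ped@sex %in% "M"] <- "old_sires"
  grp[isParent & yr > qs[1] & ped@sex %in% "M"] <- "current_sires"
  grp[isParent & yr > qs[1] & ped@sex %in% "F"] <- "current_dams"
  grp[!isParent & yr > qs[2]] <- "candidates"
  grp
}

#' Run the full inbreeding-load analysis
#'
#' Executes all stages from a configuration: data simulation (or file
#' input), Mendelian decomposition, relationship matrices (pedigree or
#' single-step), the Gibbs fit, accuracies by animal category, and --
#' when genotypes are present -- SNP back-solving with 25- and 50-SNP
#' window scans and the >1% region rule.  Writes CSV reports and a
#' reproducibility manifest to `outDir`.  All randomness derives from
#' the single root seed in the config; per-stage seeds are deterministic
#' functions of it.
#'
#' @param config list or path to a YAML file with elements `seed`,
#'   optional `sim` (arguments to [simConfig()]), or file inputs
#'   `pedigree`, `phenotypes`, optional `genotypes`/`map`; `mcmc`
#'   settings (`nIter`, `burnIn`, `thin`); `genomic` flag.
#' @param outDir output directory (created if needed).
#' @return invisible list with the fitted objects and report paths.
#' @export
runFullAnalysis <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a root seed")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  useGenomic <- isTRUE(config$genomic)
  mc <- config$mcmc %||% list()
  nIter <- mc$nIter %||% 50000
  burnIn <- mc$burnIn %||% 10000
  thin <- mc$thin %||% 10

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    cfg <- do.call(simConfig, config$sim)
    ped <- simulatePedigree(cfg, seed = .stageSeed(config$seed, "pedigree"))
    geno <- NULL
    if (useGenomic) {
      geno <- simulateGenotypes(ped, cfg, seed = .stageSeed(config$seed, "genotypes"))
    }
    partial <- partialInbreeding(ped)
    sim <- simulatePhenotypes(ped, partial, cfg,
      seed = .stageSeed(config$seed, "phenotypes"))
    records <- sim$records
    spec <- modelSpec(trait = "value", fixed = "sex",
      permanentEnv = cfg$recordsPerAnimal > 1 && cfg$sp2 > 0)
  } else {
    if (is.null(config$pedigree) || is.null(config$phenotypes)) {
      stop("config must provide either 'sim' or 'pedigree' + 'phenotypes'")
    }
    if (useGenomic && (is.null(config$genotypes) || is.null(config$map))) {
      stop("genomic stage enabled but 'genotypes'/'map' files are missing from the config")
    }
    ped <- readPedigree(config$pedigree)
    partial <- partialInbreeding(ped)
    records <- read.csv(config$phenotypes, stringsAsFactors = FALSE)
    geno <- if (useGenomic) readGenotypes(config$genotypes, config$map) else NULL
    spec <- do.call(modelSpec, config$model %||% list(trait = "value", fixed = "sex"))
  }
  records <- filterOutliers(records, valueCol = spec$trait)

  # --- pedigree reports -----------------------------------------------
  ps <- pedStats(ped)
  write.csv(ps$bins, file.path(outDir, "inbreeding_bins.csv"), row.names = FALSE)
  anc <- ancestorSummary(partial, ped,
    genotypedIds = if (!is.null(geno)) geno$genotypedIds %||% rownames(geno$geno))
  write.csv(anc$ancestors, file.path(outDir, "ancestor_contributions.csv"),
    row.names = FALSE)
  if (nrow(anc$cohorts)) {
    write.csv(anc$cohorts, file.path(outDir, "ancestor_cohorts.csv"), row.names = FALSE)
  }
  write.csv(partialTriplets(partial), file.path(outDir, "partial_inbreeding.csv"),
    row.names = FALSE)

  # --- relationship matrices ------------------------------------------
  Ainv <- aInverse(ped)
  genoQC <- NULL
  G <- NULL
  genoIdx <- integer(0)
  if (useGenomic && !is.null(geno)) {
    genoQC <- qcGenotypes(geno$geno, geno$map)
    keep <- genoQC@id %in% ped@id
    genoIdx <- match(genoQC@id[keep], ped@id)
    A22 <- relationshipMatrix(ped, genoIdx)
    # blend once; the blended matrix backs both H^-1 and the back-solving
    # (the raw G is singular when frequencies are estimated from the data)
    G <- 0.95 * vanRadenG(genoQC)[keep, keep, drop = FALSE] + 0.05 * A22
    relInv <- hInverse(Ainv, A22, G, genoIdx, blend = 0)
  } else {
    relInv <- Ainv
  }

  # --- fit -------------------------------------------------------------
  design <- assembleDesign(records, spec, ped, partial)
  fit <- fitLoadModel(design, relInv, nIter = nIter, burnIn = burnIn, thin = thin,
    seed = .stageSeed(config$seed, "fit"))
  vs <- varianceSummary(fit)
  S <- posteriorSamples(fit)
  dsum <- depressionSummary(vs$mean[vs$parameter == "d"], vs$psd[vs$parameter == "d"],
    mean(records[[spec$trait]]), sd(records[[spec$trait]]))
  summaryTab <- rbind(
    data.frame(parameter = "d", mean = vs$mean[vs$parameter == "d"],
      psd = vs$psd[vs$parameter == "d"]),
    data.frame(parameter = c("DpctM", "DpctSD"),
      mean = c(dsum$DpctM, dsum$DpctSD), psd = c(dsum$DpctM_PSD, dsum$DpctSD_PSD)),
    data.frame(parameter = vs$parameter[vs$parameter != "d"],
      mean = vs$mean[vs$parameter != "d"], psd = vs$psd[vs$parameter != "d"])
  )
  write.csv(summaryTab, file.path(outDir, "fit_summary.csv"), row.names = FALSE)
  write.csv(effectSummary(fit), file.path(outDir, "animal_effects.csv"),
    row.names = FALSE)

  hD <- hDiagonal(ped, G = G, genoIdx = genoIdx, blend = 0)
  accTab <- suppressWarnings(fitAccuracy(fit, hD))   # clamping is expected at short chain lengths
  accTab$group <- animalGroups(ped)
  write.csv(accTab, file.path(outDir, "accuracy_by_group.csv"), row.names = FALSE)

  # --- back-solving ----------------------------------------------------
  scans <- NULL
  if (!is.null(G)) {
    eff <- effectSummary(fit)
    su <- backsolveSnpEffects(genoQC, G, eff$uMean[genoIdx])
    si <- backsolveSnpEffects(genoQC, G, eff$iMean[genoIdx])
    track <- snpEffectTrack(markerMap(genoQC), su, si, alleleFreq(genoQC))
    scans <- list()
    for (w in c(25, 50)) {
      wv <- windowVariances(track, size = w)
      write.csv(wv, file.path(outDir, sprintf("window_scan_%d.csv", w)),
        row.names = FALSE)
      scans[[as.character(w)]] <- wv
    }
    regions <- topRegions(scans[["50"]])
    write.csv(regions, file.path(outDir, "regions.csv"), row.names = FALSE)
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = as.character(packageVersion("inbredload")),
    seed = config$seed,
    stageSeeds = lapply(setNames(nm = c("pedigree", "genotypes", "phenotypes",
      "fit", "backsolve")), function(s) .stageSeed(config$seed, s)),
    mcmc = list(nIter = nIter, burnIn = burnIn, thin = thin),
    nAnimals = nAnimals(ped), nRecords = nrow(records),
    genomic = useGenomic,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  invisible(list(ped = ped, partial = partial, fit = fit, summary = summaryTab,
    accuracy = accTab, scans = scans, outDir = outDir))
}
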
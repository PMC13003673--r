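## GBLUP -> SNP-BLUP back-solving and windowed variance scans.

#' Back-solve SNP effects from animal-level genetic values
#'
#' `s = W_g' G^-1 v / sum_j 2 p_j (1 - p_j)`, converting GBLUP
#' solutions (posterior means of u or i restricted to the genotyped
#' animals) into per-allele SNP effects.  For a fully genotyped
#' population with unblended G built from the same W_g, `W_g s` returns
#' the input values exactly (the GBLUP/SNP-BLUP equivalence).
#'
#' @param x a [GenotypeData-class] or a centered gene-content matrix W_g.
#' @param G genomic (or blended) relationship matrix of the same animals.
#' @param values animal-level genetic values in G's row order.
#' @param freq allele frequencies, required when `x` is a bare matrix
#'   that is already centered (used only for the denominator).
#' @return numeric vector of per-SNP effects (trait units per allele).
#' @export
backsolveSnpEffects <- function(x, G, values, freq = NULL) {
  if (is(x, "GenotypeData")) {
    W <- centeredGenotypes(x)
    freq <- x@freq
  } else {
    W <- x
    if (is.null(freq)) stop("freq is required when passing a centered matrix")
  }
  if (length(values) != nrow(W)) stop("values must be indexed to G's animals")
  k <- sum(2 * freq * (1 - freq))
  rc <- rcond(G)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("G is singular or near-singular; back-solving requires an invertible ",
      "(e.g. blended) genomic matrix")
  }
  as.numeric(crossprod(W, solve(G, values))) / k
}

#' Per-SNP variance track for additive and load effects
#'
#' Per-SNP variances `2 p_j (1 - p_j) s_j^2` for each effect vector,
#' ordered by chromosome then position.
#'
#' @param map data.frame `snp`, `chrom`, `pos`.
#' @param su,si per-SNP effect vectors (either may be NULL).
#' @param freq allele frequencies.
#' @return data.frame `snp`, `chrom`, `pos`, `var_u`, `var_i`.
#' @export
snpEffectTrack <- function(map, su = NULL, si = NULL, freq) {
  het <- 2 * freq * (1 - freq)
  out <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
    stringsAsFactors = FALSE)
  out$var_u <- if (is.null(su)) NA_real_ else het * su^2
  out$var_i <- if (is.null(si)) NA_real_ else het * si^2
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Windowed SNP variance scan
#'
#' Aggregates per-SNP variances into windows of `size` consecutive SNPs
#' within each chromosome (sliding by one SNP by default; disjoint
#' optional).  Window variance is the sum of its members' SNP variances;
#' percentages are relative to the genome-wide sum, separately for the
#' additive and load components.  A chromosome smaller than the window
#' yields a single chromosome-wide window with a warning.
#'
#' @param track data.frame from [snpEffectTrack()].
#' @param size window size in SNPs (the standard scans use 25 and 50).
#' @param mode "sliding" (default) or "disjoint".
#' @return data.frame `chrom`, `firstSnp`, `lastSnp`, `startBp`,
#'   `endBp`, `nSnp`, `var_u`, `var_i`, `pct_u`, `pct_i`, plus the scan
#'   mode in `attr(, "mode")`.
#' @export
windowVariances <- function(track, size = 25, mode = c("sliding", "disjoint")) {
  mode <- match.arg(mode)
  totU <- sum(track$var_u)
  totI <- sum(track$var_i)
  res <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    m <- nrow(sub)
    if (m < size) {
      warning("chromosome ", ch, " has fewer SNPs (", m, ") than the window size (",
        size, "); using one chromosome-wide window")
      starts <- 1L; ends <- m
    } else if (mode == "sliding") {
      starts <- seq_len(m - size + 1L); ends <- starts + size - 1L
    } else {
      starts <- seq(1L, m - size + 1L, by = size); ends <- starts + size - 1L
    }
    cu <- cumsum(c(0, sub$var_u))
    ci <- cumsum(c(0, sub$var_i))
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch,
      firstSnp = sub$snp[starts], lastSnp = sub$snp[ends],
      startBp = sub$pos[starts], endBp = sub$pos[ends],
      nSnp = ends - starts + 1L,
      var_u = cu[ends + 1L] - cu[starts],
      var_i = ci[ends + 1L] - ci[starts],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$pct_u <- 100 * out$var_u / totU
  out$pct_i <- 100 * out$var_i / totI
  attr(out, "mode") <- mode
  rownames(out) <- NULL
  out
}

#' Genomic regions explaining more than a threshold of variance
#'
#' Flags windows above the percentage threshold (the conventional rule
#' is 1% of the additive or load variance), merges overlapping
#' qualifying windows within a chromosome into regions, and reports the
#' physical span and peak percentage per component.
#'
#' @param windows data.frame from [windowVariances()].
#' @param threshold percentage threshold (default 1).
#' @return data.frame `component`, `chrom`, `startBp`, `endBp`,
#'   `nWindows`, `peakPct` (possibly empty).
#' @export
topRegions <- function(windows, threshold = 1) {
  out <- list()
  for (comp in c("u", "i")) {
    pct <- windows[[paste0("pct_", comp)]]
    if (all(is.na(pct))) next
    qual <- windows[!is.na(pct) & pct > threshold, , drop = FALSE]
    qual$pct <- pct[!is.na(pct) & pct > threshold]
    if (!nrow(qual)) next
    for (ch in unique(qual$chrom)) {
      sub <- qual[qual$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$startBp), , drop = FALSE]
      start <- sub$startBp[1L]; end <- sub$endBp[1L]; peak <- sub$pct[1L]; nw <- 1L
      flush <- function(s, e, p, k) {
        out[[length(out) + 1L]] <<- data.frame(component = comp, chrom = ch,
          startBp = s, endBp = e, nWindows = k, peakPct = p,
          stringsAsFactors = FALSE)
      }
      if (nrow(sub) > 1) {
        for (r in 2:nrow(sub)) {
          if (sub$startBp[r] <= end) {
            end <- max(end, sub$endBp[r]); peak <- max(peak, sub$pct[r]); nw <- nw + 1L
          } else {
            flush(start, end, peak, nw)
            start <- sub$startBp[r]; end <- sub$endBp[r]; peak <- sub$pct[r]; nw <- 1L
          }
        }
      }
      flush(start, end, peak, nw)
    }
  }
  if (!length(out)) {
    return(data.frame(component = character(0), chrom = character(0),
      startBp = numeric(0), endBp = numeric(0), nWindows = integer(0),
      peakPct = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
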
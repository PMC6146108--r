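## Per-OTU DNA band isolation within a gradient and weighted-mean buoyant
## density estimation. Weights throughout are ng DNA (relative abundance
## converted through the measured bulk DNA distribution), never raw reads.

#' Convert read counts to per-fraction relative abundance
#'
#' Each sequenced fraction's counts are normalized to proportions. Fractions
#' whose total reads fall below `min_fraction_reads` carry too little
#' information (a handful of reads can move a taxon's apparent density by
#' whole fractions) and are dropped before normalization.
#'
#' @param counts Integer matrix, OTUs in rows, fractions in columns.
#' @param min_fraction_reads Minimum total reads for a fraction to be kept.
#' @return Matrix of per-fraction proportions (columns sum to 1) restricted
#'   to the retained fractions; attribute `"dropped"` holds the dropped
#'   column indices (positions in the input).
#' @examples
#' m <- rbind(a = c(30, 10), b = c(10, 30))
#' relative_abundance(m, min_fraction_reads = 1)
#' @export
relative_abundance <- function(counts, min_fraction_reads = 100) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1)
  tot <- colSums(counts)
  keep <- tot >= max(min_fraction_reads, 1)
  if (!any(keep))
    stop_nsip("nsip_empty_error",
              "all fractions fall below min_fraction_reads; gradient unusable")
  prop <- sweep(counts[, keep, drop = FALSE], 2, tot[keep], "/")
  attr(prop, "dropped") <- which(!keep)
  prop
}

#' Convert relative abundance to ng DNA per OTU and fraction
#'
#' The bulk DNA distribution measured across the gradient apportions each
#' fraction's DNA mass among OTUs by their within-fraction relative
#' abundance, so OTU masses sum back to the bulk measurement exactly.
#'
#' @param proportions Matrix from [relative_abundance()] (OTUs x fractions).
#' @param bulk_dna Bulk DNA (ng) per retained fraction, aligned to the
#'   columns of `proportions`.
#' @return Matrix of ng DNA, same shape as `proportions`.
#' @export
otu_mass <- function(proportions, bulk_dna) {
  if (length(bulk_dna) != ncol(proportions))
    stop_nsip("nsip_input_error",
              "bulk_dna length (%d) does not match fraction count (%d)",
              length(bulk_dna), ncol(proportions))
  sweep(proportions, 2, bulk_dna, "*")
}

#' Peak-anchored band window of an OTU's mass profile
#'
#' Finds the density-contiguous run of fractions, anchored at the OTU's
#' peak-mass fraction, over which the mass stays at or above `band_tail_pct`
#' percent of the maximum. This is the default tail-trimming policy used to
#' cut all of an OTU's gradients to comparable densities.
#'
#' @param density Fraction densities, g/ml (any consistent order).
#' @param mass OTU DNA mass per fraction, ng.
#' @param band_tail_pct Tail threshold as a percentage of the peak mass.
#' @return `c(lo, hi)` density bounds of the window, or `NULL` when the
#'   profile carries no mass.
#' @export
band_window <- function(density, mass, band_tail_pct = 2) {
  if (all(mass <= 0)) return(NULL)
  o <- order(density)
  density <- density[o]; mass <- mass[o]
  peak <- which.max(mass)
  thr <- band_tail_pct / 100 * mass[peak]
  lo <- peak
  while (lo > 1 && mass[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < length(mass) && mass[hi + 1] >= thr) hi <- hi + 1
  c(density[lo], density[hi])
}

#' Trim a band to a common density window and renormalize
#'
#' Retains the fractions whose density lies inside `window` and re-expresses
#' the retained masses as percentages of the OTU's DNA within the window
#' (summing to 100). Trimming the tails of each gradient's profile to the
#' same densities isolates the DNA band proper and makes weighted mean
#' densities comparable across gradients.
#'
#' @param band Data frame with columns `density` (g/ml), `otu_dna` (ng), and
#'   optionally `reads`.
#' @param window `c(lo, hi)` density bounds (inclusive).
#' @param min_band_fractions Minimum retained fractions with positive mass;
#'   fewer raises a band-undefined error.
#' @return The trimmed band with an added `otu_dna_pct` column, rows sorted
#'   by density.
#' @examples
#' b <- data.frame(density = c(1.69, 1.70, 1.71), otu_dna = c(1, 8, 1))
#' trim_and_normalize(b, c(1.695, 1.715), min_band_fractions = 1)
#' @export
trim_and_normalize <- function(band, window, min_band_fractions = 3) {
  if (is.null(window) || window[1] > window[2])
    stop_nsip("nsip_band_undefined_error", "empty band window")
  keep <- band$density >= window[1] & band$density <= window[2]
  out <- band[keep, , drop = FALSE]
  out <- out[order(out$density), , drop = FALSE]
  if (sum(out$otu_dna > 0) < min_band_fractions)
    stop_nsip("nsip_band_undefined_error",
              "fewer than %d fractions with positive mass in window",
              min_band_fractions)
  out$otu_dna_pct <- 100 * out$otu_dna / sum(out$otu_dna)
  rownames(out) <- NULL
  out
}

#' Weighted mean buoyant density of a DNA band
#'
#' The density of one OTU's DNA in one gradient (or a pooled set of control
#' fractions) is the DNA-mass-weighted mean of the retained fraction
#' densities. Dispersion is the weighted variance and the information
#' content is the Kish effective sample size \eqn{(\sum w)^2 / \sum w^2},
#' which supplies the sample-size notion Welch's t-test needs for weighted
#' data.
#'
#' @param band Data frame with columns `density` and `otu_dna` (weights, ng);
#'   an optional `reads` column is summed into `total_reads`.
#' @return List of class `density_estimate`: `mean_density`,
#'   `weighted_variance`, `effective_n`, `total_reads`, `n_fractions`.
#'   A single-fraction band yields variance 0 and effective n 1 (flagged
#'   `low_information`).
#' @examples
#' b <- data.frame(density = c(1.695, 1.700, 1.705, 1.710),
#'                 otu_dna = c(10, 40, 30, 20))
#' weighted_density(b)$mean_density   # 1.7030
#' @export
weighted_density <- function(band) {
  w <- band$otu_dna
  d <- band$density
  keep <- w > 0
  w <- w[keep]; d <- d[keep]
  if (!length(w))
    stop_nsip("nsip_empty_error", "band has no positive-mass fractions")
  m <- sum(d * w) / sum(w)
  v <- sum(w * (d - m)^2) / sum(w)
  structure(list(mean_density = m,
                 weighted_variance = v,
                 effective_n = sum(w)^2 / sum(w^2),
                 total_reads = if ("reads" %in% names(band))
                   sum(band$reads[keep]) else NA_integer_,
                 n_fractions = length(w),
                 low_information = length(w) == 1L),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Weighted density estimate: %.4f g/ml (var %.3g, eff n %.2f, %d fractions%s)\n",
              x$mean_density, x$weighted_variance, x$effective_n,
              x$n_fractions,
              if (isTRUE(x$low_information)) ", low information" else ""))
  invisible(x)
}

## Per-gradient band bookkeeping for one OTU set: returns, for each OTU with
## any mass, its per-fraction (density, otu_dna, reads) profile and raw
## peak-anchored window.
.gradient_bands <- function(counts, density, bulk_dna,
                            min_fraction_reads = 100, band_tail_pct = 2) {
  prop <- relative_abundance(counts, min_fraction_reads)
  kept <- setdiff(seq_len(ncol(counts)), attr(prop, "dropped"))
  mass <- otu_mass(prop, bulk_dna[kept])
  dens <- density[kept]
  reads <- counts[, kept, drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mass))) {
    if (all(mass[i, ] <= 0)) next
    w <- band_window(dens, mass[i, ], band_tail_pct)
    out[[rownames(counts)[i]]] <- list(
      profile = data.frame(density = dens, otu_dna = mass[i, ],
                           reads = reads[i, ]),
      window = w)
  }
  out
}
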
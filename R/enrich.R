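## Per-OTU enrichment calling: pooled-control Welch tests on weighted mean
## buoyant densities, Benjamini-Hochberg FDR control, and the minimum
## percent-enrichment rule.

#' Pool control bands of one OTU into a single density estimate
#'
#' Unlabeled nitrogen does not change DNA buoyant density, so variation
#' between an OTU's control bands reflects only measurement precision.
#' Combining every control fraction of the OTU over all treatments into a
#' single weighted density estimate gives a better-constrained mean and
#' variance for its native DNA.
#'
#' @param bands List of trimmed band data frames (columns `density`,
#'   `otu_dna`, optionally `reads`), one per control gradient.
#' @return A [weighted_density()] estimate over the concatenated fractions.
#' @export
pool_controls <- function(bands) {
  bands <- Filter(Negate(is.null), bands)
  if (!length(bands))
    stop_nsip("nsip_empty_error", "no control bands to pool")
  weighted_density(do.call(rbind, bands))
}

#' Welch's t-test on two weighted density estimates
#'
#' Compares a labeled band's weighted mean density against the pooled
#' control, using the weighted variances and Kish effective sample sizes in
#' place of raw-sample moments:
#' \eqn{t = (\bar d_L - \bar d_C) / \sqrt{s^2_L/n_L + s^2_C/n_C}} with
#' Welch--Satterthwaite degrees of freedom. The default alternative is
#' one-sided for a positive shift, since \eqn{^{15}}N incorporation can only
#' increase density.
#'
#' @param labeled,control [weighted_density()] estimates.
#' @param alternative `"greater"` (labeled denser than control) or
#'   `"two.sided"`.
#' @param min_effective_n Minimum effective n required on each side.
#' @return List with `t_stat`, `df`, `p_value`, `degenerate` (both variances
#'   zero). Zero-variance ties give p = 1; zero-variance separated means are
#'   flagged degenerate with p = 0 and a warning.
#' @examples
#' b <- data.frame(density = c(1.70, 1.71, 1.72), otu_dna = c(25, 50, 25))
#' welch_density_test(weighted_density(b), weighted_density(b))$p_value
#' @export
welch_density_test <- function(labeled, control,
                               alternative = c("greater", "two.sided"),
                               min_effective_n = 2) {
  alternative <- match.arg(alternative)
  nL <- labeled$effective_n; nC <- control$effective_n
  if (nL < min_effective_n || nC < min_effective_n)
    stop_nsip("nsip_input_error",
              "effective n below %g on one side; too little information for Welch's test",
              min_effective_n)
  vL <- labeled$weighted_variance; vC <- control$weighted_variance
  diff <- labeled$mean_density - control$mean_density
  se2 <- vL / nL + vC / nC
  if (se2 == 0) {
    if (diff == 0)
      return(list(t_stat = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    warning("zero-variance bands with unequal means; degenerate comparison, p = 0")
    return(list(t_stat = sign(diff) * Inf, df = NA_real_, p_value = 0,
                degenerate = TRUE))
  }
  df <- se2^2 / ((vL / nL)^2 / (nL - 1) + (vC / nC)^2 / (nC - 1))
  t <- diff / sqrt(se2)
  p <- switch(alternative,
              greater = pt(t, df, lower.tail = FALSE),
              two.sided = 2 * pt(-abs(t), df))
  list(t_stat = t, df = df, p_value = p, degenerate = FALSE)
}

#' Flag OTUs whose bands carry too few reads
#'
#' The presence or absence of a few reads can drastically move a sparse
#' band's weighted mean density, so OTUs whose labeled or pooled-control
#' band totals fall below `min_otu_reads` are excluded before the multiple-
#' comparison correction and never enter the BH family.
#'
#' @param results Enrichment results data frame carrying
#'   `total_reads_labeled` and `total_reads_control`.
#' @param min_otu_reads Minimum summed reads per band.
#' @return `results` with `excluded`/`exclude_reason` updated
#'   (reason `"low_reads"`).
#' @export
filter_low_reads <- function(results, min_otu_reads = 500) {
  low <- !results$excluded &
    (results$total_reads_labeled < min_otu_reads |
     results$total_reads_control < min_otu_reads)
  results$excluded[low] <- TRUE
  results$exclude_reason[low] <- "low_reads"
  results
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p-values:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1; tests with
#' \eqn{q \le} `fdr` are rejected.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param fdr Target false discovery rate.
#' @return List with `q` (adjusted p-values, same order as `p`) and `reject`
#'   (logical).
#' @examples
#' bh_correct(c(0.01, 0.02, 0.04, 0.2))$q
#' @export
bh_correct <- function(p, fdr = 0.1) {
  if (!length(p)) return(list(q = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_nsip("nsip_input_error", "p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Apply the enrichment decision rule
#'
#' An OTU x treatment comparison is called enriched when it passes the FDR
#' threshold, shifts toward higher density, and the shift expressed as a
#' percentage of the full-label density gain
#' (\eqn{100 \cdot shift / \Delta\rho_{max}}) reaches `min_percent`
#' (default 30%, the precedent threshold for positive identification of
#' \eqn{^{15}}N assimilation).
#'
#' @param results Results data frame with `shift` and `q_value`.
#' @param delta_rho_max Full-label density gain, g/ml.
#' @param fdr FDR threshold on q-values.
#' @param min_percent Minimum percent enrichment; set 0 for a pure-FDR mode.
#' @return `results` with `percent_enrichment` and `enriched` filled in.
#' @export
call_enrichment <- function(results, delta_rho_max = 0.016, fdr = 0.1,
                            min_percent = 30) {
  results$percent_enrichment <- 100 * results$shift / delta_rho_max
  results$enriched <- !results$excluded &
    !is.na(results$q_value) & results$q_value <= fdr &
    !is.na(results$shift) & results$shift > 0 &
    results$percent_enrichment >= min_percent
  results
}

#' Detect per-OTU isotopic enrichment in a SIP experiment
#'
#' The full band-analysis procedure, per OTU and labeled treatment
#' (substrate x light level):
#' \enumerate{
#'   \item within each gradient, drop low-read fractions, convert counts to
#'     relative abundance and then to ng DNA per fraction via the measured
#'     bulk DNA distribution;
#'   \item locate each OTU's band window ([band_window()]) in every gradient,
#'     intersect windows across the gradients being compared, and trim all
#'     profiles to the common density window;
#'   \item estimate the labeled weighted mean density and the pooled-control
#'     density ([pool_controls()]; controls combined over all treatments);
#'   \item exclude low-read OTUs, run Welch's t-test on each remaining
#'     comparison, correct with Benjamini-Hochberg at `fdr`, and call
#'     enrichment with the `min_percent` rule.
#' }
#' Only bands of the same OTU are ever compared, so organism-to-organism
#' density differences (e.g. GC content) cancel.
#'
#' @param counts Long-format read counts (`gradient_id`, `otu_id`,
#'   `fraction`, `reads`), e.g. from [read_counts()] or a
#'   [simulate_sip_experiment()].
#' @param fractions Gradient fraction table (`gradient_id`, `fraction`,
#'   `density_g_ml`, `dna_ng`, `substrate`, `label`, `light_level`).
#' @param otus Optional OTU table with `otu_id` and `domain_flag`, used by
#'   the activity summary ([summarize_activity()]).
#' @param fdr False discovery rate for the BH correction.
#' @param min_percent Minimum percent enrichment for a positive call.
#' @param delta_rho_max Full-label density gain, g/ml.
#' @param alternative Sidedness of the Welch test.
#' @param min_fraction_reads Per-fraction read floor (see
#'   [relative_abundance()]).
#' @param band_tail_pct Band tail threshold, % of peak mass.
#' @param window_combine How per-gradient band windows are merged into the
#'   common comparison window: `"union"` (default; covers every compared
#'   band fully, so the shift estimate is not attenuated by clipping a
#'   displaced band's core) or `"intersect"` (strictly shared densities
#'   only; conservative, but biases shifts toward zero when bands are
#'   displaced by more than a fraction width).
#' @param min_band_fractions Minimum positive-mass fractions per trimmed
#'   band.
#' @param min_otu_reads Per-band read floor (see [filter_low_reads()]).
#' @param min_effective_n Minimum Kish effective n per side.
#' @return Object of class `sip_enrichment`: `$results` (one row per OTU x
#'   labeled treatment), `$params`, `$otus`, `$n_gradients`. Methods:
#'   [print()], [summary()], [plot()], [coef()].
#' @examples
#' trt <- data.frame(substrate = "NH4", light_level = "50")
#' cm <- simulate_community(20, trt,
#'                          assimilators = list(NH4.50 = c("otu_001")),
#'                          config = sim_config(seed = 3))
#' sim <- simulate_sip_experiment(cm, sim_config(seed = 3),
#'                                controls_per_treatment = 2)
#' fit <- sip_enrich(sim$counts, sim$fractions, sim$otus)
#' fit
#' @export
sip_enrich <- function(counts, fractions, otus = NULL,
                       fdr = 0.1, min_percent = 30, delta_rho_max = 0.016,
                       alternative = c("greater", "two.sided"),
                       min_fraction_reads = 100, band_tail_pct = 2,
                       window_combine = c("union", "intersect"),
                       min_band_fractions = 3, min_otu_reads = 500,
                       min_effective_n = 2) {
  alternative <- match.arg(alternative)
  window_combine <- match.arg(window_combine)
  meta <- unique(fractions[c("gradient_id", "substrate", "label",
                             "light_level")])
  if (anyDuplicated(meta$gradient_id))
    stop_nsip("nsip_format_error",
              "inconsistent treatment metadata within a gradient")
  gids <- meta$gradient_id
  control_gids <- gids[meta$label == "14N_control"]
  labeled <- meta[meta$label == "15N", , drop = FALSE]
  treatments <- unique(labeled[c("substrate", "light_level")])
  if (!nrow(treatments))
    stop_nsip("nsip_input_error", "no labeled (15N) gradients present")
  if (!length(control_gids))
    stop_nsip("nsip_input_error", "no control (14N) gradients present")

  all_otus <- sort(unique(counts$otu_id))
  ## per-gradient band bookkeeping
  bands <- list()
  for (gid in gids) {
    fr <- fractions[fractions$gradient_id == gid, ]
    fr <- fr[order(fr$fraction), ]
    sub <- counts[counts$gradient_id == gid, ]
    mat <- matrix(0L, length(all_otus), nrow(fr),
                  dimnames = list(all_otus, NULL))
    if (nrow(sub))
      mat[cbind(match(sub$otu_id, all_otus),
                match(sub$fraction, fr$fraction))] <- sub$reads
    bands[[gid]] <- tryCatch(
      .gradient_bands(mat, fr$density_g_ml, fr$dna_ng,
                      min_fraction_reads, band_tail_pct),
      nsip_empty_error = function(e) list())
  }

  rows <- list()
  for (otu in all_otus) {
    ctl_raw <- lapply(control_gids, function(g) bands[[g]][[otu]])
    ctl_raw <- Filter(Negate(is.null), ctl_raw)
    for (ti in seq_len(nrow(treatments))) {
      sub <- treatments$substrate[ti]; ll <- treatments$light_level[ti]
      lab_gids <- gids[meta$label == "15N" & meta$substrate == sub &
                         meta$light_level == ll]
      lab_raw <- lapply(lab_gids, function(g) bands[[g]][[otu]])
      lab_raw <- Filter(Negate(is.null), lab_raw)
      if (!length(lab_raw)) next  # OTU absent from this treatment
      row <- list(otu_id = otu, substrate = sub, light_level = ll,
                  control_density = NA_real_, labeled_density = NA_real_,
                  shift = NA_real_, t_stat = NA_real_, df = NA_real_,
                  p_value = NA_real_, q_value = NA_real_,
                  percent_enrichment = NA_real_, enriched = FALSE,
                  excluded = FALSE, exclude_reason = "",
                  total_reads_labeled = NA_real_,
                  total_reads_control = NA_real_,
                  effective_n_labeled = NA_real_,
                  effective_n_control = NA_real_, degenerate = FALSE)
      if (!length(ctl_raw)) {
        row$excluded <- TRUE; row$exclude_reason <- "no_control"
        rows[[length(rows) + 1L]] <- row; next
      }
      ## common density window across every band being compared
      wins <- lapply(c(lab_raw, ctl_raw), `[[`, "window")
      los <- vapply(wins, `[`, numeric(1), 1)
      his <- vapply(wins, `[`, numeric(1), 2)
      if (window_combine == "union") {
        lo <- min(los); hi <- max(his)
      } else {
        lo <- max(los); hi <- min(his)
      }
      est <- tryCatch({
        lab_trim <- lapply(lab_raw, function(b)
          trim_and_normalize(b$profile, c(lo, hi), min_band_fractions))
        ctl_trim <- lapply(ctl_raw, function(b)
          trim_and_normalize(b$profile, c(lo, hi), min_band_fractions))
        list(lab = weighted_density(do.call(rbind, lab_trim)),
             ctl = pool_controls(ctl_trim))
      }, nsip_band_undefined_error = function(e) NULL)
      if (is.null(est)) {
        row$excluded <- TRUE; row$exclude_reason <- "band_undefined"
        rows[[length(rows) + 1L]] <- row; next
      }
      row$control_density <- est$ctl$mean_density
      row$labeled_density <- est$lab$mean_density
      row$shift <- est$lab$mean_density - est$ctl$mean_density
      row$total_reads_labeled <- est$lab$total_reads
      row$total_reads_control <- est$ctl$total_reads
      row$effective_n_labeled <- est$lab$effective_n
      row$effective_n_control <- est$ctl$effective_n
      if (est$lab$effective_n < min_effective_n ||
          est$ctl$effective_n < min_effective_n) {
        row$excluded <- TRUE; row$exclude_reason <- "low_effective_n"
        rows[[length(rows) + 1L]] <- row; next
      }
      wt <- withCallingHandlers(
        welch_density_test(est$lab, est$ctl, alternative, min_effective_n),
        warning = function(w) invokeRestart("muffleWarning"))
      row$t_stat <- wt$t_stat; row$df <- wt$df; row$p_value <- wt$p_value
      row$degenerate <- wt$degenerate
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(results))
    stop_nsip("nsip_empty_error", "no testable OTU x treatment comparisons")
  results <- filter_low_reads(results, min_otu_reads)

  family <- !results$excluded & !is.na(results$p_value)
  bh <- bh_correct(results$p_value[family], fdr)
  results$q_value[family] <- bh$q
  results <- call_enrichment(results, delta_rho_max, fdr, min_percent)
  rownames(results) <- NULL

  structure(list(results = results,
                 otus = otus,
                 n_gradients = length(gids),
                 params = list(fdr = fdr, min_percent = min_percent,
                               delta_rho_max = delta_rho_max,
                               alternative = alternative,
                               min_fraction_reads = min_fraction_reads,
                               band_tail_pct = band_tail_pct,
                               window_combine = window_combine,
                               min_band_fractions = min_band_fractions,
                               min_otu_reads = min_otu_reads,
                               min_effective_n = min_effective_n),
                 call = match.call()),
            class = "sip_enrichment")
}

#' Summarize enrichment activity by treatment, domain and OTU
#'
#' @param results A `sip_enrichment` object or its `$results` data frame.
#' @param otus OTU table with `otu_id` and `domain_flag` (taken from the fit
#'   when available).
#' @return List of class `sip_activity`: `$by_treatment` (enriched OTU
#'   counts per substrate x light level x domain), `$by_otu` (treatments
#'   enriched per OTU), `$mean_treatments` (mean treatments per enriched
#'   OTU, by domain).
#' @export
summarize_activity <- function(results, otus = NULL) {
  if (inherits(results, "sip_enrichment")) {
    otus <- otus %||% results$otus
    results <- results$results
  }
  if (is.null(otus))
    otus <- data.frame(otu_id = unique(results$otu_id),
                       domain_flag = "prokaryote")
  res <- merge(results, otus[c("otu_id", "domain_flag")], by = "otu_id",
               all.x = TRUE, sort = FALSE)
  res$domain_flag[is.na(res$domain_flag)] <- "prokaryote"
  grid <- expand.grid(substrate = unique(res$substrate),
                      light_level = unique(res$light_level),
                      domain_flag = .DOMAINS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- aggregate(enriched ~ substrate + light_level + domain_flag,
                   data = res, FUN = sum)
  names(agg)[names(agg) == "enriched"] <- "n_enriched"
  by_trt <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  by_trt$n_enriched[is.na(by_trt$n_enriched)] <- 0L
  by_trt <- by_trt[order(by_trt$substrate, by_trt$light_level,
                         by_trt$domain_flag), ]
  rownames(by_trt) <- NULL

  by_otu <- aggregate(enriched ~ otu_id + domain_flag, data = res, FUN = sum)
  names(by_otu)[names(by_otu) == "enriched"] <- "n_treatments_enriched"
  enr <- by_otu[by_otu$n_treatments_enriched > 0, , drop = FALSE]
  mean_trt <- if (nrow(enr)) {
    m <- aggregate(n_treatments_enriched ~ domain_flag, data = enr,
                   FUN = mean)
    names(m)[2] <- "mean_treatments_per_enriched_otu"
    m
  } else data.frame(domain_flag = character(),
                    mean_treatments_per_enriched_otu = numeric())
  structure(list(by_treatment = by_trt, by_otu = by_otu,
                 mean_treatments = mean_trt),
            class = "sip_activity")
}

#' @export
print.sip_activity <- function(x, ...) {
  cat("Enriched OTUs per substrate x light level x domain:\n")
  print(x$by_treatment, row.names = FALSE)
  if (nrow(x$mean_treatments)) {
    cat("\nMean treatments per enriched OTU:\n")
    print(x$mean_treatments, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.sip_enrichment <- function(x, ...) {
  r <- x$results
  cat("SIP enrichment analysis\n")
  cat(sprintf("  %d OTU x treatment comparisons over %d gradients\n",
              nrow(r), x$n_gradients))
  cat(sprintf("  excluded: %d (%s)\n", sum(r$excluded),
              if (sum(r$excluded)) paste(names(table(
                r$exclude_reason[r$excluded])), table(
                r$exclude_reason[r$excluded]), collapse = ", ")
              else "none"))
  cat(sprintf("  enriched: %d at FDR %.2g with >= %.3g%% enrichment\n",
              sum(r$enriched), x$params$fdr, x$params$min_percent))
  if (sum(r$enriched)) {
    cat(sprintf("  median shift among enriched: %.4f g/ml (%.1f%% of full label)\n",
                median(r$shift[r$enriched]),
                median(r$percent_enrichment[r$enriched])))
  }
  invisible(x)
}

#' @export
summary.sip_enrichment <- function(object, ...) {
  summarize_activity(object)
}

#' @export
coef.sip_enrichment <- function(object, ...) {
  r <- object$results
  setNames(r$shift, paste(r$otu_id,
                          treatment_key(r$substrate, r$light_level)))
}

#' Density-shift overview plot
#'
#' Plots each comparison's density shift against \eqn{-\log_{10} q}, marking
#' the FDR threshold and the minimum percent-enrichment shift; enriched
#' calls are filled.
#'
#' @param x A `sip_enrichment` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sip_enrichment <- function(x, ...) {
  r <- x$results[!x$results$excluded & !is.na(x$results$q_value), ]
  q <- pmax(r$q_value, 1e-16)
  plot(r$shift, -log10(q), xlab = "density shift (g/ml)",
       ylab = expression(-log[10] ~ q),
       pch = ifelse(r$enriched, 19, 1),
       col = ifelse(r$enriched, "firebrick", "grey40"), ...)
  abline(h = -log10(x$params$fdr), lty = 2)
  abline(v = x$params$min_percent / 100 * x$params$delta_rho_max, lty = 3)
  invisible(x)
}
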
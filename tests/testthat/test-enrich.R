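band_at <- function(mean, total_mass = 10, half_width = 0.005) {
  ## symmetric 3-fraction band with the requested weighted mean and mass
  data.frame(density = mean + c(-half_width, 0, half_width),
             otu_dna = total_mass * c(0.25, 0.5, 0.25))
}

test_that("control pooling is idempotent and mass-weighted", {
  b <- band_at(1.705)
  single <- pool_controls(list(b))
  expect_equal(single$mean_density, weighted_density(b)$mean_density)

  ## two identical control bands: pooled mean unchanged
  twice <- pool_controls(list(b, b))
  expect_equal(twice$mean_density, single$mean_density)

  ## equal-mass controls at 1.705 and 1.707 pool to 1.706
  pooled <- pool_controls(list(band_at(1.705), band_at(1.707)))
  expect_equal(pooled$mean_density, 1.706)

  expect_error(pool_controls(list()), class = "nsip_empty_error")
})

test_that("the Welch test matches hand arithmetic and handles degeneracy", {
  est <- function(m, v, n) {
    structure(list(mean_density = m, weighted_variance = v, effective_n = n,
                   total_reads = 1000, n_fractions = n),
              class = "density_estimate")
  }
  ## identical estimates: t = 0, one-sided p = 0.5
  null <- welch_density_test(est(1.70, 1e-6, 8), est(1.70, 1e-6, 8))
  expect_equal(null$t_stat, 0)
  expect_equal(null$p_value, 0.5)
  ## Satterthwaite limit for equal n and variance: df = 2n - 2
  expect_equal(null$df, 14)

  ## hand case: diff 0.008, s2 = 1e-6, n = 8 on both sides
  w <- welch_density_test(est(1.712, 1e-6, 8), est(1.704, 1e-6, 8))
  expect_equal(w$t_stat, 16)
  expect_equal(w$df, 14)
  oracle <- bf_welch(1.712, 1e-6, 8, 1.704, 1e-6, 8)
  expect_equal(w$p_value, oracle$p, tolerance = 1e-12)

  ## randomized agreement with the brute-force formulas
  set.seed(19)
  for (i in 1:25) {
    mL <- 1.70 + runif(1, 0, 0.01); mC <- 1.70
    vL <- runif(1, 1e-7, 1e-4); vC <- runif(1, 1e-7, 1e-4)
    nL <- runif(1, 2.2, 30); nC <- runif(1, 2.2, 30)
    got <- welch_density_test(est(mL, vL, nL), est(mC, vC, nC))
    want <- bf_welch(mL, vL, nL, mC, vC, nC)
    expect_equal(got$t_stat, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }

  ## zero-variance ties and separations
  tie <- welch_density_test(est(1.70, 0, 5), est(1.70, 0, 5))
  expect_equal(tie$p_value, 1)
  expect_true(tie$degenerate)
  expect_warning(
    sep <- welch_density_test(est(1.71, 0, 5), est(1.70, 0, 5)),
    "degenerate")
  expect_equal(sep$p_value, 0)

  expect_error(welch_density_test(est(1.70, 1e-6, 1.2), est(1.70, 1e-6, 8)),
               class = "nsip_input_error")
})

test_that("BH correction matches the brute-force step-up procedure", {
  expect_equal(bh_correct(0.03)$q, 0.03)
  ex <- bh_correct(c(0.01, 0.02, 0.04, 0.2), fdr = 0.1)
  expect_equal(ex$q, c(0.04, 0.04, 0.16 / 3, 0.2), tolerance = 1e-12)
  expect_equal(sum(ex$reject), 3)
  expect_equal(sum(bh_correct(rep(1, 6))$reject), 0)
  expect_length(bh_correct(numeric(0))$q, 0)

  set.seed(41)
  for (i in 1:40) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_correct(p)$q, bf_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_correct(c(0.5, 1.2)), class = "nsip_input_error")
})

test_that("low-read OTUs are excluded before the BH family forms", {
  res <- data.frame(otu_id = sprintf("o%02d", 1:10),
                    total_reads_labeled = c(rep(1000, 7), 100, 200, 499),
                    total_reads_control = 1000,
                    p_value = 0.01,
                    excluded = FALSE, exclude_reason = "")
  out <- filter_low_reads(res, min_otu_reads = 500)
  expect_equal(sum(out$excluded), 3)
  expect_equal(unique(out$exclude_reason[out$excluded]), "low_reads")
  expect_equal(sum(!out$excluded), 7)  # BH family size
  ## threshold 0 is a vacuous filter
  expect_equal(sum(filter_low_reads(res, 0)$excluded), 0)
})

test_that("enrichment calls require FDR, direction and percent together", {
  res <- data.frame(shift = c(0.008, -0.004, 0.012, 0.003),
                    q_value = c(0.05, 0.05, 0.2, 0.05),
                    excluded = FALSE)
  out <- call_enrichment(res, delta_rho_max = 0.016, fdr = 0.1,
                         min_percent = 30)
  expect_equal(out$percent_enrichment, c(50, -25, 75, 18.75))
  ## q ok + 50%: enriched; negative shift: no; q above fdr: no; below 30%: no
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE, FALSE))
  ## pure-FDR mode re-admits the small positive shift
  expect_equal(call_enrichment(res, fdr = 0.1, min_percent = 0)$enriched,
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("activity summaries count enriched OTUs by treatment and domain", {
  res <- data.frame(
    otu_id = c("p1", "p2", "p3", "p4", "e1", "e2", "p1", "p1"),
    substrate = c(rep("NH4", 6), "NO3", "urea"),
    light_level = "50",
    enriched = c(rep(TRUE, 6), TRUE, TRUE),
    excluded = FALSE)
  otus <- data.frame(otu_id = c("p1", "p2", "p3", "p4", "e1", "e2"),
                     domain_flag = c(rep("prokaryote", 4),
                                     rep("eukaryote_chloroplast", 2)))
  act <- summarize_activity(res, otus)
  nh4 <- act$by_treatment[act$by_treatment$substrate == "NH4", ]
  expect_equal(nh4$n_enriched[nh4$domain_flag == "prokaryote"], 4)
  expect_equal(nh4$n_enriched[nh4$domain_flag == "eukaryote_chloroplast"], 2)
  ## eukaryote share of NH4 enrichment at this depth
  expect_equal(2 / sum(nh4$n_enriched), 1 / 3)
  ## p1 is active in three treatments
  expect_equal(act$by_otu$n_treatments_enriched[act$by_otu$otu_id == "p1"], 3)
  expect_equal(
    act$mean_treatments$mean_treatments_per_enriched_otu[
      act$mean_treatments$domain_flag == "eukaryote_chloroplast"], 1)

  ## nothing enriched: all counts zero
  none <- res; none$enriched <- FALSE
  act0 <- summarize_activity(none, otus)
  expect_true(all(act0$by_treatment$n_enriched == 0))
  expect_equal(nrow(act0$mean_treatments), 0)
})

test_that("more label never yields fewer enrichment calls", {
  counts <- c(0L, 0L, 0L)
  levels <- c(0.15, 0.45, 0.8)
  for (i in seq_along(levels)) {
    r <- run_sip_sim(seed = 77, n_otus = 60, n_assim = 15,
                     atom_fraction = levels[i], reads_per_fraction = 5000,
                     controls = 2)
    counts[i] <- sum(r$results$enriched)
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("fit objects satisfy the calling invariants and expose methods", {
  r <- run_sip_sim(seed = 55, n_otus = 40, n_assim = 8,
                   reads_per_fraction = 5000, controls = 2)
  res <- r$results
  ok <- !is.na(res$p_value) & !is.na(res$q_value)
  expect_true(all(res$q_value[ok] >= res$p_value[ok]))
  expect_true(all(!res$excluded[res$enriched]))
  expect_true(all(res$shift[res$enriched] > 0))
  expect_true(all(res$percent_enrichment[res$enriched] >= 30))

  expect_s3_class(r$fit, "sip_enrichment")
  expect_output(print(r$fit), "enriched")
  expect_s3_class(summary(r$fit), "sip_activity")
  expect_named(coef(r$fit))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(r$fit))
})
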
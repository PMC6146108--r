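## Shared simulation fixtures built in code.

one_treatment <- data.frame(substrate = "NH4", light_level = "50",
                            stringsAsFactors = FALSE)

## A full labeled-vs-control experiment with n_assim designated assimilators
## among n_otus OTUs; returns the fit plus ground truth.
run_sip_sim <- function(seed, n_otus = 200, n_assim = 0, atom_fraction = 0.5,
                        reads_per_fraction = 20000, controls = 3,
                        min_percent = 30) {
  cfg <- sim_config(seed = seed, reads_per_fraction = reads_per_fraction)
  assim <- if (n_assim > 0)
    list(NH4.50 = sprintf("otu_%03d", seq_len(n_assim))) else list()
  cm <- simulate_community(n_otus, one_treatment, assimilators = assim,
                           atom_fraction = atom_fraction, config = cfg)
  sim <- simulate_sip_experiment(cm, cfg, controls_per_treatment = controls)
  fit <- sip_enrich(sim$counts, sim$fractions, sim$otus,
                    min_percent = min_percent)
  truth <- unique(sim$truth$otu_id[sim$truth$atom_fraction_15N > 0])
  list(fit = fit, results = fit$results, true_assimilators = truth, sim = sim)
}

## weighted mean density of one OTU over the full gradient, no trimming
untrimmed_wmd <- function(gradient, otu) {
  prop <- relative_abundance(gradient$counts, min_fraction_reads = 1)
  kept <- setdiff(seq_len(ncol(gradient$counts)), attr(prop, "dropped"))
  mass <- otu_mass(prop, gradient$fractions$dna_ng[kept])
  weighted_density(data.frame(density = gradient$fractions$density_g_ml[kept],
                              otu_dna = mass[otu, ]))
}
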
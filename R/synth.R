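#' Simulation configuration for synthetic SIP experiments
#'
#' Collects the physical and measurement parameters of a simulated CsCl
#' gradient ultracentrifugation run. Defaults describe a typical nitrogen-SIP
#' setup: fifty ~100 ul fractions spanning 1.66--1.77 g/ml, Gaussian DNA
#' bands of standard deviation 0.006 g/ml, a full-label (100 atom%
#' \eqn{^{15}}N) buoyant density gain of 0.016 g/ml, and the classic linear
#' GC-content relation \eqn{\rho = 1.660 + 0.098\,GC}.
#'
#' @param n_fractions Number of fractions collected per gradient (densest
#'   first).
#' @param fraction_volume Fraction volume in microlitres (metadata only; the
#'   density grid is set by `density_min`/`density_max`).
#' @param density_min,density_max Gradient density range in g/ml.
#' @param band_sd Equilibrium band standard deviation in g/ml.
#' @param delta_rho_max Density gain at 100 atom% \eqn{^{15}}N, g/ml.
#' @param gc_slope,gc_intercept Linear GC-to-density relation, g/ml per unit
#'   GC fraction and g/ml.
#' @param reads_per_fraction Amplicon reads drawn per sequenced fraction.
#' @param dna_total_ng Total DNA mass loaded on each gradient, ng.
#' @param qubit_cv Coefficient of variation of the fluorometric bulk-DNA
#'   quantification (multiplicative lognormal noise).
#' @param refractometer_sd Standard deviation of the per-fraction density
#'   reading, g/ml.
#' @param min_seq_dna_ng Minimum measured bulk DNA (ng) for a fraction to be
#'   amplified and sequenced; fractions below it yield no reads.
#' @param abundance_sdlog Lognormal sdlog of community relative abundances.
#' @param natural_atom_pct Natural abundance of \eqn{^{15}}N, atom%.
#' @param seed Integer seed from which all per-gradient random streams are
#'   derived.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$band_sd
#' @export
sim_config <- function(n_fractions = 50L,
                       fraction_volume = 100,
                       density_min = 1.66,
                       density_max = 1.77,
                       band_sd = 0.006,
                       delta_rho_max = 0.016,
                       gc_slope = 0.098,
                       gc_intercept = 1.660,
                       reads_per_fraction = 20000L,
                       dna_total_ng = 2000,
                       qubit_cv = 0.05,
                       refractometer_sd = 2e-4,
                       min_seq_dna_ng = 0.01,
                       abundance_sdlog = 0.75,
                       natural_atom_pct = 0.366,
                       seed = 1L) {
  if (density_min >= density_max)
    stop_nsip("nsip_config_error", "density_min must be < density_max")
  if (band_sd <= 0)
    stop_nsip("nsip_config_error", "band_sd must be positive")
  if (delta_rho_max < 0)
    stop_nsip("nsip_config_error", "delta_rho_max must be >= 0")
  if (n_fractions < 2)
    stop_nsip("nsip_config_error", "need at least 2 fractions")
  structure(list(n_fractions = as.integer(n_fractions),
                 fraction_volume = fraction_volume,
                 density_min = density_min, density_max = density_max,
                 band_sd = band_sd, delta_rho_max = delta_rho_max,
                 gc_slope = gc_slope, gc_intercept = gc_intercept,
                 reads_per_fraction = as.integer(reads_per_fraction),
                 dna_total_ng = dna_total_ng, qubit_cv = qubit_cv,
                 refractometer_sd = refractometer_sd,
                 min_seq_dna_ng = min_seq_dna_ng,
                 abundance_sdlog = abundance_sdlog,
                 natural_atom_pct = natural_atom_pct,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## deterministic per-gradient seed stream, kept inside 32-bit range
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + index * 97 + 1) %% 2147483647)
}

#' Simulate a microbial community with designated assimilators
#'
#' Draws GC content uniformly on \[0.35, 0.65\] and community relative
#' abundances from a lognormal distribution (normalized to sum to 1). OTUs
#' named in `assimilators` carry a positive \eqn{^{15}}N atom fraction in the
#' corresponding labeled treatment; all other OTU x treatment combinations
#' (and every control) are at atom fraction 0.
#'
#' @param n_otus Number of OTUs.
#' @param treatments Data frame with columns `substrate`
#'   (`"NH4"`/`"NO3"`/`"urea"`) and `light_level` (`"50"`/`"10"`/`"1"`); one
#'   row per labeled treatment.
#' @param assimilators Named list mapping a treatment key
#'   (`"<substrate>.<light_level>"`) to a character vector of OTU ids that
#'   assimilate the substrate in that treatment.
#' @param atom_fraction Atom fraction \eqn{^{15}}N (0--1) reached by
#'   assimilator DNA; scalar, or named by treatment key.
#' @param config A [sim_config()].
#' @param eukaryote_fraction Proportion of OTUs flagged
#'   `eukaryote_chloroplast`.
#' @return A list of class `sip_community`: `$otus` (data frame with
#'   `otu_id`, `gc_fraction`, `domain_flag`, `baseline_abundance`), `$atom`
#'   (OTU x treatment matrix of atom fractions), `$treatments`.
#' @examples
#' trt <- data.frame(substrate = "NH4", light_level = "50")
#' cm <- simulate_community(10, trt,
#'                          assimilators = list(NH4.50 = c("otu_001")),
#'                          config = sim_config(seed = 7))
#' sum(cm$otus$baseline_abundance)
#' @export
simulate_community <- function(n_otus, treatments,
                               assimilators = list(),
                               atom_fraction = 0.5,
                               config = sim_config(),
                               eukaryote_fraction = 0.2) {
  if (n_otus < 1)
    stop_nsip("nsip_config_error", "n_otus must be >= 1")
  keys <- treatment_key(treatments$substrate, treatments$light_level)
  if (anyDuplicated(keys))
    stop_nsip("nsip_config_error", "duplicated treatment definitions")
  otu_id <- sprintf("otu_%03d", seq_len(n_otus))
  set.seed(.derive_seed(config$seed, 0L))
  gc <- runif(n_otus, 0.35, 0.65)
  raw <- rlnorm(n_otus, meanlog = 0, sdlog = config$abundance_sdlog)
  abund <- raw / sum(raw)
  domain <- ifelse(runif(n_otus) < eukaryote_fraction,
                   "eukaryote_chloroplast", "prokaryote")
  atom <- matrix(0, n_otus, length(keys), dimnames = list(otu_id, keys))
  af <- if (length(atom_fraction) == 1L && is.null(names(atom_fraction)))
    setNames(rep(atom_fraction, length(keys)), keys) else atom_fraction
  for (k in names(assimilators)) {
    if (!k %in% keys)
      stop_nsip("nsip_config_error", "unknown treatment key '%s'", k)
    ids <- assimilators[[k]]
    bad <- setdiff(ids, otu_id)
    if (length(bad))
      stop_nsip("nsip_config_error", "unknown otu_id in assimilators: %s",
                paste(bad, collapse = ", "))
    atom[ids, k] <- af[[k]]
  }
  structure(list(otus = data.frame(otu_id = otu_id, gc_fraction = gc,
                                   domain_flag = domain,
                                   baseline_abundance = abund,
                                   stringsAsFactors = FALSE),
                 atom = atom,
                 treatments = treatments),
            class = "sip_community")
}

#' Treatment key string
#'
#' @param substrate,light_level Vectors of substrate and light-level tokens.
#' @return Character vector `"<substrate>.<light_level>"`.
#' @export
treatment_key <- function(substrate, light_level) {
  paste(substrate, light_level, sep = ".")
}

#' Equilibrium band center density of an OTU's DNA
#'
#' Linear buoyant-density model: the GC relation
#' \eqn{\rho = intercept + slope \cdot GC} plus a \eqn{^{15}}N term
#' proportional to the atom fraction incorporated,
#' \eqn{\Delta\rho_{max} \cdot a}.
#'
#' @param gc_fraction GC content as a fraction in \[0, 1\].
#' @param atom_fraction Atom fraction \eqn{^{15}}N incorporated (0--1).
#' @param config A [sim_config()] supplying the constants.
#' @return Band center density, g/ml (vectorized).
#' @examples
#' band_center(0.5)                      # 1.709
#' band_center(0.5, atom_fraction = 1)   # + 0.016
#' @export
band_center <- function(gc_fraction, atom_fraction = 0, config = sim_config()) {
  if (any(gc_fraction < 0 | gc_fraction > 1))
    stop_nsip("nsip_input_error", "gc_fraction must lie in [0, 1]")
  config$gc_intercept + config$gc_slope * gc_fraction +
    config$delta_rho_max * atom_fraction
}

#' Simulate one CsCl gradient: fractions, bulk DNA and read counts
#'
#' Fractions are collected densest-first on an even density grid from
#' `density_max` down to `density_min`. Each OTU's expected DNA mass per
#' fraction is its community abundance times the Gaussian band mass
#' (center from [band_center()], sd `band_sd`) integrated over the
#' fraction's density interval. Bulk DNA per fraction is the community total
#' times `dna_total_ng`, with multiplicative lognormal quantification noise
#' of CV `qubit_cv`; reported densities carry additive refractometer noise.
#' Reads are multinomial per fraction with probabilities proportional to
#' OTU mass.
#'
#' @param community A [simulate_community()] result.
#' @param treatment Treatment key (column of `community$atom`), or `NA` for a
#'   gradient where no OTU is labeled.
#' @param label `"15N"` or `"14N_control"`; controls force atom fraction 0.
#' @param config A [sim_config()].
#' @param gradient_id Identifier for the gradient.
#' @param seed Integer seed for this gradient's random stream.
#' @return List with `$fractions` (data frame `fraction`, `density_g_ml`,
#'   `dna_ng`) and `$counts` (OTU x fraction integer matrix).
#' @export
simulate_gradient <- function(community, treatment = NA, label = "15N",
                              config = sim_config(),
                              gradient_id = "G1",
                              seed = config$seed) {
  if (!inherits(community, "sip_community"))
    stop_nsip("nsip_input_error", "community must be a sip_community")
  if (config$reads_per_fraction <= 0)
    stop_nsip("nsip_config_error", "reads_per_fraction must be positive")
  label <- match.arg(label, .LABELS)
  otus <- community$otus
  n <- nrow(otus)
  atom <- if (label == "14N_control" || is.na(treatment)) rep(0, n)
          else community$atom[, treatment]

  nf <- config$n_fractions
  edges <- seq(config$density_max, config$density_min, length.out = nf + 1)
  mid <- (edges[-1] + edges[-(nf + 1)]) / 2

  centers <- band_center(otus$gc_fraction, atom, config)
  ## expected mass of OTU o in fraction f: abundance * Gaussian band mass
  ## over [lower edge, upper edge]; rows OTUs, cols fractions
  upper <- matrix(vapply(seq_len(nf), function(j)
    pnorm(edges[j], centers, config$band_sd), numeric(n)), nrow = n)
  lower <- matrix(vapply(seq_len(nf), function(j)
    pnorm(edges[j + 1], centers, config$band_sd), numeric(n)), nrow = n)
  emass <- (upper - lower) * otus$baseline_abundance
  dimnames(emass) <- list(otus$otu_id, NULL)

  set.seed(seed)
  density <- mid + if (config$refractometer_sd > 0)
    rnorm(nf, 0, config$refractometer_sd) else 0
  total <- colSums(emass)
  noise <- if (config$qubit_cv > 0) {
    sdlog <- sqrt(log(1 + config$qubit_cv^2))
    rlnorm(nf, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, nf)
  dna_ng <- total * config$dna_total_ng * noise

  counts <- matrix(0L, n, nf, dimnames = list(otus$otu_id, NULL))
  for (j in seq_len(nf)) {
    ## fractions with (almost) no template fail to amplify and go unsequenced
    if (total[j] <= 0 || dna_ng[j] < config$min_seq_dna_ng) next
    counts[, j] <- rmultinom(1, config$reads_per_fraction, emass[, j])
  }
  list(gradient_id = gradient_id,
       fractions = data.frame(fraction = seq_len(nf),
                              density_g_ml = density, dna_ng = dna_ng),
       counts = counts)
}

#' Simulate a complete SIP experiment as the long-format pipeline tables
#'
#' For every row of `community$treatments` one \eqn{^{15}}N-labeled gradient
#' is generated, plus `controls_per_treatment` \eqn{^{14}}N control gradients
#' (atom fraction 0 for every OTU). Returns the same tables the readers
#' ([read_fractions()], [read_counts()], [read_otus()]) consume, plus a
#' ground-truth table of simulated atom fractions.
#'
#' @param community A [simulate_community()] result.
#' @param config A [sim_config()]; all randomness derives from `config$seed`.
#' @param controls_per_treatment Number of control gradients per treatment.
#' @return List of class `sip_simulation` with data frames `fractions`
#'   (gradient metadata + per-fraction density and bulk DNA), `counts`
#'   (long format reads), `otus`, and `truth` (`otu_id`, `treatment`,
#'   `atom_fraction_15N`).
#' @examples
#' trt <- data.frame(substrate = "NH4", light_level = "50")
#' cm <- simulate_community(5, trt, config = sim_config(seed = 2))
#' sim <- simulate_sip_experiment(cm, sim_config(seed = 2))
#' head(sim$fractions)
#' @export
simulate_sip_experiment <- function(community, config = sim_config(),
                                    controls_per_treatment = 1L) {
  trt <- community$treatments
  keys <- treatment_key(trt$substrate, trt$light_level)
  frac_list <- list(); count_list <- list(); idx <- 0L
  add_gradient <- function(key, i, substrate, light, label) {
    idx <<- idx + 1L
    gid <- sprintf("%s_%s_%d", gsub("\\.", "_", key),
                   if (label == "15N") "L" else "C", i)
    g <- simulate_gradient(community, treatment = key, label = label,
                           config = config, gradient_id = gid,
                           seed = .derive_seed(config$seed, idx))
    fr <- g$fractions
    fr <- data.frame(gradient_id = gid, fr, substrate = substrate,
                     label = label, light_level = light,
                     stringsAsFactors = FALSE)
    cm <- g$counts
    cl <- data.frame(gradient_id = gid,
                     otu_id = rep(rownames(cm), times = ncol(cm)),
                     fraction = rep(seq_len(ncol(cm)), each = nrow(cm)),
                     reads = as.integer(cm),
                     stringsAsFactors = FALSE)
    frac_list[[gid]] <<- fr
    count_list[[gid]] <<- cl[cl$reads > 0, , drop = FALSE]
  }
  for (r in seq_along(keys)) {
    add_gradient(keys[r], 1L, trt$substrate[r], trt$light_level[r], "15N")
    for (i in seq_len(controls_per_treatment))
      add_gradient(keys[r], i, trt$substrate[r], trt$light_level[r],
                   "14N_control")
  }
  truth <- data.frame(
    otu_id = rep(rownames(community$atom), times = ncol(community$atom)),
    treatment = rep(colnames(community$atom), each = nrow(community$atom)),
    atom_fraction_15N = as.numeric(community$atom),
    stringsAsFactors = FALSE)
  structure(list(fractions = do.call(rbind, c(frac_list,
                                              make.row.names = FALSE)),
                 counts = do.call(rbind, c(count_list,
                                           make.row.names = FALSE)),
                 otus = community$otus[, c("otu_id", "domain_flag")],
                 truth = truth,
                 config = config),
            class = "sip_simulation")
}

#' Simulate an IRMS observation pair for a tracer uptake incubation
#'
#' Inverts the tracer uptake-rate equation: given a true uptake rate, the
#' particulate-N concentration and the dissolved-pool \eqn{^{15}}N
#' enrichment, it returns the initial and final particulate atom% a mass
#' spectrometer would measure, with optional Gaussian instrument noise. With
#' `irms_sd = 0`, [uptake_rate()] recovers `true_rate` exactly.
#'
#' @param true_rate True uptake rate, umol N/l/d.
#' @param pn_conc Particulate N concentration, umol N/l.
#' @param dissolved_atom_pct Dissolved-pool enrichment, atom%.
#' @param duration Incubation length, d.
#' @param irms_sd IRMS measurement noise sd, atom%.
#' @param natural_atom_pct Natural abundance \eqn{^{15}}N, atom%.
#' @return One-row data frame with `pn_conc`, `atom_pct_t0`, `atom_pct_tf`,
#'   `dissolved_atom_pct`, `duration`.
#' @examples
#' obs <- simulate_uptake_obs(0.01, pn_conc = 1, dissolved_atom_pct = 7.177)
#' obs$atom_pct_tf - obs$atom_pct_t0   # 0.0681
#' @export
simulate_uptake_obs <- function(true_rate, pn_conc, dissolved_atom_pct,
                                duration = 1, irms_sd = 0,
                                natural_atom_pct = 0.366) {
  if (any(true_rate < 0))
    stop_nsip("nsip_input_error", "true_rate must be >= 0")
  if (any(pn_conc <= 0))
    stop_nsip("nsip_input_error", "pn_conc must be positive")
  if (any(dissolved_atom_pct <= natural_atom_pct))
    stop_nsip("nsip_input_error",
              "dissolved_atom_pct must exceed natural abundance")
  t0 <- natural_atom_pct
  tf <- t0 + true_rate * duration * (dissolved_atom_pct - t0) / pn_conc
  if (any(tf > dissolved_atom_pct))
    stop_nsip("nsip_infeasible_error",
              "implied final atom%% exceeds the dissolved pool enrichment; rate too high for pool")
  if (irms_sd > 0) {
    t0 <- t0 + rnorm(length(tf), 0, irms_sd)
    tf <- tf + rnorm(length(tf), 0, irms_sd)
  }
  data.frame(pn_conc = pn_conc, atom_pct_t0 = t0, atom_pct_tf = tf,
             dissolved_atom_pct = dissolved_atom_pct, duration = duration)
}
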
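## 15N tracer uptake rates, euphotic-zone depth integration, and the
## new-vs-regenerated production budget (f-ratio, Redfield C equivalents).

#' Isotopic enrichment of the dissolved substrate pool
#'
#' Mixing ratio of the \eqn{^{15}}N spike with the ambient (natural
#' abundance) pool:
#' \eqn{(spike \cdot A_{spike} + ambient \cdot A_{nat}) / (spike + ambient)}.
#'
#' @param ambient Ambient substrate concentration, umol/l.
#' @param spike Tracer addition, umol/l.
#' @param spike_atom_pct Atom% \eqn{^{15}}N of the tracer (> 98% for
#'   commercial stocks).
#' @param natural_atom_pct Natural abundance, atom%.
#' @return Dissolved-pool enrichment, atom% (vectorized).
#' @examples
#' dissolved_atom_pct(0.20, 0.015, 98)   # 7.177
#' @export
dissolved_atom_pct <- function(ambient, spike, spike_atom_pct = 98,
                               natural_atom_pct = 0.366) {
  if (any(ambient < 0))
    stop_nsip("nsip_input_error", "ambient concentration must be >= 0")
  if (any(spike <= 0))
    stop_nsip("nsip_input_error", "spike concentration must be positive")
  if (any(ambient + spike <= 0))
    stop_nsip("nsip_input_error", "dissolved pool is empty")
  (spike * spike_atom_pct + ambient * natural_atom_pct) / (spike + ambient)
}

#' Tracer uptake rate from particulate-N atom% enrichment
#'
#' \deqn{\rho = \frac{A_{tf} - A_{t0}}{A_{diss} - A_{t0}} \cdot
#'   \frac{PN}{t}}
#' where \eqn{A_{t0}}, \eqn{A_{tf}} are the particulate-N atom% at the start
#' and end of the incubation, \eqn{A_{diss}} the dissolved-pool enrichment,
#' \eqn{PN} the particulate N concentration and \eqn{t} the incubation
#' length. A final atom% below the initial (possible within instrument
#' noise) is floored at rate 0 with a warning.
#'
#' @param atom_pct_tf,atom_pct_t0 Final and initial particulate atom%.
#' @param dissolved_atom_pct Dissolved-pool enrichment, atom%.
#' @param pn_conc Particulate N concentration, umol N/l.
#' @param duration Incubation length, d.
#' @return Uptake rate, umol N/l/d (equivalently mmol N/m3/d); vectorized.
#' @examples
#' uptake_rate(0.50, 0.366, 10, pn_conc = 1, duration = 1)   # 0.0139
#' @export
uptake_rate <- function(atom_pct_tf, atom_pct_t0, dissolved_atom_pct,
                        pn_conc, duration) {
  if (any(duration <= 0))
    stop_nsip("nsip_input_error", "duration must be positive")
  if (any(dissolved_atom_pct <= atom_pct_t0))
    stop_nsip("nsip_input_error",
              "dissolved enrichment must exceed initial particulate atom%%")
  rate <- (atom_pct_tf - atom_pct_t0) / (dissolved_atom_pct - atom_pct_t0) *
    pn_conc / duration
  if (any(rate < 0)) {
    warning("negative apparent uptake (tf < t0 within noise); floored at 0")
    rate <- pmax(rate, 0)
  }
  rate
}

#' Uptake rates for a table of observations
#'
#' Computes the dissolved-pool enrichment from the ambient and spike
#' concentrations of each row and applies [uptake_rate()].
#'
#' @param obs Data frame as returned by [read_uptake()].
#' @return `obs` with `dissolved_atom_pct` and `rate` columns added.
#' @export
uptake_rates <- function(obs) {
  obs$dissolved_atom_pct <- dissolved_atom_pct(
    obs$ambient_conc, obs$spike_conc, obs$spike_atom_pct)
  obs$rate <- uptake_rate(obs$atom_pct_tf, obs$atom_pct_t0,
                          obs$dissolved_atom_pct, obs$pn_conc, obs$duration)
  obs
}

#' Fit a linear IRMS size-effect and drift calibration from standards
#'
#' Reference standards of known atom% measured across the run give the
#' additive bias as a linear function of the sample size signal and the run
#' position: \eqn{measured - true = a \cdot size + b \cdot drift}.
#'
#' @param standards Data frame with columns `measured`, `true`,
#'   `size_signal`, `drift_index`.
#' @return List with coefficients `a` (size effect) and `b` (drift).
#' @export
irms_calibrate <- function(standards) {
  .require_cols(standards, c("measured", "true", "size_signal",
                             "drift_index"), "standards")
  resid <- standards$measured - standards$true
  fit <- lm(resid ~ 0 + size_signal + drift_index, data = standards)
  co <- coef(fit)
  list(a = unname(co["size_signal"]), b = unname(co["drift_index"]))
}

#' Correct raw IRMS atom% for size effect and drift
#'
#' Applies `corrected = raw - (a * size_signal + b * drift_index)` with the
#' coefficients from [irms_calibrate()]. Without a calibration the data are
#' returned unchanged with a warning.
#'
#' @param raw Raw atom% measurements.
#' @param size_signal Instrument size (beam area) signal per sample.
#' @param drift_index Run-position index per sample.
#' @param calibration List with `a` and `b`, or `NULL`.
#' @return Corrected atom% (vectorized).
#' @export
irms_correct <- function(raw, size_signal, drift_index, calibration = NULL) {
  if (is.null(calibration)) {
    warning("no IRMS calibration supplied; returning raw atom% unchanged")
    return(raw)
  }
  raw - (calibration$a * size_signal + calibration$b * drift_index)
}

#' Depth-integrate a rate profile over the euphotic zone
#'
#' Trapezoidal integration of volumetric rates over depth, extending the
#' shallowest measurement unchanged up to `z_top` (surface) and stopping at
#' `z_bottom` (default the deepest sampled depth, the 1% light level).
#'
#' @param depth Sample depths, m, strictly increasing.
#' @param rate Volumetric rates, mmol N/m3/d, aligned with `depth`.
#' @param z_top,z_bottom Integration bounds, m.
#' @return Areal rate, mmol N/m2/d.
#' @examples
#' depth_integrate(c(5, 17, 35), c(0.1, 0.2, 0.4))   # 7.7
#' @export
depth_integrate <- function(depth, rate, z_top = 0, z_bottom = max(depth)) {
  if (!length(depth))
    stop_nsip("nsip_input_error", "need at least one depth")
  if (length(depth) != length(rate))
    stop_nsip("nsip_input_error", "depth and rate lengths differ")
  if (is.unsorted(depth, strictly = TRUE))
    stop_nsip("nsip_input_error", "depths must be strictly increasing")
  if (any(rate < 0))
    stop_nsip("nsip_input_error", "rates must be >= 0")
  z <- depth; r <- rate
  if (z[1] > z_top) { z <- c(z_top, z); r <- c(r[1], r) }
  if (z_bottom > z[length(z)]) {
    ## extend the deepest measurement unchanged down to the bottom bound
    z <- c(z, z_bottom); r <- c(r, r[length(r)])
  } else if (z_bottom < z[length(z)]) {
    ## interpolate the profile at the integration bottom before truncating
    rb <- approx_rate(z, r, z_bottom)
    keep <- z < z_bottom
    z <- c(z[keep], z_bottom); r <- c(r[keep], rb)
  }
  sum(diff(z) * (head(r, -1) + r[-1]) / 2)
}

approx_rate <- function(z, r, z0) {
  i <- findInterval(z0, z)
  if (i >= length(z)) return(r[length(z)])
  r[i] + (r[i + 1] - r[i]) * (z0 - z[i]) / (z[i + 1] - z[i])
}

#' f-ratio: new over total production
#'
#' New production is externally supplied nitrogen — nitrate uptake plus
#' \eqn{N_2} fixation; regenerated production is recycled nitrogen —
#' ammonium and urea uptake. The f-ratio is new / (new + regenerated). Pass
#' `total` to use an independently determined total production instead of
#' the component sum.
#'
#' @param no3,n2,nh4,urea Integrated rates, mmol N/m2/d.
#' @param total Optional total production overriding `no3 + n2 + nh4 + urea`.
#' @return The f-ratio, a proportion in \[0, 1\].
#' @examples
#' f_ratio(no3 = 3.1, n2 = 0.19, total = 8.8)   # ~0.37
#' @export
f_ratio <- function(no3, n2 = 0, nh4 = 0, urea = 0, total = NULL) {
  rates <- c(no3, n2, nh4, urea)
  if (any(rates < 0))
    stop_nsip("nsip_input_error", "integrated rates must be >= 0")
  tot <- total %||% sum(rates)
  if (tot <= 0)
    stop_nsip("nsip_input_error", "total production is zero; f-ratio undefined")
  (no3 + n2) / tot
}

#' Redfield carbon equivalent of a nitrogen uptake rate
#'
#' Converts N uptake to the C fixation it can support at the canonical
#' marine stoichiometry C:N = 106:16.
#'
#' @param n_rate N rate, mmol N/m2/d.
#' @param c_to_n C:N ratio (default 106/16).
#' @return C rate, mmol C/m2/d.
#' @examples
#' redfield_c(0.19)   # ~1.3
#' @export
redfield_c <- function(n_rate, c_to_n = 106 / 16) {
  if (any(n_rate < 0))
    stop_nsip("nsip_input_error", "n_rate must be >= 0")
  n_rate * c_to_n
}

#' Build the depth-integrated nitrogen uptake budget
#'
#' Integrates each substrate's rate profile over the euphotic zone (or takes
#' already-integrated rates), then derives each substrate's fraction of
#' total uptake, its Redfield carbon equivalent, and the f-ratio.
#'
#' @param profiles Named list over substrates (`NH4`, `NO3`, `urea`, `N2`);
#'   each element either a data frame with `depth` and `rate` columns
#'   (integrated via [depth_integrate()]) or a single already-integrated
#'   rate in mmol N/m2/d. A missing substrate is treated as 0 with a
#'   warning.
#' @param z_top,z_bottom Integration bounds passed to [depth_integrate()]
#'   (default: surface to the deepest depth of each profile).
#' @param c_to_n Redfield C:N ratio.
#' @return Object of class `n_budget`: `$table` (per-substrate integrated
#'   rate, fraction of total, C equivalent), `$total_n`, `$total_c`,
#'   `$f_ratio`.
#' @examples
#' n_budget(list(urea = 3.4, NO3 = 3.1, NH4 = 2.4, N2 = 0.19))
#' @export
n_budget <- function(profiles, z_top = 0, z_bottom = NULL,
                     c_to_n = 106 / 16) {
  miss <- setdiff(.SUBSTRATES, names(profiles))
  if (length(miss)) {
    warning(sprintf("substrate(s) missing from budget, treated as 0: %s",
                    paste(miss, collapse = ", ")))
    for (m in miss) profiles[[m]] <- 0
  }
  integrated <- vapply(.SUBSTRATES, function(s) {
    p <- profiles[[s]]
    if (is.data.frame(p))
      depth_integrate(p$depth, p$rate, z_top = z_top,
                      z_bottom = z_bottom %||% max(p$depth))
    else as.numeric(p)
  }, numeric(1))
  total <- sum(integrated)
  if (total <= 0)
    stop_nsip("nsip_input_error", "all-zero profiles; budget undefined")
  fr <- f_ratio(no3 = integrated[["NO3"]], n2 = integrated[["N2"]],
                nh4 = integrated[["NH4"]], urea = integrated[["urea"]])
  tab <- data.frame(substrate = .SUBSTRATES,
                    integrated_rate = unname(integrated),
                    fraction_of_total = unname(integrated) / total,
                    c_equivalent = redfield_c(unname(integrated), c_to_n))
  structure(list(table = tab, total_n = total,
                 total_c = redfield_c(total, c_to_n), f_ratio = fr,
                 c_to_n = c_to_n),
            class = "n_budget")
}

#' @export
print.n_budget <- function(x, digits = 3, ...) {
  cat("Depth-integrated N uptake budget\n")
  tab <- x$table
  tab$integrated_rate <- signif(tab$integrated_rate, digits)
  tab$fraction_of_total <- signif(tab$fraction_of_total, digits)
  tab$c_equivalent <- signif(tab$c_equivalent, digits)
  names(tab) <- c("substrate", "N uptake (mmol N m-2 d-1)", "fraction",
                  "C equivalent (mmol C m-2 d-1)")
  print(tab, row.names = FALSE)
  cat(sprintf("Total: %.3g mmol N m-2 d-1 (~%.3g mmol C m-2 d-1); f-ratio %.2f\n",
              x$total_n, x$total_c, x$f_ratio))
  invisible(x)
}
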
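## Synthetic extracellular metabolite time courses under exponential growth.

## starting concentrations, mM (DMEM-like medium)
default_start_conc <- function(metabolites) {
  base <- c(glucose = 25, lactate = 1,
            alanine = 0.1, arginine = 0.4, asparagine = 0.1, aspartate = 0.1,
            cysteine = 0.2, glutamate = 0.1, glutamine = 2.5, glycine = 0.25,
            histidine = 0.2, isoleucine = 0.8, leucine = 0.8, lysine = 0.8,
            methionine = 0.2, phenylalanine = 0.4, proline = 0.15,
            serine = 0.4, threonine = 0.8, tryptophan = 0.08,
            tyrosine = 0.4, valine = 0.8)
  out <- base[metabolites]
  out[is.na(out)] <- 0.5
  names(out) <- metabolites
  out
}

#' Simulate metabolite concentration time courses
#'
#' Concentrations follow
#' `C_m(t) = C_m(0) + v_m * integral(N(s) ds) / V` with exponential cell
#' growth `N(t) = N0 exp(mu t)` and the configured ground-truth exchange
#' rates `v_m` (fmol/cell/h, positive = secretion). Multiplicative Gaussian
#' measurement noise (`noise_levels$metabolite`) is applied, and a paired
#' cell-free blank series (zero exchange, optional linear drift) is
#' generated for every metabolite. Consumption never drives a concentration
#' below zero: values are clipped with a `clipped` flag.
#'
#' @param cfg a [sim_config()]; uses `true_exchange_rates`, `growth_rate`,
#'   `n0_cells`, `volume_mL`, `noise_levels$metabolite` and `seed`.
#' @param timepoints hours, sorted, starting at 0 (default `c(0, 24, 48)`).
#' @param blank_drift_mM_per_h linear cell-free drift applied to the blank
#'   (and sample) series, per metabolite (recycled; default 0).
#' @return long-format data.frame: metabolite, time_h, conc_mM, conc_sd,
#'   cell_count, volume_mL, is_blank, clipped; attribute `truth` holds the
#'   generating rates.
#' @examples
#' ts <- simulate_metabolite_timecourse(sim_config(seed = 3))
#' head(ts)
#' @export
simulate_metabolite_timecourse <- function(cfg, timepoints = c(0, 24, 48),
                                           blank_drift_mM_per_h = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be sorted and start at 0")
  rates <- cfg$true_exchange_rates
  mets <- names(rates)
  c0 <- default_start_conc(mets)
  mu <- cfg$growth_rate
  n0 <- cfg$n0_cells; V <- cfg$volume_mL
  nl <- cfg$noise_levels$metabolite %||% 0
  drift <- rep_len(blank_drift_mM_per_h, length(mets))
  names(drift) <- mets
  ncells <- n0 * exp(mu * timepoints)
  with_seed(cfg$seed + 2L, {
    rows <- lapply(mets, function(m) {
      int_n <- vapply(timepoints, function(T) growth_integral(n0, mu, T),
                      numeric(1))
      clean <- c0[[m]] + rates[[m]] * int_n / V * 1e-9 + drift[[m]] * timepoints
      clipped <- clean < 0
      clean <- pmax(clean, 0)
      noisy <- clean * (1 + stats::rnorm(length(clean), 0, nl))
      noisy[1] <- c0[[m]] * (1 + stats::rnorm(1, 0, nl))
      blank_clean <- c0[[m]] + drift[[m]] * timepoints
      blank <- blank_clean * (1 + stats::rnorm(length(clean), 0, nl))
      rbind(
        data.frame(metabolite = m, time_h = timepoints,
                   conc_mM = pmax(noisy, 0), conc_sd = nl * pmax(clean, 1e-6),
                   cell_count = ncells, volume_mL = V, is_blank = FALSE,
                   clipped = clipped),
        data.frame(metabolite = m, time_h = timepoints,
                   conc_mM = pmax(blank, 0),
                   conc_sd = nl * pmax(blank_clean, 1e-6),
                   cell_count = 0, volume_mL = V, is_blank = TRUE,
                   clipped = FALSE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(rates = rates, growth_rate = mu, n0 = n0,
                               volume_mL = V)
    out
  })
}
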
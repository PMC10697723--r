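## Synthetic-data generator: simulation configuration and the vessel
## diffusion forward model.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the experimental conditions the pipeline targets: FITC diffusing out of a
#' 300 um-diameter channel imaged every 2 s for 5 min, two-component NADH
#' decays, and 0/24/48 h metabolite time courses under exponential growth.
#' A fixed `seed` makes every generator output bit-reproducible.
#'
#' @param seed integer RNG seed.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames of the diffusion movie.
#' @param duration total movie duration, s.
#' @param vessel_radius channel radius, um (300 um needle diameter / 2).
#' @param true_permeability ground-truth diffusive permeability, um/s.
#' @param matrix_diffusivity tracer diffusivity in the collagen matrix,
#'   um^2/s (free-dye order of magnitude).
#' @param reservoir_factor connected media volume of the vessel compartment
#'   as a multiple of the channel volume; larger values make the vessel
#'   concentration decay more slowly (the channel is fed by media wells).
#' @param photon_budget expected total photons per FLIM pixel.
#' @param flim_params named vector `a1`, `tau1`, `tau2` (fractions / ns) of
#'   the two-component NADH decay; `tau1 < tau2`.
#' @param growth_rate cell growth rate, 1/h.
#' @param n0_cells cells per well at t = 0.
#' @param volume_mL culture medium volume.
#' @param true_exchange_rates named vector of ground-truth exchange rates,
#'   fmol/cell/h (positive = secretion); defaults to
#'   `default_exchange_rates("control")`.
#' @param noise_levels list of per-channel relative (multiplicative) noise
#'   SDs: `diffusion`, `metabolite`, `image`.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       pixel_size = 1.66,
                       frame_interval = 2,
                       duration = 300,
                       vessel_radius = 150,
                       true_permeability = 1,
                       matrix_diffusivity = 200,
                       reservoir_factor = 10,
                       photon_budget = 1e5,
                       flim_params = c(a1 = 0.8, tau1 = 0.4, tau2 = 2.5),
                       growth_rate = 0.025,
                       n0_cells = 1e5,
                       volume_mL = 1,
                       true_exchange_rates = default_exchange_rates("control"),
                       noise_levels = list(diffusion = 0, metabolite = 0.02,
                                           image = 0.1)) {
  cfg <- list(seed = as.integer(seed), pixel_size = pixel_size,
              frame_interval = frame_interval, duration = duration,
              vessel_radius = vessel_radius,
              true_permeability = true_permeability,
              matrix_diffusivity = matrix_diffusivity,
              reservoir_factor = reservoir_factor,
              photon_budget = photon_budget, flim_params = flim_params,
              growth_rate = growth_rate, n0_cells = n0_cells,
              volume_mL = volume_mL,
              true_exchange_rates = true_exchange_rates,
              noise_levels = noise_levels)
  for (p in c("pixel_size", "frame_interval", "duration", "vessel_radius",
              "matrix_diffusivity", "reservoir_factor", "photon_budget",
              "n0_cells", "volume_mL"))
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0)
      stop("sim_config: '", p, "' must be a positive scalar")
  if (cfg$true_permeability < 0)
    stop("sim_config: 'true_permeability' must be >= 0")
  fp <- cfg$flim_params
  if (!all(c("a1", "tau1", "tau2") %in% names(fp)))
    stop("sim_config: flim_params needs a1, tau1, tau2")
  if (fp[["a1"]] < 0 || fp[["a1"]] > 1)
    stop("sim_config: a1 must be in [0, 1]")
  if (fp[["tau1"]] <= 0 || fp[["tau2"]] < fp[["tau1"]])
    stop("sim_config: need 0 < tau1 <= tau2")
  structure(cfg, class = "sim_config")
}

#' Ground-truth exchange-rate sets for the two study conditions
#'
#' Frozen per-cell exchange rates (fmol/cell/h, positive = secretion) for a
#' control-media condition and an endothelial-conditioned-media ("huvec_cm")
#' condition. The contrasts follow the study's qualitative findings: under
#' conditioned media, glucose consumption, lactate secretion and oxygen
#' consumption increase, glutamate flips from secretion to consumption, and
#' proline secretion increases. `"null"` sets every rate to zero.
#'
#' @param condition one of "control", "huvec_cm", "null".
#' @return named numeric vector over glucose, lactate and the 20 canonical
#'   amino acids, plus attributes `ocr` (fmol O2/cell/h, positive =
#'   consumption) and `growth_rate` (1/h).
#' @export
default_exchange_rates <- function(condition = c("control", "huvec_cm",
                                                 "null")) {
  condition <- match.arg(condition)
  base <- c(glucose = -300, lactate = 500,
            alanine = 20, arginine = -15, asparagine = 8, aspartate = -5,
            cysteine = -8, glutamate = 15, glutamine = -40, glycine = 25,
            histidine = -8, isoleucine = -15, leucine = -25, lysine = -20,
            methionine = -8, phenylalanine = -10, proline = 5, serine = -30,
            threonine = -15, tryptophan = -3, tyrosine = -8, valine = -20)
  out <- switch(condition,
    control = { r <- base; attr(r, "ocr") <- 220
                attr(r, "growth_rate") <- 0.025; r },
    huvec_cm = {
      r <- base
      r[["glucose"]] <- -400; r[["lactate"]] <- 600
      r[["glutamate"]] <- -10; r[["proline"]] <- 15; r[["glycine"]] <- 15
      r[["asparagine"]] <- 4
      attr(r, "ocr") <- 320; attr(r, "growth_rate") <- 0.028; r
    },
    null = { r <- base; r[] <- 0; attr(r, "ocr") <- 0
             attr(r, "growth_rate") <- 0; r })
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: seed", x$seed,
      sprintf("| vessel r=%g um, P=%g um/s, D=%g um^2/s", x$vessel_radius,
              x$true_permeability, x$matrix_diffusivity),
      sprintf("| frames every %g s for %g s", x$frame_interval, x$duration),
      "\n")
  invisible(x)
}

## Radial finite-difference forward model for membrane-limited tracer
## release from a cylindrical channel into the surrounding matrix.
##
## Conservative flux form on a radial grid r in [R, R + L]; the vessel is a
## well-mixed compartment of volume reservoir_factor * pi R^2 (per unit
## length) exchanging through the wall with flux density J = P (c_v - c_1);
## the outer boundary is reflecting. Returns, per frame: c_vessel, the
## matrix tracer amount expressed as an equivalent vessel-ROI intensity
## (m / (pi R^2), so that conservation reads c_v * fres + ecm * 1 = const
## when fres is folded in), and the raw grid for diagnostics.
diffusion_forward <- function(P, R, D, times, reservoir_factor = 10,
                              c0 = 1, L = 300, nr = 160) {
  dr <- L / nr
  r_face <- R + (0:nr) * dr             # nr + 1 faces
  r_cent <- R + ((1:nr) - 0.5) * dr
  vol <- 2 * pi * r_cent * dr           # cell volumes per unit length
  v_vessel <- pi * R^2 * reservoir_factor
  area_face <- 2 * pi * r_face
  cmat <- numeric(nr)
  cv <- c0
  dt_stab <- 0.4 * dr^2 / D
  ## membrane + half-cell diffusion in series: second-order coupling of the
  ## wall flux to the first grid cell
  g_wall <- 1 / (1 / P + dr / (2 * D))
  out_cv <- numeric(length(times))
  out_m <- numeric(length(times))
  out_grid <- NULL
  t_now <- 0
  Dod <- D / dr
  for (k in seq_along(times)) {
    t_target <- times[k]
    while (t_now < t_target - 1e-12) {
      dt <- min(dt_stab, t_target - t_now)
      flux_in <- g_wall * (cv - cmat[1]) * area_face[1]  # wall flux
      f_int <- -Dod * (cmat[-1] - cmat[-nr]) * area_face[2:nr]
      dflux <- c(flux_in, f_int) - c(f_int, 0)           # in - out per cell
      cmat <- cmat + dt * dflux / vol
      cv <- cv - dt * flux_in / v_vessel
      t_now <- t_now + dt
    }
    out_cv[k] <- cv
    out_m[k] <- sum(cmat * vol) / (pi * R^2)
    if (k == length(times)) out_grid <- cmat
  }
  list(c_vessel = out_cv, ecm = out_m, grid = out_grid,
       total = out_cv * reservoir_factor + out_m)
}

#' Simulate a vessel-permeability fluorescence time lapse
#'
#' Forward model of membrane-limited tracer release from a cylindrical
#' channel: the well-mixed vessel compartment loses tracer through the wall
#' with flux density `J = P (c_vessel - c_wall)` into a 1D radial diffusion
#' grid (reflecting outer boundary). ROI intensities are proportional to
#' concentration; `I_ECM` is the integrated matrix density normalized to the
#' vessel ROI area, the convention under which
#' `P = (r/2) (dI_ECM/dt) / I_vessel(0)` recovers the true permeability at
#' early times.
#'
#' @param cfg a [sim_config()]; uses `true_permeability`, `vessel_radius`,
#'   `matrix_diffusivity`, `frame_interval`, `duration`, `reservoir_factor`
#'   and `noise_levels$diffusion`.
#' @param intensity_scale a.u. per unit concentration.
#' @param nr radial grid cells (default 160; halving changes I_ECM by < 1%).
#' @return an `intensity_series` (see [intensity_series()]) with attributes
#'   `truth` (generator parameters) and `total_tracer` (per-frame total for
#'   conservation checks).
#' @examples
#' s <- simulate_vessel_diffusion(sim_config(seed = 1))
#' nrow(s)  # 151 frames: every 2 s for 5 min
#' @export
simulate_vessel_diffusion <- function(cfg, intensity_scale = 1000, nr = 160) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$vessel_radius <= 0) stop("vessel radius must be positive")
  if (cfg$true_permeability < 0) stop("permeability must be >= 0")
  times <- seq(0, cfg$duration, by = cfg$frame_interval)
  fwd <- diffusion_forward(cfg$true_permeability, cfg$vessel_radius,
                           cfg$matrix_diffusivity, times,
                           cfg$reservoir_factor, c0 = 1, nr = nr)
  iv <- fwd$c_vessel * intensity_scale
  ie <- fwd$ecm * intensity_scale
  nl <- cfg$noise_levels$diffusion %||% 0
  if (nl > 0) {
    with_seed(cfg$seed, {
      iv <- iv * (1 + stats::rnorm(length(iv), 0, nl))
      ie <- pmax(ie * (1 + stats::rnorm(length(ie), 0, nl)), 0)
    })
  }
  ser <- intensity_series(times, iv, ie, r_vessel = cfg$vessel_radius)
  attr(ser, "truth") <- list(P = cfg$true_permeability,
                             D = cfg$matrix_diffusivity,
                             reservoir_factor = cfg$reservoir_factor,
                             intensity_scale = intensity_scale)
  attr(ser, "total_tracer") <- fwd$total * intensity_scale
  ser
}
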
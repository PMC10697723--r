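## Synthetic FLIM decays and invasion fields with ground truth.

#' Simulate TCSPC photon decay histograms
#'
#' Per-pixel two-component decays
#' `I(t) = A (a1 exp(-t/tau1) + (1 - a1) exp(-t/tau2))` integrated over
#' uniform time bins and Poisson-sampled with an expected total of
#' `photon_budget` photons. The default laser period (12.5 ns, 80 MHz) and
#' 256 bins match common TCSPC hardware; the bin range must cover at least
#' `4 * tau2`. By default no instrument response function is applied (delta
#' IRF); `irf_sigma > 0` convolves the expected counts with a Gaussian IRF.
#'
#' @param cfg a [sim_config()]; uses `flim_params`, `photon_budget`, `seed`.
#' @param n_pixels number of histograms to generate.
#' @param n_bins,period_ns binning of the decay window.
#' @param irf_sigma Gaussian IRF width, ns (0 = delta IRF).
#' @return list of [decay_histogram()] objects with attribute `truth`
#'   (a1, tau1, tau2, mean_tau, photon_budget).
#' @export
simulate_flim_decays <- function(cfg, n_pixels = 1, n_bins = 256,
                                 period_ns = 12.5, irf_sigma = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  fp <- cfg$flim_params
  a1 <- fp[["a1"]]; tau1 <- fp[["tau1"]]; tau2 <- fp[["tau2"]]
  if (period_ns < 4 * tau2)
    stop("bin range must cover at least 4 * tau2")
  if (cfg$photon_budget < 100)
    warning("photon budget < 100: fits will be unstable")
  edges <- seq(0, period_ns, length.out = n_bins + 1)
  lam <- biexp_bin_counts(edges, 1, a1, tau1, tau2, bg = 0)
  if (irf_sigma > 0) {
    ## discrete Gaussian convolution of the expected counts
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    kw <- stats::dnorm(mids - mids[1], 0, irf_sigma) +
      stats::dnorm(mids - mids[1] - period_ns, 0, irf_sigma)
    kw <- kw / sum(kw)
    lam <- Re(stats::fft(stats::fft(lam) * stats::fft(kw), inverse = TRUE)) /
      length(lam)
    lam <- pmax(lam, 0)
  }
  lam <- lam / sum(lam) * cfg$photon_budget
  out <- with_seed(cfg$seed, {
    lapply(seq_len(n_pixels), function(i)
      decay_histogram(edges, stats::rpois(n_bins, lam), id = i))
  })
  attr(out, "truth") <- list(a1 = a1, tau1 = tau1, tau2 = tau2,
                             mean_tau = a1 * tau1 + (1 - a1) * tau2,
                             photon_budget = cfg$photon_budget)
  out
}

#' Label mask
#'
#' A 2D integer label image (0 = background) with a pixel size. Row index =
#' y, column index = x; pixel centers, 0-based coordinates, x increasing
#' toward the endothelial channel.
#'
#' @param labels integer matrix.
#' @param pixel_size um per pixel.
#' @return `label_mask` matrix with `pixel_size` attribute.
#' @export
label_mask <- function(labels, pixel_size) {
  stopifnot(is.matrix(labels), all(labels >= 0), pixel_size > 0)
  structure(labels, pixel_size = pixel_size, class = "label_mask")
}

## Rasterize ellipses into a label image. centers in um; a, b semi-axes um;
## theta radians. Returns an integer matrix ny x nx.
raster_ellipses <- function(cx, cy, a, b, theta, nx, ny, pixel_size) {
  img <- matrix(0L, ny, nx)
  for (i in seq_along(cx)) {
    rmax <- max(a[i], b[i])
    x0 <- max(1, floor((cx[i] - rmax) / pixel_size)); x1 <- min(nx, ceiling((cx[i] + rmax) / pixel_size) + 1)
    y0 <- max(1, floor((cy[i] - rmax) / pixel_size)); y1 <- min(ny, ceiling((cy[i] + rmax) / pixel_size) + 1)
    if (x0 > x1 || y0 > y1) next
    xs <- ((x0:x1) - 0.5) * pixel_size - cx[i]
    ys <- ((y0:y1) - 0.5) * pixel_size - cy[i]
    ct <- cos(theta[i]); st <- sin(theta[i])
    for (xi in seq_along(xs)) {
      u <- xs[xi] * ct + ys * st
      v <- -xs[xi] * st + ys * ct
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      rows <- (y0:y1)[inside]
      img[rows, x0 + xi - 1L] <- i
    }
  }
  img
}

## Ramanujan approximation to the ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Simulate an invasion field with distance-dependent elongation
#'
#' Places `n_cells` non-overlapping elliptical cells in a field next to a
#' channel edge at `edge_x`. Cell x-positions are drawn around the edge with
#' a mean displacement `bias` toward positive x (toward the endothelial
#' channel); the ground-truth aspect ratio increases stochastically with the
#' distance invaded beyond the edge, emulating the elongated morphology of
#' invading cells. Returns both the rendered label image and the truth
#' table.
#'
#' @param cfg a [sim_config()]; uses `pixel_size` and `seed`.
#' @param n_cells number of cells (>= 1).
#' @param bias mean displacement toward positive x, um (>= 0).
#' @param edge_x channel edge, um.
#' @param field_width,field_height field extent, um.
#' @param placement_sd SD of the x-placement around `edge_x + bias`, um.
#' @param cell_radius equivalent circular radius of a cell, um.
#' @param ar_slope ground-truth aspect-ratio gain per 100 um invaded.
#' @param max_tries placement retries per cell before giving up.
#' @return list with `mask` (a [label_mask()]) and `cells` (data.frame:
#'   cell_id, x_um, y_um, aspect_ratio, area_um2, circularity, theta).
#' @export
simulate_invasion_field <- function(cfg, n_cells = 100, bias = 0,
                                    edge_x = 300, field_width = 900,
                                    field_height = 600, placement_sd = 120,
                                    cell_radius = 12, ar_slope = 0.5,
                                    max_tries = 200) {
  stopifnot(inherits(cfg, "sim_config"), n_cells >= 1, bias >= 0)
  px <- cfg$pixel_size
  nx <- ceiling(field_width / px); ny <- ceiling(field_height / px)
  with_seed(cfg$seed + 1L, {
    cx <- cy <- aa <- bb <- th <- ar <- numeric(n_cells)
    margin <- 3 * cell_radius
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        x <- stats::rnorm(1, edge_x + bias, placement_sd)
        y <- stats::runif(1, margin, field_height - margin)
        if (x < margin || x > field_width - margin) next
        ar_i <- 1 + pmax(0, x - edge_x) / 100 * ar_slope *
          stats::runif(1, 0.6, 1.4)
        a_i <- cell_radius * sqrt(ar_i); b_i <- cell_radius / sqrt(ar_i)
        if (i > 1) {
          d <- sqrt((cx[1:(i - 1)] - x)^2 + (cy[1:(i - 1)] - y)^2)
          if (any(d < a_i + pmax(aa[1:(i - 1)], bb[1:(i - 1)]) + 6 * px))
            next
        }
        cx[i] <- x; cy[i] <- y; ar[i] <- ar_i
        aa[i] <- a_i; bb[i] <- b_i; th[i] <- stats::runif(1, 0, pi)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", n_cells, " non-overlapping cells; ",
             "reduce density or enlarge the field")
    }
    mask <- label_mask(raster_ellipses(cx, cy, aa, bb, th, nx, ny, px), px)
    per <- ellipse_perimeter(aa, bb)
    cells <- data.frame(cell_id = seq_len(n_cells), x_um = cx, y_um = cy,
                        aspect_ratio = ar, area_um2 = pi * aa * bb,
                        circularity = 4 * pi * (pi * aa * bb) / per^2,
                        theta = th)
    list(mask = mask, cells = cells, edge_x = edge_x)
  })
}
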
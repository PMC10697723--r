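# Shared synthetic fixtures, all generated in code under fixed seeds.

# Field of identical disks rendered into a label image (truth mask) plus a
# noisy intensity image at the given SNR.
make_disk_field <- function(seed, n_cells = 50, snr = 10, radius = 12) {
  f <- simulate_invasion_field(sim_config(seed = seed), n_cells = n_cells,
                               bias = 0, ar_slope = 0,
                               cell_radius = radius)
  truth <- unclass(f$mask)
  set.seed(seed + 500)
  img <- (truth > 0) * snr + matrix(rnorm(length(truth)), nrow(truth))
  img <- img - min(img)
  list(mask = f$mask, truth = truth, img = img,
       pixel_size = attr(f$mask, "pixel_size"), cells = f$cells)
}

# Smooth stationary texture with a 2x (or other) peri-cellular contrast
# applied over a buffered zone around the cells, so the measured 10 um ring
# sits fully inside the contrast region.
make_collagen_field <- function(seed, contrast = 2, nx = 600, ny = 400) {
  mask <- label_mask(
    vesselflux:::raster_ellipses(c(120, 480, 300, 150, 450),
                                 c(120, 120, 200, 300, 300),
                                 rep(14, 5), rep(14, 5), rep(0, 5),
                                 nx, ny, 1), 1)
  cells <- unclass(mask) > 0
  zone <- as.matrix(EBImage::dilate(EBImage::Image(cells * 1),
                                    EBImage::makeBrush(2 * 18 + 1, "disc"))) > 0
  w <- 1 + (contrast - 1) * as.matrix(EBImage::gblur(EBImage::Image(zone * 1), 3))
  set.seed(seed)
  tex <- as.matrix(EBImage::gblur(
    EBImage::Image(matrix(runif(nx * ny), ny, nx)), 1.5))
  list(mask = mask, reflectance = tex * w, uniform = matrix(7, ny, nx))
}

# Per-true-cell intersection-over-union between a truth label image and a
# segmentation.
iou_per_cell <- function(truth, seg) {
  vapply(sort(unique(truth[truth > 0])), function(l) {
    t <- truth == l
    tb <- table(seg[t][seg[t] > 0])
    if (!length(tb)) return(0)
    s <- seg == as.integer(names(which.max(tb)))
    sum(t & s) / sum(t | s)
  }, numeric(1))
}

# Random bounded "network-like" LP with a feasible point at v = 0.
random_bounded_lp <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  m <- sample(2:(n - 2), 1)
  A <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, TRUE), m, n)
  list(c = rnorm(n), A = A, b = rep(0, m),
       lb = runif(n, -5, 0), ub = runif(n, 0, 5))
}

# Exchange-rate tables for the two study conditions, with the generator's
# default measurement SDs.
condition_rate_table <- function(condition) {
  r <- default_exchange_rates(condition)
  data.frame(metabolite = names(r), rate = as.numeric(r),
             sd = pmax(abs(as.numeric(r)) * 0.15, 2))
}

condition_constraints <- function(condition, net = toy_core_network()) {
  dr <- default_exchange_rates(condition)
  build_constraints(condition_rate_table(condition), net,
                    growth_rate = attr(dr, "growth_rate"), growth_sd = 0.003,
                    ocr = attr(dr, "ocr"), ocr_sd = 0.1 * attr(dr, "ocr"))
}
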
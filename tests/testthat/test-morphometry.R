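# Segmentation, shape descriptors, invasion, adhesions, collagen, motility.

test_that("a blank image segments to an empty mask with a warning", {
  expect_warning(m <- segment_cells(matrix(0, 50, 50), 1), "empty")
  expect_equal(max(m), 0L)
})

test_that("50 disks at SNR 10 segment to 50 labels with IoU > 0.7", {
  fx <- make_disk_field(seed = 7, n_cells = 50, snr = 10)
  seg <- segment_cells(fx$img, fx$pixel_size, blur_sigma = 2,
                       min_area_um2 = 50)
  expect_equal(max(seg), 50L)
  expect_gt(min(iou_per_cell(fx$truth, unclass(seg))), 0.7)
})

test_that("disks separated by a small gap get distinct labels", {
  img <- vesselflux:::raster_ellipses(c(20, 45), c(25, 25), c(8, 8),
                                      c(8, 8), c(0, 0), 70, 50, 1)
  seg <- segment_cells((img > 0) * 10, 1, blur_sigma = 1, min_area_um2 = 10)
  expect_equal(max(seg), 2L)
})

test_that("small objects are removed by the minimum-area filter", {
  img <- matrix(0, 40, 40)
  img[5, 5] <- 10                              # single pixel
  img[20:30, 20:30] <- 10                      # 11x11 block
  seg <- segment_cells(img, 1, blur_sigma = 0, min_area_um2 = 10)
  expect_equal(max(seg), 1L)
})

test_that("a rasterized disk is round: circularity >= 0.9, AR <= 1.1", {
  m <- label_mask(vesselflux:::raster_ellipses(40, 40, 30, 30, 0,
                                               80, 80, 1), 1)
  d <- shape_descriptors(m)
  expect_gte(d$circularity, 0.9)
  expect_lte(d$circularity, 1)
  expect_lte(d$circularity_raw, 1.05)
  expect_lte(d$aspect_ratio, 1.1)
})

test_that("a 4:1 ellipse measures AR in [3.6, 4.4]", {
  m <- label_mask(vesselflux:::raster_ellipses(100, 60, 60, 15, 0.5,
                                               200, 120, 1), 1)
  d <- shape_descriptors(m)
  expect_gt(d$aspect_ratio, 3.6)
  expect_lt(d$aspect_ratio, 4.4)
})

test_that("shape metrics are invariant to translation and 90-degree
           rotation within rasterization tolerance", {
  base <- vesselflux:::raster_ellipses(60, 45, 40, 16, 0.4, 160, 120, 1)
  m1 <- label_mask(base, 1)
  shifted <- matrix(0L, 120, 160)
  shifted[21:120, 31:160] <- base[1:100, 1:130]
  m2 <- label_mask(shifted, 1)
  rot <- t(base)[ncol(base):1, ]               # 90-degree rotation
  m3 <- label_mask(rot, 1)
  d1 <- shape_descriptors(m1); d2 <- shape_descriptors(m2)
  d3 <- shape_descriptors(m3)
  expect_equal(d1$area_um2, d2$area_um2)
  expect_equal(d1$aspect_ratio, d2$aspect_ratio, tolerance = 1e-9)
  expect_equal(d1$circularity_raw, d2$circularity_raw, tolerance = 1e-9)
  expect_equal(d1$aspect_ratio, d3$aspect_ratio, tolerance = 0.03)
  expect_equal(d1$circularity_raw, d3$circularity_raw, tolerance = 0.03)
})

test_that("distances and areas scale exactly with pixel size", {
  px <- vesselflux:::raster_ellipses(30, 30, 12, 12, 0, 60, 60, 1)
  d1 <- shape_descriptors(label_mask(px, 1))
  d2 <- shape_descriptors(label_mask(px, 2))
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$perimeter_um, 2 * d1$perimeter_um)
  expect_equal(d2$centroid_x_um, 2 * d1$centroid_x_um)
})

test_that("generated circular cells measure circularity in [0.9, 1]", {
  f <- simulate_invasion_field(sim_config(seed = 6), n_cells = 40,
                               bias = 0, ar_slope = 0)
  d <- shape_descriptors(f$mask)
  expect_true(all(d$circularity >= 0.9 & d$circularity <= 1))
})

test_that("invasion distance arithmetic and errors", {
  r <- invasion_distances(c(100, 200, 300), 100)
  expect_equal(r$distances, c(0, 100, 200))
  expect_equal(r$mean, 100)
  expect_equal(invasion_distances(c(50, 50), 50)$mean, 0)
  expect_error(invasion_distances(numeric(0), 0), "no nucleus")
  rn <- invasion_distances(c(100, 200), 0, control_mean = 50)
  expect_equal(rn$normalized, c(2, 4))
})

test_that("a bias of twice the placement SD is detected in >= 19/20 seeds", {
  hits <- 0L
  for (seed in 1:20) {
    fb <- simulate_invasion_field(sim_config(seed = seed), n_cells = 50,
                                  bias = 240, placement_sd = 120)
    fu <- simulate_invasion_field(sim_config(seed = seed + 300),
                                  n_cells = 50, bias = 0,
                                  placement_sd = 120)
    db <- shape_descriptors(fb$mask)
    du <- shape_descriptors(fu$mask)
    mb <- invasion_distances(db$centroid_x_um, fb$edge_x)$mean
    mu_ <- invasion_distances(du$centroid_x_um, fu$edge_x)$mean
    hits <- hits + (mb > mu_)
  }
  expect_gte(hits, 19L)
})

test_that("uniform punctate stain yields zero adhesions", {
  mask <- label_mask(vesselflux:::raster_ellipses(25, 25, 15, 15, 0,
                                                  50, 50, 1), 1)
  ad <- count_adhesions(matrix(5, 50, 50), mask)
  expect_equal(ad$adhesion_count, 0L)
})

test_that("seeded puncta counts are recovered and filter monotonically", {
  mask <- label_mask(vesselflux:::raster_ellipses(c(40, 120), c(50, 50),
                                                  c(25, 25), c(25, 25),
                                                  c(0, 0), 160, 100, 1), 1)
  pf <- matrix(0, 100, 160)
  set.seed(1)
  spots <- list(c(40, 50, 3), c(120, 50, 8))
  for (ci in 1:2) {
    k <- spots[[ci]][3]
    for (j in seq_len(k)) {
      ang <- runif(1, 0, 2 * pi); rr <- runif(1, 5, 20)
      yy <- round(spots[[ci]][2] + rr * sin(ang)) + (-1:1)
      xx <- round(spots[[ci]][1] + rr * cos(ang)) + (-1:1)
      pf[yy, xx] <- pf[yy, xx] + 5
    }
  }
  pf <- pf + matrix(abs(rnorm(16000, 0, 0.3)), 100)
  ad <- count_adhesions(pf, mask, min_size_um2 = 2)
  expect_equal(ad$adhesion_count, c(3L, 8L))
  # raising min_size can only lower counts
  ad2 <- count_adhesions(pf, mask, min_size_um2 = 8)
  ad3 <- count_adhesions(pf, mask, min_size_um2 = 40)
  expect_true(all(ad2$adhesion_count <= ad$adhesion_count))
  expect_true(all(ad3$adhesion_count <= ad2$adhesion_count))
})

test_that("homogeneous reflectance gives a contraction ratio of 1", {
  fx <- make_collagen_field(seed = 1)
  cr <- collagen_contraction_ratio(fx$uniform, fx$mask)
  expect_equal(cr$ratio, 1, tolerance = 0.02)
  expect_false(cr$enhanced)
})

test_that("a 2x peripheral contrast is recovered within 10%", {
  fx <- make_collagen_field(seed = 2, contrast = 2)
  cr <- collagen_contraction_ratio(fx$reflectance, fx$mask)
  expect_true(cr$enhanced)
  expect_gt(cr$ratio, 1.8)
  expect_lt(cr$ratio, 2.2)
})

test_that("the contraction ratio is invariant to global intensity scaling", {
  fx <- make_collagen_field(seed = 3)
  r1 <- collagen_contraction_ratio(fx$reflectance, fx$mask)$ratio
  r2 <- collagen_contraction_ratio(fx$reflectance * 37.5, fx$mask)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("dense masks with no bulk region raise an informative error", {
  full <- label_mask(matrix(1L, 30, 30), 1)
  expect_error(collagen_contraction_ratio(matrix(1, 30, 30), full),
               "bulk|peripheral")
})

test_that("track speeds: stationary, straight-line, and error cases", {
  still <- data.frame(track_id = 1, t_s = c(0, 1200, 2400),
                      x_um = 5, y_um = 5)
  m <- motility_metrics(still)
  expect_equal(m$speeds$mean_speed_um_min, 0)
  # 10 um per 20-min step -> 0.5 um/min
  straight <- data.frame(track_id = 1, t_s = seq(0, 6000, 1200),
                         x_um = seq(0, 50, 10), y_um = 0)
  expect_equal(motility_metrics(straight)$speeds$mean_speed_um_min, 0.5)
  dup <- data.frame(track_id = 1, t_s = c(0, 0, 10), x_um = 1:3, y_um = 0)
  expect_error(motility_metrics(dup), "duplicate")
})

test_that("random-walk MSD grows linearly with slope 2 sigma^2 / dt", {
  set.seed(12)
  sigma <- 4; dt <- 1200; nsteps <- 30; ntracks <- 200
  tr <- do.call(rbind, lapply(seq_len(ntracks), function(id) {
    data.frame(track_id = id, t_s = (0:nsteps) * dt,
               x_um = cumsum(c(0, rnorm(nsteps, 0, sigma))),
               y_um = cumsum(c(0, rnorm(nsteps, 0, sigma))))
  }))
  m <- motility_metrics(tr)
  lags <- 1:10
  msd <- vapply(lags, function(L) {
    mean(vapply(m$paths, function(p) {
      n <- nrow(p)
      mean((p$x_um[(1 + L):n] - p$x_um[1:(n - L)])^2 +
             (p$y_um[(1 + L):n] - p$y_um[1:(n - L)])^2)
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(msd ~ 0 + lags))[[1]] / dt    # per second
  expect_equal(slope, 2 * sigma^2 / dt, tolerance = 0.15)
})

test_that("aspect-ratio maps color by AR and decode back", {
  mask <- label_mask(vesselflux:::raster_ellipses(c(25, 75), c(25, 25),
                                                  c(12, 24), c(12, 6),
                                                  c(0, 0), 100, 50, 1), 1)
  rec <- shape_descriptors(mask)
  mp <- aspect_ratio_map(mask, rec)
  # the two cells get the colormap extremes
  px1 <- which(unclass(mask) == 1)[1]; px2 <- which(unclass(mask) == 2)[1]
  col1 <- sapply(1:3, function(ch) mp$rgb[, , ch][px1])
  col2 <- sapply(1:3, function(ch) mp$rgb[, , ch][px2])
  expect_false(isTRUE(all.equal(col1, col2)))
  # decode: nearest colormap entry maps back to the AR bin
  decode <- function(col) {
    d <- colSums((grDevices::col2rgb(mp$colors) / 255 - col)^2)
    mean(mp$breaks[which.min(d) + 0:1])
  }
  expect_equal(decode(col1), rec$aspect_ratio[1],
               tolerance = diff(mp$range) / 100)
  expect_equal(decode(col2), rec$aspect_ratio[2],
               tolerance = diff(mp$range) / 100)
  # uniform AR -> single color
  rec2 <- rec; rec2$aspect_ratio <- c(2, 2)
  mp2 <- aspect_ratio_map(mask, rec2)
  expect_equal(sapply(1:3, function(ch) mp2$rgb[, , ch][px1]),
               sapply(1:3, function(ch) mp2$rgb[, , ch][px2]))
})
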
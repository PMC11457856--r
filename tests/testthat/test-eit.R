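test_that("synthesized frames: uniform map makes every lung pixel track the global volume", {
  rec <- default_recording()
  mask <- lung_mask_grid()
  fr <- synthesize_eit(rec, default_regional_map(mask))
  share <- fr$map$regional_share
  vol <- approx(rec$time, rec$volume, xout = fr$time, rule = 2)$y
  px <- which(mask, arr.ind = TRUE)
  for (k in c(1, nrow(px))) {
    series <- fr$frames[px[k, 1], px[k, 2], ]
    expect_equal(series, share[px[k, 1], px[k, 2]] * vol, tolerance = 1e-12)
  }
})

test_that("a null left lung produces zero left-sided tidal amplitude", {
  rec <- default_recording()
  mask <- lung_mask_grid()
  w <- matrix(1, 32, 32)
  w[, 17:32] <- 0                          # zero the left half (subject left)
  fr <- synthesize_eit(rec, regional_map(w, mask))
  img <- tidal_image(fr, segments = default_segments())
  expect_equal(sum(img$amplitude[, 17:32]), 0)
  expect_gt(sum(img$amplitude[, 1:16]), 0)
})

test_that("lung-pixel sum conserves the global volume signal (r > 0.999 noise-free)", {
  rec <- default_recording()
  fr <- synthesize_eit(rec, default_regional_map(vd_skew = -0.3, right_share = 0.55))
  g <- eit_global_signal(fr)
  vol <- approx(rec$time, rec$volume, xout = fr$time, rule = 2)$y
  expect_gt(cor(g, vol), 0.999)
  expect_lt(max(abs(g - vol)), 1e-9 * max(vol) + 1e-12)
})

test_that("tidal image recovers the generating amplitude and conserves V_T", {
  rec <- default_recording()
  segs <- default_segments()
  map <- default_regional_map(vd_skew = -0.3, right_share = 0.55)
  img <- tidal_image(synthesize_eit(rec, map), segments = segs)
  vt <- mean(rec$truth$V_T)
  expect_lt(abs(sum(img$amplitude) - vt) / vt, 0.02)
  # amplitude proportional to the ground-truth shares
  m <- img$lung_mask
  expect_gt(cor(img$amplitude[m], map$regional_share[m]), 0.9999)
})

test_that("tidal image without segments detects breaths from the global signal", {
  rec <- default_recording()
  img <- tidal_image(synthesize_eit(rec, default_regional_map()))
  vt <- mean(rec$truth$V_T)
  expect_gt(img$n_breaths, 3)
  expect_lt(abs(sum(img$amplitude) - vt) / vt, 0.05)
})

test_that("CoV of a uniform symmetric phantom is exactly 50%", {
  mask <- matrix(FALSE, 20, 20)
  mask[4:17, 3:18] <- TRUE                 # rectangle: symmetric both axes
  amp <- matrix(0, 20, 20); amp[mask] <- 1
  img <- structure(list(amplitude = amp, lung_mask = mask,
                        regions = NULL, n_breaths = 1, n_clipped = 0),
                   class = "tidal_image")
  expect_equal(center_of_ventilation(img, "VD"), 50)
  expect_equal(center_of_ventilation(img, "RL"), 50)
  expect_equal(uniform_cov(mask, "VD"), 50)
})

test_that("hand-computed centroid: weights 1 and 3 at 25% and 75% give 62.5%", {
  mask <- matrix(TRUE, 5, 1)
  amp <- matrix(c(0, 1, 0, 3, 0), 5, 1)
  img <- structure(list(amplitude = amp, lung_mask = mask, regions = NULL,
                        n_breaths = 1, n_clipped = 0), class = "tidal_image")
  expect_equal(center_of_ventilation(img, "VD"), 62.5)
})

test_that("a point mass at the dorsal extreme gives CoV 100%", {
  mask <- matrix(TRUE, 6, 2)
  amp <- matrix(0, 6, 2); amp[6, 1] <- 5
  img <- structure(list(amplitude = amp, lung_mask = mask, regions = NULL,
                        n_breaths = 1, n_clipped = 0), class = "tidal_image")
  expect_equal(center_of_ventilation(img, "VD"), 100)
})

test_that("CoV is scale-invariant and obeys the mirror identity", {
  mask <- lung_mask_grid()
  amp <- matrix(0, 32, 32)
  set.seed(5)
  amp[mask] <- runif(sum(mask))
  img <- structure(list(amplitude = amp, lung_mask = mask, regions = NULL,
                        n_breaths = 1, n_clipped = 0), class = "tidal_image")
  cov1 <- center_of_ventilation(img, "VD")
  img2 <- img; img2$amplitude <- amp * 37.5
  expect_equal(center_of_ventilation(img2, "VD"), cov1, tolerance = 1e-12)
  img3 <- img
  img3$amplitude <- amp[32:1, ]; img3$lung_mask <- mask[32:1, ]
  expect_equal(center_of_ventilation(img3, "VD"), 100 - cov1, tolerance = 1e-9)
})

test_that("relative aeration: definition, ratio arithmetic and the size-weighted sum rule", {
  mask <- matrix(TRUE, 10, 10)
  amp <- matrix(1, 10, 10)
  img <- structure(list(amplitude = amp, lung_mask = mask, regions = NULL,
                        n_breaths = 1, n_clipped = 0), class = "tidal_image")
  regions <- list(top = row(mask) <= 5, bottom = row(mask) > 5)
  expect_equal(unname(relative_aeration(img, regions)), c(1, 1))

  amp2 <- amp; amp2[row(mask) <= 5] <- 1.5   # 50% of pixels, 60% of signal
  img2 <- img; img2$amplitude <- amp2
  ra <- relative_aeration(img2, regions)
  expect_equal(unname(ra[["top"]]), 1.2)
  # size-weighted mean over any partition is exactly 1
  sizes <- vapply(regions, sum, numeric(1)) / sum(mask)
  expect_equal(sum(sizes * ra), 1, tolerance = 1e-12)
  expect_error(relative_aeration(img2, list(none = mask & FALSE)), "empty region")
})

test_that("simulated 60/40 right-left split yields relative aeration 1.2 / 0.8", {
  rec <- default_recording()
  map <- default_regional_map(right_share = 0.6)
  img <- tidal_image(synthesize_eit(rec, map), segments = default_segments())
  ra <- relative_aeration(img)
  n_r <- sum(img$regions$right); n_l <- sum(img$regions$left)
  expect_equal(unname(ra[["right"]]), 0.6 / (n_r / (n_r + n_l)), tolerance = 0.01)
  expect_equal(unname(ra[["left"]]), 0.4 / (n_l / (n_r + n_l)), tolerance = 0.01)
})

test_that("unventilated fraction: uniform 0%, constructed 10%, zero threshold 0%", {
  mask <- matrix(TRUE, 10, 10)
  amp <- matrix(1, 10, 10)
  img <- structure(list(amplitude = amp, lung_mask = mask, regions = NULL,
                        n_breaths = 1, n_clipped = 0), class = "tidal_image")
  expect_equal(as.numeric(unventilated_fraction(img)), 0)
  amp[1, 1:10] <- 0                        # 10 of 100 pixels silent
  img$amplitude <- amp
  expect_equal(as.numeric(unventilated_fraction(img)), 10)
  expect_equal(as.numeric(unventilated_fraction(img, threshold_fraction = 0)), 0)
})

test_that("frame/mask shape mismatches are rejected", {
  expect_error(regional_map(matrix(1, 4, 4), matrix(TRUE, 5, 5)), "same shape")
  expect_error(regional_map(matrix(-1, 4, 4), matrix(TRUE, 4, 4)), "non-negative")
})
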
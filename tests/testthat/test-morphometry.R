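test_that("scale-bar calibration is bar_um / bar_px", {
  expect_equal(calibrate(125, 250), 2)
  expect_equal(calibrate(250, 250), 1)
  expect_error(calibrate(0, 10), "positive")
  expect_error(calibrate(10, -1), "positive")
  # measuring the simulated scale bar reproduces the configured pixel size
  img <- make_domain_image(domain_sim_config(pixel_size = 2))
  expect_equal(calibrate(img$meta$scalebar$length_px,
                         img$meta$scalebar$length_um), 2)
})

test_that("domain image stores ground truth and separates domains", {
  img <- make_domain_image(domain_sim_config(ppl_axes = c(100, 50),
                                             gap = 60, pixel_size = 2))
  expect_equal(img$meta$truth$lwr, 2)
  expect_equal(img$meta$truth$gap_um, 60)
  expect_true(any(img$labels == 1L) && any(img$labels == 2L))
  expect_false(any(img$labels == 1L & img$labels == 2L))
  expect_error(domain_sim_config(ppl_axes = c(50, 100)), "major")
  expect_error(domain_sim_config(gap = -2), "gap")
})

test_that("label image round-trips through PNG + JSON sidecar", {
  img <- make_domain_image(domain_sim_config(pixel_size = 4))
  f <- tempfile(fileext = ".png")
  write_label_image(img, f)
  back <- read_label_image(f)
  expect_identical(back$labels, img$labels)
  expect_equal(back$meta$pixel_size, 4)
  unlink(c(f, paste0(f, ".json")))
})

test_that("segment_domain keeps the largest 8-connected component", {
  img <- matrix(0, 20, 20)
  img[2:5, 2:5] <- 10        # 16 px
  img[10:16, 10:16] <- 10    # 49 px
  m <- segment_domain(img, threshold = 5)
  expect_equal(sum(m), 49)
  expect_true(all(m[10:16, 10:16]))
  expect_error(segment_domain(img, threshold = 50), "empty")
  # dark-stain direction
  md <- segment_domain(img, threshold = 5, direction = "below")
  expect_equal(sum(md), 400 - 65)
  # clean synthetic ellipse: segmentation equals the generator mask
  di <- make_domain_image(domain_sim_config(pixel_size = 2))
  ppl <- di$labels == 1L
  seg <- segment_domain(ifelse(ppl, 100, 0), threshold = 50)
  expect_identical(seg, ppl)
})

test_that("8-connected labeling matches a flood-fill oracle", {
  set.seed(19)
  for (rep in 1:30) {
    m <- matrix(runif(15 * 15) < 0.35, 15, 15)
    lab <- label_components(m)
    orc <- oracle_label(m)
    # same partition: label images equal up to renaming
    expect_equal(max(lab), max(orc))
    key <- paste(lab[m], orc[m])
    expect_equal(length(unique(key)), max(orc))
  }
})

test_that("LWR of ellipse and disc is recovered within 2%", {
  di <- make_domain_image(domain_sim_config(ppl_axes = c(100, 50),
                                            pixel_size = 1))
  r <- lwr(di$labels == 1L)
  expect_lt(abs(r$lwr - 2) / 2, 0.02)
  disc <- make_domain_image(domain_sim_config(ppl_axes = c(80, 80),
                                              pixel_size = 1))
  expect_lt(abs(lwr(disc$labels == 1L)$lwr - 1), 0.02)
  expect_error(lwr(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)), "degenerate")
})

test_that("LWR is rotation invariant and length matches a Feret sweep", {
  for (rot in c(0, 19, 37, 68, 90)) {
    di <- make_domain_image(domain_sim_config(ppl_axes = c(100, 50),
                                              rotation = rot,
                                              pixel_size = 1))
    m <- di$labels == 1L
    r <- lwr(m)
    expect_lt(abs(r$lwr - 2) / 2, 0.02)
    fer <- oracle_feret(m, step_deg = 1)
    expect_lt(abs(r$length_px - fer$max) / fer$max, 0.01)
  }
})

test_that("LWR is invariant under uniform scaling", {
  r1 <- lwr(make_domain_image(domain_sim_config(ppl_axes = c(150, 75),
                                                pixel_size = 1))$labels == 1L)
  r2 <- lwr(make_domain_image(domain_sim_config(ppl_axes = c(300, 150),
                                                pixel_size = 1))$labels == 1L)
  expect_lt(abs(r1$lwr - r2$lwr), 0.02 * r1$lwr)
})

test_that("domain distance: rectangles with a 30 px gap at 2 um/px give 60 um", {
  a <- matrix(FALSE, 40, 100); b <- a
  a[10:30, 5:20] <- TRUE
  b[10:30, 51:70] <- TRUE     # columns 20 -> 51: 31 px apart, gap 31
  expect_equal(domain_distance(a, b, um_per_px = 2), 62)
  b2 <- matrix(FALSE, 40, 100); b2[10:30, 51:70] <- TRUE
  a2 <- matrix(FALSE, 40, 100); a2[10:30, 5:21] <- TRUE  # gap exactly 30 px
  expect_equal(domain_distance(a2, b2, um_per_px = 2), 60)
  # touching domains -> 0 is approached; overlapping -> 0 with warning
  o <- matrix(FALSE, 10, 10); o[2:5, 2:5] <- TRUE
  p <- matrix(FALSE, 10, 10); p[4:8, 4:8] <- TRUE
  expect_warning(d0 <- domain_distance(o, p), "overlap")
  expect_equal(d0, 0)
  q <- matrix(FALSE, 10, 10); q[2:5, 6:9] <- TRUE
  expect_equal(domain_distance(o, q), 1)  # adjacent columns 5|6
})

test_that("domain distance matches the exhaustive boundary oracle", {
  set.seed(23)
  for (rep in 1:15) {
    a <- matrix(FALSE, 25, 25); b <- a
    a[sample(625, 40)] <- TRUE
    b[sample(625, 40)] <- TRUE
    b[a] <- FALSE
    if (!any(a) || !any(b)) next
    expect_equal(domain_distance(a, b, um_per_px = 1),
                 oracle_boundary_distance(a, b), tolerance = 1e-10)
    # symmetry and linear scaling with calibration
    expect_equal(domain_distance(b, a), domain_distance(a, b))
    expect_equal(domain_distance(a, b, um_per_px = 3.5),
                 3.5 * domain_distance(a, b), tolerance = 1e-10)
  }
})

test_that("peak finder reports prominent maxima with spacing pruning", {
  y <- c(0, 5, 0, 1, 0, 10, 9, 10, 0)
  pk <- find_peaks(y, prominence = 2)
  expect_equal(pk$position, c(2, 6, 8))
  expect_equal(pk$height, c(5, 10, 10))
  pk2 <- find_peaks(y, prominence = 2, min_spacing = 3)
  expect_equal(pk2$position, c(2, 6))   # higher/earlier peak wins
  expect_equal(find_peaks(rep(5, 10))$position, integer(0))
  # prominence of an inner peak is measured to its saddle
  y2 <- c(0, 10, 4, 6, 4, 10, 0)
  pk3 <- find_peaks(y2, prominence = 0)
  expect_equal(pk3$prominence[pk3$position == 4], 2)
})

test_that("membrane/cytosol ratio: clean profiles give the exact truth", {
  prof <- make_membrane_profile(profile_sim_config(
    n_cells = 4, membrane_peak = 200, cytosol_level = 50, noise_sigma = 0))
  r <- membrane_cytosol_ratio(prof, min_spacing = 20)
  expect_equal(r$membrane, 200, tolerance = 1e-9)
  expect_equal(r$ratio, 0.25, tolerance = 5e-3)
  expect_equal(nrow(r$peaks), 5)      # n_cells + 1 membranes
  # detected peak positions match the generator truth
  expect_equal(r$peaks$position, attr(prof, "truth")$peak_positions,
               tolerance = 1)
  # uniform profile -> no membrane pair
  flat <- data.frame(position_px = 1:50, intensity = 7)
  expect_error(membrane_cytosol_ratio(flat, prominence = 1), "no membrane")
  # degenerate zero-cell profile flagged by the generator
  expect_true(attr(make_membrane_profile(profile_sim_config(n_cells = 0)),
                   "degenerate"))
})

test_that("noisy profiles recover the ratio within 5% across 50 seeds", {
  errs <- vapply(1:50, function(s) {
    prof <- make_membrane_profile(profile_sim_config(
      n_cells = 4, membrane_peak = 200, cytosol_level = 50,
      noise_sigma = 5, seed = s))
    r <- membrane_cytosol_ratio(prof, min_spacing = 20)
    abs(r$ratio - 0.25) / 0.25
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("ratio is gain invariant but not offset invariant", {
  prof <- make_membrane_profile(profile_sim_config(noise_sigma = 0))
  r0 <- membrane_cytosol_ratio(prof, min_spacing = 20)$ratio
  gain <- prof; gain$intensity <- 3 * gain$intensity
  expect_equal(membrane_cytosol_ratio(gain, min_spacing = 20)$ratio, r0,
               tolerance = 1e-9)
  off <- prof; off$intensity <- off$intensity + 100
  expect_gt(membrane_cytosol_ratio(off, min_spacing = 20)$ratio, r0 + 0.05)
})

test_that("nuclear mean intensity equals the per-label loop oracle", {
  # uniform signal under any mask
  sig <- matrix(100, 8, 8)
  mask <- matrix(0L, 8, 8); mask[2:3, 2:3] <- 1L
  expect_equal(nuclear_mean_intensity(sig, mask)$mean_intensity, 100)
  # two nuclei with disjoint uniform signals
  sig2 <- matrix(0, 8, 8); mask2 <- matrix(0L, 8, 8)
  sig2[1:2, 1:2] <- 10; mask2[1:2, 1:2] <- 1L
  sig2[5:6, 5:6] <- 30; mask2[5:6, 5:6] <- 2L
  expect_equal(nuclear_mean_intensity(sig2, mask2)$mean_intensity, c(10, 30))
  expect_error(nuclear_mean_intensity(sig2, matrix(0L, 8, 8)), "empty")
  set.seed(29)
  for (rep in 1:20) {
    img <- matrix(runif(100), 10, 10)
    mk <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    if (!any(mk > 0)) next
    got <- nuclear_mean_intensity(img, mk)
    expect_equal(got$mean_intensity, unname(oracle_label_means(img, mk)),
                 tolerance = 1e-12)
  }
})
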
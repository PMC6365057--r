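make_tracks <- function(df) as_track_set(df)

two_cell_tracks <- function() {
  as_track_set(data.frame(
    track_id = rep(c("p1", "n1"), each = 2),
    population = rep(c("ppl", "neuroectoderm"), each = 2),
    frame = c(0L, 1L, 0L, 1L),
    t_min = c(0, 1, 0, 1),
    x_um = c(0, 2, 10, 10), y_um = c(0, 0, 10, 13), z_um = 0))
}

test_that("velocities are forward differences, gap-aware", {
  tr <- as_track_set(data.frame(
    track_id = "a", population = "ppl",
    frame = c(0L, 1L, 3L, 7L), t_min = c(0, 1, 3, 7),
    x_um = c(0, 2, 2, 6), y_um = 0, z_um = 0))
  v <- compute_velocities(tr)
  expect_equal(nrow(v), 3)
  expect_equal(v$vx, c(2, 0, 1))   # gap 3->7 spans 4 min, dx 4 -> 1 um/min
  expect_equal(v$vy, c(0, 0, 0))
  # single-frame track yields no samples
  tr1 <- as_track_set(data.frame(track_id = "s", population = "ppl",
                                 frame = 0L, t_min = 0,
                                 x_um = 0, y_um = 0, z_um = 0))
  expect_equal(nrow(compute_velocities(tr1)), 0)
})

test_that("orient_axes is a pure rotation: +y identity, +x quarter turn", {
  tr <- two_cell_tracks()
  same <- orient_axes(tr, c(0, 1, 0))
  expect_equal(same$x_um, tr$x_um, tolerance = 1e-12)
  rot <- orient_axes(tr, c(1, 0, 0))
  # +x becomes +y
  expect_equal(rot$y_um[rot$track_id == "p1"], c(0, 2), tolerance = 1e-12)
  # pairwise distances preserved
  d0 <- dist(as.matrix(as.data.frame(tr)[, c("x_um", "y_um", "z_um")]))
  d1 <- dist(as.matrix(as.data.frame(rot)[, c("x_um", "y_um", "z_um")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-10)
  expect_error(orient_axes(tr, c(0, 0, 0)), "non-zero")
})

test_that("orientation undoes a joint rotation: order parameter unchanged", {
  # rotate both populations together (animal axis ends up along `dirn`),
  # then orient back with orient_axes; the downstream order parameter must
  # be identical to the unrotated analysis
  cfg <- track_sim_config(n_cells_per_population = 60, n_frames = 10,
                          coupling = 0.6, noise_sigma = 1, seed = 21)
  tr <- simulate_correlated_tracks(cfg)
  op0 <- correlate_tracks(tr)
  set.seed(99)
  dirn <- rnorm(3)
  rot <- orient_axes(tr, dirn)              # joint rigid rotation of all cells
  # image of the original +y axis under that rotation
  probe <- as_track_set(data.frame(
    track_id = c("o", "y"), population = "probe", frame = 0L, t_min = 0,
    x_um = c(0, 0), y_um = c(0, 1), z_um = c(0, 0)))
  pr <- orient_axes(probe, dirn)
  a2 <- c(pr$x_um[2] - pr$x_um[1], pr$y_um[2] - pr$y_um[1],
          pr$z_um[2] - pr$z_um[1])
  op1 <- correlate_tracks(orient_axes(rot, a2))
  expect_equal(op1$order_parameter, op0$order_parameter, tolerance = 1e-8)
})

test_that("leading edge matches an explicit sort on the animal axis", {
  set.seed(5)
  n <- 100
  tr <- as_track_set(data.frame(
    track_id = sprintf("c%03d", 1:n), population = "ppl",
    frame = 0L, t_min = 0,
    x_um = runif(n, 0, 50), y_um = runif(n, 0, 100), z_um = runif(n, 0, 20)))
  le <- leading_edge(tr, 0, "ppl", quantile = 0.95)
  thr <- quantile(tr$y_um, 0.95, names = FALSE)
  sel <- tr$y_um >= thr
  expect_equal(le, c(mean(tr$x_um[sel]), mean(tr$y_um[sel]),
                     mean(tr$z_um[sel])), tolerance = 1e-12)
  # single cell and coincident cells
  tr1 <- as_track_set(data.frame(track_id = "a", population = "ppl",
                                 frame = 0L, t_min = 0,
                                 x_um = 3, y_um = 4, z_um = 5))
  expect_equal(leading_edge(tr1, 0, "ppl"), c(3, 4, 5))
  expect_error(leading_edge(tr1, 0, "neuroectoderm"), "empty")
})

test_that("sector assignment matches a brute-force per-cell loop", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    x <- runif(n, -120, 120); y <- runif(n, -120, 120)
    center <- runif(2, -30, 30)
    samples <- data.frame(track_id = as.character(1:n), population = "ppl",
                          t_mid = 0.5, x_um = x, y_um = y, z_um = 0,
                          vx = 1, vy = 0, vz = 0)
    f <- bin_to_grid(samples, t = 0.5, center = center, sector_um = 50)
    exp_idx <- oracle_sector_assign(x, y, center, 50)
    got <- table(paste(floor((x - center[1]) / 50),
                       floor((y - center[2]) / 50)))
    expect_equal(floor((x - center[1]) / 50), exp_idx[, 1])
    expect_equal(floor((y - center[2]) / 50), exp_idx[, 2])
    expect_equal(sum(f$n), n)
  }
})

test_that("sector means average velocities; opposite velocities cancel", {
  samples <- data.frame(track_id = c("a", "b"), population = "ppl",
                        t_mid = 0.5, x_um = c(10, 20), y_um = c(10, 20),
                        z_um = 0, vx = c(1, -1), vy = c(2, -2), vz = 0)
  f <- bin_to_grid(samples, t = 0.5, center = c(0, 0), sector_um = 50)
  expect_equal(nrow(f), 1)
  expect_equal(c(f$vx, f$vy), c(0, 0))
  expect_equal(f$n, 2L)
  expect_error(bin_to_grid(samples, t = 0.5, sector_um = 0), "positive")
})

test_that("directional correlation is the cosine between sector means", {
  f <- structure(data.frame(
    ix = c(0L, 0L, 1L, 1L), iy = 0L,
    population = c("ppl", "neuroectoderm", "ppl", "neuroectoderm"),
    n = 1L,
    vx = c(1, 2, 1, -3), vy = 0, vz = 0),
    class = c("sector_field", "data.frame"))
  d <- directional_correlation(f, "ppl", "neuroectoderm")
  expect_equal(sort(d$correlation), c(-1, 1))
  # random vectors vs brute-force dot product of unit vectors
  set.seed(13)
  for (rep in 1:100) {
    va <- rnorm(3); vb <- rnorm(3)
    f2 <- structure(data.frame(
      ix = 0L, iy = 0L, population = c("A", "B"), n = 1L,
      vx = c(va[1], vb[1]), vy = c(va[2], vb[2]), vz = c(va[3], vb[3])),
      class = c("sector_field", "data.frame"))
    d2 <- directional_correlation(f2, "A", "B")
    expected <- sum(va * vb) / sqrt(sum(va^2)) / sqrt(sum(vb^2))
    expect_equal(d2$correlation, expected, tolerance = 1e-12)
  }
})

test_that("zero-length sector means are excluded", {
  f <- structure(data.frame(
    ix = 0L, iy = 0L, population = c("A", "B"), n = 1L,
    vx = c(0, 1), vy = 0, vz = 0),
    class = c("sector_field", "data.frame"))
  expect_equal(nrow(directional_correlation(f, "A", "B")), 0)
})

test_that("order parameter averages sectors; embryos add SEM", {
  d <- data.frame(correlation = c(1, -1))
  expect_equal(order_parameter(d)$order_parameter, 0)
  d2 <- data.frame(correlation = rep(1, 5))
  expect_equal(order_parameter(d2)$order_parameter, 1)
  # across-embryo reduction: sectors averaged per embryo first
  d3 <- data.frame(correlation = c(1, 1, 0, 0.5),
                   embryo = c("e1", "e1", "e2", "e2"))
  r <- order_parameter(d3)
  expect_equal(r$order_parameter, mean(c(1, 0.25)))
  expect_equal(r$n_embryos, 2)
  expect_equal(r$sem, sd(c(1, 0.25)) / sqrt(2))
})

test_that("order parameter is symmetric in populations and scale-free", {
  cfg <- track_sim_config(n_cells_per_population = 60, n_frames = 8,
                          coupling = 0.5, noise_sigma = 1, seed = 4)
  tr <- simulate_correlated_tracks(cfg)
  v <- compute_velocities(tr)
  f <- bin_to_grid(v, t = 0.5, center = c(0, 0), sector_um = 50)
  ab <- directional_correlation(f, "ppl", "neuroectoderm")
  ba <- directional_correlation(f, "neuroectoderm", "ppl")
  expect_equal(ab$correlation, ba$correlation, tolerance = 1e-12)
  # uniform speed rescaling leaves correlations unchanged
  v2 <- v; v2$vx <- 3.7 * v$vx; v2$vy <- 3.7 * v$vy; v2$vz <- 3.7 * v$vz
  f2 <- bin_to_grid(v2, t = 0.5, center = c(0, 0), sector_um = 50)
  ab2 <- directional_correlation(f2, "ppl", "neuroectoderm")
  expect_equal(ab2$correlation, ab$correlation, tolerance = 1e-10)
  expect_true(all(abs(ab$correlation) <= 1))
})

test_that("estimated order parameter increases with simulator coupling", {
  ops <- vapply(c(0, 0.5, 1), function(cp) {
    cfg <- track_sim_config(n_cells_per_population = 100, n_frames = 15,
                            coupling = cp, noise_sigma = 1, seed = 42)
    mean(correlate_tracks(simulate_correlated_tracks(cfg))$order_parameter)
  }, numeric(1))
  expect_true(all(diff(ops) > 0))
})

test_that("ap_velocity recovers the drift and flips sign with it", {
  cfg <- track_sim_config(n_cells_per_population = 80, n_frames = 20,
                          drift_speed = 2.5, coupling = 1, noise_sigma = 1,
                          seed = 9)
  tr <- simulate_correlated_tracks(cfg)
  av <- ap_velocity(tr, "ppl", edge_quantile = 0)
  pooled <- mean(av$v_ap)
  sem <- sd(av$v_ap) / sqrt(nrow(av))
  expect_lt(abs(pooled - 2.5), 3 * max(sem, 0.05))
  # deterministic drift gives exactly the drift
  cfg0 <- track_sim_config(n_cells_per_population = 10, n_frames = 5,
                           drift_speed = 2.5, coupling = 1, noise_sigma = 0,
                           seed = 1)
  av0 <- ap_velocity(simulate_correlated_tracks(cfg0), "ppl")
  expect_equal(av0$v_ap, rep(2.5, nrow(av0)), tolerance = 1e-10)
  # reversed drift
  cfgr <- track_sim_config(n_cells_per_population = 10, n_frames = 5,
                           drift_speed = 2.5, coupling = 1, noise_sigma = 0,
                           drift_direction = c(0, -1, 0), seed = 1)
  expect_true(all(ap_velocity(simulate_correlated_tracks(cfgr),
                              "ppl")$v_ap < 0))
})
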
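#' Rotate tracks so a given animal-pole direction becomes +y
#'
#' Applies the rigid rotation that maps `animal_direction` onto the +y axis
#' to every position. Pairwise distances are preserved; no scaling or
#' reflection. Used to put all embryos into a common animal--vegetal frame
#' before binning.
#'
#' @param tracks a `track_set`.
#' @param animal_direction non-zero 3-vector pointing vegetal-to-animal.
#' @return The rotated `track_set`.
#' @export
orient_axes <- function(tracks, animal_direction) {
  stopifnot(length(animal_direction) == 3)
  n <- sqrt(sum(animal_direction^2))
  if (n == 0) stop("animal_direction must be non-zero")
  a <- animal_direction / n
  y <- c(0, 1, 0)
  R <- rotation_between(a, y)
  xyz <- as.matrix(tracks[, c("x_um", "y_um", "z_um")]) %*% t(R)
  tracks$x_um <- xyz[, 1]
  tracks$y_um <- xyz[, 2]
  tracks$z_um <- xyz[, 3]
  tracks
}

# minimal rotation taking unit vector a to unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Compute per-interval 3D velocity samples from tracks
#'
#' Forward difference over consecutive observed frames of each track:
#' `v = dposition / dt` in um/min. Intervals spanning frame gaps use the
#' actual time difference. Each sample is stamped with the interval start
#' position and the mid-interval time. Single-frame tracks yield no samples.
#'
#' @param tracks a `track_set`.
#' @return data.frame with columns `track_id, population, t_mid, x_um, y_um,
#'   z_um` (interval-start position) and `vx, vy, vz` (um/min).
#' @export
compute_velocities <- function(tracks) {
  df <- as.data.frame(tracks)
  df <- df[order(df$track_id, df$frame), ]
  same <- df$track_id[-1] == df$track_id[-nrow(df)]
  i0 <- which(same)          # interval start rows
  i1 <- i0 + 1L
  dt <- df$t_min[i1] - df$t_min[i0]
  if (any(dt <= 0)) stop("non-positive dt within a track")
  v <- data.frame(
    track_id = df$track_id[i0],
    population = df$population[i0],
    t_mid = (df$t_min[i0] + df$t_min[i1]) / 2,
    x_um = df$x_um[i0], y_um = df$y_um[i0], z_um = df$z_um[i0],
    vx = (df$x_um[i1] - df$x_um[i0]) / dt,
    vy = (df$y_um[i1] - df$y_um[i0]) / dt,
    vz = (df$z_um[i1] - df$z_um[i0]) / dt,
    stringsAsFactors = FALSE
  )
  rownames(v) <- NULL
  v
}

#' Leading-edge position of a population
#'
#' The leading edge is the centroid of the cells at or beyond the given
#' animal-axis (y) quantile of the population at time `t`. With the default
#' quantile 0.95 this is the anterior-most 5 percent of cells.
#'
#' @param tracks a `track_set` (oriented, +y = animal).
#' @param t time in minutes (frames at exactly this `t_min` are used).
#' @param population population label, default `"ppl"`.
#' @param quantile animal-axis quantile defining "leading", default 0.95.
#' @return numeric length-3 position (um).
#' @export
leading_edge <- function(tracks, t, population = "ppl", quantile = 0.95) {
  df <- as.data.frame(tracks)
  sel <- df$population == population & df$t_min == t
  if (!any(sel)) stop("population '", population, "' empty at t = ", t)
  y <- df$y_um[sel]
  thr <- stats::quantile(y, quantile, names = FALSE, type = 7)
  lead <- sel & df$y_um >= thr
  c(mean(df$x_um[lead]), mean(df$y_um[lead]), mean(df$z_um[lead]))
}

#' Bin velocity samples into an xy sector grid
#'
#' Sectors are squares of `sector_um` (default 50 um) in the xy plane; the z
#' direction is collapsed. The grid is anchored at `center` (typically the
#' prechordal-plate leading edge) and sector intervals are half-open
#' `[low, high)`, so every sample is assigned deterministically. Per sector
#' and per population the arithmetic mean velocity vector and the occupancy
#' count are recorded.
#'
#' @param samples velocity samples from [compute_velocities()].
#' @param t time point; samples with `t_mid == t` are used. `NULL` uses all.
#' @param center grid anchor, length >= 2 (x, y) in um.
#' @param sector_um sector edge length in um, default 50.
#' @return data.frame of class `sector_field` with columns `ix, iy,
#'   population, n, vx, vy, vz` plus attributes `center` and `sector_um`.
#' @export
bin_to_grid <- function(samples, t = NULL, center = c(0, 0), sector_um = 50) {
  if (sector_um <= 0) stop("sector_um must be positive")
  s <- samples
  if (!is.null(t)) s <- s[s$t_mid == t, , drop = FALSE]
  if (!nrow(s)) stop("no velocity samples at the requested time")
  ix <- floor((s$x_um - center[1]) / sector_um)
  iy <- floor((s$y_um - center[2]) / sector_um)
  key <- interaction(ix, iy, s$population, drop = TRUE)
  agg <- data.frame(
    ix = as.integer(tapply(ix, key, `[`, 1)),
    iy = as.integer(tapply(iy, key, `[`, 1)),
    population = as.character(tapply(as.character(s$population), key, `[`, 1)),
    n = as.integer(tapply(rep(1L, nrow(s)), key, sum)),
    vx = as.numeric(tapply(s$vx, key, mean)),
    vy = as.numeric(tapply(s$vy, key, mean)),
    vz = as.numeric(tapply(s$vz, key, mean)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  structure(agg, class = c("sector_field", "data.frame"),
            center = center, sector_um = sector_um)
}

#' Directional correlation between two populations per sector
#'
#' For every sector where both populations have occupancy >= 1 and non-zero
#' mean velocity vectors, computes the cosine of the angle between the two
#' sector-mean velocity vectors (dot product of unit vectors), a value in
#' \[-1, 1\]: +1 when the tissues move in the same direction, -1 when they
#' move in opposite directions. Sectors missing a population or with a
#' zero-length mean vector are excluded.
#'
#' @param field a `sector_field` from [bin_to_grid()].
#' @param popA,popB population labels.
#' @return data.frame `ix, iy, correlation, nA, nB`.
#' @export
directional_correlation <- function(field, popA, popB) {
  a <- field[field$population == popA, , drop = FALSE]
  b <- field[field$population == popB, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("field must contain both populations")
  m <- merge(a, b, by = c("ix", "iy"), suffixes = c(".a", ".b"))
  if (!nrow(m)) return(data.frame(ix = integer(), iy = integer(),
                                  correlation = numeric(),
                                  nA = integer(), nB = integer()))
  na <- sqrt(m$vx.a^2 + m$vy.a^2 + m$vz.a^2)
  nb <- sqrt(m$vx.b^2 + m$vy.b^2 + m$vz.b^2)
  ok <- na > 0 & nb > 0
  dot <- (m$vx.a * m$vx.b + m$vy.a * m$vy.b + m$vz.a * m$vz.b) / (na * nb)
  out <- data.frame(ix = m$ix[ok], iy = m$iy[ok],
                    correlation = pmin(1, pmax(-1, dot[ok])),
                    nA = m$n.a[ok], nB = m$n.b[ok])
  rownames(out) <- NULL
  out
}

#' Order parameter of local correlation
#'
#' The order parameter at a time point is the unweighted mean of per-sector
#' directional correlations (occupancy weighting available via `weighted`).
#' When several embryos are supplied the across-embryo mean and SEM are
#' reported per time point.
#'
#' @param per_sector data.frame with a `correlation` column, plus optional
#'   `t` and `embryo` columns for grouping.
#' @param weighted if TRUE, weight sectors by `pmin(nA, nB)` occupancy.
#' @return One row per (t) group: `t, order_parameter, sd, sem, n_sectors`
#'   (or `n_embryos` when an `embryo` column is present).
#' @export
order_parameter <- function(per_sector, weighted = FALSE) {
  if (!nrow(per_sector)) stop("no valid sectors")
  df <- per_sector
  if (is.null(df$t)) df$t <- 0
  sector_mean <- function(d) {
    if (weighted && !is.null(d$nA)) {
      w <- pmin(d$nA, d$nB)
      sum(d$correlation * w) / sum(w)
    } else mean(d$correlation)
  }
  if (!is.null(df$embryo)) {
    # average sectors within each embryo first, then across embryos
    per_embryo <- do.call(rbind, lapply(
      split(df, list(df$t, df$embryo), drop = TRUE),
      function(d) data.frame(t = d$t[1], embryo = d$embryo[1],
                             value = sector_mean(d))))
    out <- do.call(rbind, lapply(split(per_embryo, per_embryo$t), function(d)
      data.frame(t = d$t[1], order_parameter = mean(d$value),
                 sd = stats::sd(d$value),
                 sem = stats::sd(d$value) / sqrt(nrow(d)),
                 n_embryos = nrow(d))))
  } else {
    out <- do.call(rbind, lapply(split(df, df$t), function(d)
      data.frame(t = d$t[1], order_parameter = sector_mean(d),
                 sd = stats::sd(d$correlation),
                 sem = stats::sd(d$correlation) / sqrt(nrow(d)),
                 n_sectors = nrow(d))))
  }
  rownames(out) <- NULL
  out
}

#' End-to-end order parameter from tracks
#'
#' Convenience wrapper: velocities, per-time-point leading-edge-anchored
#' sector grid, directional correlation, order parameter time series.
#'
#' @inheritParams directional_correlation
#' @param tracks oriented `track_set`.
#' @param sector_um sector size, default 50 um.
#' @param edge_population population whose leading edge anchors the grid.
#' @param edge_quantile leading-edge quantile, default 0.95.
#' @return data.frame as from [order_parameter()] with one row per interval.
#' @export
correlate_tracks <- function(tracks, popA = "ppl", popB = "neuroectoderm",
                             sector_um = 50, edge_population = popA,
                             edge_quantile = 0.95) {
  v <- compute_velocities(tracks)
  times <- sort(unique(v$t_mid))
  frame_t <- sort(unique(tracks$t_min))
  per <- lapply(times, function(tm) {
    # anchor on the leading edge at the frame opening the interval
    t0 <- max(frame_t[frame_t <= tm])
    ctr <- leading_edge(tracks, t0, population = edge_population,
                        quantile = edge_quantile)
    f <- bin_to_grid(v, t = tm, center = ctr[1:2], sector_um = sector_um)
    d <- directional_correlation(f, popA, popB)
    if (nrow(d)) d$t <- tm
    d
  })
  per <- do.call(rbind, per[vapply(per, nrow, 1L) > 0])
  order_parameter(per)
}

#' Animal-pole-directed velocity of leading-edge cells
#'
#' Per time point, the mean projection of leading-edge cell velocities onto
#' the animal axis (+y after [orient_axes()]); positive values mean movement
#' toward the animal pole, in um/min.
#'
#' @param tracks oriented `track_set`.
#' @param population population label.
#' @param edge_quantile leading-edge quantile (same rule as
#'   [leading_edge()]); use 0 to include every cell.
#' @return data.frame `t, v_ap, sd, sem, n_cells`.
#' @export
ap_velocity <- function(tracks, population = "ppl", edge_quantile = 0.95) {
  v <- compute_velocities(tracks)
  v <- v[v$population == population, , drop = FALSE]
  if (!nrow(v)) stop("population '", population, "' has no velocity samples")
  out <- do.call(rbind, lapply(split(v, v$t_mid), function(d) {
    thr <- stats::quantile(d$y_um, edge_quantile, names = FALSE, type = 7)
    sel <- d$y_um >= thr
    data.frame(t = d$t_mid[1], v_ap = mean(d$vy[sel]),
               sd = stats::sd(d$vy[sel]),
               sem = stats::sd(d$vy[sel]) / sqrt(sum(sel)),
               n_cells = sum(sel))
  }))
  rownames(out) <- NULL
  out
}
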
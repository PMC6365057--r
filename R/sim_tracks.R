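#' Configuration for the two-population correlated track simulator
#'
#' Builds a validated configuration for [simulate_correlated_tracks()]. The
#' simulator emulates two cell populations (by default a prechordal-plate-like
#' mesendoderm group and an overlying neuroectoderm group) performing biased
#' random walks toward the animal pole. The per-step displacement of a cell in
#' population \eqn{p} is
#' \deqn{\Delta x = [c \, d_{shared} + (1 - c) \, d_p] \, s \, \Delta t + \epsilon,}
#' where \eqn{c} is `coupling`, \eqn{s} is `drift_speed` (um/min),
#' \eqn{d_{shared}} and \eqn{d_p} are unit direction vectors and
#' \eqn{\epsilon \sim N(0, \sigma^2 I_3)} is isotropic Gaussian step noise.
#' `coupling = 1` makes both populations share one drift; `coupling = 0`
#' decouples them entirely.
#'
#' @param n_cells_per_population integer, cells per population.
#' @param n_frames integer >= 2, number of time points.
#' @param dt frame interval in minutes.
#' @param drift_speed drift speed in um/min (animal-pole migration is
#'   2--3 um/min; default 2.5).
#' @param drift_direction shared drift direction (3-vector, normalized
#'   internally). Default `+y`, the vegetal-to-animal axis.
#' @param population_drifts list of two 3-vectors: the population-private
#'   drift directions used with weight `1 - coupling`. Defaults to `+y` for
#'   the first population and `+x` for the second so that `coupling` acts as
#'   a monotone correlation dial.
#' @param coupling fraction in \[0, 1\] of drift shared between populations.
#' @param noise_sigma um per step, standard deviation of isotropic step noise.
#' @param box spatial extent in um of the initial uniform cell placement
#'   (cube edge, populations offset in z to mimic tissue layers).
#' @param populations character vector of two population labels.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_cells_per_population = 100,
                             n_frames = 30,
                             dt = 1,
                             drift_speed = 2.5,
                             drift_direction = c(0, 1, 0),
                             population_drifts = list(c(0, 1, 0), c(1, 0, 0)),
                             coupling = 0.8,
                             noise_sigma = 1.0,
                             box = 300,
                             populations = c("ppl", "neuroectoderm"),
                             seed = 1L) {
  stopifnot(length(drift_direction) == 3, length(populations) == 2,
            length(population_drifts) == 2)
  if (!is.finite(coupling) || coupling < 0 || coupling > 1)
    stop("coupling must be in [0, 1]")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (dt <= 0) stop("dt must be positive")
  if (drift_speed < 0) stop("drift_speed must be >= 0")
  norm3 <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("direction vectors must be non-zero")
    v / n
  }
  structure(list(
    n_cells_per_population = as.integer(n_cells_per_population),
    n_frames = as.integer(n_frames),
    dt = dt,
    drift_speed = drift_speed,
    drift_direction = norm3(drift_direction),
    population_drifts = lapply(population_drifts, norm3),
    coupling = coupling,
    noise_sigma = noise_sigma,
    box = box,
    populations = as.character(populations),
    seed = as.integer(seed)
  ), class = "track_sim_config")
}

#' Simulate two populations of coupled biased random walks
#'
#' Generates 3D cell tracks whose movement correlation between populations is
#' controlled by `config$coupling` (see [track_sim_config()]). Positions are
#' in micrometers, time in minutes. The ground truth each downstream
#' estimator must recover (coupling, drift speed, effective drift vectors) is
#' attached as the `truth` attribute.
#'
#' @param config a `track_sim_config`.
#' @return A data.frame of class `track_set` with columns
#'   `track_id, population, frame, t_min, x_um, y_um, z_um`.
#' @export
simulate_correlated_tracks <- function(config) {
  stopifnot(inherits(config, "track_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells_per_population
  nf <- config$n_frames
  out <- vector("list", 2L)
  for (p in 1:2) {
    drift_dir <- config$coupling * config$drift_direction +
      (1 - config$coupling) * config$population_drifts[[p]]
    step_mean <- drift_dir * config$drift_speed * config$dt
    # initial positions: uniform in box, populations stacked in z
    x0 <- cbind(stats::runif(n, 0, config$box),
                stats::runif(n, 0, config$box),
                stats::runif(n, 0, config$box / 6) + (p - 1) * config$box / 6)
    steps <- array(stats::rnorm(n * (nf - 1) * 3, sd = config$noise_sigma),
                   dim = c(n, nf - 1, 3))
    pos <- array(0, dim = c(n, nf, 3))
    pos[, 1, ] <- x0
    for (f in 2:nf) {
      pos[, f, ] <- pos[, f - 1, ] +
        matrix(step_mean, n, 3, byrow = TRUE) + steps[, f - 1, ]
    }
    out[[p]] <- data.frame(
      track_id = rep(sprintf("%s_%03d", config$populations[p], seq_len(n)),
                     times = nf),
      population = config$populations[p],
      frame = rep(seq_len(nf) - 1L, each = n),
      t_min = rep((seq_len(nf) - 1L) * config$dt, each = n),
      x_um = as.vector(pos[, , 1]),
      y_um = as.vector(pos[, , 2]),
      z_um = as.vector(pos[, , 3]),
      stringsAsFactors = FALSE
    )
  }
  tracks <- rbind(out[[1]], out[[2]])
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  class(tracks) <- c("track_set", "data.frame")
  attr(tracks, "truth") <- list(
    coupling = config$coupling,
    drift_speed = config$drift_speed,
    effective_drifts = lapply(1:2, function(p)
      (config$coupling * config$drift_direction +
         (1 - config$coupling) * config$population_drifts[[p]]) *
        config$drift_speed)
  )
  tracks
}

#' Write / read track tables
#'
#' CSV dialect: header `track_id,population,frame,t_min,x_um,y_um,z_um`.
#' `read_tracks()` validates the table: duplicate `(track_id, frame)` pairs
#' and non-monotone frames within a track are rejected with the offending
#' row reported.
#'
#' @param tracks a `track_set` data.frame.
#' @param path file path.
#' @return `read_tracks()` returns a validated `track_set`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[, c("track_id", "population",
                                             "frame", "t_min",
                                             "x_um", "y_um", "z_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "population", "frame", "t_min", "x_um", "y_um", "z_um")
  if (!all(req %in% names(df)))
    stop("track CSV must have columns: ", paste(req, collapse = ","))
  as_track_set(df)
}

#' Validate a data.frame of tracks
#'
#' @param df data.frame with the track CSV columns.
#' @return A `track_set`.
#' @export
as_track_set <- function(df) {
  num <- c("t_min", "x_um", "y_um", "z_um")
  for (cl in num) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop("non-finite value in column '", cl, "' at row ", bad[1])
  }
  key <- paste(df$track_id, df$frame)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (track_id, frame) pair at row ", dup[1], ": ", key[dup[1]])
  df <- df[order(df$track_id, df$frame), ]
  bad <- which(ave(df$frame, df$track_id, FUN = function(f)
    c(1, diff(f)) <= 0) == 1)
  if (length(bad))
    stop("non-increasing frames within track at row ", bad[1])
  if (length(unique(df$population)) < 1) stop("no population present")
  rownames(df) <- NULL
  class(df) <- c("track_set", "data.frame")
  df
}
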
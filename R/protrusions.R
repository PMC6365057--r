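#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used as the circular noise model for
#' protrusion orientations: mean direction `mu` (degrees), concentration
#' `kappa` (kappa = 0 is circular uniform; large kappa concentrates tightly
#' around `mu`).
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter >= 0.
#' @return angles in degrees in \[0, 360).
#' @export
rvonmises_deg <- function(n, mu = 0, kappa = 4) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  if (kappa > 1e6) return(rep(mu %% 360, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (mu + theta * 180 / pi) %% 360
}

#' Simulate annotated protrusion event streams
#'
#' Per cell and protrusion type, event counts are Poisson with mean
#' `rate * duration`; event times are uniform over the observation window
#' and orientation angles are von Mises centered on 0 degrees (the animal
#' pole). Default rates emulate a wild-type-like lamellipodium/pseudopodium
#' rate of 0.33 events/cell/min; a mutant-like stream uses 0.14.
#'
#' @param rates named numeric vector of per-type rates (events/cell/min);
#'   names from `{lamellipodium_pseudopodium, filopodium, bleb}`.
#' @param n_cells number of observed cells.
#' @param duration observation window length in minutes (> 0).
#' @param orientation_concentration von Mises kappa for angles.
#' @param seed integer seed.
#' @return list with `events` (data.frame `cell_id, t_min, type, angle_deg`)
#'   and `windows` (data.frame `cell_id, minutes`); ground-truth rates in
#'   attribute `truth`.
#' @export
simulate_protrusion_events <- function(rates = c(lamellipodium_pseudopodium = 0.33),
                                       n_cells = 15, duration = 60,
                                       orientation_concentration = 2,
                                       seed = 1L) {
  if (any(rates < 0)) stop("rates must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  types <- protrusion_types()
  if (is.null(names(rates)) || !all(names(rates) %in% types))
    stop("rates must be named with types from: ", paste(types, collapse = ", "))
  set.seed(seed)
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  ev <- list()
  for (ty in names(rates)) {
    counts <- stats::rpois(n_cells, rates[[ty]] * duration)
    n_ev <- sum(counts)
    if (n_ev == 0) next
    ev[[ty]] <- data.frame(
      cell_id = rep(cells, counts),
      t_min = stats::runif(n_ev, 0, duration),
      type = ty,
      angle_deg = rvonmises_deg(n_ev, 0, orientation_concentration),
      stringsAsFactors = FALSE
    )
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell_id = character(), t_min = numeric(),
               type = character(), angle_deg = numeric())
  events <- events[order(events$cell_id, events$t_min), ]
  rownames(events) <- NULL
  windows <- data.frame(cell_id = cells, minutes = duration,
                        stringsAsFactors = FALSE)
  structure(list(events = events, windows = windows),
            truth = list(rates = rates,
                         kappa = orientation_concentration))
}

#' Closed vocabulary of protrusion types
#' @return character vector of the three annotated morphologies.
#' @export
protrusion_types <- function() {
  c("lamellipodium_pseudopodium", "filopodium", "bleb")
}

#' Protrusion rate in events per cell per minute
#'
#' Per-cell rate = event count / observed minutes; the cohort value is the
#' mean over cells with its SD (scatter-plot-with-mean-and-SD convention).
#' Cells with a window but no events contribute rate 0.
#'
#' @param events data.frame `cell_id, t_min, type, angle_deg`.
#' @param windows data.frame `cell_id, minutes` (minutes > 0); every event's
#'   cell must have a window.
#' @param type protrusion type to count, or `NULL` for all types.
#' @return list `mean, sd, sem, n_cells, per_cell` (data.frame
#'   `cell_id, count, minutes, rate`).
#' @export
protrusion_rate <- function(events, windows, type = NULL) {
  if (any(windows$minutes <= 0)) stop("observation windows must be > 0 min")
  if (anyDuplicated(windows$cell_id)) stop("duplicate cell in windows")
  unknown <- setdiff(unique(events$cell_id), windows$cell_id)
  if (length(unknown))
    stop("event for unknown cell: ", unknown[1])
  ev <- events
  if (!is.null(type)) {
    if (!type %in% protrusion_types()) stop("unknown type: ", type)
    ev <- ev[ev$type == type, , drop = FALSE]
  }
  counts <- table(factor(ev$cell_id, levels = windows$cell_id))
  per_cell <- data.frame(cell_id = windows$cell_id,
                         count = as.integer(counts),
                         minutes = windows$minutes,
                         stringsAsFactors = FALSE)
  per_cell$rate <- per_cell$count / per_cell$minutes
  list(mean = mean(per_cell$rate),
       sd = stats::sd(per_cell$rate),
       sem = stats::sd(per_cell$rate) / sqrt(nrow(per_cell)),
       n_cells = nrow(per_cell),
       per_cell = per_cell)
}

#' Rose-plot orientation histogram
#'
#' Counts per half-open angular bin `[k*w, (k+1)*w)`; an angle exactly on a
#' bin boundary goes to the higher bin. 0 degrees is the animal pole.
#'
#' @param angles_deg angles in degrees (wrapped into \[0, 360)).
#' @param bin_deg bin width in degrees; must divide 360. Default 30.
#' @return data.frame `bin_start, bin_end, count`.
#' @export
orientation_histogram <- function(angles_deg, bin_deg = 30) {
  if (bin_deg <= 0 || 360 %% bin_deg != 0)
    stop("bin_deg must be a positive divisor of 360")
  a <- angles_deg %% 360
  k <- floor(a / bin_deg)
  nb <- 360 / bin_deg
  counts <- tabulate(k + 1L, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_deg,
             bin_end = seq_len(nb) * bin_deg,
             count = counts)
}

#' Circular mean direction and resultant length
#'
#' Vector-sum statistics: mean direction (degrees) of the unit vectors and
#' resultant length `R = |mean unit vector|` in \[0, 1\]. `R = 1` iff all
#' angles are identical; `R` near 0 indicates no preferred orientation.
#'
#' @param angles_deg angles in degrees; at least one required.
#' @return list `mean_deg, R, n`.
#' @export
circular_summary <- function(angles_deg) {
  if (!length(angles_deg)) stop("at least one angle required")
  th <- angles_deg * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mu <- if (R < .Machine$double.eps^0.5) NA_real_ else
    (atan2(S, C) * 180 / pi) %% 360
  list(mean_deg = mu, R = R, n = length(angles_deg))
}

#' Fraction of marginal cells displaying protrusions
#'
#' @param n_with cells with at least one protrusion (0 <= n_with <= n_total).
#' @param n_total total marginal cells (> 0).
#' @return fraction in \[0, 1\].
#' @export
marginal_cell_fraction <- function(n_with, n_total) {
  if (n_total <= 0) stop("n_total must be > 0")
  if (n_with < 0 || n_with > n_total)
    stop("n_with must be in [0, n_total]")
  n_with / n_total
}
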
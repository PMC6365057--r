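#' Configuration for the synthetic expression-domain image
#'
#' Fixture generator for the in-situ morphometry stages: a rotated ellipse
#' standing in for the prechordal-plate (`hgg`) expression domain and a
#' rectangular bar for the notochord (`ntl`) domain, separated by a known
#' gap along the major-axis direction, with a scale-bar annotation record
#' from which the calibration is recovered.
#'
#' @param ppl_axes (major, minor) full axis lengths in um of the elliptical
#'   ppl domain; major >= minor > 0.
#' @param nc_size (length, width) of the notochord bar in um; length runs
#'   along the major-axis direction.
#' @param gap boundary-to-boundary separation between ppl and nc in um, >= 0.
#' @param rotation image-plane rotation of the whole arrangement in degrees.
#' @param pixel_size um per pixel, > 0.
#' @param scalebar_um physical length of the annotated scale bar in um.
#' @param pad_um padding around the domains in um.
#' @param seed integer seed (reserved for noisy variants).
#' @return list of class `domain_sim_config`.
#' @export
domain_sim_config <- function(ppl_axes = c(100, 50), nc_size = c(160, 30),
                              gap = 60, rotation = 0, pixel_size = 2,
                              scalebar_um = 250, pad_um = 40, seed = 1L) {
  if (!(ppl_axes[1] >= ppl_axes[2] && ppl_axes[2] > 0))
    stop("ppl_axes must satisfy major >= minor > 0")
  if (gap < 0) stop("gap must be >= 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(ppl_axes = ppl_axes, nc_size = nc_size, gap = gap,
                 rotation = rotation, pixel_size = pixel_size,
                 scalebar_um = scalebar_um, pad_um = pad_um,
                 seed = as.integer(seed)),
            class = "domain_sim_config")
}

#' Rasterize the synthetic two-domain expression image
#'
#' Builds a label image (background 0, ppl 1, nc 2) on a pixel grid with
#' pixel centers at integer coordinates. The ppl ellipse is centered left of
#' the nc bar; `gap` separates the ppl's right (posterior) boundary from the
#' nc's left (anterior) boundary along the pre-rotation x axis. The returned
#' metadata carries the ground truth every estimator must recover.
#'
#' @param config a `domain_sim_config`.
#' @return list of class `label_image`: `labels` (integer matrix, row-major,
#'   origin top-left), `meta` (pixel_size, scalebar px/um record, truth).
#' @export
make_domain_image <- function(config) {
  stopifnot(inherits(config, "domain_sim_config"))
  px <- config$pixel_size
  a <- config$ppl_axes[1] / 2; b <- config$ppl_axes[2] / 2
  ncl <- config$nc_size[1]; ncw <- config$nc_size[2]
  th <- config$rotation * pi / 180
  # um-space layout before rotation: ellipse centered at origin,
  # bar from x = a + gap to a + gap + ncl, centered on y = 0
  xmin <- -a - config$pad_um
  xmax <- a + config$gap + ncl + config$pad_um
  half_h <- max(b, ncw / 2) + config$pad_um
  # rotated bounding box
  corners <- rbind(c(xmin, -half_h), c(xmin, half_h),
                   c(xmax, -half_h), c(xmax, half_h))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # column-major
  rc <- corners %*% t(R)
  # grid anchored on integer multiples of the pixel size, so that the
  # um-space origin always falls on a pixel center
  ox <- floor(min(rc[, 1]) / px) * px
  oy <- floor(min(rc[, 2]) / px) * px
  nx <- ceiling((max(rc[, 1]) - ox) / px) + 1L
  ny <- ceiling((max(rc[, 2]) - oy) / px) + 1L
  # pixel centers in um, mapped back into the unrotated frame
  gx <- (seq_len(nx) - 1) * px + ox
  gy <- (seq_len(ny) - 1) * px + oy
  X <- matrix(gx, ny, nx, byrow = TRUE)
  Y <- matrix(gy, ny, nx)
  U <- cos(th) * X + sin(th) * Y    # inverse rotation
  V <- -sin(th) * X + cos(th) * Y
  labels <- matrix(0L, ny, nx)
  labels[(U / a)^2 + (V / b)^2 <= 1] <- 1L
  in_bar <- U >= a + config$gap & U <= a + config$gap + ncl &
    abs(V) <= ncw / 2
  if (any(labels[in_bar] == 1L)) stop("domain construction overlap")
  labels[in_bar] <- 2L
  meta <- list(
    pixel_size = px,
    scalebar = list(length_px = config$scalebar_um / px,
                    length_um = config$scalebar_um),
    truth = list(lwr = config$ppl_axes[1] / config$ppl_axes[2],
                 gap_um = config$gap, rotation = config$rotation,
                 ppl_axes = config$ppl_axes)
  )
  structure(list(labels = labels, meta = meta), class = "label_image")
}

#' Write / read a label image as PNG plus JSON metadata sidecar
#'
#' Masks are written as 8-bit PNG (label values scaled by 1); the metadata
#' (pixel size, scale-bar record, ground truth) goes into `<path>.json`.
#'
#' @param img a `label_image`.
#' @param path output PNG path.
#' @return `read_label_image()` returns the `label_image`.
#' @export
write_label_image <- function(img, path) {
  png::writePNG(img$labels / 255, path)
  jsonlite::write_json(img$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  labels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  structure(list(labels = labels, meta = meta), class = "label_image")
}

#' Configuration for the synthetic membrane line profile
#'
#' Emulates a fluorescence intensity profile along a line drawn across
#' `n_cells` adjacent cells: `n_cells + 1` Gaussian-shaped membrane peaks at
#' known, evenly spaced positions rising above a cytosolic plateau, with
#' optional additive Gaussian noise. Ground-truth cytosol/membrane ratio is
#' `cytosol_level / membrane_peak`.
#'
#' @param n_cells number of cells crossed by the line (>= 0).
#' @param membrane_peak absolute peak intensity at membranes (>
#'   `cytosol_level`).
#' @param cytosol_level plateau intensity between membranes (>= 0).
#' @param peak_width Gaussian sigma of a membrane peak in px.
#' @param noise_sigma additive noise SD in intensity units.
#' @param length profile length in px.
#' @param seed integer seed.
#' @return list of class `profile_sim_config`.
#' @export
profile_sim_config <- function(n_cells = 4, membrane_peak = 200,
                               cytosol_level = 50, peak_width = 3,
                               noise_sigma = 0, length = 400, seed = 1L) {
  if (!(membrane_peak > cytosol_level && cytosol_level >= 0))
    stop("need membrane_peak > cytosol_level >= 0")
  if (n_cells > 0) {
    spacing <- length / (n_cells + 2)
    if (spacing <= 4 * peak_width)
      stop("peak spacing smaller than peak width: lengthen the profile")
  }
  structure(list(n_cells = as.integer(n_cells),
                 membrane_peak = membrane_peak,
                 cytosol_level = cytosol_level, peak_width = peak_width,
                 noise_sigma = noise_sigma, length = as.integer(length),
                 seed = as.integer(seed)),
            class = "profile_sim_config")
}

#' Generate the synthetic membrane/cytosol intensity profile
#'
#' @param config a `profile_sim_config`.
#' @return data.frame of class `intensity_profile` with columns
#'   `position_px, intensity`; attributes `truth` (peak positions, ratio)
#'   and `degenerate` (TRUE when `n_cells = 0`, i.e. a flat profile).
#' @export
make_membrane_profile <- function(config) {
  stopifnot(inherits(config, "profile_sim_config"))
  set.seed(config$seed)
  x <- seq_len(config$length)
  n_peaks <- config$n_cells + 1L
  y <- rep(config$cytosol_level, config$length)
  peaks <- numeric(0)
  if (config$n_cells > 0) {
    spacing <- config$length / (config$n_cells + 2)
    peaks <- round(spacing * seq_len(n_peaks))
    # compact bumps: Gaussian truncated at 3 sigma, so the cytosolic
    # plateau between membranes is exactly cytosol_level in the clean case
    for (p in peaks) {
      w <- abs(x - p) <= 3 * config$peak_width
      y[w] <- pmax(y[w], config$cytosol_level +
                     (config$membrane_peak - config$cytosol_level) *
                     exp(-(x[w] - p)^2 / (2 * config$peak_width^2)))
    }
  }
  if (config$noise_sigma > 0)
    y <- y + stats::rnorm(config$length, sd = config$noise_sigma)
  prof <- data.frame(position_px = x, intensity = y)
  class(prof) <- c("intensity_profile", "data.frame")
  attr(prof, "truth") <- list(
    peak_positions = peaks,
    ratio = config$cytosol_level / config$membrane_peak,
    membrane_peak = config$membrane_peak,
    cytosol_level = config$cytosol_level,
    peak_width = config$peak_width
  )
  attr(prof, "degenerate") <- config$n_cells == 0L
  prof
}
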
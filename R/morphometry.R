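#' Scale-bar calibration
#'
#' Pixel size from an annotated scale bar: um/px = bar_um / bar_px.
#'
#' @param bar_px scale-bar length in pixels (> 0).
#' @param bar_um physical scale-bar length in um (> 0).
#' @return um per pixel (scalar, isotropic).
#' @export
calibrate <- function(bar_px, bar_um) {
  if (bar_px <= 0 || bar_um <= 0) stop("scale-bar lengths must be positive")
  bar_um / bar_px
}

#' Segment an expression domain by threshold + largest component
#'
#' Replaces the interactive ROI selection of the original workflow: pixels
#' above (or below, for dark chromogenic stain) the threshold are kept and
#' the largest 8-connected component is returned as the domain mask.
#'
#' @param image numeric or integer matrix (row-major, origin top-left).
#' @param threshold intensity threshold.
#' @param direction `"above"` (default) keeps `image >= threshold`,
#'   `"below"` keeps `image <= threshold`.
#' @return logical matrix mask of the largest component.
#' @export
segment_domain <- function(image, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  fg <- if (direction == "above") image >= threshold else image <= threshold
  if (!any(fg)) stop("empty segmentation: no pixels pass the threshold")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' 8-connected component labeling
#'
#' Labels foreground pixels of a logical matrix by 8-connectivity, via
#' connected components of the pixel adjacency graph.
#'
#' @param mask logical matrix.
#' @return integer matrix: 0 background, 1..k component ids (id order is by
#'   first pixel in column-major order).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  r <- (idx - 1L) %% nr + 1L
  c_ <- (idx - 1L) %/% nr + 1L
  # edges to 4 forward neighbors (E, SE, S, SW) cover all 8-adjacency
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    rn <- r + o[1]; cn <- c_ + o[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- mask[nb]
    from <- c(from, idx[ok][hit]); to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(from, idx), match(to, idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# pixel-center coordinates (x = col, y = row) of mask pixels
mask_points <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(x = (idx - 1L) %/% nr + 1L, y = (idx - 1L) %% nr + 1L)
}

#' Length-to-width ratio of a domain mask
#'
#' Length is the maximum Feret diameter (largest pixel-center pairwise
#' distance, computed on the convex hull); width is the maximal extent of
#' the mask projected perpendicular to the max-Feret direction. The ratio
#' length/width is >= 1 by construction and invariant under rotation,
#' translation and uniform scaling up to pixel discretization.
#'
#' @param mask logical matrix (non-empty, more than one pixel).
#' @return list `lwr, length_px, width_px, direction` (unit 2-vector of the
#'   longest axis, x = column, y = row).
#' @export
lwr <- function(mask) {
  pts <- mask_points(mask)
  if (nrow(pts) < 2) stop("degenerate mask: need more than one pixel")
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d <- as.matrix(stats::dist(hull))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  len <- d[ij[1], ij[2]]
  if (len == 0) stop("degenerate mask: all pixels coincident")
  dir <- (hull[ij[2], ] - hull[ij[1], ]) / len
  perp <- c(-dir[2], dir[1])
  proj <- pts %*% perp
  width <- max(proj) - min(proj)
  if (width == 0) stop("degenerate mask: zero width")
  list(lwr = len / width, length_px = len, width_px = width,
       direction = as.numeric(dir))
}

#' Boundary pixels of a mask
#'
#' A boundary pixel is a mask pixel 4-adjacent to background (or to the
#' image edge).
#'
#' @param mask logical matrix.
#' @return logical matrix marking boundary pixels.
#' @export
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)]
  mask & !inner
}

#' Minimum distance between two expression domains
#'
#' Minimum Euclidean distance between boundary pixel centers of the two
#' masks, converted to um with the calibration. Overlapping masks give 0
#' with a warning. An along-axis variant projects boundary points onto a
#' given direction first (distance along the AP axis rather than shortest
#' 2D distance).
#'
#' @param mask_a,mask_b logical matrices on the same pixel grid (non-empty).
#' @param um_per_px calibration, um per pixel.
#' @param axis optional unit 2-vector (x = col, y = row); when given, the
#'   distance is the gap between the projections of the two boundaries onto
#'   this axis.
#' @return distance in um.
#' @export
domain_distance <- function(mask_a, mask_b, um_per_px = 1, axis = NULL) {
  if (!any(mask_a) || !any(mask_b)) stop("masks must be non-empty")
  if (any(mask_a & mask_b)) {
    warning("masks overlap; distance is 0")
    return(0)
  }
  pa <- mask_points(mask_boundary(mask_a))
  pb <- mask_points(mask_boundary(mask_b))
  if (!is.null(axis)) {
    axis <- axis / sqrt(sum(axis^2))
    qa <- pa %*% axis; qb <- pb %*% axis
    gap <- max(0, max(min(qb) - max(qa), min(qa) - max(qb)))
    return(gap * um_per_px)
  }
  # blockwise pairwise distances to bound memory
  best <- Inf
  step <- 2000L
  for (i0 in seq(1L, nrow(pa), by = step)) {
    ia <- i0:min(i0 + step - 1L, nrow(pa))
    dx <- outer(pa[ia, 1], pb[, 1], "-")
    dy <- outer(pa[ia, 2], pb[, 2], "-")
    best <- min(best, min(dx * dx + dy * dy))
  }
  sqrt(best) * um_per_px
}

#' Prominence-filtered local maxima of a 1D signal
#'
#' A sample is a peak when strictly greater than both neighbors (plateaus
#' take the first sample). Prominence of a peak is its height minus the
#' higher of the two minima separating it from nearer higher terrain, the
#' usual topographic definition. Peaks closer than `min_spacing` are pruned
#' keeping the higher peak.
#'
#' @param y numeric signal.
#' @param prominence minimal prominence to keep a peak.
#' @param min_spacing minimal index spacing between kept peaks.
#' @return data.frame `position, height, prominence`, ordered by position.
#' @export
find_peaks <- function(y, prominence = 0, min_spacing = 1) {
  n <- length(y)
  if (n < 3) return(data.frame(position = integer(), height = numeric(),
                               prominence = numeric()))
  # candidate local maxima; plateaus take their first sample
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[vapply(cand, function(i) {
    # a summit: the next differing sample on the right is lower (or absent)
    j <- i + 1L
    while (j <= n && y[j] == y[i]) j <- j + 1L
    j > n || y[j] < y[i]
  }, logical(1))]
  if (!length(cand)) return(data.frame(position = integer(),
                                       height = numeric(),
                                       prominence = numeric()))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1) y[1:(i - 1)] else numeric(0)
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
              else min(left)
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[1:(min(higher_r) - 1)])
              else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence
  pos <- cand[keep]; hgt <- y[pos]; prm <- prom[keep]
  # spacing pruning, highest first
  ord <- order(hgt, decreasing = TRUE)
  sel <- logical(length(pos))
  for (k in ord)
    if (!any(sel & abs(pos - pos[k]) < min_spacing)) sel[k] <- TRUE
  o <- order(pos[sel])
  data.frame(position = pos[sel][o], height = hgt[sel][o],
             prominence = prm[sel][o])
}

#' Cytosol-to-membrane fluorescence intensity ratio from a line profile
#'
#' Membrane intensity is the mean of detected peak values (peaks = local
#' maxima with the given prominence and spacing); cytosolic intensity is the
#' mean of samples farther than `peak_halfwidth` from every peak. The
#' reported ratio is cytosol/membrane. At least two peaks are required (a
#' cell crossed by the line has two membranes).
#'
#' @param profile data.frame `position_px, intensity` (an
#'   `intensity_profile`), >= 3 samples with strictly increasing positions.
#' @param prominence minimal peak prominence; default 1/4 of the profile's
#'   dynamic range.
#' @param min_spacing minimal peak spacing in samples.
#' @param peak_halfwidth samples within this distance of a peak are excluded
#'   from the cytosol estimate; default `min_spacing / 2`.
#' @return list `ratio, membrane, cytosol, peaks` (data.frame).
#' @export
membrane_cytosol_ratio <- function(profile, prominence = NULL,
                                   min_spacing = 10,
                                   peak_halfwidth = min_spacing / 2) {
  y <- profile$intensity
  x <- profile$position_px
  if (length(y) < 3) stop("profile needs at least 3 samples")
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing")
  if (is.null(prominence)) prominence <- (max(y) - min(y)) / 4
  pk <- find_peaks(y, prominence = prominence, min_spacing = min_spacing)
  if (nrow(pk) < 2) stop("no membrane pair found (< 2 peaks detected)")
  membrane <- mean(pk$height)
  near <- rep(FALSE, length(y))
  for (p in pk$position)
    near <- near | abs(seq_along(y) - p) <= peak_halfwidth
  if (all(near)) stop("no cytosolic samples outside peak neighborhoods")
  cytosol <- mean(y[!near])
  list(ratio = cytosol / membrane, membrane = membrane, cytosol = cytosol,
       peaks = data.frame(position = x[pk$position], height = pk$height,
                          prominence = pk$prominence))
}

#' Per-nucleus mean intensity under a label mask
#'
#' Mean of the signal channel over each labeled nucleus of the mask (the
#' DAPI-derived nuclear segmentation), label by label.
#'
#' @param signal_image numeric matrix, the channel to quantify.
#' @param nuclear_mask integer matrix of nucleus labels (0 = background),
#'   same dimensions.
#' @return data.frame `label, mean_intensity, n_px`, ordered by label.
#' @export
nuclear_mean_intensity <- function(signal_image, nuclear_mask) {
  stopifnot(all(dim(signal_image) == dim(nuclear_mask)))
  labs <- sort(unique(nuclear_mask[nuclear_mask > 0]))
  if (!length(labs)) stop("empty nuclear mask")
  data.frame(
    label = labs,
    mean_intensity = vapply(labs, function(l)
      mean(signal_image[nuclear_mask == l]), numeric(1)),
    n_px = vapply(labs, function(l) sum(nuclear_mask == l), numeric(1))
  )
}
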
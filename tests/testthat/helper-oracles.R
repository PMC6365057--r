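# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the most literal algorithm available, so that
# the package implementations are checked against something that shares no
# code with them.

# recursive flood fill, 8-connectivity
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] > 0L) next
      lab[p[1], p[2]] <- cur
      for (di in -1:1) for (dj in -1:1)
        if (di || dj) stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
    }
  }
  lab
}

# Feret extents by direction sweep over fine angular steps
oracle_feret <- function(mask, step_deg = 0.5) {
  pts <- which(mask, arr.ind = TRUE)
  xy <- cbind(pts[, 2], pts[, 1])
  angs <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ext <- vapply(angs, function(a) {
    pr <- xy %*% c(cos(a), sin(a))
    max(pr) - min(pr)
  }, numeric(1))
  list(max = max(ext), angle_of_max = angs[which.max(ext)])
}

# all-pairs minimum distance between boundary pixel centers
oracle_boundary_distance <- function(mask_a, mask_b) {
  bd <- function(m) {
    pts <- which(m, arr.ind = TRUE)
    keep <- apply(pts, 1, function(p) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nrow(m) || q[2] < 1 || q[2] > ncol(m) ||
            !m[q[1], q[2]]) return(TRUE)
      }
      FALSE
    })
    pts[keep, , drop = FALSE]
  }
  pa <- bd(mask_a); pb <- bd(mask_b)
  best <- Inf
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    best <- min(best, sum((pa[i, ] - pb[j, ])^2))
  sqrt(best)
}

# per-label mean by explicit loop
oracle_label_means <- function(img, mask) {
  labs <- sort(unique(mask[mask > 0]))
  sapply(labs, function(l) {
    s <- 0; k <- 0
    for (j in seq_len(ncol(img))) for (i in seq_len(nrow(img)))
      if (mask[i, j] == l) { s <- s + img[i, j]; k <- k + 1 }
    s / k
  })
}

# exhaustive atom-pair contact scan
oracle_contacts <- function(atoms, segmap, tolerance = 0.5,
                            radii = gastruquant::vdw_radii()) {
  a <- atoms[as.character(atoms$resno) %in% names(segmap), ]
  seen <- character(0)
  count <- 0L
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    si <- segmap[[as.character(a$resno[i])]]
    sj <- segmap[[as.character(a$resno[j])]]
    if (si == sj || a$resno[i] == a$resno[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    ri <- radii[[toupper(a$element[i])]]; rj <- radii[[toupper(a$element[j])]]
    if (d <= ri + rj + tolerance) {
      key <- paste(min(a$resno[i], a$resno[j]), max(a$resno[i], a$resno[j]))
      if (!key %in% seen) { seen <- c(seen, key); count <- count + 1L }
    }
  }
  count
}

# sector index by per-cell loop
oracle_sector_assign <- function(x, y, center, sector) {
  t(vapply(seq_along(x), function(k) {
    ix <- 0L
    while (center[1] + (ix + 1) * sector <= x[k]) ix <- ix + 1L
    while (center[1] + ix * sector > x[k]) ix <- ix - 1L
    iy <- 0L
    while (center[2] + (iy + 1) * sector <= y[k]) iy <- iy + 1L
    while (center[2] + iy * sector > y[k]) iy <- iy - 1L
    c(ix, iy)
  }, integer(2)))
}
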
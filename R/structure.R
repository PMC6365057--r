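#' Generate an idealized transmembrane helix bundle (CA trace)
#'
#' Fixture generator for the superposition and contact analyses: `n_helices`
#' ideal alpha-helical CA traces (rise 1.5 A/residue, 100 degrees/residue,
#' helical radius 2.3 A) arranged with their axes parallel to z on a circle
#' whose radius is set by the axis-to-axis `spacing` between neighboring
#' helices. Optionally returns a paired copy that is Gaussian-perturbed and
#' then rigidly transformed, with the ground-truth RMSD (computed on the
#' stored paired coordinates before the rigid motion) in the metadata.
#'
#' @param n_helices number of helices (>= 2 for contact fixtures).
#' @param residues_per_helix residues per helix.
#' @param spacing axis-to-axis distance between adjacent helices in A.
#' @param perturbation_sigma per-coordinate Gaussian displacement SD (A)
#'   applied to the copy.
#' @param transform_copy apply a random rigid rotation + translation to the
#'   perturbed copy.
#' @param seed integer seed.
#' @return list of class `structure_model`: `atoms` (data.frame `element,
#'   name, resno, chain, x, y, z, segment`), `annotation` (segment ->
#'   residue ranges), and when a copy is made, `copy` (another
#'   `structure_model`) plus `truth$rmsd`.
#' @export
make_helix_bundle <- function(n_helices = 7, residues_per_helix = 25,
                              spacing = 10, perturbation_sigma = 0,
                              transform_copy = FALSE, seed = 1L) {
  if (n_helices < 2) stop("n_helices must be >= 2")
  set.seed(seed)
  rise <- 1.5; twist <- 100 * pi / 180; rhelix <- 2.3
  Rbundle <- spacing / (2 * sin(pi / n_helices))
  atoms <- list()
  res0 <- 0L
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    cx <- Rbundle * cos(phi); cy <- Rbundle * sin(phi)
    i <- seq_len(residues_per_helix)
    atoms[[h]] <- data.frame(
      element = "C", name = "CA",
      resno = res0 + i, chain = "A",
      x = cx + rhelix * cos(twist * i),
      y = cy + rhelix * sin(twist * i),
      z = rise * i,
      segment = sprintf("TM%d", h),
      stringsAsFactors = FALSE
    )
    res0 <- res0 + residues_per_helix
  }
  atoms <- do.call(rbind, atoms)
  ann <- split(atoms$resno, atoms$segment)
  ann <- lapply(ann[order(as.integer(sub("TM", "", names(ann))))], range)
  model <- structure(list(atoms = atoms, annotation = ann, source = "synthetic"),
                     class = "structure_model")
  if (perturbation_sigma > 0 || transform_copy) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    pert <- xyz + matrix(stats::rnorm(length(xyz), sd = perturbation_sigma),
                         ncol = 3)
    truth_rmsd <- sqrt(mean(rowSums((pert - xyz)^2)))
    if (transform_copy) {
      R <- random_rotation()
      tr <- stats::runif(3, -20, 20)
      pert <- sweep(pert %*% t(R), 2, tr, "+")
    }
    copy <- model
    copy$atoms$x <- pert[, 1]; copy$atoms$y <- pert[, 2]
    copy$atoms$z <- pert[, 3]
    model$copy <- copy
    model$truth <- list(rmsd = truth_rmsd,
                        perturbation_sigma = perturbation_sigma)
  }
  model
}

# uniform random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Write a structure model as PDB
#'
#' @param model a `structure_model`.
#' @param path output PDB path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  n <- nrow(a)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, chain = a$chain, resid = rep("ALA", n),
    elety = a$name, eleno = seq_len(n))
  invisible(path)
}

#' Read a protein structure for TM analysis
#'
#' Parses a PDB file, restricts to one chain, drops hydrogens and water,
#' keeps altloc "A" (or blank) only, and optionally excludes residue ranges
#' (e.g. fusion-construct domains such as the BRIL insertions of some GPCR
#' crystal structures).
#'
#' @param path PDB file.
#' @param chain chain identifier, default `"A"`.
#' @param exclusions list of `c(from, to)` residue-number ranges to drop.
#' @return a `structure_model` (atoms: element, name, resno, chain, x, y, z).
#' @export
read_structure <- function(path, chain = "A", exclusions = list()) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$chain == chain & a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("chain '", chain, "' not found in ", path)
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  for (ex in exclusions)
    a <- a[!(a$resno >= ex[1] & a$resno <= ex[2]), , drop = FALSE]
  elem <- ifelse(is.na(a$elesy) | a$elesy == "",
                 substr(gsub("[0-9]", "", a$elety), 1, 1), a$elesy)
  keep <- toupper(elem) != "H"
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  structure(list(
    atoms = data.frame(element = toupper(elem), name = a$elety,
                       resno = a$resno, chain = a$chain,
                       x = a$x, y = a$y, z = a$z,
                       stringsAsFactors = FALSE),
    annotation = NULL, source = basename(path)), class = "structure_model")
}

#' Read a TM segment annotation from YAML
#'
#' YAML maps segment names (TM1..TM7, H8) to residue ranges `[from, to]` (or
#' a list of ranges). Such annotations are curated (GPCRdb-style segment
#' boundaries), not computed.
#'
#' @param path YAML file; top level may be keyed by structure id.
#' @param id optional structure id key.
#' @return named list segment -> list of c(from, to) ranges.
#' @export
read_annotation <- function(path, id = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(id)) {
    if (is.null(y[[id]])) stop("no annotation for id '", id, "'")
    y <- y[[id]]
  }
  if (!is.null(y$segments)) y <- y$segments
  lapply(y, function(seg) {
    if (is.list(seg)) lapply(seg, function(r) as.integer(r[1:2]))
    else list(as.integer(seg[1:2]))
  })
}

# flat residue -> segment lookup from an annotation
segment_of <- function(annotation) {
  res <- integer(0); seg <- character(0)
  for (s in names(annotation)) {
    rs <- annotation[[s]]
    if (!is.list(rs)) rs <- list(rs)
    for (r in rs) {
      rr <- r[1]:r[2]
      res <- c(res, rr); seg <- c(seg, rep(s, length(rr)))
    }
  }
  if (anyDuplicated(res)) stop("annotation segments overlap")
  stats::setNames(seg, res)
}

#' Pair residues between two annotated structures
#'
#' Mode `"trim"` pairs each segment's residues index-by-index after trimming
#' the longer segment symmetrically to the shorter one's length (on an odd
#' surplus the extra residue is dropped from the C-terminal end). Mode
#' `"generic"` pairs residues sharing a generic number given in the
#' annotations as named vectors `generic_numbers` (residue -> label).
#'
#' @param annotA,annotB segment annotations (segment -> ranges), same
#'   segment names for the segments to pair.
#' @param mode `"trim"` or `"generic"`.
#' @param genericA,genericB named character vectors residue -> generic
#'   number (mode `"generic"`).
#' @param segments segments to use; default intersection of names.
#' @return data.frame `segment, resA, resB`.
#' @export
pair_residues <- function(annotA, annotB, mode = c("trim", "generic"),
                          genericA = NULL, genericB = NULL,
                          segments = NULL) {
  mode <- match.arg(mode)
  if (mode == "generic") {
    if (is.null(genericA) || is.null(genericB))
      stop("generic mode needs genericA and genericB")
    common <- intersect(genericA, genericB)
    if (!length(common)) stop("empty pairing")
    ra <- as.integer(names(genericA)[match(common, genericA)])
    rb <- as.integer(names(genericB)[match(common, genericB)])
    segA <- segment_of(annotA)
    return(data.frame(segment = unname(segA[as.character(ra)]),
                      resA = ra, resB = rb, stringsAsFactors = FALSE))
  }
  if (is.null(segments)) segments <- intersect(names(annotA), names(annotB))
  if (!length(segments)) stop("empty pairing: no shared segments")
  out <- list()
  for (s in segments) {
    ra <- unlist(lapply(if (is.list(annotA[[s]])) annotA[[s]] else
      list(annotA[[s]]), function(r) r[1]:r[2]))
    rb <- unlist(lapply(if (is.list(annotB[[s]])) annotB[[s]] else
      list(annotB[[s]]), function(r) r[1]:r[2]))
    n <- min(length(ra), length(rb))
    trim_to <- function(v, n) {
      extra <- length(v) - n
      head_cut <- extra %/% 2           # tie: drop extra from C-terminal end
      v[(head_cut + 1):(head_cut + n)]
    }
    out[[s]] <- data.frame(segment = s, resA = trim_to(ra, n),
                           resB = trim_to(rb, n), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Least-squares rigid superposition (Kabsch) of paired CA atoms
#'
#' Superposes the CA atoms of the paired residues of two models by the
#' optimal proper rotation + translation and reports the RMSD over all
#' pairs; no outlier pruning by default (optional iterative pruning drops
#' pairs beyond `prune_sd` SDs of the pair distances and refits).
#'
#' @param modelA,modelB `structure_model`s.
#' @param pairing data.frame `resA, resB` from [pair_residues()]; >= 3 pairs.
#' @param prune_sd if finite, iteratively drop pairs with residual distance
#'   beyond this many SDs above the mean and refit (max 5 rounds).
#' @return list `rmsd, n_pairs, rotation, translation` (mapping A onto B).
#' @export
superpose <- function(modelA, modelB, pairing, prune_sd = Inf) {
  ca <- function(m) m$atoms[m$atoms$name == "CA", , drop = FALSE]
  a <- ca(modelA); b <- ca(modelB)
  ia <- match(pairing$resA, a$resno)
  ib <- match(pairing$resB, b$resno)
  ok <- !is.na(ia) & !is.na(ib)
  P <- as.matrix(a[ia[ok], c("x", "y", "z")])
  Q <- as.matrix(b[ib[ok], c("x", "y", "z")])
  if (nrow(P) < 3) stop("need >= 3 paired CA atoms")
  fit <- kabsch(P, Q)
  if (is.finite(prune_sd)) {
    for (round in 1:5) {
      d <- sqrt(rowSums((sweep(P %*% t(fit$rotation), 2, fit$translation,
                               "+") - Q)^2))
      keep <- d <= mean(d) + prune_sd * stats::sd(d)
      if (all(keep) || sum(keep) < 3) break
      P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
      fit <- kabsch(P, Q)
    }
  }
  c(fit, list(n_pairs = nrow(P)))
}

# Kabsch: optimal proper rotation R and translation t minimizing |PR' + t - Q|
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- cq - as.numeric(R %*% cp)
  aligned <- sweep(P %*% t(R), 2, t_, "+")
  list(rmsd = sqrt(mean(rowSums((aligned - Q)^2))),
       rotation = R, translation = t_)
}

#' Default van der Waals radii (A) for heavy atoms
#' @return named numeric vector by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

#' Residue contact network within an annotated structure
#'
#' Two residues are in contact when any heavy-atom pair lies within
#' `r_vdw(i) + r_vdw(j) + tolerance` (default tolerance 0.5 A, the
#' Protein-Contacts-Atlas-style criterion). Only residues inside annotated
#' segments participate; intra-segment pairs and residue pairs closer than
#' `min_seq_sep` in sequence are excluded; each unordered pair is counted
#' once with its minimal inter-atomic distance.
#'
#' @param model a `structure_model`.
#' @param annotation segment annotation (segment -> ranges); defaults to the
#'   model's own.
#' @param tolerance added to the vdW-radii sum, in A.
#' @param min_seq_sep minimal residue-number separation, default 1 (only
#'   self-pairs excluded; inter-segment pairs are never sequence neighbors
#'   in practice).
#' @param radii named vdW radius table; unknown elements fall back to 1.7 A
#'   with a warning.
#' @return data.frame of class `contact_network`: `resA, resB, segA, segB,
#'   min_dist`.
#' @export
contact_network <- function(model, annotation = NULL, tolerance = 0.5,
                            min_seq_sep = 1, radii = vdw_radii()) {
  if (is.null(annotation)) annotation <- model$annotation
  if (is.null(annotation)) stop("an annotation is required")
  segmap <- segment_of(annotation)
  a <- model$atoms
  a <- a[as.character(a$resno) %in% names(segmap), , drop = FALSE]
  if (!nrow(a)) stop("no atoms inside annotated segments")
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    warning("unknown element(s) ", paste(unknown, collapse = ","),
            "; using default radius 1.7 A")
    radii[unknown] <- 1.7
  }
  r <- radii[el]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  seg <- unname(segmap[as.character(a$resno)])
  resno <- a$resno
  maxr <- max(r)
  cutoff <- 2 * maxr + tolerance
  # chunked pairwise scan
  n <- nrow(xyz)
  hits <- list(); hk <- 0L
  step <- 1500L
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(i0 + step - 1L, n)
    d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[ii, , drop = FALSE] %*% t(xyz)
    d2[d2 < 0] <- 0
    cand <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(cand)) next
    gi <- ii[cand[, 1]]; gj <- cand[, 2]
    keep <- gi < gj & seg[gi] != seg[gj] &
      abs(resno[gi] - resno[gj]) >= min_seq_sep
    gi <- gi[keep]; gj <- gj[keep]
    if (!length(gi)) next
    d <- sqrt(d2[cand][keep])
    inc <- d <= r[gi] + r[gj] + tolerance
    if (!any(inc)) next
    hk <- hk + 1L
    hits[[hk]] <- data.frame(resA = resno[gi][inc], resB = resno[gj][inc],
                             segA = seg[gi][inc], segB = seg[gj][inc],
                             dist = d[inc], stringsAsFactors = FALSE)
  }
  if (!hk) {
    net <- data.frame(resA = integer(), resB = integer(),
                      segA = character(), segB = character(),
                      min_dist = numeric())
    class(net) <- c("contact_network", "data.frame")
    return(net)
  }
  h <- do.call(rbind, hits)
  # order each residue pair and keep the minimal distance once
  lo <- pmin(h$resA, h$resB); hi <- pmax(h$resA, h$resB)
  sw <- h$resA > h$resB
  sa <- ifelse(sw, h$segB, h$segA); sb <- ifelse(sw, h$segA, h$segB)
  key <- paste(lo, hi)
  o <- order(key, h$dist)
  first <- !duplicated(key[o])
  net <- data.frame(resA = lo[o][first], resB = hi[o][first],
                    segA = sa[o][first], segB = sb[o][first],
                    min_dist = h$dist[o][first], stringsAsFactors = FALSE)
  rownames(net) <- NULL
  class(net) <- c("contact_network", "data.frame")
  net
}

#' Inter-helical contact counts per segment pair
#'
#' @param network a `contact_network`.
#' @return list `counts` (data.frame `pair, count`, unordered segment pairs)
#'   and `total`.
#' @export
interhelical_counts <- function(network) {
  if (!nrow(network))
    return(list(counts = data.frame(pair = character(), count = integer()),
                total = 0L))
  pr <- apply(cbind(network$segA, network$segB), 1, function(v)
    paste(sort(v), collapse = "-"))
  tab <- table(pr)
  list(counts = data.frame(pair = names(tab), count = as.integer(tab),
                           stringsAsFactors = FALSE),
       total = nrow(network))
}

#' Contact distribution over segment pairs
#'
#' Fraction of all inter-helical contacts carried by each segment pair;
#' fractions sum to 1. `focus_pairs` reports the summed fraction over a
#' named pair set (e.g. the sequence-adjacent helix pairs).
#'
#' @param counts result of [interhelical_counts()].
#' @param focus_pairs optional character vector of pair names (`"TM1-TM2"`).
#' @return list `fractions` (data.frame `pair, fraction`) and, when
#'   requested, `focus_fraction`.
#' @export
contact_distribution <- function(counts, focus_pairs = NULL) {
  if (counts$total == 0) stop("zero total contacts")
  fr <- data.frame(pair = counts$counts$pair,
                   fraction = counts$counts$count / counts$total,
                   stringsAsFactors = FALSE)
  out <- list(fractions = fr)
  if (!is.null(focus_pairs))
    out$focus_fraction <- sum(fr$fraction[fr$pair %in% focus_pairs])
  out
}
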
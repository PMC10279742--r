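## Per-frame and per-ensemble structural measurements.

# position of a DNA bead along its helix (1 = top). Strand 2 is
# antiparallel, so its paired residue j sits at position bp + 1 - j.
# Loop beads are placed past the strand ends: strand 1 loops below the
# bottom, strand 2 loops above the top.
.helix_position <- function(topology) {
  spec <- attr(topology, "spec")
  bp <- spec$bp_per_duplex
  pos <- rep(NA_real_, nrow(topology))
  dna <- topology$role %in% c("backbone", "base")
  s1 <- dna & topology$strand == 1L
  s2 <- dna & topology$strand == 2L
  pos[s1] <- topology$residue[s1]
  pos[s2] <- bp + 1L - topology$residue[s2]
  lp <- topology$role == "loop"
  pos[lp & topology$strand == 1L] <- bp + 1L   # below the bottom
  pos[lp & topology$strand == 2L] <- 0L        # above the top
  pos
}

#' Fit a helix axis by principal component analysis
#'
#' The axis of a duplex (or of its top/bottom segment about the nick) is
#' the principal axis of its base-pair midpoint positions, oriented from
#' residue 1 toward the strand end so that segment directions are
#' comparable. The residual is the RMS perpendicular distance of the
#' midpoints from the fitted line.
#'
#' @param conformation n x 3 coordinate matrix.
#' @param topology a `bundle_topology`.
#' @param helix helix id.
#' @param segment `"whole"`, `"top"` (pairs 1..`split`) or `"bottom"`.
#' @param split pair index ending the top segment (default the nick).
#' @return list of class `hb_axis` with `helix`, `segment`, `centroid`,
#'   `direction` (unit vector), `residual` (Angstrom) and `n`.
#' @export
fit_helix_axis <- function(conformation, topology, helix,
                           segment = c("whole", "top", "bottom"),
                           split = NULL) {
  segment <- match.arg(segment)
  spec <- attr(topology, "spec")
  if (is.null(split)) split <- spec$nick_residue
  bp <- spec$bp_per_duplex
  pairs <- base_pair_table(topology, split = split)
  pairs <- pairs[pairs$helix == helix, , drop = FALSE]
  keep <- switch(segment, whole = rep(TRUE, nrow(pairs)),
                 top = pairs$pair <= split, bottom = pairs$pair > split)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L)
    .stopf("helix %s segment '%s': need >= 3 base pairs, have %d",
           helix, segment, nrow(pairs))
  mid <- (conformation[pairs$bead1, , drop = FALSE] +
            conformation[pairs$bead2, , drop = FALSE]) / 2
  ctr <- colMeans(mid)
  cen <- sweep(mid, 2L, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  if (ev$values[1L] < 1e-12)
    .stopf("degenerate segment: base-pair midpoints are coincident")
  dir <- ev$vectors[, 1L]
  proj <- drop(cen %*% dir)
  # orient residue-1 -> end
  if (stats::cov(proj, pairs$pair) < 0) dir <- -dir
  resid <- sqrt(mean(pmax(rowSums(cen^2) - drop(cen %*% dir)^2, 0)))
  structure(list(helix = helix, segment = segment, centroid = ctr,
                 direction = dir, residual = max(resid, 0), n = nrow(pairs)),
            class = "hb_axis")
}

#' Kink angle of a duplex at the nick
#'
#' Angle between the principal axes of the segment above the nick (pairs
#' 1..`split`) and the segment below it, in degrees. A straight duplex
#' gives 0; the range is \[0, 180).
#'
#' @inheritParams fit_helix_axis
#' @return kink angle, degrees.
#' @export
kink_angle <- function(conformation, topology, helix, split = NULL) {
  top <- fit_helix_axis(conformation, topology, helix, "top", split)
  bot <- fit_helix_axis(conformation, topology, helix, "bottom", split)
  d <- sum(top$direction * bot$direction)
  .rad2deg(acos(max(-1, min(1, d))))
}

#' Lumen width profile between opposing duplexes
#'
#' For each of three axial slabs (the first, second and third set of 7
#' base pairs of a 21-bp duplex) and each pair of opposing helices
#' ((1,4), (2,5), (3,6) on the hexagon), the minimum backbone bead-centre
#' distance restricted to beads in the slab is found; the reported top,
#' centre and bottom widths are the means over the three opposing pairs.
#' Distances are bead centre to centre, with no surface correction.
#'
#' @param conformation n x 3 coordinate matrix.
#' @param topology a `bundle_topology`.
#' @param pairs list of length-2 vectors of opposing helix ids.
#' @return list of class `hb_lumen` with `top`, `centre`, `bottom`
#'   (Angstrom) and `per_pair` (3 slabs x pairs matrix of minima).
#' @export
lumen_profile <- function(conformation, topology,
                          pairs = list(c(1L, 4L), c(2L, 5L), c(3L, 6L))) {
  spec <- attr(topology, "spec")
  bp <- spec$bp_per_duplex
  n_slab <- 3L
  bnd <- round(seq(0L, bp, length.out = n_slab + 1L))
  pos <- .helix_position(topology)
  bb <- topology$role == "backbone"
  per_pair <- matrix(NA_real_, n_slab, length(pairs))
  slab_names <- c("top", "centre", "bottom")
  for (s in seq_len(n_slab)) {
    in_slab <- bb & pos > bnd[s] & pos <= bnd[s + 1L]
    for (p in seq_along(pairs)) {
      ia <- which(in_slab & topology$helix == pairs[[p]][1L])
      ib <- which(in_slab & topology$helix == pairs[[p]][2L])
      if (!length(ia) || !length(ib))
        .stopf("no backbone beads in slab '%s' for helix pair (%d,%d)",
               slab_names[s], pairs[[p]][1L], pairs[[p]][2L])
      a <- conformation[ia, , drop = FALSE]
      b <- conformation[ib, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
      per_pair[s, p] <- sqrt(max(min(d2), 0))
    }
  }
  rownames(per_pair) <- slab_names
  vals <- rowMeans(per_pair)
  structure(list(top = vals[["top"]], centre = vals[["centre"]],
                 bottom = vals[["bottom"]], per_pair = per_pair),
            class = "hb_lumen")
}

#' Minimum enclosing circle of 2D points
#'
#' Exact smallest enclosing circle, found by reducing to the convex hull
#' and scanning the two- and three-point support candidates.
#'
#' @param points m x 2 matrix.
#' @return list with `centre` (length 2) and `radius`.
#' @export
min_enclosing_circle <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) == 1L) return(list(centre = p[1L, ], radius = 0))
  hull <- unique(grDevices::chull(p))
  h <- p[hull, , drop = FALSE]
  m <- nrow(h)
  tol <- 1e-9
  contains <- function(ctr, r2) {
    all((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2 <= r2 * (1 + 1e-12) +
          tol)
  }
  best_r2 <- Inf; best <- NULL
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ctr <- (h[i, ] + h[j, ]) / 2
    r2 <- sum((h[i, ] - ctr)^2)
    if (r2 < best_r2 && contains(ctr, r2)) { best_r2 <- r2; best <- ctr }
  }
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) for (j in (i + 1L):(m - 1L))
      for (k in (j + 1L):m) {
        a <- h[i, ]; b <- h[j, ]; c <- h[k, ]
        d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
                    c[1L] * (a[2L] - b[2L]))
        if (abs(d) < 1e-12) next
        ux <- (sum(a^2) * (b[2L] - c[2L]) + sum(b^2) * (c[2L] - a[2L]) +
                 sum(c^2) * (a[2L] - b[2L])) / d
        uy <- (sum(a^2) * (c[1L] - b[1L]) + sum(b^2) * (a[1L] - c[1L]) +
                 sum(c^2) * (b[1L] - a[1L])) / d
        ctr <- c(ux, uy)
        r2 <- sum((a - ctr)^2)
        if (r2 < best_r2 && contains(ctr, r2)) { best_r2 <- r2; best <- ctr }
      }
  }
  list(centre = best, radius = sqrt(best_r2))
}

#' Height and outer width of the bundle
#'
#' Height is the extent of the duplex backbone beads projected on the
#' bundle's principal axis; outer width is the diameter of the smallest
#' circle enclosing the backbone beads projected on the orthogonal
#' plane. Loop and cholesterol beads are excluded (the disordered loops
#' would otherwise dominate the extents). Values are bead centre based;
#' pass `bead_radius` to add a surface correction of one bead radius per
#' side.
#'
#' @param conformation n x 3 coordinate matrix.
#' @param topology a `bundle_topology`.
#' @param bead_radius optional bead radius added to both extremes,
#'   Angstrom.
#' @return list of class `hb_dimensions` with `height` and `width`
#'   (Angstrom).
#' @export
bundle_dimensions <- function(conformation, topology, bead_radius = 0) {
  bb <- .topo_which(topology, role = "backbone")
  if (!length(bb)) .stopf("no backbone beads in topology")
  # bundle axis = sign-aligned mean of the per-helix axis directions;
  # unlike a point-cloud PCA this stays the barrel axis however wide
  # the bundle breathes. Extents are then measured on backbone beads.
  helices <- sort(unique(topology$helix[!is.na(topology$helix)]))
  dirs <- t(vapply(helices, function(h)
    fit_helix_axis(conformation, topology, h, "whole")$direction,
    numeric(3L)))
  for (i in seq_len(nrow(dirs)))
    if (sum(dirs[i, ] * dirs[1L, ]) < 0) dirs[i, ] <- -dirs[i, ]
  axis <- colMeans(dirs)
  axis <- axis / sqrt(sum(axis^2))
  e <- diag(3L)[, which.min(abs(axis))]
  v1 <- c(axis[2L] * e[3L] - axis[3L] * e[2L],
          axis[3L] * e[1L] - axis[1L] * e[3L],
          axis[1L] * e[2L] - axis[2L] * e[1L])
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(axis[2L] * v1[3L] - axis[3L] * v1[2L],
          axis[3L] * v1[1L] - axis[1L] * v1[3L],
          axis[1L] * v1[2L] - axis[2L] * v1[1L])
  xyz <- conformation[bb, , drop = FALSE]
  cen <- sweep(xyz, 2L, colMeans(xyz))
  height <- diff(range(cen %*% axis)) + 2 * bead_radius
  plane <- cen %*% cbind(v1, v2)
  width <- 2 * min_enclosing_circle(plane)$radius + 2 * bead_radius
  structure(list(height = height, width = width),
            class = "hb_dimensions")
}

## ---- superposition and RMSD ----

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation (no reflection) of `mobile` onto
#' `target`, fitted on `selection` and applied to all rows of `mobile`.
#'
#' @param mobile,target n x 3 coordinate matrices with matching rows.
#' @param selection row indices used for the fit (default all).
#' @return transformed copy of `mobile`.
#' @export
superpose_frames <- function(mobile, target, selection = NULL) {
  fit <- .kabsch(mobile, target, selection)
  sweep(unclass(mobile) %*% fit$R, 2L, fit$shift, `+`)
}

.kabsch <- function(mobile, target, selection = NULL) {
  P <- unclass(mobile); Q <- unclass(target)
  if (is.null(selection)) selection <- seq_len(nrow(P))
  if (length(selection) < 3L) .stopf("superposition needs >= 3 beads")
  Ps <- P[selection, , drop = FALSE]; Qs <- Q[selection, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  H <- crossprod(sweep(Ps, 2L, cp), sweep(Qs, 2L, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)  # applied as x %*% R
  list(R = R, shift = cq - drop(cp %*% R))
}

#' Root-mean-squared deviation between two frames
#'
#' @param frame_a,frame_b n x 3 coordinate matrices.
#' @param selection bead indices compared (default all; both frames must
#'   give equal selection sizes).
#' @param superpose if `TRUE` (default) an optimal rigid-body alignment
#'   of the selection precedes the RMS distance.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, selection = NULL, superpose = TRUE) {
  A <- unclass(frame_a); B <- unclass(frame_b)
  if (is.null(selection)) selection <- seq_len(nrow(A))
  if (max(selection) > nrow(A) || max(selection) > nrow(B))
    .stopf("selection exceeds frame size")
  A <- A[selection, , drop = FALSE]; B <- B[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) .stopf("selection sizes differ")
  if (superpose) A <- superpose_frames(A, B)
  sqrt(mean(rowSums((A - B)^2)))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each nucleotide about its time-mean position, computed per
#' replica and then ensemble-averaged. With `align = TRUE` each frame is
#' first superposed onto the replica-mean structure (two-pass: align to
#' the first frame, form the mean, realign to it), removing global rigid
#' motion; with `align = FALSE` fluctuations include any global drift.
#' Both conventions are legitimate and can differ by large factors, so
#' the flag is recorded in the result.
#'
#' @param ensemble an `hb_ensemble` with >= 2 frames per replica.
#' @param selection bead indices analysed (default all DNA beads).
#' @param align superpose frames before measuring (default `TRUE`).
#' @param split residue position ending the "top" region (default nick).
#' @return list of class `hb_rmsf`: `per_residue` (data.frame `helix`,
#'   `strand`, `residue`, `rmsf`), `per_helix`, `per_region`, `align`.
#' @export
rmsf <- function(ensemble, selection = NULL, align = TRUE, split = NULL) {
  stopifnot(inherits(ensemble, "hb_ensemble"))
  topo <- ensemble$topology
  spec <- attr(topo, "spec")
  if (is.null(split)) split <- spec$nick_residue
  if (is.null(selection))
    selection <- .topo_which(topo, role = c("backbone", "base", "loop"))
  per_rep <- list()
  for (r in seq_along(ensemble$replicas)) {
    co <- ensemble$replicas[[r]]$coords
    nf <- dim(co)[3L]
    if (nf < 2L) .stopf("replica %d has < 2 frames", r)
    sub <- co[selection, , , drop = FALSE]
    if (align) {
      for (f in seq_len(nf))
        sub[, , f] <- superpose_frames(sub[, , f], sub[, , 1L])
      mean1 <- apply(sub, c(1L, 2L), mean)
      for (f in seq_len(nf))
        sub[, , f] <- superpose_frames(sub[, , f], mean1)
    }
    mu <- apply(sub, c(1L, 2L), mean)
    dev2 <- 0
    for (f in seq_len(nf)) dev2 <- dev2 + rowSums((sub[, , f] - mu)^2)
    per_rep[[r]] <- sqrt(dev2 / nf)
  }
  bead_rmsf <- rowMeans(do.call(cbind, per_rep))
  key <- data.frame(helix = topo$helix[selection],
                    strand = topo$strand[selection],
                    residue = topo$residue[selection])
  agg <- stats::aggregate(bead_rmsf,
                          by = list(helix = key$helix, strand = key$strand,
                                    residue = key$residue), FUN = mean)
  names(agg)[4L] <- "rmsf"
  agg <- agg[order(agg$helix, agg$strand, agg$residue), ]
  rownames(agg) <- NULL
  per_helix <- stats::aggregate(agg$rmsf, by = list(helix = agg$helix),
                                FUN = mean)
  names(per_helix)[2L] <- "rmsf"
  pos <- .helix_position(topo)[selection]
  region <- ifelse(pos <= split, "top", "bottom")
  per_region <- stats::aggregate(bead_rmsf, by = list(region = region),
                                 FUN = mean)
  names(per_region)[2L] <- "rmsf"
  structure(list(per_residue = agg, per_helix = per_helix,
                 per_region = per_region, align = align),
            class = "hb_rmsf")
}

#' Base-pair breakage statistics
#'
#' A designed base pair is broken in a frame iff the distance between its
#' two base bead centres exceeds `cutoff`. Fractions are averaged over
#' frames and pairs, reported overall and grouped per helix and per
#' region about the nick; the overall value is the pair-count-weighted
#' mean of the groups by construction.
#'
#' @param x an `hb_ensemble` or a single n x 3 conformation (then
#'   `topology` is required).
#' @param topology a `bundle_topology` (taken from the ensemble when
#'   omitted).
#' @param cutoff breakage cutoff between base bead centres, Angstrom.
#'   The default of 8 sits well above the paired-bead distance and below
#'   typical frayed separations.
#' @param split pair index ending the "top" region (default nick).
#' @return list of class `hb_bpb` with `overall`, `per_helix`,
#'   `per_region` (fractions in \[0,1\]), `n_frames`, `cutoff`.
#' @export
broken_base_pairs <- function(x, topology = NULL, cutoff = 8,
                              split = NULL) {
  if (inherits(x, "hb_ensemble")) {
    topology <- x$topology
    frames <- .flatten_frames(x)$frames
  } else {
    if (is.null(topology)) .stopf("topology required for a bare frame")
    frames <- list(unclass(x))
  }
  if (cutoff <= 0) .stopf("cutoff must be > 0")
  pairs <- base_pair_table(topology, split = split)
  if (!nrow(pairs)) .stopf("topology defines no base pairs")
  broken <- matrix(NA, nrow(pairs), length(frames))
  for (f in seq_along(frames)) {
    d <- sqrt(rowSums((frames[[f]][pairs$bead1, , drop = FALSE] -
                         frames[[f]][pairs$bead2, , drop = FALSE])^2))
    broken[, f] <- d > cutoff
  }
  frac_pair <- rowMeans(broken)
  per_helix <- tapply(frac_pair, pairs$helix, mean)
  per_region <- tapply(frac_pair, pairs$region, mean)
  structure(list(overall = mean(frac_pair),
                 per_helix = per_helix,
                 per_region = per_region[c("top", "bottom")],
                 n_frames = length(frames), cutoff = cutoff),
            class = "hb_bpb")
}

#' @export
print.hb_bpb <- function(x, ...) {
  cat(sprintf("base-pair breakage over %d frame(s), cutoff %.1f A\n",
              x$n_frames, x$cutoff))
  cat(sprintf("  overall: %.1f%%\n", 100 * x$overall))
  cat(sprintf("  region top: %.1f%%  bottom: %.1f%%\n",
              100 * x$per_region[["top"]], 100 * x$per_region[["bottom"]]))
  cat("  per helix:",
      paste(sprintf("%s=%.1f%%", names(x$per_helix), 100 * x$per_helix),
            collapse = " "), "\n")
  invisible(x)
}

#' Conformational clustering by the greedy neighbour-count rule
#'
#' GROMOS-style clustering on the matrix of pairwise superposed RMSDs:
#' repeatedly take the unassigned frame with the most unassigned
#' neighbours within `rmsd_cutoff` (ties broken by lowest frame index),
#' make it and its neighbours a cluster, remove them, and iterate.
#' Deterministic for a given ensemble.
#'
#' @param ensemble an `hb_ensemble`, or a list of n x 3 frames.
#' @param rmsd_cutoff neighbour cutoff, Angstrom (required).
#' @param selection bead indices used in the RMSD (default all).
#' @return list of class `hb_clusters`: `assignment` (integer per
#'   frame, clusters numbered in discovery order), `centers` (frame
#'   index of each cluster centre), `n_clusters`, `rmsd_cutoff`.
#' @export
cluster_conformations <- function(ensemble, rmsd_cutoff,
                                  selection = NULL) {
  frames <- if (inherits(ensemble, "hb_ensemble"))
    .flatten_frames(ensemble)$frames else ensemble
  m <- length(frames)
  if (m < 1L) .stopf("need at least one frame")
  D <- matrix(0, m, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      D[i, j] <- D[j, i] <- rmsd(frames[[i]], frames[[j]],
                                 selection = selection, superpose = TRUE)
  }
  adj <- D <= rmsd_cutoff
  assignment <- rep(NA_integer_, m)
  centers <- integer(0L)
  cl <- 0L
  active <- rep(TRUE, m)
  while (any(active)) {
    counts <- rowSums(adj[, active, drop = FALSE])
    counts[!active] <- -1L
    ctr <- which.max(counts)   # ties -> lowest index
    members <- which(active & adj[ctr, ])
    cl <- cl + 1L
    assignment[members] <- cl
    centers <- c(centers, ctr)
    active[members] <- FALSE
  }
  structure(list(assignment = assignment, centers = centers,
                 n_clusters = cl, rmsd_cutoff = rmsd_cutoff),
            class = "hb_clusters")
}

#' @export
print.hb_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) at RMSD cutoff %.2f A; sizes: %s\n",
              x$n_clusters, x$rmsd_cutoff,
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}
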
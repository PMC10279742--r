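## Ideal bundle construction: six parallel duplexes on a regular hexagon.

#' Build an idealised six-helix bundle conformation
#'
#' Places the bead model of the designed bundle: helix axes on a regular
#' hexagon of circumradius `axis_spacing_s` (so adjacent axes sit exactly
#' one spacing apart and opposing axes 2 spacings apart), backbone beads
#' on helical paths of radius 9.4 Angstrom about each axis with the given
#' rise and twist, base beads offset toward the duplex axis, poly-T loop
#' beads bridging neighbouring duplexes beyond the duplex ends, and one
#' cholesterol bead per anchored helix at the nick. Residue 1 of strand 1
#' sits at the top of the helix (largest z); the paired duplex spans
#' `(bp - 1) * rise` Angstrom in z.
#'
#' The construction is deterministic: no random numbers are used.
#'
#' @param spec a [strand_map_spec()].
#' @param geom a [distortion_params()]; only the geometric fields
#'   (`axis_spacing_s`, `rise`, `twist`) are used here.
#' @return list with elements `topology` (a `bundle_topology`) and
#'   `conformation` (an n x 3 coordinate matrix in Angstrom, carrying
#'   `box` and `bundle_info` attributes).
#' @export
build_ideal_bundle <- function(spec = strand_map_spec(),
                               geom = distortion_params()) {
  stopifnot(inherits(spec, "strand_map_spec"),
            inherits(geom, "distortion_params"))
  s <- geom$axis_spacing_s
  if (s < 2 * .BB_RADIUS)
    .stopf(paste0("steric overlap: axis spacing %.1f A is smaller than ",
                  "twice the backbone path radius (%.1f A)"),
           s, 2 * .BB_RADIUS)
  topo <- build_topology(spec)
  bp <- spec$bp_per_duplex
  nh <- spec$n_helices
  # helix axes on the hexagon (circumradius = side length = spacing)
  ang <- 2 * pi * (seq_len(nh) - 1L) / nh
  axis_xy <- cbind(s * cos(ang), s * sin(ang))
  zmax <- (bp - 1L) * geom$rise

  xyz <- matrix(NA_real_, nrow(topo), 3L)
  for (h in seq_len(nh)) {
    ax <- axis_xy[h, ]
    for (st in 1:2) {
      idx <- .topo_which(topo, role = c("backbone", "base"),
                         helix = h, strand = st)
      res <- topo$residue[idx]
      pair <- if (st == 1L) res else bp + 1L - res  # position along helix
      z <- (bp - pair) * geom$rise
      # backbone beads follow the strand's helical path; base beads sit
      # antipodally about the duplex axis (bases meet at the centre), so
      # base-pair midpoints lie exactly on the axis
      theta_bb <- .deg2rad((pair - 1L) * geom$twist +
                             (st - 1L) * .STRAND2_PHASE)
      theta_base <- .deg2rad((pair - 1L) * geom$twist +
                               .STRAND2_PHASE / 2 + (st - 1L) * 180)
      is_bb <- topo$role[idx] == "backbone"
      r <- ifelse(is_bb, .BB_RADIUS, .BASE_RADIUS)
      theta <- ifelse(is_bb, theta_bb, theta_base)
      xyz[idx, ] <- cbind(ax[1L] + r * cos(theta),
                          ax[2L] + r * sin(theta), z)
    }
    # loops: strand 1 continues below the bottom toward the previous
    # helix, strand 2 above the top toward the next helix
    for (st in 1:2) {
      idx <- .topo_which(topo, role = "loop", helix = h, strand = st)
      if (!length(idx)) next
      nb <- if (st == 1L) ((h - 2L) %% nh) + 1L else (h %% nh) + 1L
      tfrac <- (topo$residue[idx] - bp) / (spec$loop_len + 1)
      zl <- if (st == 1L) -4 - 4 * sin(pi * tfrac) else
        zmax + 4 + 4 * sin(pi * tfrac)
      xyz[idx, ] <- cbind(ax[1L] + tfrac * (axis_xy[nb, 1L] - ax[1L]),
                          ax[2L] + tfrac * (axis_xy[nb, 2L] - ax[2L]), zl)
    }
  }
  # cholesterol anchors: radially outward at the nick height
  chol <- .topo_which(topo, role = "cholesterol")
  if (length(chol)) {
    for (b in chol) {
      h <- topo$helix[b]
      u <- axis_xy[h, ] / sqrt(sum(axis_xy[h, ]^2))
      zc <- (bp - spec$nick_residue) * geom$rise
      xyz[b, ] <- c(axis_xy[h, ] + u * (.BB_RADIUS + 6), zc)
    }
  }

  info <- list(axis_xy = axis_xy, centre = c(0, 0), circumradius = s,
               hinge_z = (bp - spec$nick_residue - 0.5) * geom$rise,
               rise = geom$rise, bp = bp, nick = spec$nick_residue)
  ext <- apply(xyz, 2L, function(v) diff(range(v)))
  attr(xyz, "box") <- c(ext[1L] + 60, ext[2L] + 60, ext[3L] + 60)
  attr(xyz, "bundle_info") <- info
  list(topology = topo, conformation = xyz)
}
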
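## Ensemble container and the kinematic ensemble generator.

#' Construct an ensemble of replica trajectories
#'
#' The universal analysis input: a shared bead topology plus one or more
#' replicas, each an ordered series of frames of bead coordinates.
#'
#' @param topology a `bundle_topology` (or extended topology).
#' @param replicas list of replicas; each a list with `times` (ns,
#'   strictly increasing) and `coords` (array `n_beads x 3 x n_frames`).
#' @param box box edge lengths, Angstrom.
#' @return object of class `hb_ensemble`.
#' @export
hb_ensemble <- function(topology, replicas, box = NULL) {
  nb <- nrow(topology)
  for (r in seq_along(replicas)) {
    rep <- replicas[[r]]
    d <- dim(rep$coords)
    if (length(d) != 3L || d[1L] != nb || d[2L] != 3L)
      .stopf("replica %d: coords must be an %d x 3 x n_frames array", r, nb)
    if (length(rep$times) != d[3L])
      .stopf("replica %d: %d times for %d frames", r, length(rep$times),
             d[3L])
    if (d[3L] > 1L && any(diff(rep$times) <= 0))
      .stopf("replica %d: times must be strictly increasing", r)
  }
  structure(list(topology = topology, replicas = replicas, box = box),
            class = "hb_ensemble")
}

#' @export
print.hb_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r$coords)[3L], integer(1L))
  cat(sprintf("hb_ensemble: %d replica(s), %s frame(s), %d beads\n",
              length(x$replicas),
              paste(unique(nf), collapse = "/"), nrow(x$topology)))
  invisible(x)
}

#' Extract one frame of an ensemble
#'
#' @param ensemble an `hb_ensemble`.
#' @param replica replica index.
#' @param frame frame index within the replica.
#' @return n x 3 coordinate matrix (Angstrom) with the ensemble box
#'   attached as attribute `box`.
#' @export
get_frame <- function(ensemble, replica = 1L, frame = 1L) {
  stopifnot(inherits(ensemble, "hb_ensemble"))
  xyz <- ensemble$replicas[[replica]]$coords[, , frame]
  attr(xyz, "box") <- ensemble$box
  xyz
}

#' Total number of frames across replicas
#' @param ensemble an `hb_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ensemble) {
  sum(vapply(ensemble$replicas, function(r) dim(r$coords)[3L], integer(1L)))
}

# flatten frames to a list of matrices plus a (replica, frame) index table
.flatten_frames <- function(ensemble) {
  frames <- list(); idx <- list(); k <- 0L
  for (r in seq_along(ensemble$replicas)) {
    co <- ensemble$replicas[[r]]$coords
    for (f in seq_len(dim(co)[3L])) {
      k <- k + 1L
      frames[[k]] <- co[, , f]
      idx[[k]] <- c(r, f)
    }
  }
  list(frames = frames,
       index = do.call(rbind, idx))
}

# bundle_info fallback when a conformation lacks the attribute
.bundle_info <- function(conformation, topology, rise = 3.4) {
  info <- attr(conformation, "bundle_info")
  if (!is.null(info)) return(info)
  spec <- attr(topology, "spec")
  hel <- sort(unique(topology$helix[!is.na(topology$helix)]))
  axis_xy <- t(vapply(hel, function(h) {
    idx <- .topo_which(topology, role = "backbone", helix = h)
    colMeans(conformation[idx, 1:2, drop = FALSE])
  }, numeric(2L)))
  centre <- colMeans(axis_xy)
  list(axis_xy = axis_xy, centre = centre,
       circumradius = mean(sqrt(rowSums(sweep(axis_xy, 2L, centre)^2))),
       hinge_z = (spec$bp_per_duplex - spec$nick_residue - 0.5) * rise,
       rise = rise, bp = spec$bp_per_duplex, nick = spec$nick_residue)
}

#' Generate a synthetic conformational ensemble
#'
#' Kinematic motion model standing in for molecular dynamics: each frame
#' applies, in order, (1) the per-helix kink - a rigid rotation of the
#' helix segment below the nick hinge about a hinge axis perpendicular to
#' the helix axis; (2) radial breathing - a sinusoidal scaling of the
#' hexagon circumradius of stated amplitude and period; (3) fraying -
#' Bernoulli(`fray_prob`) displacement of targeted base beads beyond the
#' breakage cutoff; (4) a global rigid tilt and time-linear twist; and
#' (5) isotropic Gaussian noise. Every imposed parameter is recoverable
#' by the corresponding analysis operation.
#'
#' All randomness derives from `params$seed` via per-replica streams, so
#' a replica's trajectory does not depend on how many replicas are
#' requested and identical inputs give bit-identical coordinates.
#'
#' @param topology a `bundle_topology`.
#' @param base base conformation (from [build_ideal_bundle()]).
#' @param params a [distortion_params()].
#' @param n_replicas number of replicas.
#' @param n_frames frames per replica.
#' @param dt_ns time step between frames, ns.
#' @return an [hb_ensemble()].
#' @export
generate_ensemble <- function(topology, base, params = distortion_params(),
                              n_replicas = 1L, n_frames = 100L, dt_ns = 1) {
  stopifnot(inherits(params, "distortion_params"), n_replicas >= 1L,
            n_frames >= 1L, dt_ns > 0)
  info <- .bundle_info(base, topology, params$rise)
  spec <- attr(topology, "spec")
  nb <- nrow(topology)
  helices <- sort(unique(topology$helix[!is.na(topology$helix)]))
  kink <- rep_len(params$kink_per_helix, length(helices))

  # kink is constant over time: apply once to the base conformation
  kinked <- unclass(base)
  for (i in seq_along(helices)) {
    if (kink[i] <= 0) next
    h <- helices[i]
    hidx <- which(!is.na(topology$helix) & topology$helix == h &
                    topology$role != "lipid")
    seg <- hidx[base[hidx, 3L] < info$hinge_z]  # below-nick segment
    u <- info$axis_xy[i, ] - info$centre
    u <- u / sqrt(sum(u^2))
    hinge_axis <- c(-u[2L], u[1L], 0)           # tangential, perp. to z
    R <- .rotation_matrix(hinge_axis, kink[i])
    hinge_pt <- c(info$axis_xy[i, ], info$hinge_z)
    kinked[seg, ] <- .rotate_about(kinked[seg, , drop = FALSE], hinge_pt, R)
  }

  # per-helix bead lists for breathing displacements
  helix_beads <- lapply(helices, function(h)
    which(!is.na(topology$helix) & topology$helix == h))
  axis_off <- sweep(info$axis_xy, 2L, info$centre)

  # fray targets
  pairs <- base_pair_table(topology)
  fray_res <- if (is.null(params$fray_residues))
    c(1L, spec$bp_per_duplex) else params$fray_residues
  fpairs <- pairs[pairs$pair %in% fray_res, , drop = FALSE]

  centre3 <- c(info$centre, mean(range(base[, 3L])))
  s0 <- info$circumradius

  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    set.seed(.replica_seed(params$seed, r))
    coords <- array(NA_real_, c(nb, 3L, n_frames))
    times <- seq_len(n_frames) * dt_ns
    for (f in seq_len(n_frames)) {
      t_ns <- times[f]
      xyz <- kinked
      if (params$breathing_amplitude > 0) {
        k_t <- (s0 + params$breathing_amplitude *
                  sin(2 * pi * t_ns / params$breathing_period)) / s0
        for (i in seq_along(helices)) {
          d <- (k_t - 1) * axis_off[i, ]
          xyz[helix_beads[[i]], 1L] <- xyz[helix_beads[[i]], 1L] + d[1L]
          xyz[helix_beads[[i]], 2L] <- xyz[helix_beads[[i]], 2L] + d[2L]
        }
      }
      if (params$fray_prob > 0 && nrow(fpairs)) {
        broken <- stats::runif(nrow(fpairs)) < params$fray_prob
        for (j in which(broken)) {
          b1 <- fpairs$bead1[j]; b2 <- fpairs$bead2[j]
          v <- xyz[b1, ] - xyz[b2, ]
          v <- v / sqrt(sum(v^2))
          xyz[b1, ] <- xyz[b1, ] + v * params$fray_displacement
        }
      }
      if (params$tilt_deg != 0 || params$twist_rate != 0) {
        R <- .rotation_matrix(c(0, 0, 1), params$twist_rate * t_ns) %*%
          .rotation_matrix(c(1, 0, 0), params$tilt_deg)
        xyz <- .rotate_about(xyz, centre3, R)
      }
      if (params$noise_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(nb * 3L, 0, params$noise_sigma),
                            nb, 3L)
      coords[, , f] <- xyz
    }
    replicas[[r]] <- list(times = times, coords = coords)
  }
  hb_ensemble(topology, replicas, box = attr(base, "box"))
}

#' Embed a bundle in a membrane-mode system
#'
#' Emulates the effect of lateral membrane pressure geometrically: the
#' helix axes are radially rescaled toward the bundle centre until the
#' axis spacing equals `compressed_spacing`, and lipid beads fill a slab
#' of the stated bilayer thickness around the bundle midsection, leaving
#' a cylindrical cavity of radius `toroid_inner_radius` that stands in
#' for the lipid toroid enclosing the pore.
#'
#' @param topology a `bundle_topology`.
#' @param conformation bundle coordinates (n x 3 matrix).
#' @param mparams a [membrane_params()].
#' @param seed RNG seed for lipid placement.
#' @return list with `topology` (lipid beads appended, role `"lipid"`)
#'   and `conformation`.
#' @export
generate_membrane_system <- function(topology, conformation,
                                     mparams = membrane_params(),
                                     seed = 1L) {
  stopifnot(inherits(mparams, "membrane_params"))
  info <- .bundle_info(conformation, topology)
  s0 <- info$circumradius
  if (mparams$compressed_spacing > s0 + 1e-9)
    .stopf("compressed_spacing (%.1f) exceeds current axis spacing (%.1f)",
           mparams$compressed_spacing, s0)
  k <- mparams$compressed_spacing / s0
  xyz <- unclass(conformation)
  helices <- sort(unique(topology$helix[!is.na(topology$helix)]))
  for (i in seq_along(helices)) {
    idx <- which(!is.na(topology$helix) & topology$helix == helices[i])
    d <- (k - 1) * (info$axis_xy[i, ] - info$centre)
    xyz[idx, 1L] <- xyz[idx, 1L] + d[1L]
    xyz[idx, 2L] <- xyz[idx, 2L] + d[2L]
  }
  bb <- .topo_which(topology, role = "backbone")
  rad <- sqrt(rowSums(sweep(xyz[bb, 1:2, drop = FALSE], 2L,
                            info$centre)^2))
  if (mparams$toroid_inner_radius < max(rad))
    .stopf("overlap: toroid inner radius %.1f A is inside the bundle (%.1f A)",
           mparams$toroid_inner_radius, max(rad))

  box <- attr(conformation, "box")
  if (is.null(box)) box <- c(160, 160, 180)
  z_mid <- mean(range(xyz[bb, 3L]))
  th <- mparams$bilayer_thickness
  r_in <- mparams$toroid_inner_radius
  slab_vol_nm3 <- (box[1L] * box[2L] - pi * r_in^2) * th / 1000
  n_lip <- round(mparams$lipid_bead_density * slab_vol_nm3)

  set.seed(as.integer(seed))
  lip <- matrix(NA_real_, n_lip, 3L)
  filled <- 0L
  while (filled < n_lip) {
    m <- (n_lip - filled) * 2L + 16L
    cand <- cbind(stats::runif(m, -box[1L] / 2, box[1L] / 2) + info$centre[1L],
                  stats::runif(m, -box[2L] / 2, box[2L] / 2) + info$centre[2L],
                  stats::runif(m, z_mid - th / 2, z_mid + th / 2))
    ok <- sqrt((cand[, 1L] - info$centre[1L])^2 +
                 (cand[, 2L] - info$centre[2L])^2) >= r_in
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n_lip - filled)
    if (take > 0L) {
      lip[(filled + 1L):(filled + take), ] <- cand[seq_len(take), ]
      filled <- filled + take
    }
  }

  topo2 <- rbind(as.data.frame(topology),
                 data.frame(bead = nrow(topology) + seq_len(n_lip),
                            helix = NA_integer_, strand = NA_integer_,
                            residue = NA_integer_, role = "lipid",
                            partner = NA_integer_))
  attr(topo2, "spec") <- attr(topology, "spec")
  class(topo2) <- c("bundle_topology", "data.frame")
  out <- rbind(xyz, lip)
  attr(out, "box") <- box
  attr(out, "bundle_info") <- NULL
  list(topology = topo2, conformation = out)
}
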
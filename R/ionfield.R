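## Synthetic ion/water bead fields with a controlled lumen enhancement.

#' Cylindrical analysis region
#'
#' @param centre `c(x, y)` of the cylinder axis, Angstrom.
#' @param radius cylinder radius, Angstrom.
#' @param zmin,zmax axial extent, Angstrom.
#' @return object of class `hb_region`.
#' @export
cylinder_region <- function(centre = c(0, 0), radius, zmin, zmax) {
  if (radius <= 0 || zmax <= zmin) .stopf("degenerate cylinder region")
  structure(list(type = "cylinder", centre = centre, radius = radius,
                 zmin = zmin, zmax = zmax), class = "hb_region")
}

#' Annular (hollow cylinder) analysis region
#'
#' Typical bulk reference region: everything between an inner and an
#' outer radius over an axial window.
#'
#' @param centre `c(x, y)` of the axis, Angstrom.
#' @param r_inner,r_outer inner and outer radii, Angstrom.
#' @param zmin,zmax axial extent, Angstrom.
#' @return object of class `hb_region`.
#' @export
annulus_region <- function(centre = c(0, 0), r_inner, r_outer, zmin, zmax) {
  if (r_inner < 0 || r_outer <= r_inner || zmax <= zmin)
    .stopf("degenerate annulus region")
  structure(list(type = "annulus", centre = centre, r_inner = r_inner,
                 r_outer = r_outer, zmin = zmin, zmax = zmax),
            class = "hb_region")
}

.region_volume_nm3 <- function(region) {
  h <- region$zmax - region$zmin
  a <- switch(region$type,
              cylinder = pi * region$radius^2,
              annulus = pi * (region$r_outer^2 - region$r_inner^2))
  a * h / 1000  # A^3 -> nm^3
}

.region_contains <- function(region, xyz) {
  r <- sqrt((xyz[, 1L] - region$centre[1L])^2 +
              (xyz[, 2L] - region$centre[2L])^2)
  inz <- xyz[, 3L] >= region$zmin & xyz[, 3L] < region$zmax
  switch(region$type,
         cylinder = inz & r < region$radius,
         annulus = inz & r >= region$r_inner & r < region$r_outer)
}

.regions_disjoint <- function(a, b) {
  if (a$zmax <= b$zmin || b$zmax <= a$zmin) return(TRUE)
  if (a$type == "cylinder" && b$type == "annulus")
    return(a$radius <= b$r_inner &&
             all(abs(a$centre - b$centre) < 1e-9))
  if (a$type == "annulus" && b$type == "cylinder")
    return(.regions_disjoint(b, a))
  FALSE
}

#' Default lumen cylinder for the bundle pore
#'
#' The water-filled interior channel, operationalised as a cylinder on
#' the box axis. The designed pore lumen is ~18 Angstrom wide, hence a
#' default radius of 9 Angstrom; the axial window spans the membrane
#' region of the default box.
#'
#' @param box box edge lengths, Angstrom.
#' @param radius cylinder radius, Angstrom.
#' @return an [cylinder_region()] centred in the box.
#' @export
default_lumen_cylinder <- function(box = c(160, 160, 180), radius = 9) {
  cylinder_region(centre = c(0, 0), radius = radius,
                  zmin = box[3L] / 2 - 50, zmax = box[3L] / 2 + 50)
}

#' Generate a synthetic ion/water bead field
#'
#' Places beads uniformly in the box at the bulk number density implied
#' by the NaCl concentration (and the water bead density), then adds
#' Poisson-distributed extra beads uniformly inside the lumen cylinder to
#' realise the configured per-species enhancement. Per-frame counts are
#' Poisson, so densities are recovered with Poisson sampling error.
#' Coordinates are box-centred in x/y (origin on the box axis) and span
#' `[0, Lz)` in z.
#'
#' @param iparams an [ion_field_params()].
#' @param n_frames number of independent frames.
#' @param lumen_cylinder an [cylinder_region()]; default from
#'   [default_lumen_cylinder()] for the configured box.
#' @param species species to generate, subset of `c("Na","Cl","water")`.
#' @return object of class `hb_ionfield`: list of frames, each with
#'   `species` (factor) and `xyz`; plus `box`, `bulk` densities and the
#'   generating parameters.
#' @export
generate_ion_field <- function(iparams = ion_field_params(),
                               n_frames = 100L, lumen_cylinder = NULL,
                               species = c("Na", "Cl", "water")) {
  stopifnot(inherits(iparams, "ion_field_params"))
  species <- match.arg(species, several.ok = TRUE)
  box <- iparams$box
  if (is.null(lumen_cylinder)) lumen_cylinder <- default_lumen_cylinder(box)
  vol_nm3 <- prod(box) / 1000
  cyl_nm3 <- .region_volume_nm3(lumen_cylinder)
  bulk <- .bulk_densities(iparams$concentration, iparams$water_density)
  set.seed(iparams$seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sp <- list(); pts <- list()
    for (s in species) {
      n_bulk <- stats::rpois(1L, bulk[[s]] * vol_nm3)
      p <- cbind(stats::runif(n_bulk, -box[1L] / 2, box[1L] / 2),
                 stats::runif(n_bulk, -box[2L] / 2, box[2L] / 2),
                 stats::runif(n_bulk, 0, box[3L]))
      enh <- iparams$lumen_enhancement[[s]]
      if (enh > 0) {
        n_extra <- stats::rpois(1L, enh * cyl_nm3)
        if (n_extra > 0L) {
          rr <- lumen_cylinder$radius * sqrt(stats::runif(n_extra))
          th <- stats::runif(n_extra, 0, 2 * pi)
          pe <- cbind(lumen_cylinder$centre[1L] + rr * cos(th),
                      lumen_cylinder$centre[2L] + rr * sin(th),
                      stats::runif(n_extra, lumen_cylinder$zmin,
                                   lumen_cylinder$zmax))
          p <- rbind(p, pe)
        }
      }
      sp[[s]] <- rep(s, nrow(p)); pts[[s]] <- p
    }
    frames[[f]] <- list(species = factor(unlist(sp, use.names = FALSE),
                                         levels = c("Na", "Cl", "water")),
                        xyz = do.call(rbind, pts))
  }
  structure(list(frames = frames, box = box, bulk = bulk,
                 lumen_cylinder = lumen_cylinder, params = iparams),
            class = "hb_ionfield")
}

#' @export
print.hb_ionfield <- function(x, ...) {
  n <- vapply(x$frames, function(f) length(f$species), integer(1L))
  cat(sprintf("hb_ionfield: %d frame(s), %.0f beads/frame (mean), box %s A\n",
              length(x$frames), mean(n),
              paste(round(x$box), collapse = " x ")))
  invisible(x)
}
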
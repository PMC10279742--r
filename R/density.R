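## Number-density profiles along the membrane normal and region-resolved
## density differences.

#' Number-density profile along the box z axis
#'
#' Counts of one species per z bin, averaged over the frames in the time
#' window and divided by the bin slab volume, in nm^-3. The z axis is
#' the fixed box axis (the membrane normal), not the instantaneous
#' bundle axis. By construction the binned densities conserve the mean
#' particle count: sum(density * bin volume) equals the mean count per
#' frame exactly.
#'
#' @param field an `hb_ionfield` (or a list with `frames` and `box` in
#'   the same layout).
#' @param species one of `"Na"`, `"Cl"`, `"water"`.
#' @param bin bin width, Angstrom.
#' @param time_window `c(first, last)` frame indices to use (default
#'   all). The study convention of analysing only an initial portion of
#'   each trajectory maps to a prefix window here.
#' @return data.frame of class `hb_density_profile` with columns `z`
#'   (bin centre, Angstrom) and `density` (nm^-3); attributes `species`,
#'   `n_frames`, `bin`.
#' @export
number_density_z <- function(field, species, bin = 1,
                             time_window = NULL) {
  if (bin <= 0) .stopf("bin width must be > 0")
  box <- field$box
  frames <- field$frames
  if (!is.null(time_window))
    frames <- frames[seq(max(1L, time_window[1L]),
                         min(length(frames), time_window[2L]))]
  if (!length(frames)) .stopf("no frames in window")
  present <- unique(unlist(lapply(frames, function(f)
    levels(droplevels(f$species)))))
  if (!species %in% present)
    .stopf("species '%s' absent from the field", species)
  breaks <- seq(0, box[3L], by = bin)
  if (breaks[length(breaks)] < box[3L])
    breaks <- c(breaks, box[3L])
  counts <- numeric(length(breaks) - 1L)
  for (f in frames) {
    z <- f$xyz[f$species == species, 3L]
    z <- z %% box[3L]  # periodic wrap
    counts <- counts + tabulate(findInterval(z, breaks,
                                             rightmost.closed = TRUE),
                                nbins = length(breaks) - 1L)
  }
  counts <- counts / length(frames)
  widths <- diff(breaks)
  vol_nm3 <- box[1L] * box[2L] * widths / 1000
  out <- data.frame(z = (breaks[-length(breaks)] + breaks[-1L]) / 2,
                    density = counts / vol_nm3)
  attr(out, "species") <- species
  attr(out, "n_frames") <- length(frames)
  attr(out, "bin") <- bin
  class(out) <- c("hb_density_profile", "data.frame")
  out
}

#' Region-resolved number-density difference
#'
#' Mean number density of a species inside an analysis region (e.g. the
#' pore lumen / membrane-torus cylinder) minus the mean density in a
#' disjoint bulk reference region, in nm^-3, averaged over frames.
#'
#' @param field an `hb_ionfield`.
#' @param species species name.
#' @param region an [cylinder_region()] (the lumen/torus region).
#' @param bulk_region a disjoint reference region, e.g.
#'   [annulus_region()].
#' @param time_window `c(first, last)` frame indices (default all).
#' @return list of class `hb_density_diff`: `difference` (nm^-3),
#'   `region_density`, `bulk_density`, `n_frames`.
#' @export
region_density_difference <- function(field, species, region, bulk_region,
                                      time_window = NULL) {
  stopifnot(inherits(region, "hb_region"),
            inherits(bulk_region, "hb_region"))
  v_r <- .region_volume_nm3(region)
  v_b <- .region_volume_nm3(bulk_region)
  if (v_r <= 0 || v_b <= 0) .stopf("zero-volume region")
  if (!.regions_disjoint(region, bulk_region))
    .stopf("region and bulk_region must be disjoint")
  frames <- field$frames
  if (!is.null(time_window))
    frames <- frames[seq(max(1L, time_window[1L]),
                         min(length(frames), time_window[2L]))]
  if (!length(frames)) .stopf("no frames in window")
  cr <- cb <- 0
  for (f in frames) {
    xyz <- f$xyz[f$species == species, , drop = FALSE]
    cr <- cr + sum(.region_contains(region, xyz))
    cb <- cb + sum(.region_contains(bulk_region, xyz))
  }
  rho_r <- cr / length(frames) / v_r
  rho_b <- cb / length(frames) / v_b
  structure(list(difference = rho_r - rho_b, region_density = rho_r,
                 bulk_density = rho_b, n_frames = length(frames)),
            class = "hb_density_diff")
}

#' @export
print.hb_density_diff <- function(x, ...) {
  cat(sprintf(
    "density difference %+.3f nm^-3 (region %.3f, bulk %.3f; %d frames)\n",
    x$difference, x$region_density, x$bulk_density, x$n_frames))
  invisible(x)
}

#' Plot a number-density profile
#'
#' @param x an `hb_density_profile`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.hb_density_profile <- function(x, ...) {
  graphics::plot(x$z, x$density, type = "l",
                 xlab = "z (Angstrom)",
                 ylab = expression(density ~ (nm^-3)),
                 main = attr(x, "species"), ...)
  invisible(x)
}
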
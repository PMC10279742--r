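## Coarse-graining utilities: Boltzmann inversion of bonded-term
## histograms and radius-of-gyration comparison between representations.

#' Boltzmann inversion of a bond/angle histogram
#'
#' Converts a sampled distribution of a bonded coordinate (bond length,
#' angle, dihedral) into an effective potential, the standard route from
#' reference simulations to coarse-grained bonded terms:
#' `U(x) = -kB * T * ln P(x)`, shifted so the minimum is zero. Bins with
#' zero counts have an undefined (infinite free-energy) potential and are
#' returned as `NA`.
#'
#' @param histogram either an object from [hist()] or a data.frame with
#'   columns `x` (bin centres) and `count` (nonnegative).
#' @param temperature temperature, K.
#' @return data.frame with columns `x`, `P` (normalised probability per
#'   bin) and `U` (kcal/mol, min 0, `NA` where `P = 0`).
#' @export
boltzmann_invert <- function(histogram, temperature = 300) {
  if (inherits(histogram, "histogram"))
    histogram <- data.frame(x = histogram$mids, count = histogram$counts)
  stopifnot(is.data.frame(histogram),
            all(c("x", "count") %in% names(histogram)))
  cnt <- histogram$count
  if (any(cnt < 0)) .stopf("histogram counts must be nonnegative")
  tot <- sum(cnt)
  if (tot <= 0) .stopf("empty histogram: nothing to invert")
  if (temperature <= 0) .stopf("temperature must be > 0")
  P <- cnt / tot
  U <- ifelse(P > 0, -.KB_KCAL * temperature * log(P), NA_real_)
  U <- U - min(U, na.rm = TRUE)
  data.frame(x = histogram$x, P = P, U = U)
}

#' Mass-weighted radius of gyration
#'
#' @param conformation n x 3 coordinate matrix, Angstrom.
#' @param selection bead indices (default all rows).
#' @param masses per-bead masses for the selection (default uniform).
#' @return radius of gyration about the mass-weighted centroid, Angstrom.
#'   A single bead gives 0.
#' @export
radius_of_gyration <- function(conformation, selection = NULL,
                               masses = NULL) {
  xyz <- unclass(conformation)
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  n <- nrow(xyz)
  if (n == 0L) .stopf("empty selection")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n) .stopf("need one mass per selected bead")
  w <- masses / sum(masses)
  com <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2L, com)^2)))
}

#' Percentage difference between two radii of gyration
#'
#' Comparison utility for checking that two representations of the same
#' group (e.g. a coarse-grained anchor against its reference model) agree
#' in compactness; agreement is conventionally required to be within a
#' few percent.
#'
#' @param rg_a,rg_b radii of gyration, Angstrom.
#' @param threshold_pct acceptance threshold in percent (default 5).
#' @return list with `pct_diff` (percent, relative to the mean) and
#'   `within` (logical).
#' @export
rg_percent_difference <- function(rg_a, rg_b, threshold_pct = 5) {
  m <- (rg_a + rg_b) / 2
  pct <- if (m == 0) 0 else abs(rg_a - rg_b) / m * 100
  list(pct_diff = pct, within = pct < threshold_pct)
}
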
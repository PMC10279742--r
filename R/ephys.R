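## Computational-electrophysiology post-processing: swap ledgers ->
## per-slice currents -> IV dataset -> conductance fit -> conductance
## state distribution.

#' Instantaneous current of one trajectory slice
#'
#' The current through one pore of the double-bilayer setup estimated
#' from the ion/water swap events of one (replica, slice):
#' `I = Sum_i(q_i * n_i) / (2 * dt)`, where `n_i` is the directed swap
#' count of species i (A->B positive, B->A negative) and `q_i` its
#' charge; the factor 2 reflects the two pores of the double-bilayer
#' geometry. Converted from e/ns to pA (1 e/ns = 160.2 pA).
#'
#' @param rows ledger rows of one (replica, slice): data.frame with
#'   columns `species`, `charge_e`, `direction`. An empty slice gives
#'   0 pA.
#' @param dt_ns slice duration, ns.
#' @return current in pA.
#' @export
slice_current <- function(rows, dt_ns = 20) {
  if (dt_ns <= 0) .stopf("slice duration must be > 0")
  if (!nrow(rows)) return(0)
  sgn <- ifelse(rows$direction == "A->B", 1, -1)
  e_per_ns <- sum(rows$charge_e * sgn) / (2 * dt_ns)
  e_per_ns_to_pA(e_per_ns)
}

#' Per-slice currents for a whole ledger
#'
#' Applies [slice_current()] to every (replica, slice) of a swap ledger
#' and joins the per-slice voltages. Slices without events get 0 pA.
#'
#' @param ledger an `hb_swap_ledger`, or a ledger data.frame (then
#'   `voltages` is required).
#' @param voltages data.frame `replica`, `slice`, `V_mV` (taken from the
#'   ledger object when omitted).
#' @param dt_ns slice duration, ns (default from the ledger object, else
#'   20).
#' @return data.frame of class `hb_slices` with columns `replica`,
#'   `slice`, `V_mV`, `I_pA`, `n_events`.
#' @export
compute_slice_currents <- function(ledger, voltages = NULL, dt_ns = NULL) {
  if (inherits(ledger, "hb_swap_ledger")) {
    if (is.null(voltages)) voltages <- ledger$voltages
    if (is.null(dt_ns)) dt_ns <- ledger$params$slice_ns
    ledger <- ledger$ledger
  }
  if (is.null(voltages)) .stopf("per-slice voltages are required")
  if (is.null(dt_ns)) dt_ns <- 20
  key <- paste(ledger$replica, ledger$slice, sep = ":")
  out <- voltages[order(voltages$replica, voltages$slice), , drop = FALSE]
  out$I_pA <- NA_real_
  out$n_events <- 0L
  grp <- split(seq_len(nrow(ledger)), key)
  okey <- paste(out$replica, out$slice, sep = ":")
  for (i in seq_len(nrow(out))) {
    idx <- grp[[okey[i]]]
    if (is.null(idx)) {
      out$I_pA[i] <- 0
    } else {
      out$I_pA[i] <- slice_current(ledger[idx, , drop = FALSE], dt_ns)
      out$n_events[i] <- length(idx)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("hb_slices", "data.frame")
  attr(out, "dt_ns") <- dt_ns
  out
}

#' Assemble the current-voltage dataset under the voltage filter
#'
#' Keeps slices whose potential stays within the voltage range used in
#' electrophysiology experiments on DNA nanopores (|V| <= `v_max`,
#' default 100 mV); excluded slices are logged with the reason.
#'
#' @param slices an `hb_slices` data.frame (from
#'   [compute_slice_currents()]).
#' @param v_max voltage window half-width, mV.
#' @return list of class `hb_iv`: `points` (data.frame `V_mV`, `I_pA`,
#'   `replica`, `slice`), `excluded` (same columns plus `reason`),
#'   `v_max`.
#' @export
assemble_iv <- function(slices, v_max = 100) {
  keep <- abs(slices$V_mV) <= v_max
  pts <- slices[keep, c("replica", "slice", "V_mV", "I_pA"), drop = FALSE]
  exc <- slices[!keep, c("replica", "slice", "V_mV", "I_pA"), drop = FALSE]
  if (nrow(exc)) exc$reason <- "voltage range"
  else exc$reason <- character(0L)
  rownames(pts) <- rownames(exc) <- NULL
  structure(list(points = pts, excluded = exc, v_max = v_max),
            class = "hb_iv")
}

#' @export
print.hb_iv <- function(x, ...) {
  cat(sprintf("IV dataset: %d usable points, %d excluded (|V| > %g mV)\n",
              nrow(x$points), nrow(x$excluded), x$v_max))
  invisible(x)
}

#' Fit the conductance from an IV dataset
#'
#' Least-squares slope of the current-voltage relation in nS
#' (pA/mV = nS), with a bootstrap-over-points standard error. The
#' default fit is constrained through the origin (an ohmic pore passes
#' zero current at zero bias, and the zero-imbalance replicas anchor
#' that point); a free-intercept fit is available for comparison and its
#' intercept is reported.
#'
#' @param iv an `hb_iv`.
#' @param method `"through_origin"` or `"free_intercept"`.
#' @param n_resamples bootstrap resamples over IV points.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `hb_conductance`: `G_nS`, `se_nS`,
#'   `intercept_pA` (0 for through-origin), `method`, `n_points`,
#'   `seed`.
#' @export
fit_conductance <- function(iv, method = c("through_origin",
                                           "free_intercept"),
                            n_resamples = 1000L, seed = 1L) {
  method <- match.arg(method)
  pts <- iv$points
  if (nrow(pts) < 2L) .stopf("need >= 2 IV points")
  if (length(unique(pts$V_mV)) < 2L)
    .stopf("all voltages identical: slope is undetermined")
  fit1 <- function(V, I) {
    if (method == "through_origin") c(sum(V * I) / sum(V^2), 0)
    else unname(rev(stats::coef(stats::lm(I ~ V))))
  }
  est <- fit1(pts$V_mV, pts$I_pA)
  set.seed(as.integer(seed))
  n <- nrow(pts)
  boots <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(pts$V_mV[idx])) < 2L) return(NA_real_)
    fit1(pts$V_mV[idx], pts$I_pA[idx])[1L]
  }, numeric(1L))
  structure(list(G_nS = est[1L], se_nS = stats::sd(boots, na.rm = TRUE),
                 intercept_pA = est[2L], method = method,
                 n_points = n, seed = as.integer(seed)),
            class = "hb_conductance")
}

#' @export
print.hb_conductance <- function(x, ...) {
  cat(sprintf("conductance %.3f +/- %.3f nS (%s fit, %d points)\n",
              x$G_nS, x$se_nS, x$method, x$n_points))
  invisible(x)
}

#' Distribution of per-slice conductance states
#'
#' Per-slice conductance `G = I/V` (nS) for slices with |V| at or above
#' a floor (default 10 mV, avoiding division blow-up near zero bias),
#' binned into a histogram. Sub-conductance states appear as distinct
#' modes.
#'
#' @param slices an `hb_slices` data.frame.
#' @param min_abs_V voltage floor, mV.
#' @param breaks passed to [hist()] (default `"FD"`).
#' @return list of class `hb_gdist`: `G_nS` (per-slice values),
#'   `histogram` (a [hist()] object, not plotted), `min_abs_V`.
#' @export
conductance_distribution <- function(slices, min_abs_V = 10,
                                     breaks = "FD") {
  keep <- abs(slices$V_mV) >= min_abs_V
  g <- slices$I_pA[keep] / slices$V_mV[keep]
  if (!length(g)) .stopf("no slices at |V| >= %g mV", min_abs_V)
  h <- graphics::hist(g, breaks = breaks, plot = FALSE)
  structure(list(G_nS = g, histogram = h, min_abs_V = min_abs_V),
            class = "hb_gdist")
}

#' Locations of the modes of a conductance distribution
#'
#' Kernel-density local maxima of the per-slice conductance values,
#' strongest first. Used to read off sub-conductance states.
#'
#' @param gdist an `hb_gdist`.
#' @param n_modes number of modes to return.
#' @param bw kernel bandwidth (default [stats::bw.nrd0()]).
#' @return numeric vector of mode locations, nS.
#' @export
conductance_modes <- function(gdist, n_modes = 2L, bw = NULL) {
  g <- gdist$G_nS
  d <- if (is.null(bw)) stats::density(g) else stats::density(g, bw = bw)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(locmax)) return(d$x[which.max(y)])
  locmax <- locmax[order(y[locmax], decreasing = TRUE)]
  d$x[locmax[seq_len(min(n_modes, length(locmax)))]]
}

#' Plot an IV dataset with its conductance fit
#'
#' @param x an `hb_iv`.
#' @param fit optional `hb_conductance` whose line is drawn.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.hb_iv <- function(x, fit = NULL, ...) {
  graphics::plot(x$points$V_mV, x$points$I_pA, xlab = "V (mV)",
                 ylab = "I (pA)", ...)
  if (!is.null(fit))
    graphics::abline(a = fit$intercept_pA, b = fit$G_nS, col = 2)
  invisible(x)
}
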
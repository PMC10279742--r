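## Ensemble averaging, bootstrap standard errors, convergence
## diagnostics and small table statistics.

#' Tidy metric time series over replicas
#'
#' @param replica integer replica ids.
#' @param time times, ns.
#' @param value metric values (no NaN/NA allowed).
#' @param metric metric name.
#' @return data.frame of class `metric_series`.
#' @export
metric_series <- function(replica, time, value, metric = "metric") {
  if (any(!is.finite(value))) .stopf("metric values must be finite")
  out <- data.frame(replica = as.integer(replica), time = time,
                    value = value)
  attr(out, "metric") <- metric
  class(out) <- c("metric_series", "data.frame")
  out
}

#' Bootstrap standard error of the mean
#'
#' SD of resampled means under resampling with replacement. With
#' `exhaustive = TRUE` (feasible for very small n) all `n^n` resamples
#' are enumerated and the exact SD of the resample-mean distribution is
#' returned; otherwise `n_resamples` Monte-Carlo resamples are drawn
#' under the seed, so the result is reproducible.
#'
#' @param values numeric vector, length >= 2.
#' @param n_resamples bootstrap resamples (a warning is logged below
#'   100).
#' @param seed RNG seed.
#' @param exhaustive enumerate all resamples instead of sampling.
#' @return list of class `bootstrap_result`: `estimate` (mean), `se`,
#'   `n_resamples`, `seed`, `unit`.
#' @export
bootstrap_sem <- function(values, n_resamples = 1000L, seed = 1L,
                          exhaustive = FALSE) {
  n <- length(values)
  if (n < 2L) .stopf("bootstrap needs >= 2 values")
  if (exhaustive) {
    if (n > 8L) .stopf("exhaustive enumeration is limited to n <= 8")
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    means <- rowMeans(matrix(values[idx], nrow(idx), n))
    se <- sqrt(mean((means - mean(means))^2))
    return(structure(list(estimate = mean(values), se = se,
                          n_resamples = nrow(idx), seed = NA_integer_,
                          unit = "value"), class = "bootstrap_result"))
  }
  if (n_resamples < 100L)
    warning("fewer than 100 bootstrap resamples; SE will be noisy")
  set.seed(as.integer(seed))
  means <- vapply(seq_len(n_resamples), function(i)
    mean(values[sample.int(n, n, replace = TRUE)]), numeric(1L))
  structure(list(estimate = mean(values), se = stats::sd(means),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), unit = "value"),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (bootstrap SE, B = %d)\n", x$estimate, x$se,
              x$n_resamples))
  invisible(x)
}

#' Ensemble mean of a metric with bootstrap SE over replicas
#'
#' The estimate is the mean of per-replica time means inside the window;
#' the uncertainty is the bootstrap SE over replicas (the replica is the
#' natural resampling unit for concurrently run trajectories). A single
#' replica yields an SE of `NA`.
#'
#' @param series a [metric_series()].
#' @param window `c(t_min, t_max)` in ns (inclusive).
#' @param n_resamples,seed passed to [bootstrap_sem()].
#' @return list of class `ensemble_mean`: `mean`, `se`,
#'   `replica_means`, `window`.
#' @export
ensemble_mean <- function(series, window = c(-Inf, Inf),
                          n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(series, "metric_series"))
  sel <- series$time >= window[1L] & series$time <= window[2L]
  if (!any(sel)) .stopf("empty time window [%g, %g]", window[1L],
                        window[2L])
  sub <- series[sel, , drop = FALSE]
  rm <- tapply(sub$value, sub$replica, mean)
  se <- if (length(rm) >= 2L)
    bootstrap_sem(as.numeric(rm), n_resamples, seed)$se else NA_real_
  structure(list(mean = mean(rm), se = se,
                 replica_means = as.numeric(rm), window = window),
            class = "ensemble_mean")
}

#' @export
print.ensemble_mean <- function(x, ...) {
  cat(sprintf("ensemble mean %.4g +/- %.4g over %d replica(s)\n",
              x$mean, x$se, length(x$replica_means)))
  invisible(x)
}

#' Convergence of the ensemble mean with replicas or duration
#'
#' Recomputes mean and bootstrap SE on nested prefixes (first k
#' replicas, or first fraction of the duration) to show whether the
#' standard error has converged, and summarises the monotone trend.
#'
#' @param series a [metric_series()].
#' @param vs `"n_replicas"` or `"duration"`.
#' @param n_resamples,seed passed to [bootstrap_sem()].
#' @return data.frame with columns `size`, `mean`, `se`, plus attribute
#'   `trend` (Spearman correlation of SE with size).
#' @export
convergence_curve <- function(series, vs = c("n_replicas", "duration"),
                              n_resamples = 1000L, seed = 1L) {
  vs <- match.arg(vs)
  stopifnot(inherits(series, "metric_series"))
  reps <- sort(unique(series$replica))
  if (length(reps) < 2L) .stopf("need >= 2 replicas")
  if (vs == "n_replicas") {
    sizes <- 2:length(reps)
    rows <- lapply(sizes, function(k) {
      sub <- series[series$replica %in% reps[seq_len(k)], , drop = FALSE]
      em <- ensemble_mean(sub, n_resamples = n_resamples, seed = seed)
      data.frame(size = k, mean = em$mean, se = em$se)
    })
  } else {
    tmax <- max(series$time)
    fracs <- seq(0.25, 1, by = 0.25)
    rows <- lapply(fracs, function(fr) {
      em <- ensemble_mean(series, window = c(-Inf, fr * tmax),
                          n_resamples = n_resamples, seed = seed)
      data.frame(size = fr * tmax, mean = em$mean, se = em$se)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "trend") <- if (nrow(out) >= 3L && stats::sd(out$se) > 0)
    stats::cor(out$size, out$se, method = "spearman") else 0
  out
}

#' Simple table statistics: unweighted mean or range
#'
#' Utility mirroring the derived statistics reported in class-average
#' tables: the unweighted mean across classes (relative class
#' populations are deliberately not used as weights) or the span
#' (max - min) of per-class extremes.
#'
#' @param values numeric vector, length >= 1.
#' @param op `"mean"` or `"range"`.
#' @return scalar.
#' @export
table_stats <- function(values, op = c("mean", "range")) {
  op <- match.arg(op)
  if (!length(values)) .stopf("empty value set")
  switch(op, mean = mean(values), range = max(values) - min(values))
}
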
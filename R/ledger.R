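## Ohmic ion-swap event simulator: the inverse of the slice-current
## estimator. For a slice at voltage V the directed net charge count is
## chosen so that I = Sum(q_i * n_i) / (2 * dt) has expectation G * V.

#' Generate synthetic ion-swap ledgers with known conductance
#'
#' For every replica and 20-ns slice, the slice voltage is drawn around
#' the schedule's expected value, and cation/anion swap counts in both
#' directions are drawn as Poisson variables whose means combine a
#' current-neutral baseline with a directed component such that the
#' slice-current estimator has expectation `G * V` (in pA, with
#' 1 e/ns = 160.2 pA). The directed charge is shared equally between
#' sodium moving with the field and chloride moving against it. When
#' several conductance states are configured, each slice samples its
#' state independently, producing a mixture of sub-conductance states.
#'
#' @param lparams a [ledger_params()].
#' @return object of class `hb_swap_ledger`: list with `ledger`
#'   (data.frame `time_ns`, `species`, `charge_e`, `direction`,
#'   `replica`, `slice`), `voltages` (data.frame `replica`, `slice`,
#'   `V_mV`, `dq`, `G_state`) and `params`.
#' @export
generate_swap_ledger <- function(lparams = ledger_params()) {
  stopifnot(inherits(lparams, "ledger_params"))
  sched <- lparams$voltage_schedule
  rep_group <- rep(seq_len(nrow(sched)), sched$n_replicas)
  dt <- lparams$slice_ns
  rows <- list(); volts <- list(); k <- 0L
  for (r in seq_len(lparams$n_replicas)) {
    set.seed(.replica_seed(lparams$seed, r))
    g <- rep_group[r]
    for (sl in seq_len(lparams$n_slices)) {
      V <- sched$V_mV[g] +
        if (lparams$v_jitter_sd > 0) stats::rnorm(1L, 0, lparams$v_jitter_sd)
        else 0
      state <- if (length(lparams$conductance_G) > 1L)
        sample.int(length(lparams$conductance_G), 1L,
                   prob = lparams$state_probs) else 1L
      G <- lparams$conductance_G[state]
      # target net charge per slice (e): I = mu/(2 dt) e/ns = G*V pA
      mu <- 2 * dt * (G * V) / .E_PER_NS_PA
      lam0 <- lparams$baseline_rate
      mup <- max(mu, 0) / 2; mum <- max(-mu, 0) / 2
      n_na_ab <- stats::rpois(1L, lam0 + mup)
      n_na_ba <- stats::rpois(1L, lam0 + mum)
      n_cl_ab <- stats::rpois(1L, lam0 + mum)
      n_cl_ba <- stats::rpois(1L, lam0 + mup)
      counts <- c(n_na_ab, n_na_ba, n_cl_ab, n_cl_ba)
      n_ev <- sum(counts)
      if (n_ev > 0L) {
        t0 <- (sl - 1L) * dt
        k <- k + 1L
        rows[[k]] <- data.frame(
          time_ns = t0 + sort(stats::runif(n_ev, 0, dt)),
          species = rep(c("Na", "Na", "Cl", "Cl"), counts),
          charge_e = rep(c(1, 1, -1, -1), counts),
          direction = rep(c("A->B", "B->A", "A->B", "B->A"), counts),
          replica = r, slice = sl, stringsAsFactors = FALSE)
      }
      volts[[length(volts) + 1L]] <-
        data.frame(replica = r, slice = sl, V_mV = V, dq = sched$dq[g],
                   G_state = G)
    }
  }
  ledger <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
    data.frame(time_ns = numeric(), species = character(),
               charge_e = numeric(), direction = character(),
               replica = integer(), slice = integer())
  ledger <- ledger[order(ledger$replica, ledger$time_ns), , drop = FALSE]
  rownames(ledger) <- NULL
  structure(list(ledger = ledger, voltages = do.call(rbind, volts),
                 params = lparams),
            class = "hb_swap_ledger")
}

#' @export
print.hb_swap_ledger <- function(x, ...) {
  cat(sprintf(
    "hb_swap_ledger: %d events, %d replicas x %d slices of %g ns\n",
    nrow(x$ledger), x$params$n_replicas, x$params$n_slices,
    x$params$slice_ns))
  invisible(x)
}
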
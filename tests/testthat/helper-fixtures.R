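# Shared fixtures and independent oracles. Everything is generated in
# code; the reference bundle is built once per test run.

ref_bundle <- build_ideal_bundle()

# small bundle for expensive per-frame operations
small_spec <- strand_map_spec(n_helices = 3L, bp_per_duplex = 9L,
                              nick_residue = 6L, loop_len = 0L,
                              cholesterol_helices = integer(0L))
small_bundle <- build_ideal_bundle(small_spec, distortion_params())

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3L)
  hexbundle:::.rotation_matrix(ax, runif(1L, 0, 360))
}

rigid_move <- function(xyz, seed = 1L) {
  R <- random_rotation(seed)
  set.seed(seed + 1L)
  sweep(unclass(xyz) %*% R, 2L, rnorm(3L, 0, 20), `+`)
}

# --- independent oracles -------------------------------------------------

# exhaustive minimum pairwise distance between two coordinate sets
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# RMSD after superposition by brute-force search over Euler angles,
# refined on a shrinking grid
oracle_rmsd_grid <- function(P, Q) {
  P <- sweep(P, 2L, colMeans(P)); Q <- sweep(Q, 2L, colMeans(Q))
  val <- function(a, b, c) {
    R <- hexbundle:::.rotation_matrix(c(0, 0, 1), a) %*%
      hexbundle:::.rotation_matrix(c(0, 1, 0), b) %*%
      hexbundle:::.rotation_matrix(c(1, 0, 0), c)
    sqrt(mean(rowSums((P %*% R - Q)^2)))
  }
  ctr <- c(0, 0, 0); step <- 45
  best <- Inf
  for (it in 1:10) {
    grid <- expand.grid(a = ctr[1L] + step * (-4:4),
                        b = ctr[2L] + step * (-4:4),
                        c = ctr[3L] + step * (-4:4))
    v <- mapply(val, grid$a, grid$b, grid$c)
    best <- min(v)
    ctr <- as.numeric(grid[which.min(v), ])
    step <- step / 3
  }
  best
}

# smallest enclosing circle by exhaustive candidate search over all
# point pairs and triples (no hull reduction)
oracle_mec_brute <- function(p) {
  n <- nrow(p)
  inside <- function(ctr, r2) all((p[, 1L] - ctr[1L])^2 +
                                    (p[, 2L] - ctr[2L])^2 <= r2 + 1e-9)
  best <- Inf
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ctr <- (p[i, ] + p[j, ]) / 2
    r2 <- sum((p[i, ] - ctr)^2)
    if (r2 < best && inside(ctr, r2)) best <- r2
  }
  if (n >= 3L) for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L))
    for (k in (j + 1L):n) {
      a <- p[i, ]; b <- p[j, ]; cc <- p[k, ]
      d <- 2 * (a[1L] * (b[2L] - cc[2L]) + b[1L] * (cc[2L] - a[2L]) +
                  cc[1L] * (a[2L] - b[2L]))
      if (abs(d) < 1e-12) next
      ctr <- c((sum(a^2) * (b[2L] - cc[2L]) + sum(b^2) * (cc[2L] - a[2L]) +
                  sum(cc^2) * (a[2L] - b[2L])) / d,
               (sum(a^2) * (cc[1L] - b[1L]) + sum(b^2) * (a[1L] - cc[1L]) +
                  sum(cc^2) * (b[1L] - a[1L])) / d)
      r2 <- sum((a - ctr)^2)
      if (r2 < best && inside(ctr, r2)) best <- r2
    }
  sqrt(best)
}

# greedy neighbour-count clustering, written directly from the rule
oracle_greedy_cluster <- function(D, cutoff) {
  m <- nrow(D)
  assignment <- rep(NA_integer_, m)
  remaining <- seq_len(m)
  cl <- 0L
  while (length(remaining)) {
    nb <- lapply(remaining, function(i)
      remaining[D[i, remaining] <= cutoff])
    counts <- lengths(nb)
    pick <- which(counts == max(counts))[1L]  # lowest index on ties
    cl <- cl + 1L
    assignment[nb[[pick]]] <- cl
    remaining <- setdiff(remaining, nb[[pick]])
  }
  assignment
}

# hand-summed slice current oracle: signed charge sum / (2 dt), in pA
oracle_slice_current <- function(rows, dt) {
  tot <- 0
  for (i in seq_len(nrow(rows))) {
    s <- if (rows$direction[i] == "A->B") 1 else -1
    tot <- tot + rows$charge_e[i] * s
  }
  tot / (2 * dt) * 160.2
}
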
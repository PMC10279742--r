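# Geometry module: axis fits, kink, lumen, dimensions, RMSD/RMSF,
# breakage and clustering, with independent oracles and invariance
# properties.

test_that("helix axis fit recovers direction and residual", {
  topo <- ref_bundle$topology
  xyz <- ref_bundle$conformation
  ax <- fit_helix_axis(xyz, topo, 1L, "whole")
  expect_equal(sqrt(sum(ax$direction^2)), 1)
  # ideal duplex: base-pair midpoints are exactly axial
  expect_lt(ax$residual, 0.8)
  expect_gt(abs(ax$direction[3L]), 0.9999)
  # orientation: residue 1 sits at the top, so the axis points down
  expect_lt(ax$direction[3L], 0)
  # segments need at least 3 pairs
  expect_error(fit_helix_axis(xyz, topo, 1L, "top", split = 2L),
               ">= 3")
})

test_that("axis fit equals a direct search over directions", {
  # perturbed small helix: compare the PCA direction with a brute-force
  # variance maximisation over a dense direction grid
  topo <- small_bundle$topology
  xyz <- unclass(small_bundle$conformation)
  set.seed(5L)
  xyz <- xyz + matrix(rnorm(length(xyz), 0, 1.5), nrow(xyz), 3L)
  ax <- fit_helix_axis(xyz, topo, 2L, "whole")
  pairs <- base_pair_table(topo)
  pairs <- pairs[pairs$helix == 2L, ]
  mid <- (xyz[pairs$bead1, ] + xyz[pairs$bead2, ]) / 2
  cen <- sweep(mid, 2L, colMeans(mid))
  # Fibonacci sphere of candidate directions
  i <- seq_len(20000L)
  phi <- acos(1 - 2 * (i - 0.5) / 20000)
  th <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  v <- rowSums((dirs %*% t(cen))^2)
  best <- dirs[which.max(v), ]
  expect_gt(abs(sum(best * ax$direction)), 0.999)
})

test_that("kink angle spans the straight and orthogonal limits", {
  expect_equal(kink_angle(ref_bundle$conformation, ref_bundle$topology,
                          3L), 0, tolerance = 1e-6)
  for (ang in c(40, 90)) {
    p <- distortion_params(kink_per_helix = rep(ang, 6L))
    e <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                           p, 1L, 1L)
    fr <- get_frame(e)
    for (h in 1:6)
      expect_equal(kink_angle(fr, e$topology, h), ang,
                   tolerance = 0.5 / ang)
  }
})

test_that("lumen profile equals the exhaustive pair-distance oracle", {
  topo <- ref_bundle$topology
  xyz <- unclass(ref_bundle$conformation)
  lp <- lumen_profile(xyz, topo)
  pos <- hexbundle:::.helix_position(topo)
  slabs <- list(top = 1:7, centre = 8:14, bottom = 15:21)
  pairs <- list(c(1L, 4L), c(2L, 5L), c(3L, 6L))
  for (s in names(slabs)) {
    mins <- vapply(pairs, function(pr) {
      ia <- which(topo$role == "backbone" & topo$helix == pr[1L] &
                    pos %in% slabs[[s]])
      ib <- which(topo$role == "backbone" & topo$helix == pr[2L] &
                    pos %in% slabs[[s]])
      oracle_min_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    }, numeric(1L))
    expect_equal(lp[[s]], mean(mins), tolerance = 1e-9)
  }
  # each reported value is the mean of exactly 3 pair minima
  expect_equal(dim(lp$per_pair), c(3L, 3L))
  expect_true(all(lp$per_pair >= 0))
})

test_that("lumen scales with uniform radial expansion of the axes", {
  topo <- ref_bundle$topology
  base <- ref_bundle$conformation
  info <- attr(base, "bundle_info")
  scaled <- unclass(base)
  for (h in 1:6) {
    idx <- which(!is.na(topo$helix) & topo$helix == h)
    scaled[idx, 1:2] <- sweep(scaled[idx, 1:2, drop = FALSE], 2L,
                              info$axis_xy[h, ], `+`)
  }
  l0 <- lumen_profile(base, topo)
  l2 <- lumen_profile(scaled, topo)
  expect_gt(l2$top, l0$top)
  expect_gt(l2$centre, l0$centre)
  expect_gt(l2$bottom, l0$bottom)
})

test_that("dimensions match construction and the brute-force circle", {
  d <- bundle_dimensions(ref_bundle$conformation, ref_bundle$topology)
  expect_equal(d$height, 68)
  expect_equal(d$width, 2 * (21 + 9.4), tolerance = 1e-4)
  # surface-corrected variant adds one bead radius each side
  d2 <- bundle_dimensions(ref_bundle$conformation, ref_bundle$topology,
                          bead_radius = 2.35)
  expect_equal(d2$height, 68 + 4.7)
  # smallest enclosing circle vs exhaustive search on small point sets
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:10, 1L)
    p <- matrix(rnorm(2L * n, 0, 10), n, 2L)
    expect_equal(min_enclosing_circle(p)$radius, oracle_mec_brute(p),
                 tolerance = 1e-9)
  }
  # radial scaling multiplies the width, height unchanged
  topo <- ref_bundle$topology
  info <- attr(ref_bundle$conformation, "bundle_info")
  scaled <- unclass(ref_bundle$conformation)
  for (h in 1:6) {
    idx <- which(!is.na(topo$helix) & topo$helix == h)
    scaled[idx, 1:2] <- sweep(scaled[idx, 1:2, drop = FALSE], 2L,
                              0.5 * info$axis_xy[h, ], `+`)
  }
  d3 <- bundle_dimensions(scaled, topo)
  expect_equal(d3$height, d$height, tolerance = 1e-6)
  expect_gt(d3$width, d$width)
})

test_that("RMSD is exact on toys and matches the rotation-grid oracle", {
  X <- matrix(rnorm(12L), 4L, 3L)
  expect_equal(rmsd(X, X), 0)
  # rigid motion is removed by superposition
  expect_lt(rmsd(X, rigid_move(X, 3L), superpose = TRUE), 1e-6)
  expect_gt(rmsd(X, rigid_move(X, 3L), superpose = FALSE), 1)
  # 4-point toy sets vs brute-force rotation search
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(12L, 0, 3), 4L, 3L)
    B <- matrix(rnorm(12L, 0, 3), 4L, 3L)
    expect_equal(rmsd(A, B), oracle_rmsd_grid(A, B), tolerance = 1e-2)
  }
  expect_error(rmsd(X, X, selection = 1:9), "selection")
})

test_that("RMSD is a pseudometric and agrees with bio3d", {
  set.seed(8L)
  frames <- lapply(1:4, function(i) matrix(rnorm(30L, 0, 4), 10L, 3L))
  for (i in 1:3) for (j in (i + 1L):4) {
    dij <- rmsd(frames[[i]], frames[[j]])
    expect_equal(dij, rmsd(frames[[j]], frames[[i]]), tolerance = 1e-8)
    for (k in seq_len(4L)[-c(i, j)])
      expect_lte(dij, rmsd(frames[[i]], frames[[k]]) +
                   rmsd(frames[[k]], frames[[j]]) + 1e-8)
  }
  # independent implementation: bio3d's Kabsch fit
  a <- as.numeric(t(frames[[1L]])); b <- as.numeric(t(frames[[2L]]))
  ref <- bio3d::rmsd(a, b, fit = TRUE)
  expect_equal(rmsd(frames[[1L]], frames[[2L]]), ref, tolerance = 1e-3)
})

test_that("RMSF vanishes for static ensembles and hits the Gaussian
           limit", {
  e0 <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                          distortion_params(), 1L, 5L)
  r0 <- rmsf(e0, align = FALSE)
  expect_lt(max(r0$per_residue$rmsf), 1e-10)
  # i.i.d. Gaussian displacement sigma per coordinate -> sigma * sqrt(3)
  sig <- 1.2
  e <- generate_ensemble(ref_bundle$topology, ref_bundle$conformation,
                         distortion_params(noise_sigma = sig, seed = 4L),
                         1L, 250L)
  r <- rmsf(e, align = FALSE)
  expect_equal(mean(r$per_residue$rmsf), sig * sqrt(3),
               tolerance = 0.03)
  # aggregates are means of their constituents
  expect_equal(mean(r$per_helix$rmsf), mean(r$per_residue$rmsf),
               tolerance = 0.02)
})

test_that("RMSF matches a hand-computed two-frame toy", {
  topo <- small_bundle$topology
  nb <- nrow(topo)
  co <- array(rep(unclass(small_bundle$conformation), 2L),
              c(nb, 3L, 2L))
  co[1L, 1L, 2L] <- co[1L, 1L, 1L] + 4  # one bead moves 4 A in x
  e <- hb_ensemble(topo, list(list(times = c(1, 2), coords = co)))
  r <- rmsf(e, align = FALSE)
  # that bead deviates 2 A from its mean in both frames
  key <- r$per_residue
  moved <- key[key$helix == topo$helix[1L] & key$strand == topo$strand[1L] &
                 key$residue == topo$residue[1L], ]
  # residue rmsf averages the residue's two beads: (2 + 0) / 2
  expect_equal(moved$rmsf, 1)
  expect_equal(sum(key$rmsf > 1e-12), 1L)
})

test_that("base-pair breakage counts displaced pairs exactly", {
  topo <- ref_bundle$topology
  xyz <- unclass(ref_bundle$conformation)
  expect_equal(broken_base_pairs(xyz, topo)$overall, 0)
  # displace exactly one of 21 pairs in helix 2 beyond the cutoff
  pairs <- base_pair_table(topo)
  b <- pairs$bead1[pairs$helix == 2L & pairs$pair == 1L]
  xyz2 <- xyz
  xyz2[b, ] <- xyz2[b, ] + c(20, 0, 0)
  rep <- broken_base_pairs(xyz2, topo)
  expect_equal(rep$per_helix[["2"]], 1 / 21)
  expect_equal(rep$overall, 1 / (21 * 6))
  # overall is the pair-count-weighted mean of the regions
  w <- c(top = 14 / 21, bottom = 7 / 21)
  expect_equal(sum(w * rep$per_region), rep$overall)
})

test_that("clustering reproduces the greedy rule and its limits", {
  base <- unclass(small_bundle$conformation)
  # identical frames -> one cluster
  same <- replicate(4L, base, simplify = FALSE)
  expect_equal(cluster_conformations(same, rmsd_cutoff = 0.5)$n_clusters,
               1L)
  # three well-separated conformers, slight intra-cluster noise
  make_noisy <- function(center_shift, seed) {
    set.seed(seed)
    base + matrix(rnorm(length(base), 0, 0.05), nrow(base), 3L) +
      matrix(rep(c(center_shift, 0, 0), each = nrow(base)), nrow(base))
  }
  frames <- c(lapply(1:3, function(i) make_noisy(0, i)),
              lapply(4:6, function(i) make_noisy(0, i) *
                       matrix(rep(c(1.5, 1.5, 1), each = nrow(base)),
                              nrow(base))),
              lapply(7:9, function(i) make_noisy(0, i) *
                       matrix(rep(c(1, 1, 1.7), each = nrow(base)),
                              nrow(base))))
  cl <- cluster_conformations(frames, rmsd_cutoff = 1)
  expect_equal(cl$n_clusters, 3L)
  expect_equal(cl$assignment, rep(1:3, each = 3L))
  # 10-frame toy vs direct evaluation of the rule
  set.seed(21L)
  toy <- lapply(1:10, function(i)
    base + matrix(rnorm(length(base), 0, runif(1L, 0.05, 2)),
                  nrow(base), 3L))
  m <- length(toy)
  D <- matrix(0, m, m)
  for (i in 1:(m - 1L)) for (j in (i + 1L):m)
    D[i, j] <- D[j, i] <- rmsd(toy[[i]], toy[[j]])
  expect_equal(cluster_conformations(toy, rmsd_cutoff = 1.6)$assignment,
               oracle_greedy_cluster(D, 1.6))
})

test_that("geometric measures are rigid-motion invariant", {
  topo <- ref_bundle$topology
  p <- distortion_params(kink_per_helix = c(30, 10, 0, 45, 5, 60),
                         noise_sigma = 0.3, seed = 13L)
  e <- generate_ensemble(topo, ref_bundle$conformation, p, 1L, 1L)
  fr <- get_frame(e)
  moved <- rigid_move(fr, 17L)
  l1 <- lumen_profile(fr, topo); l2 <- lumen_profile(moved, topo)
  expect_equal(l2$centre, l1$centre, tolerance = 1e-8)
  d1 <- bundle_dimensions(fr, topo); d2 <- bundle_dimensions(moved, topo)
  expect_equal(d2$height, d1$height, tolerance = 1e-6)
  expect_equal(d2$width, d1$width, tolerance = 1e-6)
  for (h in c(1L, 4L))
    expect_equal(kink_angle(moved, topo, h), kink_angle(fr, topo, h),
                 tolerance = 1e-6)
  expect_equal(broken_base_pairs(moved, topo)$overall,
               broken_base_pairs(fr, topo)$overall)
  expect_lt(rmsd(fr, moved, superpose = TRUE), 1e-6)
})
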
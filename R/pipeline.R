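## End-to-end orchestration: generate -> geometry -> rmsf -> bpb ->
## cluster -> density -> ephys -> report. Stages communicate through
## files in the output directory so each is independently rerunnable,
## and a manifest records inputs, outputs and the seed.

.stage_file <- function(dir, name) file.path(dir, name)

.require_dep <- function(stage, path) {
  if (!file.exists(path))
    .stopf("stage '%s': missing dependency %s", stage, path)
  path
}

.stage_generate <- function(cfg, dir) {
  built <- build_ideal_bundle(cfg$spec, cfg$distortions)
  write_topology_table(built$topology, .stage_file(dir, "topology.tsv"))
  ens <- generate_ensemble(built$topology, built$conformation,
                           cfg$distortions,
                           n_replicas = cfg$ensemble$n_replicas,
                           n_frames = cfg$ensemble$n_frames,
                           dt_ns = cfg$ensemble$dt_ns)
  for (r in seq_along(ens$replicas)) {
    one <- hb_ensemble(ens$topology, ens$replicas[r], box = ens$box)
    write_bundle_pdb(one, .stage_file(dir, sprintf("ensemble_rep%d.pdb", r)))
  }
  led <- generate_swap_ledger(cfg$ledger)
  write_swap_ledger(led, .stage_file(dir, "ledger.tsv"))
  write_voltage_table(led$voltages, .stage_file(dir, "voltages.tsv"))
  invisible(NULL)
}

.read_pipeline_ensemble <- function(cfg, dir, stage) {
  topo <- read_topology_table(.require_dep(stage,
                                           .stage_file(dir, "topology.tsv")))
  reps <- list()
  for (r in seq_len(cfg$ensemble$n_replicas)) {
    p <- .require_dep(stage, .stage_file(dir,
                                         sprintf("ensemble_rep%d.pdb", r)))
    one <- read_multi_model_pdb(p, topology = topo,
                                dt_ns = cfg$ensemble$dt_ns)
    reps[[r]] <- one$replicas[[1L]]
  }
  hb_ensemble(topo, reps)
}

.stage_geometry <- function(cfg, dir) {
  ens <- .read_pipeline_ensemble(cfg, dir, "geometry")
  topo <- ens$topology
  nh <- attr(topo, "spec")$n_helices
  kink <- list(); lum <- list(); dims <- list(); k <- 0L
  for (r in seq_along(ens$replicas)) {
    co <- ens$replicas[[r]]$coords
    for (f in seq_len(dim(co)[3L])) {
      fr <- co[, , f]
      k <- k + 1L
      kink[[k]] <- data.frame(replica = r, frame = f, helix = seq_len(nh),
                              kink_deg = vapply(seq_len(nh), function(h)
                                kink_angle(fr, topo, h), numeric(1L)))
      lp <- lumen_profile(fr, topo)
      dm <- bundle_dimensions(fr, topo)
      lum[[k]] <- data.frame(replica = r, frame = f, top = lp$top,
                             centre = lp$centre, bottom = lp$bottom)
      dims[[k]] <- data.frame(replica = r, frame = f,
                              height = dm$height, width = dm$width)
    }
  }
  .write_tsv(do.call(rbind, kink), .stage_file(dir, "kink.tsv"))
  .write_tsv(do.call(rbind, lum), .stage_file(dir, "lumen.tsv"))
  .write_tsv(do.call(rbind, dims), .stage_file(dir, "dimensions.tsv"))
  invisible(NULL)
}

.stage_rmsf <- function(cfg, dir) {
  ens <- .read_pipeline_ensemble(cfg, dir, "rmsf")
  prof <- rmsf(ens, align = isTRUE(cfg$analysis$rmsf_align))
  .write_tsv(prof$per_residue, .stage_file(dir, "rmsf.tsv"))
  invisible(NULL)
}

.stage_bpb <- function(cfg, dir) {
  ens <- .read_pipeline_ensemble(cfg, dir, "bpb")
  rep <- broken_base_pairs(ens, cutoff = cfg$analysis$bpb_cutoff)
  out <- data.frame(
    group = c("overall", "top", "bottom",
              paste0("helix", names(rep$per_helix))),
    pct_broken = 100 * c(rep$overall, rep$per_region[["top"]],
                         rep$per_region[["bottom"]], rep$per_helix))
  .write_tsv(out, .stage_file(dir, "bpb.tsv"))
  invisible(NULL)
}

.stage_cluster <- function(cfg, dir) {
  ens <- .read_pipeline_ensemble(cfg, dir, "cluster")
  fl <- .flatten_frames(ens)
  m <- length(fl$frames)
  keep <- if (m > cfg$analysis$cluster_max_frames)
    round(seq(1L, m, length.out = cfg$analysis$cluster_max_frames))
  else seq_len(m)
  cl <- cluster_conformations(fl$frames[keep],
                              rmsd_cutoff = cfg$analysis$cluster_cutoff)
  .write_tsv(data.frame(replica = fl$index[keep, 1L],
                        frame = fl$index[keep, 2L],
                        cluster = cl$assignment),
             .stage_file(dir, "clusters.tsv"))
  invisible(NULL)
}

.stage_density <- function(cfg, dir) {
  field <- generate_ion_field(cfg$ions,
                              n_frames = cfg$analysis$density_frames,
                              species = c("Na", "Cl"))
  prof <- do.call(rbind, lapply(c("Na", "Cl"), function(sp) {
    p <- number_density_z(field, sp, bin = cfg$analysis$density_bin)
    data.frame(species = sp, z = p$z, density = p$density)
  }))
  .write_tsv(prof, .stage_file(dir, "density_profile.tsv"))
  cyl <- field$lumen_cylinder
  bulk <- annulus_region(cyl$centre, r_inner = cyl$radius + 20,
                         r_outer = cfg$analysis$bulk_outer_radius,
                         zmin = cyl$zmin, zmax = cyl$zmax)
  dd <- lapply(c("Na", "Cl"), function(sp)
    region_density_difference(field, sp, cyl, bulk))
  .write_tsv(data.frame(species = c("Na", "Cl"),
                        difference_nm3 = vapply(dd, `[[`, numeric(1L),
                                                "difference")),
             .stage_file(dir, "density_difference.tsv"))
  invisible(NULL)
}

.stage_ephys <- function(cfg, dir) {
  ledger <- read_swap_ledger(.require_dep("ephys",
                                          .stage_file(dir, "ledger.tsv")))
  volts <- read_voltage_table(.require_dep("ephys",
                                           .stage_file(dir, "voltages.tsv")))
  slices <- compute_slice_currents(ledger, volts,
                                   dt_ns = cfg$ledger$slice_ns)
  .write_tsv(as.data.frame(slices), .stage_file(dir, "slices.tsv"))
  iv <- assemble_iv(slices, v_max = cfg$analysis$v_max)
  .write_tsv(iv$points, .stage_file(dir, "iv.tsv"))
  fit <- fit_conductance(iv, method = cfg$analysis$fit_method,
                         n_resamples = cfg$analysis$bootstrap_B,
                         seed = cfg$seed)
  .write_tsv(data.frame(G_nS = fit$G_nS, se_nS = fit$se_nS,
                        intercept_pA = fit$intercept_pA,
                        method = fit$method, n_points = fit$n_points),
             .stage_file(dir, "conductance.tsv"))
  gd <- conductance_distribution(slices,
                                 min_abs_V = cfg$analysis$min_abs_V)
  .write_tsv(data.frame(G_nS = gd$G_nS),
             .stage_file(dir, "conductance_states.tsv"))
  invisible(NULL)
}

.stage_report <- function(cfg, dir) {
  kink <- .read_tsv(.require_dep("report", .stage_file(dir, "kink.tsv")),
                    c("helix", "kink_deg"))
  ks <- stats::aggregate(kink$kink_deg, by = list(helix = kink$helix),
                         FUN = function(v) c(mean = mean(v),
                                             sd = stats::sd(v)))
  kink_sum <- data.frame(helix = ks$helix, mean_deg = ks$x[, "mean"],
                         sd_deg = ks$x[, "sd"])
  .write_tsv(kink_sum, .stage_file(dir, "report_kink.tsv"))
  dims <- .read_tsv(.require_dep("report",
                                 .stage_file(dir, "dimensions.tsv")),
                    c("replica", "height", "width"))
  em_h <- ensemble_mean(metric_series(dims$replica, dims$frame,
                                      dims$height), seed = cfg$seed)
  em_w <- ensemble_mean(metric_series(dims$replica, dims$frame,
                                      dims$width), seed = cfg$seed)
  .write_tsv(data.frame(quantity = c("height_A", "width_A"),
                        mean = c(em_h$mean, em_w$mean),
                        bootstrap_se = c(em_h$se, em_w$se)),
             .stage_file(dir, "report_dimensions.tsv"))
  lum <- .read_tsv(.require_dep("report", .stage_file(dir, "lumen.tsv")),
                   c("top", "centre", "bottom"))
  .write_tsv(data.frame(region = c("top", "centre", "bottom"),
                        mean_A = c(mean(lum$top), mean(lum$centre),
                                   mean(lum$bottom)),
                        sd_A = c(stats::sd(lum$top), stats::sd(lum$centre),
                                 stats::sd(lum$bottom))),
             .stage_file(dir, "report_lumen.tsv"))
  invisible(NULL)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages generate, geometry, rmsf, bpb, cluster, density,
#' ephys and report in dependency order, exchanging data through files
#' in `out_dir`. A failure aborts with an error naming the stage. A run
#' manifest (seed, package version, config echo, per-file MD5 checksums,
#' timestamps) is written last; rerunning with the same configuration
#' and seed reproduces the numeric tables byte for byte.
#'
#' @param config an `hb_config` from [load_config()], or a YAML path.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (default all, in
#'   order).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("generate", "geometry", "rmsf", "bpb",
                                    "cluster", "density", "ephys",
                                    "report")) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "hb_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(generate = .stage_generate, geometry = .stage_geometry,
                  rmsf = .stage_rmsf, bpb = .stage_bpb,
                  cluster = .stage_cluster, density = .stage_density,
                  ephys = .stage_ephys, report = .stage_report)
  stages <- match.arg(stages, names(runners), several.ok = TRUE)
  t0 <- Sys.time()
  for (st in stages) {
    tryCatch(runners[[st]](config, out_dir),
             error = function(e) {
               msg <- conditionMessage(e)
               if (grepl("^stage '", msg)) stop(e)
               .stopf("stage '%s' failed: %s", st, msg)
             })
  }
  outputs <- sort(setdiff(list.files(out_dir), "manifest.yaml"))
  manifest <- list(
    package = "hexbundle",
    version = as.character(utils::packageVersion("hexbundle")),
    seed = config$seed,
    config = attr(config, "resolved"),
    stages = stages,
    outputs = lapply(outputs, function(f)
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
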
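## YAML configuration: one structured file holding every generator and
## analysis parameter, with defaults filled, unknown keys rejected and
## the resolved configuration echoed for reproducibility.

.ensemble_defaults <- function()
  list(n_replicas = 3L, n_frames = 20L, dt_ns = 1)

.analysis_defaults <- function()
  list(bpb_cutoff = 8, cluster_cutoff = 3, cluster_max_frames = 60L,
       density_bin = 1, density_frames = 50L, lumen_radius = 9,
       bulk_outer_radius = 70, v_max = 100, min_abs_V = 10,
       fit_method = "through_origin", bootstrap_B = 1000L,
       rmsf_align = TRUE)

# fill `defaults` with `given`, rejecting unknown keys; `where` names
# the config section in error messages
.merge_section <- function(given, defaults, where) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    .stopf("unknown config key '%s.%s'", where, unknown[1L])
  defaults[names(given)] <- given
  defaults
}

# run a parameter constructor, prefixing errors with the section path
.build_params <- function(ctor, args, where) {
  tryCatch(do.call(ctor, args),
           error = function(e)
             .stopf("config section '%s': %s", where, conditionMessage(e)))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with optional sections `bundle`, `distortions`,
#' `membrane`, `ions`, `ledger`, `ensemble`, `analysis` and a top-level
#' `seed`. Every omitted key takes its documented default (the defaults
#' of the parameter constructors); unknown keys and out-of-range values
#' are rejected with the offending key path. The top-level seed is
#' propagated to every seeded component that does not set its own.
#'
#' The fully resolved configuration (including the seed) is attached as
#' attribute `resolved` and, with `verbose = TRUE`, echoed as YAML so a
#' run's log records the exact parameter set.
#'
#' @param path YAML file path.
#' @param verbose echo the resolved configuration via [message()].
#' @return list of class `hb_config` with elements `seed`, `spec`,
#'   `distortions`, `membrane` (or NULL), `ions`, `ledger`, `ensemble`,
#'   `analysis`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) .stopf("no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "bundle", "distortions", "membrane", "ions",
             "ledger", "ensemble", "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) .stopf("unknown config section '%s'", unknown[1L])
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  bundle <- .merge_section(raw$bundle,
                           formals_defaults(strand_map_spec), "bundle")
  spec <- .build_params(strand_map_spec, bundle, "bundle")

  dist <- .merge_section(raw$distortions,
                         formals_defaults(distortion_params), "distortions")
  if (is.null(raw$distortions$seed)) dist$seed <- seed
  distortions <- .build_params(distortion_params, dist, "distortions")

  membrane <- NULL
  if (!is.null(raw$membrane)) {
    memb <- .merge_section(raw$membrane,
                           formals_defaults(membrane_params), "membrane")
    membrane <- .build_params(membrane_params, memb, "membrane")
  }

  ion <- .merge_section(raw$ions, formals_defaults(ion_field_params),
                        "ions")
  if (is.null(raw$ions$seed)) ion$seed <- seed
  if (!is.null(raw$ions$lumen_enhancement))
    ion$lumen_enhancement <- unlist(raw$ions$lumen_enhancement)
  ions <- .build_params(ion_field_params, ion, "ions")

  led <- .merge_section(raw$ledger, formals_defaults(ledger_params),
                        "ledger")
  if (is.null(raw$ledger$seed)) led$seed <- seed
  if (!is.null(raw$ledger$voltage_schedule))
    led$voltage_schedule <-
      do.call(rbind, lapply(raw$ledger$voltage_schedule, as.data.frame))
  ledger <- .build_params(ledger_params, led, "ledger")

  ens <- .merge_section(raw$ensemble, .ensemble_defaults(), "ensemble")
  ana <- .merge_section(raw$analysis, .analysis_defaults(), "analysis")

  cfg <- structure(list(seed = seed, spec = spec,
                        distortions = distortions, membrane = membrane,
                        ions = ions, ledger = ledger, ensemble = ens,
                        analysis = ana),
                   class = "hb_config")
  resolved <- list(seed = seed, bundle = unclass(spec),
                   distortions = unclass(distortions),
                   membrane = if (is.null(membrane)) NULL
                   else unclass(membrane),
                   ions = unclass(ions),
                   ledger = unclass(ledger)[c(
                     "conductance_G", "state_probs", "slice_ns",
                     "total_ns", "v_jitter_sd", "baseline_rate", "seed")],
                   ensemble = ens, analysis = ana)
  attr(cfg, "resolved") <- resolved
  if (verbose) message(yaml::as.yaml(resolved))
  cfg
}

#' Default values of a function's formals, as a list
#'
#' @param fn a function whose formals all have defaults.
#' @return named list of evaluated defaults.
#' @keywords internal
#' @export
formals_defaults <- function(fn) {
  fm <- formals(fn)
  fm <- fm[!vapply(fm, is.symbol, logical(1L)) |
             vapply(fm, function(x) !identical(as.character(x), ""),
                    logical(1L))]
  lapply(fm, function(x) eval(x, envir = asNamespace("hexbundle")))
}
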
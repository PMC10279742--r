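## File formats connecting the pipeline stages: multi-model PDB for
## coordinates (viewable in standard molecular viewers), tab-separated
## tables for topology / swap ledgers / voltages, and a YAML config.
## All delimited text is tab-separated, "." decimal, UTF-8, with a
## mandatory header row; writers are deterministic byte-for-byte.

.role_elety <- c(backbone = "BB", base = "SC1", loop = "BB",
                 cholesterol = "ROH", lipid = "PO4")
.role_resid <- c(backbone = "DT", base = "DT", loop = "DT",
                 cholesterol = "CHL", lipid = "POP")

# PDB encoding: helices as chains A..F; strand 2 residues offset by 100,
# cholesterol 200 + helix, lipids in chain X numbered serially.
.pdb_fields <- function(topology) {
  chain <- ifelse(is.na(topology$helix), "X", LETTERS[topology$helix])
  resno <- topology$residue
  resno[!is.na(topology$strand) & topology$strand == 2L] <-
    resno[!is.na(topology$strand) & topology$strand == 2L] + 100L
  chol <- topology$role == "cholesterol"
  resno[chol] <- 200L + topology$helix[chol]
  lip <- topology$role == "lipid"
  if (any(lip)) resno[lip] <- seq_len(sum(lip))
  list(chain = chain, resno = resno,
       resid = .role_resid[topology$role],
       elety = .role_elety[topology$role], eleno = topology$bead)
}

#' Write an ensemble (or single conformation) as multi-model PDB
#'
#' One `MODEL` block per frame, helices encoded as chains A-F,
#' coordinates in Angstrom at the 3-decimal PDB precision. Replicas are
#' concatenated in order. A sidecar topology table (see
#' [write_topology_table()]) carries the full bead identity.
#'
#' @param x an `hb_ensemble`, or an n x 3 conformation matrix (then
#'   `topology` is required).
#' @param path output PDB path.
#' @param topology required when `x` is a bare matrix.
#' @return invisibly, `path`.
#' @export
write_bundle_pdb <- function(x, path, topology = NULL) {
  if (inherits(x, "hb_ensemble")) {
    topology <- x$topology
    fl <- .flatten_frames(x)
    xyz <- do.call(rbind, lapply(fl$frames, function(f) as.numeric(t(f))))
  } else {
    if (is.null(topology)) .stopf("topology required for a bare frame")
    xyz <- matrix(as.numeric(t(unclass(x))), nrow = 1L)
  }
  f <- .pdb_fields(topology)
  bio3d::write.pdb(file = path, xyz = xyz, resno = f$resno,
                   chain = f$chain, resid = f$resid, eleno = f$eleno,
                   elety = f$elety)
  invisible(path)
}

#' Read a multi-model PDB as a single-replica ensemble
#'
#' One frame per `MODEL` block. Bead identities come from the sidecar
#' topology table (preferred) or are reconstructed from the chain /
#' residue-number convention of [write_bundle_pdb()]. Models with
#' mismatched bead counts are rejected with the offending model index;
#' truncated files (no coordinates) are rejected rather than returned
#' partially.
#'
#' @param path PDB path.
#' @param topology a `bundle_topology`, or the path of a sidecar table
#'   written by [write_topology_table()]; `NULL` requires the file to
#'   match a default-spec bundle.
#' @param dt_ns frame spacing used for the reconstructed time axis, ns.
#' @return an [hb_ensemble()] with one replica.
#' @export
read_multi_model_pdb <- function(path, topology = NULL, dt_ns = 1) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  # validate per-model atom counts before parsing coordinates
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts)) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts)) > 1L)
      .stopf("model %d has %d beads where %d were expected",
             which(counts != counts[1L])[1L],
             counts[counts != counts[1L]][1L], counts[1L])
  }
  if (!any(is_atom)) .stopf("no coordinates in %s (truncated file?)", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.character(topology) && length(topology) == 1L)
    topology <- read_topology_table(topology)
  if (is.null(topology)) topology <- build_topology(strand_map_spec())
  nb <- nrow(topology)
  xyz <- pdb$xyz
  if (ncol(xyz) != 3L * nb)
    .stopf("PDB has %d beads per model; topology expects %d",
           ncol(xyz) / 3L, nb)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nb, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], nb, 3L, byrow = TRUE)
  hb_ensemble(topology,
              list(list(times = seq_len(nf) * dt_ns, coords = coords)))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stopf("%s: missing required column(s) %s", path,
           paste(miss, collapse = ", "))
  df
}

#' Write / read the bead topology sidecar table
#'
#' Tab-separated: `bead`, `helix`, `strand`, `residue`, `role`,
#' `partner`.
#'
#' @param topology a `bundle_topology`.
#' @param path file path.
#' @return `write_topology_table()` returns `path` invisibly;
#'   `read_topology_table()` returns a `bundle_topology`.
#' @export
write_topology_table <- function(topology, path) {
  .write_tsv(as.data.frame(topology)[, c("bead", "helix", "strand",
                                         "residue", "role", "partner")],
             path)
}

#' @rdname write_topology_table
#' @export
read_topology_table <- function(path) {
  df <- .read_tsv(path, c("bead", "helix", "strand", "residue", "role",
                          "partner"))
  # pairing must be symmetric and involutive
  has <- which(!is.na(df$partner))
  if (any(df$partner[df$partner[has]] != df$bead[has]))
    .stopf("%s: base-pair partnering is not symmetric", path)
  # reconstruct the spec for downstream region/pairing logic
  dna <- df$role %in% c("backbone", "base")
  bp <- max(df$residue[dna])
  loop_len <- if (any(df$role == "loop"))
    max(df$residue[df$role == "loop"]) - bp else 0L
  nick <- if (any(df$role == "cholesterol"))
    df$residue[df$role == "cholesterol"][1L] else ceiling(bp * 2 / 3)
  spec <- strand_map_spec(
    n_helices = max(df$helix, na.rm = TRUE), bp_per_duplex = bp,
    nick_residue = nick, loop_len = loop_len,
    cholesterol_helices = unique(df$helix[df$role == "cholesterol"]))
  attr(df, "spec") <- spec
  class(df) <- c("bundle_topology", "data.frame")
  df
}

#' Write / read a swap ledger table
#'
#' Tab-separated: `time_ns`, `species`, `charge_e`, `direction`,
#' `replica`, `slice`. Reading validates species/charge consistency
#' (Na -> +1, Cl -> -1) and direction labels, reporting offending rows,
#' and returns rows sorted by (replica, time). An empty ledger (header
#' only) is valid.
#'
#' @param ledger an `hb_swap_ledger` or a ledger data.frame.
#' @param path file path.
#' @return `write_swap_ledger()` returns `path` invisibly;
#'   `read_swap_ledger()` returns the ledger data.frame.
#' @export
write_swap_ledger <- function(ledger, path) {
  if (inherits(ledger, "hb_swap_ledger")) ledger <- ledger$ledger
  .write_tsv(ledger, path)
}

#' @rdname write_swap_ledger
#' @export
read_swap_ledger <- function(path) {
  df <- .read_tsv(path, c("time_ns", "species", "charge_e", "direction",
                          "replica", "slice"))
  if (!nrow(df)) return(df)
  want <- c(Na = 1, Cl = -1)
  bad_sp <- which(!df$species %in% names(want))
  if (length(bad_sp))
    .stopf("%s: unknown species '%s' at row %d", path,
           df$species[bad_sp[1L]], bad_sp[1L])
  bad_q <- which(df$charge_e != want[df$species])
  if (length(bad_q))
    .stopf("%s: species %s with charge %+g at row %d", path,
           df$species[bad_q[1L]], df$charge_e[bad_q[1L]], bad_q[1L])
  bad_d <- which(!df$direction %in% c("A->B", "B->A"))
  if (length(bad_d))
    .stopf("%s: unknown direction '%s' at row %d", path,
           df$direction[bad_d[1L]], bad_d[1L])
  df <- df[order(df$replica, df$time_ns), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a per-slice voltage table
#'
#' Tab-separated: `replica`, `slice`, `V_mV`.
#'
#' @param voltages data.frame with `replica`, `slice`, `V_mV`.
#' @param path file path.
#' @return `write_voltage_table()` returns `path` invisibly;
#'   `read_voltage_table()` the data.frame.
#' @export
write_voltage_table <- function(voltages, path) {
  .write_tsv(voltages[, intersect(c("replica", "slice", "V_mV", "dq",
                                    "G_state"), names(voltages))], path)
}

#' @rdname write_voltage_table
#' @export
read_voltage_table <- function(path) {
  .read_tsv(path, c("replica", "slice", "V_mV"))
}
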
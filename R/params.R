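## Parameter objects for the synthetic-data generators. Each constructor
## validates its invariants and returns a classed list so downstream code
## and the config loader share a single source of defaults.

#' Strand map specification for the six-helix bundle
#'
#' Describes the designed connectivity of the bundle: six duplexes of 21
#' base pairs arranged hexagonally, each duplex carrying a single-stranded
#' nick in its midsection (residue 14, the cholesterol attachment point on
#' the modified duplexes) and poly-thymidine loops joining neighbouring
#' duplexes at top and bottom.
#'
#' @param n_helices number of duplexes (>= 3).
#' @param bp_per_duplex paired residues per duplex.
#' @param nick_residue residue index of the nick/region split; must lie
#'   strictly inside the strand.
#' @param loop_len poly-T loop residues appended per strand end. The
#'   designed loop length is not part of the topology's ground truth and is
#'   therefore configurable; the default of 4 gives 25 residues per strand.
#' @param cholesterol_helices helix ids carrying a cholesterol anchor.
#' @param beads_per_nt beads per paired nucleotide (backbone + base).
#' @return object of class `strand_map_spec`.
#' @export
strand_map_spec <- function(n_helices = 6L, bp_per_duplex = 21L,
                            nick_residue = 14L, loop_len = 4L,
                            cholesterol_helices = c(2L, 4L, 6L),
                            beads_per_nt = 2L) {
  n_helices <- as.integer(n_helices)
  bp_per_duplex <- as.integer(bp_per_duplex)
  nick_residue <- as.integer(nick_residue)
  loop_len <- as.integer(loop_len)
  cholesterol_helices <- as.integer(cholesterol_helices)
  if (n_helices < 3L) .stopf("n_helices must be >= 3 (got %d)", n_helices)
  n_res <- bp_per_duplex + loop_len
  if (nick_residue <= 1L || nick_residue >= n_res)
    .stopf("nick_residue must lie strictly within 1..%d (got %d)",
           n_res, nick_residue)
  if (loop_len < 0L) .stopf("loop_len must be >= 0")
  if (length(cholesterol_helices) &&
      !all(cholesterol_helices %in% seq_len(n_helices)))
    .stopf("cholesterol_helices must be a subset of 1..%d", n_helices)
  if (beads_per_nt != 2L)
    .stopf("only the 2-bead (backbone + base) nucleotide model is supported")
  structure(list(n_helices = n_helices, bp_per_duplex = bp_per_duplex,
                 nick_residue = nick_residue, loop_len = loop_len,
                 cholesterol_helices = cholesterol_helices,
                 beads_per_nt = 2L),
            class = "strand_map_spec")
}

#' Distortion parameters for the kinematic ensemble generator
#'
#' Ground-truth generative parameters for synthetic conformational
#' ensembles: hexagon spacing and duplex helical geometry, per-helix kink
#' at the nick hinge, radial breathing, terminal fraying, global rigid
#' tilt/twist, and isotropic Gaussian noise.
#'
#' @param axis_spacing_s adjacent helix axis-to-axis distance, Angstrom.
#'   Equals the circumradius of the hexagon of helix axes.
#' @param rise helical rise, Angstrom per bp.
#' @param twist helical twist, degrees per bp.
#' @param kink_per_helix numeric vector (recycled to `n_helices`) of hinge
#'   rotation angles in degrees, each in \[0, 180).
#' @param breathing_amplitude radial breathing amplitude, Angstrom (added
#'   sinusoidally to the hexagon circumradius).
#' @param breathing_period breathing period, ns.
#' @param fray_prob probability per targeted base pair per frame of a
#'   breakage displacement.
#' @param fray_residues base-pair indices targeted by fraying; `NULL`
#'   means the terminal pairs (1 and `bp_per_duplex`).
#' @param fray_displacement Angstrom by which a frayed base bead is pushed
#'   away from its partner (default safely beyond the breakage cutoff).
#' @param tilt_deg global rigid tilt about the x axis, degrees.
#' @param twist_rate global rigid rotation rate about z, degrees per ns.
#' @param noise_sigma isotropic Gaussian positional noise, Angstrom.
#' @param seed master RNG seed; all replica streams derive from it.
#' @return object of class `distortion_params`.
#' @export
distortion_params <- function(axis_spacing_s = 21, rise = 3.4, twist = 34.3,
                              kink_per_helix = 0, breathing_amplitude = 0,
                              breathing_period = 100, fray_prob = 0,
                              fray_residues = NULL, fray_displacement = 10,
                              tilt_deg = 0, twist_rate = 0,
                              noise_sigma = 0, seed = 1L) {
  kink_per_helix <- as.numeric(unlist(kink_per_helix))
  if (!is.null(fray_residues))
    fray_residues <- as.integer(unlist(fray_residues))
  if (axis_spacing_s <= 0) .stopf("axis_spacing_s must be > 0")
  if (rise <= 0 || twist <= 0) .stopf("rise and twist must be > 0")
  if (any(kink_per_helix < 0) || any(kink_per_helix >= 180))
    .stopf("kink angles must lie in [0, 180) degrees")
  if (breathing_amplitude < 0) .stopf("breathing_amplitude must be >= 0")
  if (breathing_period <= 0) .stopf("breathing_period must be > 0")
  if (fray_prob < 0 || fray_prob > 1)
    .stopf("fray_prob must lie in [0, 1] (got %g)", fray_prob)
  if (fray_displacement < 0) .stopf("fray_displacement must be >= 0")
  if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  structure(list(axis_spacing_s = axis_spacing_s, rise = rise, twist = twist,
                 kink_per_helix = kink_per_helix,
                 breathing_amplitude = breathing_amplitude,
                 breathing_period = breathing_period,
                 fray_prob = fray_prob, fray_residues = fray_residues,
                 fray_displacement = fray_displacement,
                 tilt_deg = tilt_deg, twist_rate = twist_rate,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "distortion_params")
}

#' Membrane-mode parameters
#'
#' Parameters for the geometric membrane emulation: lateral compression of
#' the bundle to a tighter hexagon and a lipid bead slab with a cylindrical
#' cavity standing in for the lipid toroid around the inserted pore.
#'
#' @param bilayer_thickness slab thickness, Angstrom.
#' @param toroid_inner_radius cavity radius around the bundle, Angstrom.
#' @param compressed_spacing target axis spacing under lateral membrane
#'   pressure, Angstrom; must not exceed the solution-state spacing.
#' @param lipid_bead_density lipid beads per nm^3 in the slab.
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(bilayer_thickness = 40, toroid_inner_radius = 32,
                            compressed_spacing = 15.35,
                            lipid_bead_density = 1.0) {
  if (bilayer_thickness <= 0) .stopf("bilayer_thickness must be > 0")
  if (toroid_inner_radius <= 0) .stopf("toroid_inner_radius must be > 0")
  if (compressed_spacing <= 0) .stopf("compressed_spacing must be > 0")
  if (lipid_bead_density < 0) .stopf("lipid_bead_density must be >= 0")
  structure(list(bilayer_thickness = bilayer_thickness,
                 toroid_inner_radius = toroid_inner_radius,
                 compressed_spacing = compressed_spacing,
                 lipid_bead_density = lipid_bead_density),
            class = "membrane_params")
}

#' Ion/water field parameters
#'
#' Bulk NaCl concentration, water bead density, box dimensions and the
#' lumen density enhancement realised inside a stated cylinder. Defaults
#' follow the membrane-inserted high-salt condition: 1.0 M NaCl in a
#' 160 x 160 x 180 Angstrom box with a sodium lumen enhancement of
#' +0.19 nm^-3 and a water enhancement of +1.8 nm^-3.
#'
#' @param concentration NaCl concentration, mol/L (1 M = 0.6022 nm^-3 per
#'   species).
#' @param lumen_enhancement named numeric vector of added number density
#'   (nm^-3) inside the lumen cylinder, names among `Na`, `Cl`, `water`.
#' @param water_density bulk water bead density, nm^-3 (polarisable
#'   coarse-grained water maps four molecules per bead, bulk ~8.3 nm^-3).
#' @param box box edge lengths `c(Lx, Ly, Lz)` in Angstrom.
#' @param seed RNG seed.
#' @return object of class `ion_field_params`.
#' @export
ion_field_params <- function(concentration = 1.0,
                             lumen_enhancement = c(Na = 0.19, Cl = 0,
                                                   water = 1.8),
                             water_density = 8.3,
                             box = c(160, 160, 180), seed = 1L) {
  if (concentration < 0) .stopf("concentration must be >= 0")
  if (water_density < 0) .stopf("water_density must be >= 0")
  if (length(box) != 3L || any(box <= 0)) .stopf("box edges must be > 0")
  enh <- c(Na = 0, Cl = 0, water = 0)
  if (length(lumen_enhancement)) {
    if (is.null(names(lumen_enhancement)) ||
        !all(names(lumen_enhancement) %in% names(enh)))
      .stopf("lumen_enhancement must be named with species among Na, Cl, water")
    enh[names(lumen_enhancement)] <- lumen_enhancement
  }
  bulk <- .bulk_densities(concentration, water_density)
  if (any(bulk[names(enh)] + enh < 0))
    .stopf("lumen_enhancement would make a species density negative")
  structure(list(concentration = concentration, lumen_enhancement = enh,
                 water_density = water_density, box = as.numeric(box),
                 seed = as.integer(seed)),
            class = "ion_field_params")
}

# bulk number densities (nm^-3) per species implied by the parameters
.bulk_densities <- function(concentration, water_density) {
  # 1 mol/L = 0.60221408 particles / nm^3
  c(Na = concentration * 0.60221408, Cl = concentration * 0.60221408,
    water = water_density)
}

#' Ohmic swap-ledger parameters
#'
#' Ground truth for the computational-electrophysiology event simulator:
#' pore conductance (optionally a mixture of sub-conductance states), the
#' charge-imbalance/voltage schedule across replica ensembles, slice
#' length, total duration and replica count. Defaults reproduce the study
#' design: 30 replicas of 100 ns in 20-ns slices, ten replicas each at
#' charge imbalances of 0, 2 and 4 e holding mean voltages of about 0, 50
#' and 100 mV.
#'
#' @param conductance_G ground-truth conductance(s), nS. A vector together
#'   with `state_probs` defines a mixture of sub-conductance states sampled
#'   independently per slice.
#' @param state_probs mixing probabilities for `conductance_G` states.
#' @param voltage_schedule data.frame with columns `dq` (charge imbalance,
#'   e), `V_mV` (expected slice voltage) and `n_replicas`.
#' @param slice_ns slice duration, ns.
#' @param total_ns replica duration, ns; must be a multiple of `slice_ns`.
#' @param v_jitter_sd per-slice voltage jitter SD about the schedule's
#'   expected value, mV (swap enforcement makes the instantaneous potential
#'   fluctuate sharply; jitter emulates that).
#' @param baseline_rate mean bidirectional (current-neutral) swap events
#'   per slice per species and direction.
#' @param seed RNG seed.
#' @return object of class `ledger_params`.
#' @export
ledger_params <- function(conductance_G = 1.19, state_probs = NULL,
                          voltage_schedule = data.frame(
                            dq = c(0, 2, 4), V_mV = c(0, 50, 100),
                            n_replicas = c(10L, 10L, 10L)),
                          slice_ns = 20, total_ns = 100,
                          v_jitter_sd = 25, baseline_rate = 2, seed = 1L) {
  if (any(conductance_G < 0)) .stopf("conductance_G must be >= 0")
  if (is.null(state_probs)) state_probs <- rep(1, length(conductance_G))
  if (length(state_probs) != length(conductance_G) || any(state_probs < 0) ||
      sum(state_probs) <= 0)
    .stopf("state_probs must be nonnegative weights matching conductance_G")
  if (slice_ns <= 0) .stopf("slice_ns must be > 0")
  n_slices <- total_ns / slice_ns
  if (abs(n_slices - round(n_slices)) > 1e-9)
    .stopf("total_ns must be a multiple of slice_ns")
  need <- c("dq", "V_mV", "n_replicas")
  if (!is.data.frame(voltage_schedule) ||
      !all(need %in% names(voltage_schedule)))
    .stopf("voltage_schedule needs columns dq, V_mV, n_replicas")
  if (v_jitter_sd < 0) .stopf("v_jitter_sd must be >= 0")
  if (baseline_rate < 0) .stopf("baseline_rate must be >= 0")
  structure(list(conductance_G = conductance_G,
                 state_probs = state_probs / sum(state_probs),
                 voltage_schedule = voltage_schedule,
                 slice_ns = slice_ns, total_ns = total_ns,
                 n_slices = as.integer(round(n_slices)),
                 n_replicas = as.integer(sum(voltage_schedule$n_replicas)),
                 v_jitter_sd = v_jitter_sd, baseline_rate = baseline_rate,
                 seed = as.integer(seed)),
            class = "ledger_params")
}
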
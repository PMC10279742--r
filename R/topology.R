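## Bundle topology: the structural address book every analysis keys on.
## One row per bead: helix id, strand (1/2 within the duplex; NA for
## non-strand beads), residue index, role, and the partner bead id for
## paired base beads. Pairing is symmetric and involutive.

#' Build the bead topology of a six-helix bundle
#'
#' Lays out the bead identity table implied by a [strand_map_spec()]:
#' for each duplex, two antiparallel strands whose paired residues
#' (1..`bp_per_duplex`) carry a backbone and a base bead, loop residues
#' (role `"loop"`, one bead, unpaired), and one cholesterol bead per
#' anchored helix at the nick residue. Strand-1 residue `i` pairs
#' strand-2 residue `bp_per_duplex + 1 - i`.
#'
#' Residues above the nick (index <= `nick_residue`) form the "top"
#' region of each helix; the remainder the "bottom" region.
#'
#' @param spec a [strand_map_spec()].
#' @return data.frame of class `bundle_topology` with columns `bead`,
#'   `helix`, `strand`, `residue`, `role`, `partner`.
#' @export
build_topology <- function(spec = strand_map_spec()) {
  stopifnot(inherits(spec, "strand_map_spec"))
  bp <- spec$bp_per_duplex
  n_res <- bp + spec$loop_len
  rows <- vector("list", spec$n_helices * 2L + 1L)
  k <- 0L
  for (h in seq_len(spec$n_helices)) {
    for (s in 1:2) {
      res <- seq_len(n_res)
      paired <- res <= bp
      role <- ifelse(paired, NA_character_, "loop")
      # paired residues: backbone + base bead; loops: single bead
      res_expand <- c(rbind(res[paired], res[paired]), res[!paired])
      role_expand <- c(rep(c("backbone", "base"), sum(paired)),
                       role[!paired])
      k <- k + 1L
      rows[[k]] <- data.frame(helix = h, strand = s, residue = res_expand,
                              role = role_expand,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(spec$cholesterol_helices)) {
    k <- k + 1L
    rows[[k]] <- data.frame(helix = spec$cholesterol_helices,
                            strand = NA_integer_,
                            residue = spec$nick_residue,
                            role = "cholesterol", stringsAsFactors = FALSE)
  }
  topo <- do.call(rbind, rows[seq_len(k)])
  topo <- data.frame(bead = seq_len(nrow(topo)), topo,
                     stringsAsFactors = FALSE)
  # base-bead pairing: strand 1 residue i <-> strand 2 residue bp+1-i
  topo$partner <- NA_integer_
  base1 <- topo$bead[topo$role == "base" & topo$strand == 1L]
  for (b in base1) {
    h <- topo$helix[b]; i <- topo$residue[b]
    p <- topo$bead[topo$role == "base" & topo$strand == 2L &
                     topo$helix == h & topo$residue == (bp + 1L - i)]
    topo$partner[b] <- p
    topo$partner[p] <- b
  }
  attr(topo, "spec") <- spec
  class(topo) <- c("bundle_topology", "data.frame")
  topo
}

#' Table of designed base pairs
#'
#' One row per designed base pair, labelled by the strand-1 residue index
#' (which equals the position along the helix from the top), with the bead
#' ids of the two partnered base beads and the region implied by the nick.
#'
#' @param topology a `bundle_topology`.
#' @param split residue index ending the "top" region (default the spec's
#'   nick residue).
#' @return data.frame with columns `helix`, `pair`, `bead1`, `bead2`,
#'   `region` (`"top"`/`"bottom"`).
#' @export
base_pair_table <- function(topology, split = NULL) {
  spec <- attr(topology, "spec")
  if (is.null(split)) split <- spec$nick_residue
  sel <- topology$role == "base" & topology$strand == 1L &
    !is.na(topology$partner)
  out <- data.frame(helix = topology$helix[sel],
                    pair = topology$residue[sel],
                    bead1 = topology$bead[sel],
                    bead2 = topology$partner[sel])
  out$region <- ifelse(out$pair <= split, "top", "bottom")
  out[order(out$helix, out$pair), , drop = FALSE]
}

# index helper: beads matching role/helix/strand/residue filters
.topo_which <- function(topology, role = NULL, helix = NULL,
                        strand = NULL, residue = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(role)) keep <- keep & topology$role %in% role
  if (!is.null(helix)) keep <- keep & topology$helix %in% helix
  if (!is.null(strand)) keep <- keep & !is.na(topology$strand) &
      topology$strand %in% strand
  if (!is.null(residue)) keep <- keep & topology$residue %in% residue
  which(keep)
}

#' @export
print.bundle_topology <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("bundle_topology: %d beads, %d helices x %d bp (nick at %d)\n",
              nrow(x), spec$n_helices, spec$bp_per_duplex,
              spec$nick_residue))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$role)),
                              table(x$role)), collapse = ", "), "\n")
  invisible(x)
}
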
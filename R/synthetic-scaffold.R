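# Synthetic ideal-geometry mini-protein scaffolds.

#' Configuration for a synthetic scaffold
#'
#' @param n_residues number of residues (>= 3).
#' @param topology `"helix"`, `"hairpin"`, or `"helix-hairpin"`.
#' @param sequence one-letter sequence string, or `"poly-ALA"`.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   part of the config so every generator shares the same contract).
#' @return list of class `scaffold_config`.
#' @export
scaffold_config <- function(n_residues, topology = c("helix", "hairpin",
                                                     "helix-hairpin"),
                            sequence = "poly-ALA", seed = 1L) {
  topology <- match.arg(topology)
  if (n_residues < 3) abort("n_residues must be >= 3")
  if (!identical(sequence, "poly-ALA")) {
    s <- seq_split(sequence)
    if (length(s) != n_residues) {
      abort("sequence length must equal n_residues")
    }
    aa_three(s)  # validates codes
  }
  structure(list(n_residues = as.integer(n_residues), topology = topology,
                 sequence = sequence, seed = as.integer(seed)),
            class = "scaffold_config")
}

# per-residue target phi/psi for a topology
target_phi_psi <- function(n, topology, geom = ideal_geometry()) {
  pp <- geom$phi_psi
  assign_block <- function(kind, m) {
    matrix(rep(unlist(pp[[kind]]), each = m), ncol = 2)
  }
  if (topology == "helix") {
    m <- assign_block("helix", n)
  } else if (topology == "hairpin") {
    n1 <- max(1, (n - 2) %/% 2)
    n2 <- n - 2 - n1
    m <- rbind(assign_block("strand", n1),
               assign_block("turn1", 1), assign_block("turn2", 1),
               assign_block("strand", n2))
  } else {  # helix-hairpin
    nh <- ceiling(n / 2)
    rest <- n - nh
    if (rest < 3) {
      m <- rbind(assign_block("helix", nh), assign_block("strand", rest))
    } else {
      n1 <- max(1, (rest - 2) %/% 2)
      n2 <- rest - 2 - n1
      m <- rbind(assign_block("helix", nh),
                 assign_block("strand", n1),
                 assign_block("turn1", 1), assign_block("turn2", 1),
                 assign_block("strand", n2))
    }
  }
  colnames(m) <- c("phi", "psi")
  m
}

#' Generate an ideal-geometry synthetic scaffold
#'
#' Builds a single-chain backbone with ideal covalent geometry (packaged
#' bond lengths/angles; helix phi/psi = -57/-47, strand -139/+135) and adds
#' native side chains in their first library rotamer. The generator is a
#' pure function of its config: identical configs give identical scaffolds.
#'
#' @param config a [scaffold_config()].
#' @param params force-field parameters (topology table for side chains).
#' @return a [backbone_scaffold()]; the per-residue table records the target
#'   `phi`/`psi` used for construction.
#' @export
make_scaffold <- function(config, params = design_params()) {
  stopifnot(inherits(config, "scaffold_config"))
  n <- config$n_residues
  tpp <- target_phi_psi(n, config$topology)
  seq3 <- if (identical(config$sequence, "poly-ALA")) {
    rep("ALA", n)
  } else {
    aa_three(seq_split(config$sequence))
  }
  bb <- build_backbone(tpp[, "phi"], tpp[, "psi"])
  lib <- default_rotamer_library()
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    m <- bb[[i]]
    res_at <- tibble(res_idx = i, res_id = i, res_name = seq3[i],
                     atom = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
    if (seq3[i] != "GLY") {
      chi <- lib[[seq3[i]]][1, ]
      side <- build_sidechain_xyz(m["N", ], m["CA", ], m["C", ], seq3[i],
                                  chi, params$topology)
      side$res_idx <- i
      side$res_id <- i
      side$res_name <- seq3[i]
      res_at <- bind_rows(res_at, side[, names(res_at)])
    }
    parts[[i]] <- res_at
  }
  atoms <- bind_rows(parts)
  residues <- tibble(res_idx = seq_len(n), res_id = seq_len(n),
                     res_name = seq3, phi = tpp[, "phi"], psi = tpp[, "psi"])
  backbone_scaffold(atoms, residues, chain = "A")
}

#' Backbone phi/psi measured from coordinates
#'
#' @param scaffold a [backbone_scaffold()].
#' @return tibble with `res_idx`, `phi`, `psi` (NA at chain termini).
#' @export
backbone_dihedrals <- function(scaffold) {
  n <- nrow(scaffold$residues)
  get <- function(i, nm) {
    a <- scaffold$atoms
    j <- which(a$res_idx == i & a$atom == nm)[1]
    c(a$x[j], a$y[j], a$z[j])
  }
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral(get(i - 1, "C"), get(i, "N"), get(i, "CA"),
                         get(i, "C"))
    }
    if (i < n) {
      psi[i] <- dihedral(get(i, "N"), get(i, "CA"), get(i, "C"),
                         get(i + 1, "N"))
    }
  }
  tibble(res_idx = seq_len(n), phi = phi, psi = psi)
}
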
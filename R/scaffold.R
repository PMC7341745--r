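# Backbone scaffold container, side-chain building, state realization.

#' Construct a backbone scaffold
#'
#' A `backbone_scaffold` holds the fixed backbone of a single-chain protein:
#' a per-residue table and a per-atom coordinate table (backbone N/CA/C/O
#' plus any native side-chain atoms). The backbone is immutable for design:
#' no operation in the package alters its coordinates.
#'
#' @param atoms tibble with columns `res_idx`, `res_id`, `res_name`, `atom`,
#'   `x`, `y`, `z`.
#' @param residues tibble with columns `res_idx`, `res_id`, `res_name` and
#'   optionally `phi`, `psi` (target dihedrals for synthetic scaffolds).
#' @param chain single chain identifier.
#' @return object of class `backbone_scaffold`.
#' @export
backbone_scaffold <- function(atoms, residues, chain = "A") {
  atoms <- as_tibble(atoms)
  residues <- as_tibble(residues)
  if (nrow(residues) < 1) abort("scaffold must contain at least one residue")
  if (any(diff(residues$res_id) <= 0)) {
    abort("residue ids must be strictly increasing")
  }
  bb <- c("N", "CA", "C", "O")
  for (i in residues$res_idx) {
    have <- atoms$atom[atoms$res_idx == i]
    missing <- setdiff(bb, have)
    if (length(missing)) {
      abort(paste0("residue ", residues$res_id[residues$res_idx == i],
                   " (", residues$res_name[residues$res_idx == i],
                   ") is missing backbone atom(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  # chain connectivity: consecutive C-N distances
  n <- nrow(residues)
  if (n > 1) {
    Cx <- atoms[atoms$atom == "C", ]
    Nx <- atoms[atoms$atom == "N", ]
    Cx <- Cx[order(Cx$res_idx), ]
    Nx <- Nx[order(Nx$res_idx), ]
    d <- sqrt((Cx$x[-n] - Nx$x[-1])^2 + (Cx$y[-n] - Nx$y[-1])^2 +
                (Cx$z[-n] - Nx$z[-1])^2)
    if (any(d >= 2.0)) {
      abort(paste0("chain break: C-N distance >= 2 A after residue ",
                   paste(residues$res_id[which(d >= 2.0)], collapse = ", ")))
    }
  }
  structure(list(atoms = atoms, residues = residues, chain = chain),
            class = "backbone_scaffold")
}

#' @export
print.backbone_scaffold <- function(x, ...) {
  cat("<backbone_scaffold>", nrow(x$residues), "residues, chain", x$chain,
      "\n  sequence:",
      paste(aa_one(x$residues$res_name), collapse = ""), "\n")
  invisible(x)
}

#' @export
length.backbone_scaffold <- function(x) nrow(x$residues)

# backbone N/CA/C coordinates of residue i as a 3 x 3 matrix
bb_frame <- function(scaffold, i) {
  a <- scaffold$atoms
  sel <- a$res_idx == i & a$atom %in% c("N", "CA", "C")
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$atom[sel]
  m[c("N", "CA", "C"), , drop = FALSE]
}

#' Build side-chain coordinates on the fixed backbone
#'
#' Places the side-chain heavy atoms of `type` at scaffold position
#' `position` by sequential internal-coordinate construction: ideal bond
#' lengths and angles from the packaged topology table, and the requested
#' chi dihedrals. Building then measuring is the identity on chi.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param position residue index (1-based position in the chain).
#' @param type three-letter amino-acid code (not `"GLY"`).
#' @param chi numeric vector of chi angles in degrees; its length must match
#'   the type's chi count.
#' @param params force-field parameter set (for the topology table).
#' @return tibble with columns `atom`, `x`, `y`, `z`.
#' @export
build_sidechain <- function(scaffold, position, type, chi = numeric(),
                            params = design_params()) {
  type <- toupper(type)
  if (type == "GLY") abort("GLY has no side chain to build")
  if (!type %in% AA3) abort(paste0("unknown residue type: ", type))
  nchi <- chi_counts(params$topology)[[type]]
  if (length(chi) != nchi) {
    abort(paste0(type, " expects ", nchi, " chi angle(s), got ", length(chi)))
  }
  fr <- bb_frame(scaffold, position)
  build_sidechain_xyz(fr["N", ], fr["CA", ], fr["C", ], type, chi,
                      params$topology)
}

# core builder from explicit backbone coordinates; returns tibble
build_sidechain_xyz <- function(N, CA, C, type, chi, topo) {
  rows <- topo[topo$res == type, , drop = FALSE]
  coords <- list(N = N, CA = CA, C = C)
  out_atom <- character(nrow(rows))
  out_xyz <- matrix(0, nrow(rows), 3)
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    tor <- r$tor_offset
    if (r$tor_base != "") {
      idx <- as.integer(substring(r$tor_base, 4))
      tor <- tor + chi[idx]
    }
    p <- place_atom(coords[[r$p1]], coords[[r$p2]], coords[[r$p3]],
                    r$length, r$angle, tor)
    coords[[r$atom]] <- p
    out_atom[k] <- r$atom
    out_xyz[k, ] <- p
  }
  tibble(atom = out_atom, x = out_xyz[, 1], y = out_xyz[, 2],
         z = out_xyz[, 3])
}

#' Measure chi dihedrals of a built residue
#'
#' Recomputes the chi angles of a residue from explicit coordinates, using
#' the same topology definitions as [build_sidechain()].
#'
#' @param atoms tibble of the residue's atoms (`atom`, `x`, `y`, `z`),
#'   backbone included.
#' @param type three-letter code.
#' @param params parameter set.
#' @return numeric vector of chi angles in degrees.
#' @export
measure_chi <- function(atoms, type, params = design_params()) {
  topo <- params$topology
  rows <- topo[topo$res == type & topo$tor_base != "", , drop = FALSE]
  if (nrow(rows) == 0) return(numeric())
  rows <- rows[rows$tor_offset == 0, , drop = FALSE]  # defining atom of each chi
  rows <- rows[!duplicated(rows$tor_base), , drop = FALSE]
  rows <- rows[order(as.integer(substring(rows$tor_base, 4))), , drop = FALSE]
  get <- function(nm) {
    i <- match(nm, atoms$atom)
    if (is.na(i)) abort(paste0("atom ", nm, " absent"))
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  vapply(seq_len(nrow(rows)), function(k) {
    r <- rows[k, ]
    dihedral(get(r$p3), get(r$p2), get(r$p1), get(r$atom))
  }, numeric(1))
}

#' Create a (sequence, rotamer) design state
#'
#' A `system_state` is one point of the design space: an amino-acid type and
#' a rotamer index for every position, attached to a fixed scaffold and a
#' design specification. Frozen and rotamer-only positions must carry the
#' native type; mutable positions must carry an allowed type.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param spec a [make_design_spec()] result.
#' @param sequence character vector of three-letter codes (default: native).
#' @param rotamers integer vector of rotamer indices (default: all 1).
#' @param library rotamer library.
#' @return object of class `system_state`.
#' @export
system_state <- function(scaffold, spec, sequence = NULL, rotamers = NULL,
                         library = default_rotamer_library()) {
  n <- nrow(scaffold$residues)
  sequence <- sequence %||% scaffold$residues$res_name
  rotamers <- rotamers %||% rep(1L, n)
  if (length(sequence) != n || length(rotamers) != n) {
    abort("sequence and rotamer vectors must match the scaffold length")
  }
  native <- scaffold$residues$res_name
  for (i in seq_len(n)) {
    cls <- spec$class[i]
    if (cls %in% c("frozen", "rotamer_only") && sequence[i] != native[i]) {
      abort(paste0("position ", spec$res_id[i], " is ", cls,
                   " and must keep its native type ", native[i]))
    }
    if (cls == "mutable" && !sequence[i] %in% spec$allowed[[i]]) {
      abort(paste0("type ", sequence[i], " not allowed at position ",
                   spec$res_id[i]))
    }
    nr <- nrow(library[[sequence[i]]])
    if (rotamers[i] < 1 || rotamers[i] > nr) {
      abort(paste0("rotamer index ", rotamers[i], " out of range for ",
                   sequence[i], " at position ", spec$res_id[i]))
    }
  }
  structure(list(scaffold = scaffold, spec = spec, sequence = sequence,
                 rotamers = as.integer(rotamers), library = library),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat("<system_state>", paste(aa_one(x$sequence), collapse = ""), "\n")
  invisible(x)
}

#' Native reference state of a scaffold
#'
#' The native sequence in each type's first library rotamer, constructed
#' without design-spec validation (the native type at a position need not
#' be among that position's allowed types). This is the reference state
#' whose environment the NEA solvation model freezes.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param spec a design spec (carried along, not used for validation).
#' @param library rotamer library.
#' @return a `system_state`.
#' @export
native_state <- function(scaffold, spec = NULL,
                         library = default_rotamer_library()) {
  structure(list(scaffold = scaffold, spec = spec,
                 sequence = scaffold$residues$res_name,
                 rotamers = rep(1L, nrow(scaffold$residues)),
                 library = library),
            class = "system_state")
}

#' Realize a state into full-atom coordinates
#'
#' Backbone coordinates are taken verbatim from the scaffold; every
#' side chain is built from its type and rotamer by internal-coordinate
#' construction. Two states differing at one position differ only in that
#' residue's side-chain atoms.
#'
#' @param state a [system_state()].
#' @param params force-field parameters.
#' @return tibble with columns `res_idx`, `res_name`, `atom`, `x`, `y`, `z`.
#' @export
realize_state <- function(state, params = design_params()) {
  sc <- state$scaffold
  topo <- params$topology
  n <- nrow(sc$residues)
  bb <- sc$atoms[sc$atoms$atom %in% c("N", "CA", "C", "O"), ]
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    t3 <- state$sequence[i]
    res_bb <- bb[bb$res_idx == i, c("res_idx", "atom", "x", "y", "z")]
    res_bb$res_name <- t3
    if (t3 == "GLY") {
      parts[[i]] <- res_bb
    } else {
      chi <- state$library[[t3]][state$rotamers[i], ]
      fr <- bb_frame(sc, i)
      side <- build_sidechain_xyz(fr["N", ], fr["CA", ], fr["C", ], t3,
                                  chi, topo)
      side$res_idx <- i
      side$res_name <- t3
      parts[[i]] <- bind_rows(res_bb, side[, names(res_bb)])
    }
  }
  out <- bind_rows(parts)
  out[, c("res_idx", "res_name", "atom", "x", "y", "z")]
}
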
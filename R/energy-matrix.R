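# Pairwise energy matrix for the frozen-environment (NEA) energy.

# terms for a single residue block in isolation
self_terms <- function(at, B, params) {
  D <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
  sc <- scale_mats(at, params)
  sum(block_terms(at, B, D, sc, seq_len(nrow(at)), NULL, params))
}

# interaction terms between two residue blocks
joint_pair_terms <- function(at1, B1, at2, B2, params) {
  ap <- rbind(at1, at2)
  B <- c(B1, B2)
  D <- as.matrix(stats::dist(as.matrix(ap[, c("x", "y", "z")])))
  sc <- scale_mats(ap, params)
  sum(block_terms(ap, B, D, sc, seq_len(nrow(at1)),
                  nrow(at1) + seq_len(nrow(at2)), params))
}

# atoms (with parameters) of one residue for a given type/rotamer choice
choice_atoms <- function(scaffold, i, type, rot, library, params) {
  bb <- scaffold$atoms[scaffold$atoms$res_idx == i &
                         scaffold$atoms$atom %in% c("N", "CA", "C", "O"),
                       c("res_idx", "atom", "x", "y", "z")]
  bb$res_name <- type
  at <- bb
  if (type != "GLY") {
    chi <- library[[type]][rot, ]
    fr <- bb_frame(scaffold, i)
    side <- build_sidechain_xyz(fr["N", ], fr["CA", ], fr["C", ], type, chi,
                                params$topology)
    side$res_idx <- i
    side$res_name <- type
    at <- bind_rows(bb, side[, names(bb)])
  }
  assign_ff_params(at[, c("res_idx", "res_name", "atom", "x", "y", "z")],
                   params)
}

#' Precompute the NEA pairwise energy matrix
#'
#' In the frozen-environment model the folded-state energy is exactly a
#' constant plus per-position self terms plus position-pair terms, because
#' Born radii, the screened Coulomb/LJ sums and the pairwise surface model
#' all decompose over residue pairs. This function evaluates every
#' (position, type, rotamer) self term and every pair term once, after
#' which any state's energy is a table lookup. The decomposition is only
#' defined for the NEA mode; the fluctuating-boundary energy is many-body
#' and a request for it raises an error.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param spec a [make_design_spec()] result.
#' @param library rotamer library.
#' @param params force-field parameters.
#' @param mode must be `"NEA"`.
#' @return object of class `energy_matrix`.
#' @export
precompute_energy_matrix <- function(scaffold, spec,
                                     library = default_rotamer_library(),
                                     params = design_params(),
                                     mode = "NEA") {
  if (!identical(mode, "NEA")) {
    abort("the energy-matrix decomposition exists only in NEA mode (the fluctuating-boundary energy is many-body)")
  }
  nat_state <- native_state(scaffold, spec, library)
  nat <- assign_ff_params(realize_state(nat_state, params), params)
  B_nat <- born_radii(nat, params, mode = "NEA", native_atoms = nat)
  design_pos <- spec$res_idx[spec$class != "frozen"]
  frozen_pos <- spec$res_idx[spec$class == "frozen"]

  # choice sets
  choices <- lapply(design_pos, function(i) {
    cls <- spec$class[spec$res_idx == i]
    types <- if (cls == "mutable") spec$allowed[[which(spec$res_idx == i)]]
             else spec$native_type[spec$res_idx == i]
    bind_rows(lapply(types, function(t3) {
      tibble(type = t3, rot = seq_len(nrow(library[[t3]])))
    }))
  })
  names(choices) <- as.character(design_pos)

  # frozen-frozen constant (self + pairs), using native NEA radii
  frozen_atoms <- lapply(frozen_pos, function(i) {
    list(at = nat[nat$res_idx == i, , drop = FALSE],
         B = B_nat[nat$res_idx == i])
  })
  e_bb <- 0
  nf <- length(frozen_atoms)
  if (nf > 0) {
    for (a in seq_len(nf)) {
      e_bb <- e_bb + self_terms(frozen_atoms[[a]]$at, frozen_atoms[[a]]$B,
                                params)
      if (a < nf) {
        for (b in seq(a + 1, nf)) {
          e_bb <- e_bb + joint_pair_terms(frozen_atoms[[a]]$at,
                                          frozen_atoms[[a]]$B,
                                          frozen_atoms[[b]]$at,
                                          frozen_atoms[[b]]$B, params)
        }
      }
    }
  }

  # per-choice atoms and Born radii
  cache <- lapply(seq_along(design_pos), function(pi) {
    i <- design_pos[pi]
    ch <- choices[[pi]]
    lapply(seq_len(nrow(ch)), function(k) {
      at <- choice_atoms(scaffold, i, ch$type[k], ch$rot[k], library, params)
      B <- born_radii(at, params, mode = "NEA", native_atoms = nat)
      list(at = at, B = B)
    })
  })

  # self terms: intra-residue plus interactions with all frozen residues
  e_self <- lapply(seq_along(design_pos), function(pi) {
    vapply(cache[[pi]], function(cc) {
      e <- self_terms(cc$at, cc$B, params)
      for (f in frozen_atoms) {
        e <- e + joint_pair_terms(cc$at, cc$B, f$at, f$B, params)
      }
      e
    }, numeric(1))
  })

  # pair terms for i < j
  np <- length(design_pos)
  e_pair <- vector("list", np)
  for (a in seq_len(np)) {
    e_pair[[a]] <- vector("list", np)
    if (a < np) {
      for (b in seq(a + 1, np)) {
        m <- matrix(0, nrow(choices[[a]]), nrow(choices[[b]]))
        for (ka in seq_len(nrow(choices[[a]]))) {
          for (kb in seq_len(nrow(choices[[b]]))) {
            m[ka, kb] <- joint_pair_terms(cache[[a]][[ka]]$at,
                                          cache[[a]][[ka]]$B,
                                          cache[[b]][[kb]]$at,
                                          cache[[b]][[kb]]$B, params)
          }
        }
        e_pair[[a]][[b]] <- m
      }
    }
  }

  structure(list(positions = design_pos, frozen = frozen_pos,
                 choices = choices, e_bb = e_bb, e_self = e_self,
                 e_pair = e_pair),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  nc <- vapply(x$choices, nrow, integer(1))
  cat("<energy_matrix>", length(x$positions), "designable positions,",
      "choices:", paste(nc, collapse = "/"),
      sprintf("; E_bb = %.4f kcal/mol\n", x$e_bb))
  invisible(x)
}

# choice index of (type, rot) at matrix position pi
choice_index <- function(em, pi, type, rot) {
  ch <- em$choices[[pi]]
  k <- which(ch$type == type & ch$rot == rot)
  if (length(k) != 1) {
    abort(paste0("no choice ", type, "/", rot, " at position ",
                 em$positions[pi]))
  }
  k
}

# state -> per-position choice indices
state_choice_vector <- function(em, state) {
  vapply(seq_along(em$positions), function(pi) {
    i <- em$positions[pi]
    choice_index(em, pi, state$sequence[i], state$rotamers[i])
  }, integer(1))
}

#' Reconstruct a state's NEA energy from the matrix
#'
#' `E = E_bb + sum_i e_i + sum_(i<j) e_ij`; equal to
#' `folded_energy(state, mode = "NEA")$total` for every state.
#'
#' @param em an [precompute_energy_matrix()] result.
#' @param state a [system_state()] (or an integer choice vector).
#' @return total energy, kcal/mol.
#' @export
energy_from_matrix <- function(em, state) {
  cv <- if (inherits(state, "system_state")) state_choice_vector(em, state)
        else as.integer(state)
  np <- length(em$positions)
  e <- em$e_bb
  for (a in seq_len(np)) {
    e <- e + em$e_self[[a]][cv[a]]
    if (a < np) {
      for (b in seq(a + 1, np)) {
        e <- e + em$e_pair[[a]][[b]][cv[a], cv[b]]
      }
    }
  }
  e
}

# energy change for replacing choice cv[p] by knew (used by the MC kernel)
matrix_delta <- function(em, cv, p, knew) {
  d <- em$e_self[[p]][knew] - em$e_self[[p]][cv[p]]
  np <- length(em$positions)
  if (np > 1) {
    for (q in seq_len(np)) {
      if (q == p) next
      if (q > p) {
        d <- d + em$e_pair[[p]][[q]][knew, cv[q]] -
          em$e_pair[[p]][[q]][cv[p], cv[q]]
      } else {
        d <- d + em$e_pair[[q]][[p]][cv[q], knew] -
          em$e_pair[[q]][[p]][cv[q], cv[p]]
      }
    }
  }
  d
}
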
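# Extended-peptide unfolded-state model and the folding energy difference.

#' Calibrate per-type extended-state energies
#'
#' For every amino-acid type, builds an Ala-X-Ala tripeptide on an extended
#' backbone (phi/psi = -139/+135), evaluates the central residue's energy
#' contribution (its intra-residue terms plus its interactions with the two
#' flanking residues, with fluctuating-boundary Born radii computed on the
#' tripeptide) for each rotamer in the library, and stores the minimum.
#' Proline's pyrrolidine ring excludes the generic extended phi, so its
#' reference conformation is polyproline-II (phi/psi = -75/+145). The
#' result is deterministic.
#'
#' @param params force-field parameters.
#' @param library rotamer library.
#' @return named numeric vector `E_ext` over the 20 three-letter codes,
#'   kcal/mol.
#' @export
calibrate_extended_energies <- function(params = design_params(),
                                        library = default_rotamer_library()) {
  mk_atoms <- function(types, rots) {
    central <- if (types[2] == "PRO") c(-75, 145) else c(-139, 135)
    bb <- build_backbone(c(-139, central[1], -139),
                         c(135, central[2], 135))
    parts <- lapply(1:3, function(i) {
      m <- bb[[i]]
      at <- tibble(res_idx = i, res_name = types[i], atom = rownames(m),
                   x = m[, 1], y = m[, 2], z = m[, 3])
      if (types[i] != "GLY") {
        chi <- library[[types[i]]][rots[i], ]
        side <- build_sidechain_xyz(m["N", ], m["CA", ], m["C", ], types[i],
                                    chi, params$topology)
        side$res_idx <- i
        side$res_name <- types[i]
        at <- bind_rows(at, side[, names(at)])
      }
      at
    })
    assign_ff_params(bind_rows(parts), params)
  }
  central_contribution <- function(t3, rot) {
    ap <- mk_atoms(c("ALA", t3, "ALA"), c(1, rot, 1))
    B <- born_radii(ap, params, mode = "FDB")
    D <- as.matrix(stats::dist(as.matrix(ap[, c("x", "y", "z")])))
    sc <- scale_mats(ap, params)
    i2 <- which(ap$res_idx == 2)
    e <- sum(block_terms(ap, B, D, sc, i2, NULL, params))
    for (j in c(1, 3)) {
      e <- e + sum(block_terms(ap, B, D, sc, i2, which(ap$res_idx == j),
                               params))
    }
    e
  }
  vapply(setNames(AA3, AA3), function(t3) {
    nrot <- nrow(library[[t3]])
    min(vapply(seq_len(nrot), function(r) central_contribution(t3, r),
               numeric(1)))
  }, numeric(1))
}

#' Unfolded-state model
#'
#' Per-type extended-state energies plus per-type chemical potentials. The
#' chemical potentials default to zero and act as composition controls: a
#' shift of `mu` for one type shifts the folding energy of any sequence by
#' minus the shift times that type's count, and nothing else.
#'
#' @param e_ext named vector over the 20 types (default: calibrated once
#'   and cached).
#' @param mu named vector of chemical potentials; missing types are 0.
#' @return object of class `unfolded_model`.
#' @export
unfolded_model <- function(e_ext = NULL, mu = NULL) {
  if (is.null(e_ext)) {
    if (is.null(the$e_ext)) the$e_ext <- calibrate_extended_energies()
    e_ext <- the$e_ext
  }
  if (!all(AA3 %in% names(e_ext))) abort("e_ext must cover all 20 types")
  mu_full <- setNames(numeric(20), AA3)
  if (!is.null(mu)) {
    nm <- names(mu)
    if (is.null(nm) || !all(nm %in% AA3)) {
      abort("mu must be named with three-letter codes")
    }
    mu_full[nm] <- mu
  }
  structure(list(e_ext = e_ext[AA3], mu = mu_full), class = "unfolded_model")
}

#' @export
print.unfolded_model <- function(x, ...) {
  cat("<unfolded_model> extended-peptide reference; mu non-zero for",
      sum(x$mu != 0), "type(s)\n")
  invisible(x)
}

#' Unfolded-state energy of a sequence
#'
#' Strictly additive and conformation-independent:
#' `sum_i E_ext(type_i) + mu(type_i)`.
#'
#' @param sequence character vector of three-letter codes (or a one-letter
#'   string).
#' @param model an [unfolded_model()].
#' @return energy in kcal/mol.
#' @export
unfolded_energy <- function(sequence, model = unfolded_model()) {
  s <- sequence
  if (length(s) == 1 && nchar(s[1]) > 3) s <- aa_three(seq_split(s))
  if (length(s) == 0) abort("sequence must be non-empty")
  if (!all(s %in% AA3)) s <- aa_three(s)
  sum(model$e_ext[s]) + sum(model$mu[s])
}

#' Folding energy of a design state
#'
#' The design objective: folded-state total minus unfolded-state energy.
#' Lower values are more favourable.
#'
#' @param state a [system_state()].
#' @param model an [unfolded_model()].
#' @param params force-field parameters.
#' @param mode `"NEA"` or `"FDB"`.
#' @param native_state NEA reference state (see [folded_energy()]).
#' @return list of class `folding_energy`: `e_folded`, `e_unfolded`,
#'   `delta`, `mode`.
#' @export
folding_energy <- function(state, model = unfolded_model(),
                           params = design_params(),
                           mode = c("NEA", "FDB"), native_state = NULL) {
  mode <- match.arg(mode)
  ef <- folded_energy(state, params, mode, native_state)$total
  eu <- unfolded_energy(state$sequence, model)
  structure(list(e_folded = ef, e_unfolded = eu, delta = ef - eu,
                 mode = mode),
            class = "folding_energy")
}

#' @export
print.folding_energy <- function(x, ...) {
  cat(sprintf("<folding_energy> delta = %.4f kcal/mol (%s mode)\n",
              x$delta, x$mode))
  invisible(x)
}
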
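# Folded-state energy: LJ + screened Coulomb + GB polarization + surface
# term, with a residue-blocked evaluation that yields the NEA pair matrix.

#' Attach force-field parameters to realized atoms
#'
#' Adds partial charge `q`, LJ `sig`/`eps`, intrinsic GB radius `rho` and
#' surface tension `tens` columns, keyed by residue type and atom name
#' (element inferred from the atom-name first letter).
#'
#' @param atoms realized atom table (see [realize_state()]).
#' @param params force-field parameters.
#' @return the atom table with parameter columns appended.
#' @export
assign_ff_params <- function(atoms, params = design_params()) {
  elem <- substr(atoms$atom, 1, 1)
  pe <- params$atoms
  m <- match(elem, pe$elem)
  if (anyNA(m)) {
    abort(paste0("no element parameters for atom(s): ",
                 paste(unique(atoms$atom[is.na(m)]), collapse = ", ")))
  }
  ch <- params$charges
  key <- ifelse(atoms$atom %in% c("N", "CA", "C", "O"), "BB", atoms$res_name)
  cm <- match(paste(key, atoms$atom), paste(ch$res, ch$atom))
  if (anyNA(cm)) {
    abort(paste0("no charge parameters for: ",
                 paste(unique(paste(key, atoms$atom)[is.na(cm)]),
                       collapse = ", ")))
  }
  atoms$q <- ch$q[cm]
  atoms$sig <- pe$sigma[m]
  atoms$eps <- pe$eps[m]
  atoms$rho <- pe$rho_gb[m]
  atoms$tens <- pe$tension[m]
  atoms
}

# ring-closure bonds not expressible in the z-matrix topology
RING_CLOSURES <- list(
  PRO = list(c("CD", "N")),
  HIS = list(c("NE2", "CD2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("CE2", "CD2"), c("CH2", "CZ3")))

# covalent bond list (atom-index pairs) for an atom table; backbone bonds,
# the inter-residue peptide C-N bond, side-chain bonds from topology, and
# ring closures
bond_list <- function(atoms, topo) {
  idx <- function(res, name) {
    which(atoms$res_idx == res & atoms$atom == name)[1]
  }
  bonds <- list()
  k <- 0
  add <- function(i, j) {
    if (!is.na(i) && !is.na(j)) {
      k <<- k + 1
      bonds[[k]] <<- c(i, j)
    }
  }
  for (res in unique(atoms$res_idx)) {
    add(idx(res, "N"), idx(res, "CA"))
    add(idx(res, "CA"), idx(res, "C"))
    add(idx(res, "C"), idx(res, "O"))
    nxt <- res + 1
    if (any(atoms$res_idx == nxt)) add(idx(res, "C"), idx(nxt, "N"))
    t3 <- atoms$res_name[atoms$res_idx == res][1]
    rows <- topo[topo$res == t3, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      add(idx(res, rows$atom[r]), idx(res, rows$p1[r]))
    }
    for (cl in RING_CLOSURES[[t3]] %||% list()) {
      add(idx(res, cl[1]), idx(res, cl[2]))
    }
  }
  if (k == 0) return(matrix(integer(), 0, 2))
  do.call(rbind, bonds)
}

# pair scale matrices from the bonded topology: 1-2/1-3 excluded (0),
# 1-4 scaled, others 1; returns list(lj, coul)
scale_mats <- function(atoms, params) {
  n <- nrow(atoms)
  A <- matrix(FALSE, n, n)
  b <- bond_list(atoms, params$topology)
  if (nrow(b) > 0) {
    A[b] <- TRUE
    A[b[, 2:1, drop = FALSE]] <- TRUE
  }
  A1 <- A
  A2 <- (A %*% A) > 0
  A3 <- (A2 %*% A) > 0
  excl <- A1 | A2
  diag(excl) <- TRUE
  onefour <- A3 & !excl
  s_lj <- matrix(1, n, n)
  s_lj[excl] <- 0
  s_lj[onefour] <- params$global$scale14_lj
  s_c <- matrix(1, n, n)
  s_c[excl] <- 0
  s_c[onefour] <- params$global$scale14_coul
  list(lj = s_lj, coul = s_c)
}

# residue-blocked energy terms over an atom table with parameters and Born
# radii; idx_i/idx_j are atom index vectors of the two blocks (idx_j NULL
# for a self block). Returns c(lj, coul, gb, surf).
block_terms <- function(ap, B, D, sc, idx_i, idx_j, params) {
  g <- params$global
  contrast <- 1 / g$eps_p - 1 / g$eps_w
  Ra <- ap$rho + g$probe
  if (is.null(idx_j)) {
    ii <- idx_i
    ni <- length(ii)
    lj <- coul <- gb <- 0
    if (ni > 1) {
      pr <- which(upper.tri(matrix(0, ni, ni)), arr.ind = TRUE)
      a <- ii[pr[, 1]]
      b <- ii[pr[, 2]]
      r <- D[cbind(a, b)]
      sig <- (ap$sig[a] + ap$sig[b]) / 2
      epsv <- sqrt(ap$eps[a] * ap$eps[b])
      sr6 <- (sig / r)^6
      lj <- sum(sc$lj[cbind(a, b)] * 4 * epsv * (sr6^2 - sr6))
      coul <- sum(sc$coul[cbind(a, b)] * g$k_coul * ap$q[a] * ap$q[b] /
                    (g$eps_p * r))
      gb <- -g$k_coul * contrast *
        sum(ap$q[a] * ap$q[b] / f_gb(r, B[a], B[b]))
    }
    gb <- gb - (g$k_coul / 2) * contrast * sum(ap$q[ii]^2 / B[ii])
    # surface: self spheres minus intra-block burial
    surf <- sum(ap$tens[ii] * 4 * pi * Ra[ii]^2)
    if (ni > 1) {
      for (a in ii) {
        oth <- setdiff(ii, a)
        surf <- surf - g$burial_scale * ap$tens[a] *
          sum(cap_area(D[a, oth], Ra[a], Ra[oth]))
      }
    }
    c(lj, coul, gb, surf)
  } else {
    a <- rep(idx_i, times = length(idx_j))
    b <- rep(idx_j, each = length(idx_i))
    r <- D[cbind(a, b)]
    sig <- (ap$sig[a] + ap$sig[b]) / 2
    epsv <- sqrt(ap$eps[a] * ap$eps[b])
    sr6 <- (sig / r)^6
    lj <- sum(sc$lj[cbind(a, b)] * 4 * epsv * (sr6^2 - sr6))
    coul <- sum(sc$coul[cbind(a, b)] * g$k_coul * ap$q[a] * ap$q[b] /
                  (g$eps_p * r))
    gb <- -g$k_coul * contrast * sum(ap$q[a] * ap$q[b] / f_gb(r, B[a], B[b]))
    surf <- -g$burial_scale *
      sum(ap$tens[a] * cap_area(r, Ra[a], Ra[b]) +
            ap$tens[b] * cap_area(r, Ra[b], Ra[a]))
    c(lj, coul, gb, surf)
  }
}

#' Folded-state energy of a design state
#'
#' Lennard-Jones plus Coulomb (screened by the protein dielectric, 1-2/1-3
#' pairs excluded, 1-4 scaled) over all nonbonded atom pairs, plus the GB
#' polarization energy, plus the surface-tension-weighted pairwise
#' accessible areas. In `FDB` mode Born radii are recomputed from the
#' current state; in `NEA` mode each residue's radii come from its own
#' atoms in the frozen native environment.
#'
#' @param state a [system_state()].
#' @param params force-field parameters.
#' @param mode `"NEA"` or `"FDB"`.
#' @param native_state reference state defining the NEA environment
#'   (default: the native sequence in its first rotamers).
#' @return list of class `energy_breakdown` with components `lj`,
#'   `coulomb`, `gb_polarization`, `nonpolar_surface`, `total` (kcal/mol).
#' @export
folded_energy <- function(state, params = design_params(),
                          mode = c("NEA", "FDB"), native_state = NULL) {
  mode <- match.arg(mode)
  ap <- assign_ff_params(realize_state(state, params), params)
  if (mode == "NEA") {
    native_state <- native_state %||% native_state(state$scaffold, state$spec,
                                                   state$library)
    nat <- assign_ff_params(realize_state(native_state, params), params)
    B <- born_radii(ap, params, mode = "NEA", native_atoms = nat)
  } else {
    B <- born_radii(ap, params, mode = "FDB")
  }
  D <- as.matrix(stats::dist(as.matrix(ap[, c("x", "y", "z")])))
  sc <- scale_mats(ap, params)
  resv <- unique(ap$res_idx)
  tot <- c(0, 0, 0, 0)
  for (i in seq_along(resv)) {
    ii <- which(ap$res_idx == resv[i])
    tot <- tot + block_terms(ap, B, D, sc, ii, NULL, params)
    if (i < length(resv)) {
      for (j in seq(i + 1, length(resv))) {
        jj <- which(ap$res_idx == resv[j])
        tot <- tot + block_terms(ap, B, D, sc, ii, jj, params)
      }
    }
  }
  energy_breakdown(tot)
}

energy_breakdown <- function(v) {
  structure(list(lj = v[1], coulomb = v[2], gb_polarization = v[3],
                 nonpolar_surface = v[4], total = sum(v)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<energy_breakdown> total %.4f kcal/mol\n  LJ %.4f | ",
                     "Coulomb %.4f | GB %.4f | surface %.4f\n"),
              x$total, x$lj, x$coulomb, x$gb_polarization,
              x$nonpolar_surface))
  invisible(x)
}

#' @export
tidy.energy_breakdown <- function(x, ...) {
  tibble(term = c("lj", "coulomb", "gb_polarization", "nonpolar_surface",
                  "total"),
         energy = c(x$lj, x$coulomb, x$gb_polarization, x$nonpolar_surface,
                    x$total))
}
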
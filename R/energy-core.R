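# Elementary energy terms: Lennard-Jones, HCT Born radii, GB polarization,
# and accessible surface areas (numerical Shrake-Rupley and the analytic
# pairwise model used inside the folded-state energy).

#' Lennard-Jones pair energy
#'
#' `4*eps*((sigma/r)^12 - (sigma/r)^6)` with Lorentz-Berthelot combining
#' (arithmetic mean sigma, geometric mean eps) when two parameter sets are
#' given.
#'
#' @param r distance in Angstrom (> 0); vectorized.
#' @param sigma1,eps1 LJ parameters of the first atom.
#' @param sigma2,eps2 LJ parameters of the second atom (default: same).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(r, sigma1, eps1, sigma2 = sigma1, eps2 = eps1) {
  if (any(r <= 0)) abort("r must be > 0")
  sig <- (sigma1 + sigma2) / 2
  eps <- sqrt(eps1 * eps2)
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6)
}

# HCT pairwise-descreening integral: contribution of a neighbour sphere
# (scaled radius s, centre distance r) to the inverse Born radius of an
# atom with intrinsic radius rho. Vectorized over r and s.
hct_integral <- function(r, s, rho) {
  U <- r + s
  out <- numeric(length(r))
  act <- U > rho & s > 0
  if (!any(act)) return(out)
  r1 <- r[act]
  s1 <- s[act]
  L <- pmax(rho, abs(r1 - s1))
  base <- 0.5 * (1 / L - 1 / U[act]) +
    (r1^2 - s1^2) / (8 * r1) * (1 / U[act]^2 - 1 / L^2) +
    log(L / U[act]) / (4 * r1)
  engulf <- (s1 - r1) > rho
  base[engulf] <- base[engulf] + 1 / rho - 1 / (s1[engulf] - r1[engulf])
  out[act] <- base
  out
}

#' Effective Born radii by pairwise descreening
#'
#' Computes per-atom effective Born radii with Hawkins-Cramer-Truhlar
#' pairwise descreening. In `FDB` mode (fluctuating dielectric boundary)
#' each atom is descreened by all other atoms of the current state, so the
#' dielectric environment follows every mutation and rotamer move. In `NEA`
#' mode (native environment approximation) each atom is descreened by its
#' own residue's current atoms plus the *native* atoms of all other
#' residues: the radii assigned to a residue state are then independent of
#' the rest of the query state, which is what makes the NEA energy exactly
#' pairwise-decomposable.
#'
#' @param atoms realized atom table (from [realize_state()]) with parameter
#'   columns attached (see [assign_ff_params()]).
#' @param params force-field parameters.
#' @param mode `"FDB"` or `"NEA"`.
#' @param native_atoms realized native-state atom table with parameters
#'   (required for `NEA`).
#' @return numeric vector of Born radii (Angstrom), with attribute
#'   `provenance` (`"FDB-current"` or `"NEA-frozen"`).
#' @export
born_radii <- function(atoms, params = design_params(),
                       mode = c("FDB", "NEA"), native_atoms = NULL) {
  mode <- match.arg(mode)
  need <- c("x", "y", "z", "rho")
  if (!all(need %in% names(atoms))) {
    abort("atoms must carry coordinates and GB radii; see assign_ff_params()")
  }
  hs <- params$global$hct_scale
  bmax <- params$global$b_max
  compute_block <- function(target, env) {
    # env includes the target atoms themselves; self-pairs are dropped by
    # matching coordinates is unsafe, so callers pass env *without* target
    # duplicates and we descreen against every env atom at r > 0
    n <- nrow(target)
    B <- numeric(n)
    for (a in seq_len(n)) {
      dx <- env$x - target$x[a]
      dy <- env$y - target$y[a]
      dz <- env$z - target$z[a]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      self <- r < 1e-9
      if (sum(self) > 1) {
        abort("degenerate geometry: atoms with identical coordinates")
      }
      keep <- !self
      inv <- 1 / target$rho[a] -
        sum(hct_integral(r[keep], hs * env$rho[keep], target$rho[a]))
      B[a] <- if (inv <= 1 / bmax) bmax else 1 / inv
    }
    B
  }
  if (mode == "FDB") {
    B <- compute_block(atoms, atoms)
    attr(B, "provenance") <- "FDB-current"
  } else {
    if (is.null(native_atoms)) abort("NEA mode requires native_atoms")
    B <- numeric(nrow(atoms))
    for (i in unique(atoms$res_idx)) {
      own <- atoms[atoms$res_idx == i, , drop = FALSE]
      env <- rbind(own, native_atoms[native_atoms$res_idx != i, ,
                                     drop = FALSE])
      B[atoms$res_idx == i] <- compute_block(own, env)
    }
    attr(B, "provenance") <- "NEA-frozen"
  }
  B
}

# Still's interpolation formula
f_gb <- function(r, Bi, Bj) {
  bb <- Bi * Bj
  sqrt(r^2 + bb * exp(-r^2 / (4 * bb)))
}

#' Generalized Born polarization energy
#'
#' `-(k/2) (1/eps_p - 1/eps_w) * sum_ij q_i q_j / f_gb(r_ij, B_i, B_j)`,
#' over all ordered atom pairs including the `i = j` self terms, with
#' Still's `f_gb = sqrt(r^2 + B_i B_j exp(-r^2 / (4 B_i B_j)))`.
#'
#' @param atoms atom table with `x`, `y`, `z`, `q`.
#' @param born Born radii vector (one per atom).
#' @param params force-field parameters (for `eps_p`, `eps_w`, `k_coul`).
#' @return polarization energy in kcal/mol.
#' @export
gb_polarization_energy <- function(atoms, born, params = design_params()) {
  n <- nrow(atoms)
  if (length(born) != n) abort("born radii must match the atom count")
  g <- params$global
  contrast <- 1 / g$eps_p - 1 / g$eps_w
  if (contrast == 0 || all(atoms$q == 0)) return(0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  Fm <- f_gb(D, matrix(born, n, n), matrix(born, n, n, byrow = TRUE))
  diag(Fm) <- born
  Q <- outer(atoms$q, atoms$q)
  -(g$k_coul / 2) * contrast * sum(Q / Fm)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n = 960) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Numerical accessible surface areas (Shrake-Rupley)
#'
#' Per-atom solvent-accessible areas computed with a fixed deterministic
#' golden-spiral point set. A boundary tie (a test point exactly on a
#' neighbouring sphere, as for coincident identical atoms) is owned by the
#' lower-index atom so the summed area equals the union area.
#'
#' @param coords numeric matrix (n x 3) of atom centres.
#' @param radii per-atom radii, Angstrom.
#' @param probe probe radius, Angstrom.
#' @param n_points points per atom (>= 960 by default).
#' @return numeric vector of per-atom areas, Angstrom^2.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(radii <= 0)) abort("radii must be positive")
  pts <- sphere_points(n_points)
  R <- radii + probe
  out <- numeric(n)
  eps <- 1e-9
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, coords[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      lim <- R[j]^2
      buried <- d2 < lim - eps | (abs(d2 - lim) <= eps & j < i)
      exposed <- exposed & !buried
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  out
}

# Analytic two-sphere burial: area of atom a's accessible sphere (radius
# Ra) covered by a neighbour's accessible sphere (radius Rb) at distance d.
cap_area <- function(d, Ra, Rb) {
  n <- length(d)
  Ra <- rep_len(Ra, n)
  Rb <- rep_len(Rb, n)
  out <- numeric(n)
  full <- d + Ra <= Rb
  out[full] <- 4 * pi * Ra[full]^2
  part <- !full & d < Ra + Rb & d + Rb > Ra
  if (any(part)) {
    dd <- d[part]
    h <- Ra[part] - (dd^2 + Ra[part]^2 - Rb[part]^2) / (2 * dd)
    out[part] <- 2 * pi * Ra[part] * h
  }
  out
}

#' Pairwise-additive accessible surface areas
#'
#' The analytic surface model used inside the folded-state energy: each
#' atom's accessible area is its isolated-sphere area minus a scaled sum of
#' two-sphere overlap caps. Unlike the numerical union area this model is
#' exactly decomposable over residue pairs, which is what allows the frozen
#' dielectric (NEA) energy to be written as a pairwise matrix. The scale
#' factor compensates multiple counting of overlapping caps; areas are not
#' clamped at zero.
#'
#' @param coords numeric matrix (n x 3).
#' @param radii per-atom radii, Angstrom.
#' @param probe probe radius, Angstrom.
#' @param burial_scale cap-area scale factor.
#' @return per-atom areas, Angstrom^2.
#' @export
pairwise_area <- function(coords, radii, probe = 1.4, burial_scale = 0.8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  R <- radii + probe
  D <- as.matrix(stats::dist(coords))
  out <- numeric(n)
  for (i in seq_len(n)) {
    cov <- cap_area(D[i, -i], R[i], R[-i])
    out[i] <- 4 * pi * R[i]^2 - burial_scale * sum(cov)
  }
  out
}
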
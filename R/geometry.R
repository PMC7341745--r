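# Internal-coordinate geometry: atom placement and dihedral measurement.

DEG <- pi / 180

# Place atom X given bonded parent p1, angle reference p2, torsion reference
# p3: |X-p1| = len, angle(X, p1, p2) = ang, dihedral(X, p1, p2, p3) = tor.
# Angles in degrees. Standard NeRF construction.
place_atom <- function(p1, p2, p3, len, ang, tor) {
  bc <- p1 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p3
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) abort("degenerate geometry: collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  a <- ang * DEG
  t <- tor * DEG
  d2 <- c(-len * cos(a), len * sin(a) * cos(t), -len * sin(a) * sin(t))
  p1 + bc * d2[1] + m * d2[2] + n * d2[3]
}

#' Measure a dihedral angle
#'
#' Dihedral defined by four points `a-b-c-d`, in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric xyz vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
          n1[3] * b2u[1] - n1[1] * b2u[3],
          n1[1] * b2u[2] - n1[2] * b2u[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Build N/CA/C/O backbone coordinates for given per-residue phi/psi
# (vectors of length n; phi[1] and psi[n] are unused) with ideal geometry.
# Returns a list of n matrices (4 x 3, rows N, CA, C, O).
build_backbone <- function(phi, psi, geom = ideal_geometry()) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  b <- geom$bonds
  a <- geom$angles
  omega <- geom$omega
  res <- vector("list", n)
  # seed the first three atoms in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(b$n_ca, 0, 0)
  th <- (180 - a$n_ca_c) * DEG
  C1 <- CA1 + b$ca_c * c(cos(th), sin(th), 0)
  Ns <- matrix(0, n, 3)
  CAs <- matrix(0, n, 3)
  Cs <- matrix(0, n, 3)
  Ns[1, ] <- N1
  CAs[1, ] <- CA1
  Cs[1, ] <- C1
  for (i in seq_len(n - 1)) {
    Ns[i + 1, ] <- place_atom(Cs[i, ], CAs[i, ], Ns[i, ],
                              b$c_n, a$ca_c_n, psi[i])
    CAs[i + 1, ] <- place_atom(Ns[i + 1, ], Cs[i, ], CAs[i, ],
                               b$n_ca, a$c_n_ca, omega)
    Cs[i + 1, ] <- place_atom(CAs[i + 1, ], Ns[i + 1, ], Cs[i, ],
                              b$ca_c, a$n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    # carbonyl O anti to the following N (psi + 180), same convention for
    # the final residue
    O <- place_atom(Cs[i, ], CAs[i, ], Ns[i, ], b$c_o, a$ca_c_o,
                    psi[i] + 180)
    m <- rbind(Ns[i, ], CAs[i, ], Cs[i, ], O)
    rownames(m) <- c("N", "CA", "C", "O")
    res[[i]] <- m
  }
  res
}
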
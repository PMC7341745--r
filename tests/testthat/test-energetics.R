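# Energy terms: LJ closed forms, Born radii vs numeric integration, GB
# closed forms and invariances, surface areas, NEA/FDB consistency, and
# the pairwise energy-matrix decomposition.

test_that("Lennard-Jones closed forms hold", {
  expect_equal(lj_energy(3.4, 3.4, 0.1), 0)
  expect_equal(lj_energy(2^(1 / 6) * 3.4, 3.4, 0.1), -0.1)
  # independent evaluation of the formula with combining rules
  sig <- (3.4 + 3.0) / 2
  eps <- sqrt(0.1 * 0.2)
  r <- 4.0
  expect_equal(lj_energy(4.0, 3.4, 0.1, 3.0, 0.2),
               4 * eps * ((sig / r)^12 - (sig / r)^6))
  expect_error(lj_energy(0, 3.4, 0.1), "r must be")
})

test_that("Born radii match a numerical shell-integration oracle", {
  p <- fx_params()
  hct_oracle <- function(r, s, rho, n = 6000) {
    lo <- if (r < s) max(rho, 0) else max(rho, r - s)
    hi <- r + s
    if (hi <= rho) return(0)
    g <- seq(lo, hi, length.out = n)
    integrand <- vapply(g, function(rp) {
      if (rp < 1e-12) return(0)
      if (rp <= s - r) return(2 / rp^2)
      mu <- (rp^2 + r^2 - s^2) / (2 * rp * r)
      if (mu > 1) return(0)
      (1 - mu) / rp^2
    }, numeric(1))
    0.5 * sum((integrand[-1] + integrand[-n]) / 2 * diff(g))
  }
  # two-atom system at 4 A: analytic HCT within 2% of the quadrature
  at <- tibble::tibble(res_idx = 1:2, res_name = "ALA",
                       atom = c("CB", "CB"), x = c(0, 4), y = 0, z = 0,
                       q = 0, sig = 3.8, eps = 0.09, rho = c(1.5, 1.9),
                       tens = 0)
  B <- born_radii(at, p, "FDB")
  hs <- p$global$hct_scale
  for (i in 1:2) {
    inv_oracle <- 1 / at$rho[i] - hct_oracle(4, hs * at$rho[3 - i],
                                             at$rho[i])
    expect_lt(abs(B[i] - 1 / inv_oracle) / (1 / inv_oracle), 0.02)
  }
  # isolated atom: no descreening
  expect_equal(as.numeric(born_radii(at[1, ], p, "FDB")), 1.5)
  # identical coordinates are degenerate
  at2 <- at
  at2$x <- c(0, 0)
  expect_error(born_radii(at2, p, "FDB"), "degenerate")
})

test_that("NEA Born radii are frozen: independent of the rest of the state", {
  d <- fx_small_design()
  lib <- fx_lib()
  p <- fx_params()
  nat <- assign_ff_params(realize_state(d$native), p)
  base_seq <- replace(d$native$sequence, 6, "LEU")
  mk <- function(t4) {
    st <- system_state(d$scaffold, d$spec,
                       replace(base_seq, 4, t4), rep(1L, 6), lib)
    ap <- assign_ff_params(realize_state(st), p)
    list(ap = ap, B = born_radii(ap, p, "NEA", native_atoms = nat))
  }
  a <- mk("SER")
  b <- mk("LEU")
  # radii of every *other* residue's atoms are identical across the two states
  for (i in c(1, 2, 3, 5, 6)) {
    expect_identical(a$B[a$ap$res_idx == i], b$B[b$ap$res_idx == i])
  }
  expect_identical(attr(a$B, "provenance"), "NEA-frozen")
})

test_that("GB polarization reproduces closed forms and is frame-invariant", {
  p <- fx_params()
  k <- p$global$k_coul
  contrast <- 1 / 4 - 1 / 80
  ion <- tibble::tibble(res_idx = 1, res_name = "X", atom = "CB",
                        x = 0, y = 0, z = 0, q = 1, rho = 2)
  expect_equal(gb_polarization_energy(ion, 2, p), -(k / 2) * contrast / 2)

  two <- tibble::tibble(res_idx = 1:2, res_name = "X", atom = "CB",
                        x = c(0, 20), y = 0, z = 0, q = 1, rho = 2)
  f <- sqrt(20^2 + 4 * exp(-400 / 16))
  expected <- -(k / 2) * contrast * (1 / 2 + 1 / 2 + 2 / f)
  expect_equal(gb_polarization_energy(two, c(2, 2), p), expected,
               tolerance = 1e-12)

  expect_equal(gb_polarization_energy(dplyr::mutate(two, q = 0),
                                      c(2, 2), p), 0)

  # rigid-body invariance
  set.seed(1)
  n <- 8
  at <- tibble::tibble(res_idx = 1, res_name = "X", atom = "CB",
                       x = rnorm(n, sd = 3), y = rnorm(n, sd = 3),
                       z = rnorm(n, sd = 3), q = runif(n, -1, 1), rho = 1.8)
  B <- runif(n, 1.8, 4)
  e0 <- gb_polarization_energy(at, B, p)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at2 <- at
  at2$x <- xyz[, 1] + 5
  at2$y <- xyz[, 2] - 2
  at2$z <- xyz[, 3] + 11
  expect_lt(abs(gb_polarization_energy(at2, B, p) - e0), 1e-9)
})

test_that("surface areas match sphere closed forms and a grid oracle", {
  r <- 1.9
  probe <- 1.4
  a1 <- sasa(matrix(0, 1, 3), r, probe)
  expect_lt(abs(a1 - 4 * pi * (r + probe)^2) / a1, 0.005)
  # coincident identical atoms: union equals one sphere
  a2 <- sasa(matrix(0, 2, 3), c(r, r), probe)
  expect_lt(abs(sum(a2) - 4 * pi * (r + probe)^2) / (4 * pi * (r + probe)^2),
            0.005)
  # three-atom toy against a dense-point oracle
  coords <- rbind(c(0, 0, 0), c(2.2, 0, 0), c(1.1, 1.8, 0))
  radii <- c(1.9, 1.7, 1.5)
  fine <- sasa(coords, radii, probe, n_points = 20000)
  std <- sasa(coords, radii, probe)
  expect_lt(max(abs(std - fine) / fine), 0.02)
})

test_that("NEA equals FDB on the native state of synthetic scaffolds", {
  p <- fx_params()
  for (cfg in list(scaffold_config(5, "helix", "ASLVK"),
                   scaffold_config(8, "hairpin"),
                   scaffold_config(9, "helix-hairpin", "AATNQLSVM"))) {
    sc <- make_scaffold(cfg)
    spec <- make_design_spec(sc)
    st <- native_state(sc, spec)
    e_nea <- folded_energy(st, p, "NEA", native_state = st)
    e_fdb <- folded_energy(st, p, "FDB")
    expect_lt(abs(e_nea$total - e_fdb$total), 1e-6)
    expect_equal(e_nea$total,
                 e_nea$lj + e_nea$coulomb + e_nea$gb_polarization +
                   e_nea$nonpolar_surface)
  }
})

test_that("solvent contrast switches polarization off", {
  st <- native_state(fx_helix6(), NULL)
  pz <- design_params(eps_w = 4.0)
  expect_equal(folded_energy(st, pz, "FDB")$gb_polarization, 0)
})

test_that("energy matrix reconstructs direct NEA evaluation exactly", {
  d <- fx_small_design()
  p <- fx_params()
  lib <- fx_lib()
  types <- c("SER", "VAL", "LEU")
  set.seed(10)
  errs <- replicate(50, {
    s3 <- d$spec$native_type
    rt <- rep(1L, 6)
    for (i in c(2, 4, 6)) {
      s3[i] <- sample(types, 1)
      rt[i] <- sample(nrow(lib[[s3[i]]]), 1)
    }
    st <- system_state(d$scaffold, d$spec, s3, rt, lib)
    abs(energy_from_matrix(d$em, st) -
          folded_energy(st, p, "NEA", native_state = d$native)$total)
  })
  expect_lt(max(errs), 1e-6)
  # reconstruction at the in-space state closest to native
  s3 <- replace(d$spec$native_type, 6, "LEU")
  st_nat <- system_state(d$scaffold, d$spec, s3, rep(1L, 6), lib)
  expect_lt(abs(energy_from_matrix(d$em, st_nat) -
                  folded_energy(st_nat, p, "NEA",
                                native_state = d$native)$total), 1e-6)
  # FDB decomposition is undefined
  expect_error(precompute_energy_matrix(d$scaffold, d$spec, lib, p,
                                        mode = "FDB"), "many-body")
})

test_that("FDB and NEA disagree for at least one non-native state", {
  d <- fx_small_design()
  p <- fx_params()
  st <- system_state(d$scaffold, d$spec,
                     replace(replace(d$spec$native_type, 6, "LEU"), 4,
                             "LEU"),
                     rep(1L, 6), fx_lib())
  e1 <- folded_energy(st, p, "NEA", native_state = d$native)$total
  e2 <- folded_energy(st, p, "FDB")$total
  expect_gt(abs(e1 - e2), 1e-3)
})
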
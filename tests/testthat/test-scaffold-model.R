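# Structure I/O, design specs, sequence-space size, side-chain building.

test_that("read_pdb reports missing backbone atoms and rejects empty files", {
  sc <- make_scaffold(scaffold_config(4, "helix"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sc, f)
  lines <- readLines(f)
  # drop residue 2's CA
  drop <- grepl("^ATOM", lines) & grepl(" CA ", lines) &
    substr(lines, 23, 26) == "   2"
  writeLines(lines[!drop], f)
  expect_error(read_pdb(f), "residue 2.*CA")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(read_pdb(f2), "ATOM|parse")
})

test_that("altloc A coordinates are preferred over altloc B", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA BALA A   1       9.999   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.423   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), f)
  sc <- read_pdb(f)
  ca <- sc$atoms[sc$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.458)
})

test_that("design spec implements the mutability classes", {
  # CASK-like bookkeeping: 83 residues, 7 Gly, 2 Pro, 13 interface
  set.seed(4)
  seq83 <- rep("A", 83)
  seq83[c(5, 15, 25, 35, 45, 55, 65)] <- "G"
  seq83[c(10, 70)] <- "P"
  interface <- c(2, 8, 12, 20, 28, 33, 40, 48, 52, 60, 68, 75, 80)
  sc <- make_scaffold(scaffold_config(83, "helix",
                                      paste(seq83, collapse = "")))
  spec <- make_design_spec(sc, interface_ids = interface)
  expect_equal(sum(spec$class == "mutable"), 61)
  expect_equal(sum(spec$class == "frozen"), 9)
  expect_equal(sum(spec$class == "rotamer_only"), 13)
  expect_true(all(vapply(spec$allowed[spec$class == "mutable"],
                         function(a) !any(c("GLY", "PRO") %in% a),
                         logical(1))))

  # all-Gly scaffold: nothing to design
  scg <- make_scaffold(scaffold_config(5, "helix", "GGGGG"))
  expect_equal(sum(make_design_spec(scg)$class == "mutable"), 0)

  # 10-residue poly-ALA, 3 interface ids -> 7 mutable x 18 types
  sc10 <- make_scaffold(scaffold_config(10, "helix"))
  sp10 <- make_design_spec(sc10, interface_ids = c(2, 5, 8))
  expect_equal(sum(sp10$class == "mutable"), 7)
  expect_true(all(vapply(sp10$allowed[sp10$class == "mutable"], length,
                         integer(1)) == 18))
  expect_error(make_design_spec(sc10, interface_ids = 99), "99")
})

test_that("sequence-space size is exact and multiplicative", {
  sc10 <- make_scaffold(scaffold_config(10, "helix"))
  sp <- make_design_spec(sc10, interface_ids = c(2, 5, 8))
  # 3 mutable positions with 2, 3, 4 allowed types -> 24 by enumeration
  sp2 <- sp
  sp2$class[!(sp2$res_idx %in% c(1, 3, 4))] <- "frozen"
  sp2$allowed[[1]] <- c("ALA", "SER")
  sp2$allowed[[3]] <- c("ALA", "SER", "VAL")
  sp2$allowed[[4]] <- c("ALA", "SER", "VAL", "LEU")
  n_enum <- nrow(expand.grid(sp2$allowed[[1]], sp2$allowed[[3]],
                             sp2$allowed[[4]]))
  expect_equal(as.character(sequence_space_size(sp2)),
               as.character(n_enum))

  # no mutable positions -> 1
  spf <- sp
  spf$class[] <- "frozen"
  expect_equal(as.character(sequence_space_size(spf)), "1")

  # multiplicativity: size(A) * size(B) computed exactly
  a <- sequence_space_size(sp2)
  full <- sequence_space_size(sp)   # 18^7
  expect_equal(as.character(big_mul(a, full)),
               as.character({
                 x <- a
                 for (k in rep(18, 7)) x <- cpdesign:::big_mul_small(x, k)
                 x
               }))
})

test_that("side-chain building inverts to the requested chi angles", {
  sc <- fx_helix6()
  for (case in list(list("LEU", c(-60, 175)), list("MET", c(-65, 180, 75)),
                    list("LYS", c(180, 65, 180, 180)),
                    list("TRP", c(-65, 95)))) {
    side <- build_sidechain(sc, 3, case[[1]], case[[2]])
    chi <- measure_chi(residue_atoms(sc, 3, side), case[[1]])
    expect_lt(max(abs(chi - case[[2]])), 1e-6)
  }
  # ALA: single CB at the ideal bond length
  cb <- build_sidechain(sc, 2, "ALA")
  ca <- sc$atoms[sc$atoms$res_idx == 2 & sc$atoms$atom == "CA", ]
  expect_lt(abs(sqrt((cb$x - ca$x)^2 + (cb$y - ca$y)^2 +
                       (cb$z - ca$z)^2) - 1.53), 1e-3)
  expect_error(build_sidechain(sc, 2, "GLY"), "GLY")
  expect_error(build_sidechain(sc, 2, "LEU", c(-60)), "2 chi")
})

test_that("identical side chains superpose across backbone positions", {
  sc <- fx_helix6()
  fit_frame <- function(i) {
    fr <- bb <- sc$atoms[sc$atoms$res_idx == i &
                           sc$atoms$atom %in% c("N", "CA", "C"), ]
    as.matrix(bb[match(c("N", "CA", "C"), bb$atom), c("x", "y", "z")])
  }
  s2 <- build_sidechain(sc, 2, "VAL", 175)
  s4 <- build_sidechain(sc, 4, "VAL", 175)
  # Kabsch superposition of local frames maps one side chain onto the other
  a <- fit_frame(2)
  b <- fit_frame(4)
  ca <- colMeans(a)
  cb <- colMeans(b)
  s <- svd(t(sweep(b, 2, cb)) %*% sweep(a, 2, ca))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    s$u[, 3] <- -s$u[, 3]
    R <- s$u %*% t(s$v)
  }
  mapped <- sweep(as.matrix(s4[, c("x", "y", "z")]), 2, cb) %*% R
  mapped <- sweep(mapped, 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((mapped - as.matrix(s2[, c("x", "y", "z")]))^2)))
  expect_lt(rmsd, 1e-3)
})

test_that("realize_state is local and leaves the backbone untouched", {
  sc <- fx_helix6()
  spec <- make_design_spec(sc)
  st <- system_state(sc, spec)
  at <- realize_state(st)
  # poly-ALA-like atom counts: 4 backbone + CB for every non-GLY residue
  counts <- table(at$res_idx)
  topo <- fx_params()$topology
  for (i in 1:6) {
    t3 <- st$sequence[i]
    expect_equal(unname(counts[as.character(i)]),
                 4 + sum(topo$res == t3))
  }
  # backbone identical to scaffold
  bb <- at[at$atom %in% c("N", "CA", "C", "O"), ]
  sb <- sc$atoms[sc$atoms$atom %in% c("N", "CA", "C", "O"), ]
  expect_identical(as.matrix(bb[, c("x", "y", "z")]),
                   as.matrix(sb[, c("x", "y", "z")]))
  # two states differing at one position differ only there
  st2 <- system_state(sc, spec, replace(st$sequence, 4, "TRP"),
                      st$rotamers)
  at2 <- realize_state(st2)
  same <- intersect(paste(at$res_idx, at$atom),
                    paste(at2$res_idx, at2$atom))
  m1 <- at[match(same, paste(at$res_idx, at$atom)), ]
  m2 <- at2[match(same, paste(at2$res_idx, at2$atom)), ]
  moved <- rowSums(abs(as.matrix(m1[, c("x", "y", "z")]) -
                         as.matrix(m2[, c("x", "y", "z")]))) > 0
  expect_true(all(m1$res_idx[moved] == 4))
})

test_that("state validation enforces the design spec", {
  sc <- fx_helix6()
  spec <- make_design_spec(sc, interface_ids = 2)
  expect_error(system_state(sc, spec, replace(spec$native_type, 2, "TRP")),
               "rotamer_only")
  expect_error(system_state(sc, spec,
                            replace(spec$native_type, 4, "GLY")),
               "not allowed")
  expect_error(system_state(sc, spec, rotamers = rep(99L, 6)),
               "out of range")
})
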
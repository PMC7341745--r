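# Packaged force-field, topology, and rotamer parameter tables.

the <- new.env(parent = emptyenv())

#' Force-field and solvation parameters
#'
#' Loads the packaged reduced parameter set: per-element Lennard-Jones
#' parameters, intrinsic Generalized Born radii and atomic surface tensions,
#' per-atom partial charges, the side-chain topology table used for
#' internal-coordinate building, and global constants (protein dielectric
#' `eps_p = 4`, solvent dielectric `eps_w = 80`, probe radius 1.4 A,
#' electrostatic constant 332.0636 kcal A/mol/e^2, 1-4 scale factors).
#'
#' The set is united-atom: heavy atoms only, with polar-group charges placed
#' on the heavy atoms. Individual constants can be overridden through `...`
#' (e.g. `design_params(eps_w = 4)` switches off the solvent contrast).
#'
#' @param ... named scalar overrides of the global constants.
#' @return an object of class `ff_params`: a list with elements `global`
#'   (named list of constants), `atoms` (per-element tibble), `charges`
#'   (per residue/atom tibble), `topology` (side-chain z-matrix tibble).
#' @export
design_params <- function(...) {
  if (is.null(the$params_base)) {
    glob <- yaml::read_yaml(extdata_path("params.yaml"))
    atoms <- readr::read_csv(extdata_path("atom_params.csv"),
                             show_col_types = FALSE)
    charges <- readr::read_csv(extdata_path("charges.csv"),
                               show_col_types = FALSE)
    topo <- readr::read_csv(extdata_path("topology.csv"),
                            show_col_types = FALSE)
    topo$tor_base[is.na(topo$tor_base)] <- ""
    the$params_base <- structure(
      list(global = glob, atoms = atoms, charges = charges, topology = topo),
      class = "ff_params")
  }
  p <- the$params_base
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p$global))
    if (length(bad)) abort(paste0("unknown parameter(s): ",
                                  paste(bad, collapse = ", ")))
    p$global[names(dots)] <- dots
  }
  p
}

#' @export
print.ff_params <- function(x, ...) {
  cat("<ff_params> united-atom reduced set\n")
  cat("  elements:", paste(x$atoms$elem, collapse = " "), "\n")
  cat("  eps_p =", x$global$eps_p, " eps_w =", x$global$eps_w,
      " probe =", x$global$probe, "A\n")
  invisible(x)
}

#' Packaged rotamer library
#'
#' A coarse, backbone-independent library built from canonical chi wells
#' (gauche-/trans/gauche+), one to nine rotamers per side-chain type.
#' Alanine and glycine carry a single chi-less entry so every residue state
#' is indexable the same way.
#'
#' @return named list (three-letter type -> numeric matrix, rotamers in rows,
#'   chi angles in columns), class `rotamer_library`.
#' @export
default_rotamer_library <- function() {
  if (!is.null(the$rotlib)) return(the$rotlib)
  raw <- readr::read_csv(extdata_path("rotamers.csv"), show_col_types = FALSE)
  topo <- design_params()$topology
  nchi <- chi_counts(topo)
  lib <- lapply(AA3, function(t3) {
    k <- nchi[[t3]]
    rows <- raw[raw$res == t3, , drop = FALSE]
    if (nrow(rows) == 0) {
      matrix(numeric(0), nrow = 1, ncol = k)  # GLY/ALA: one chi-less rotamer
    } else {
      m <- as.matrix(rows[, paste0("chi", seq_len(4)), drop = FALSE])
      m <- m[, seq_len(k), drop = FALSE]
      storage.mode(m) <- "double"
      if (k > 0 && anyNA(m)) abort(paste0("rotamer table incomplete for ", t3))
      if (k == 0) m <- matrix(numeric(0), nrow = max(1, nrow(rows)), ncol = 0)
      m
    }
  })
  names(lib) <- AA3
  the$rotlib <- structure(lib, class = "rotamer_library")
  the$rotlib
}

# number of chi angles per type, derived from the topology table
chi_counts <- function(topo = design_params()$topology) {
  if (!is.null(the$nchi)) return(the$nchi)
  counts <- setNames(integer(length(AA3)), AA3)
  for (t3 in AA3) {
    bases <- topo$tor_base[topo$res == t3]
    bases <- bases[bases != ""]
    counts[[t3]] <- if (length(bases)) length(unique(bases)) else 0L
  }
  the$nchi <- counts
  counts
}

#' @export
print.rotamer_library <- function(x, ...) {
  nr <- vapply(x, nrow, integer(1))
  nc <- vapply(x, ncol, integer(1))
  cat("<rotamer_library>", sum(nr), "rotamers over", length(x), "types\n")
  cat(paste0("  ", names(x), ": ", nr, " x ", nc, "chi", collapse = "\n"), "\n")
  invisible(x)
}

#' Ideal peptide geometry table
#'
#' Standard bond lengths and angles for the backbone, plus canonical
#' secondary-structure phi/psi values used by the synthetic scaffold
#' generator.
#'
#' @return named list with `bonds`, `angles`, `omega`, `phi_psi`.
#' @export
ideal_geometry <- function() {
  if (is.null(the$geom)) the$geom <- yaml::read_yaml(extdata_path("geometry.yaml"))
  the$geom
}

#' Packaged pKa set
#'
#' EMBOSS-style side-chain and terminal pKa values used by
#' [isoelectric_point()].
#'
#' @return named list of pKa values (one-letter codes plus `nterm`, `cterm`).
#' @export
default_pka_set <- function() {
  if (is.null(the$pka)) the$pka <- yaml::read_yaml(extdata_path("pka.yaml"))
  the$pka
}

#' Substitution matrices
#'
#' `blosum_matrix("BLOSUM62")` returns the Biostrings copy of BLOSUM62;
#' `blosum_matrix("BLOSUM40")` the packaged canonical NCBI BLOSUM40.
#' Both are returned as 20 x 20 integer matrices over the standard
#' amino-acid alphabet (one-letter row/column names).
#'
#' @param name "BLOSUM62" or "BLOSUM40".
#' @return integer matrix with dimnames over the 20 amino acids.
#' @export
blosum_matrix <- function(name = c("BLOSUM62", "BLOSUM40")) {
  name <- match.arg(name)
  key <- paste0("mat_", name)
  if (!is.null(the[[key]])) return(the[[key]])
  if (name == "BLOSUM62") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA1, AA1]
  } else {
    raw <- utils::read.csv(extdata_path("blosum40.csv"), row.names = 1)
    m <- as.matrix(raw)[AA1, AA1]
    colnames(m) <- rownames(m)
  }
  storage.mode(m) <- "integer"
  the[[key]] <- m
  m
}
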
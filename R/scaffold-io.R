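# PDB input/output (via bio3d) for backbone scaffolds.

#' Read a backbone scaffold from a PDB file
#'
#' Reads the first model and (by default) the first chain; where alternate
#' locations exist, altloc `"A"` (or blank) is preferred. Residues with
#' insertion codes are rejected. Every residue must provide the four
#' backbone atoms N/CA/C/O; a missing atom is reported with the residue it
#' belongs to. Author residue numbering is preserved in `res_id`.
#'
#' @param path PDB file path.
#' @param chain chain identifier; `NULL` selects the first chain present.
#' @return a [backbone_scaffold()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse error: ",
                                                   conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort("no ATOM records in file")
  chain <- chain %||% at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no ATOM records for chain ", chain))
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  resnos <- unique(at$resno)
  atoms <- tibble(res_idx = match(at$resno, resnos), res_id = at$resno,
                  res_name = at$resid, atom = at$elety,
                  x = at$x, y = at$y, z = at$z)
  # drop duplicate atoms (two altlocs A kept twice cannot occur; safety net)
  atoms <- atoms[!duplicated(atoms[, c("res_idx", "atom")]), ]
  residues <- atoms |>
    dplyr::distinct(.data$res_idx, .data$res_id, .data$res_name)
  bad <- !residues$res_name %in% AA3
  if (any(bad)) {
    abort(paste0("non-standard residue(s): ",
                 paste(unique(residues$res_name[bad]), collapse = ", ")))
  }
  backbone_scaffold(atoms, residues, chain = chain)
}

#' Write a scaffold to a PDB file
#'
#' Emits single-chain ATOM records with occupancy 1.00. Writing then
#' reading recovers the scaffold to within the PDB format's coordinate
#' precision (3 decimals).
#'
#' @param scaffold a [backbone_scaffold()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(scaffold, path) {
  a <- scaffold$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$res_id, resid = a$res_name, eleno = seq_len(nrow(a)),
                   elety = a$atom, chain = rep(scaffold$chain, nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
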
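# Buried-cavity detection by occupancy-grid flood fill.

#' Detect buried cavities
#'
#' Builds a 3D occupancy grid (voxels within `radius + probe` of any atom
#' are occupied), flood-fills the free space from the bounding-box
#' boundary, and reports every unreached free component as a buried cavity
#' with volume `voxel count * spacing^3`, sorted descending.
#'
#' @param coords numeric matrix (n x 3) of atom centres, Angstrom.
#' @param radii per-atom radii, Angstrom.
#' @param spacing grid spacing, Angstrom (> 0).
#' @param probe probe radius, Angstrom.
#' @param pad empty margin added around the structure, Angstrom.
#' @return numeric vector of cavity volumes (Angstrom^3), possibly empty.
#' @export
detect_cavities <- function(coords, radii, spacing = 1.0, probe = 1.4,
                            pad = 2.0) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) abort("need at least one atom")
  if (spacing <= 0) abort("spacing must be > 0")
  R <- radii + probe
  lo <- apply(coords, 2, min) - max(R) - pad
  hi <- apply(coords, 2, max) + max(R) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  occ <- array(FALSE, dims)
  for (a in seq_len(nrow(coords))) {
    ix <- which(abs(gx - coords[a, 1]) <= R[a])
    iy <- which(abs(gy - coords[a, 2]) <= R[a])
    iz <- which(abs(gz - coords[a, 3]) <= R[a])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - coords[a, 1])^2
    dy2 <- (gy[iy] - coords[a, 2])^2
    dz2 <- (gz[iz] - coords[a, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    occ[ix, iy, iz] <- occ[ix, iy, iz] | (d2 <= R[a]^2)
  }
  free <- !occ
  lab <- array(0L, dims)          # 0 = unvisited, 1 = outside
  nvox <- prod(dims)
  # linear-index BFS from all boundary free voxels
  nb_off <- c(-1, 1, -dims[1], dims[1], -dims[1] * dims[2], dims[1] * dims[2])
  idx3 <- function(i, j, k) i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1)
  boundary <- unique(c(
    idx3(1, rep(seq_len(dims[2]), dims[3]),
         rep(seq_len(dims[3]), each = dims[2])),
    idx3(dims[1], rep(seq_len(dims[2]), dims[3]),
         rep(seq_len(dims[3]), each = dims[2])),
    idx3(rep(seq_len(dims[1]), dims[3]), 1,
         rep(seq_len(dims[3]), each = dims[1])),
    idx3(rep(seq_len(dims[1]), dims[3]), dims[2],
         rep(seq_len(dims[3]), each = dims[1])),
    idx3(rep(seq_len(dims[1]), dims[2]),
         rep(seq_len(dims[2]), each = dims[1]), 1),
    idx3(rep(seq_len(dims[1]), dims[2]),
         rep(seq_len(dims[2]), each = dims[1]), dims[3])))
  # coordinates per linear index, for edge-safe neighbour moves
  ii <- ((seq_len(nvox) - 1) %% dims[1]) + 1
  jj <- (((seq_len(nvox) - 1) %/% dims[1]) %% dims[2]) + 1
  kk <- ((seq_len(nvox) - 1) %/% (dims[1] * dims[2])) + 1
  flood <- function(seeds, label) {
    frontier <- seeds[free[seeds] & lab[seeds] == 0L]
    lab[frontier] <<- label
    count <- length(frontier)
    while (length(frontier)) {
      nxt <- integer(0)
      for (o in seq_along(nb_off)) {
        cand <- frontier + nb_off[o]
        ok <- switch(o,
                     ii[frontier] > 1, ii[frontier] < dims[1],
                     jj[frontier] > 1, jj[frontier] < dims[2],
                     kk[frontier] > 1, kk[frontier] < dims[3])
        cand <- cand[ok]
        cand <- cand[free[cand] & lab[cand] == 0L]
        if (length(cand)) {
          cand <- unique(cand)
          lab[cand] <<- label
          nxt <- c(nxt, cand)
          count <- count + length(cand)
        }
      }
      frontier <- nxt
    }
    count
  }
  flood(boundary, 1L)
  vols <- numeric(0)
  remaining <- which(free & lab == 0L)
  label <- 1L
  while (length(remaining)) {
    label <- label + 1L
    n <- flood(remaining[1], label)
    vols <- c(vols, n * spacing^3)
    remaining <- remaining[lab[remaining] == 0L]
  }
  sort(vols, decreasing = TRUE)
}
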
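# Shared fixtures, memoized so expensive objects are built once per run.

fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(fx[[name]])) fx[[name]] <- build()
  fx[[name]]
}

fx_params <- function() fx_get("params", design_params)
fx_lib <- function() fx_get("lib", default_rotamer_library)

fx_helix6 <- function() fx_get("helix6", function() {
  make_scaffold(scaffold_config(6, "helix", "ASLVKE"))
})

fx_model <- function() fx_get("model", unfolded_model)

# restricted 3-position design problem on the 6-residue helix
fx_small_design <- function() fx_get("small_design", function() {
  sc <- fx_helix6()
  spec <- make_design_spec(sc)
  for (i in c(1, 3, 5)) {
    spec$class[i] <- "frozen"
    spec$allowed[[i]] <- character()
  }
  for (i in c(2, 4, 6)) spec$allowed[[i]] <- c("SER", "VAL", "LEU")
  em <- precompute_energy_matrix(sc, spec, fx_lib(), fx_params())
  list(scaffold = sc, spec = spec, em = em,
       native = native_state(sc, spec, fx_lib()))
})

fx_toy <- function() fx_get("toy", toy_design_system)

# residue atom table (backbone + side chain) for chi measurement
residue_atoms <- function(scaffold, i, side) {
  bb <- scaffold$atoms[scaffold$atoms$res_idx == i &
                         scaffold$atoms$atom %in% c("N", "CA", "C"),
                       c("atom", "x", "y", "z")]
  rbind(bb, side)
}
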
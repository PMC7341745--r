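# Small fully enumerable design systems for validation and examples.

#' Construct an enumerable two-position toy design system
#'
#' Builds a hairpin scaffold with two designable strand positions, a
#' trimmed rotamer library (`n_rotamers` per type), and an unfolded model
#' whose chemical potentials are set so the two types are equally
#' populated on average (the documented role of the chemical potentials is
#' exactly this composition control). The resulting sequence-rotamer space
#' is small enough to enumerate exactly, and with the default types every
#' state is thermally accessible at `kT` around 0.6 kcal/mol, which makes
#' the system suitable for validating Boltzmann sampling against the exact
#' partition function.
#'
#' @param n_residues scaffold length.
#' @param positions two designable positions (all others frozen).
#' @param types allowed amino-acid types at those positions.
#' @param n_rotamers rotamers kept per type.
#' @param balance_mu set chemical potentials to equalize mean type
#'   energies.
#' @param params force-field parameters.
#' @return list with `scaffold`, `spec`, `library`, `model`, `em` (energy
#'   matrix), `params`.
#' @export
toy_design_system <- function(n_residues = 10, positions = c(2, 9),
                              types = c("SER", "GLU"), n_rotamers = 2,
                              balance_mu = TRUE, params = design_params()) {
  scaffold <- make_scaffold(scaffold_config(n_residues, "hairpin"),
                            params)
  lib <- default_rotamer_library()
  for (t in types) {
    lib[[t]] <- lib[[t]][seq_len(min(n_rotamers, nrow(lib[[t]]))), ,
                         drop = FALSE]
  }
  spec <- make_design_spec(scaffold)
  for (i in seq_len(n_residues)) {
    if (!(i %in% positions)) {
      spec$class[i] <- "frozen"
      spec$allowed[[i]] <- character()
    } else {
      spec$allowed[[i]] <- types
    }
  }
  em <- precompute_energy_matrix(scaffold, spec, lib, params)
  model <- unfolded_model()
  if (balance_mu) {
    ch <- em$choices
    selfadj <- lapply(seq_along(ch), function(k) {
      em$e_self[[k]] - model$e_ext[ch[[k]]$type]
    })
    by_type <- lapply(seq_along(ch), function(k) {
      tapply(selfadj[[k]], ch[[k]]$type, mean)
    })
    mt <- Reduce(`+`, by_type) / length(by_type)
    model <- unfolded_model(mu = mt - mean(mt))
  }
  list(scaffold = scaffold, spec = spec, library = lib, model = model,
       em = em, params = params)
}

#' Enumerate all states of a toy design system
#'
#' Evaluates every (type, rotamer) combination of the designable positions
#' with the direct folded-state energy (no matrix shortcut) and the
#' unfolded model, so the result can serve as an independent oracle for
#' the Monte Carlo sampler.
#'
#' @param toy a [toy_design_system()] result.
#' @param mode energy mode for the direct evaluation.
#' @return tibble with one row per state: choice indices, sequence, and
#'   folding energy `delta`.
#' @export
enumerate_toy_states <- function(toy, mode = "NEA") {
  em <- toy$em
  np <- length(em$positions)
  grids <- lapply(em$choices, function(ch) seq_len(nrow(ch)))
  combos <- expand.grid(grids)
  ns <- native_state(toy$scaffold, toy$spec, toy$library)
  delta <- vapply(seq_len(nrow(combos)), function(r) {
    cv <- as.integer(combos[r, ])
    s3 <- toy$spec$native_type
    rt <- rep(1L, nrow(toy$spec))
    for (p in seq_len(np)) {
      s3[em$positions[p]] <- em$choices[[p]]$type[cv[p]]
      rt[em$positions[p]] <- em$choices[[p]]$rot[cv[p]]
    }
    st <- system_state(toy$scaffold, toy$spec, s3, rt, toy$library)
    folding_energy(st, toy$model, toy$params, mode = mode,
                   native_state = ns)$delta
  }, numeric(1))
  out <- as_tibble(setNames(combos, paste0("c", seq_len(np))))
  out$sequence <- vapply(seq_len(nrow(combos)), function(r) {
    cv <- as.integer(combos[r, ])
    paste(vapply(seq_len(np), function(p) {
      aa_one(em$choices[[p]]$type[cv[p]])
    }, character(1)), collapse = "")
  }, character(1))
  out$delta <- delta
  out
}

#' Planted-ground-truth benchmark for the filtering cascade
#'
#' Generates a synthetic sequence archive in which every sequence is
#' constructed to fail exactly one known stage of the selection cascade
#' (or none), together with the matching reference alignment,
#' fold-recognition table, per-sequence structures, and wild type. Group
#' sizes: 20 high-energy, 20 isoelectric-point violations, 30 poor
#' E-values, 25 short fold-recognition matches, 30 low-similarity
#' scrambles, 20 buried-cavity structures, 25 over-charged, 20 with too
#' many drastic mutations, and 30 clean survivors (220 sequences total,
#' `top_n = 200`).
#'
#' The generator asserts the separations that make the planted truth
#' exact: similarity scores of scrambled sequences sit far below the
#' survivor-group mean, and the in-window isoelectric points are verified
#' to lie inside the exclusion window.
#'
#' @param seed integer seed for the per-sequence "wiggle" variation that
#'   makes all sequences unique.
#' @return list with `archive`, `structures`, `references`, `records`,
#'   `wildtype`, `config`, and `truth` (tibble: `id`, `group`,
#'   `expected_stage` — NA for survivors).
#' @export
make_cascade_benchmark <- function(seed = 1L) {
  base <- paste0("VVVV", strrep("Q", 10), "DED", strrep("FL", 8), "ATSMATS")
  stopifnot(nchar(base) == 40)
  groups <- c(rep("energy", 20), rep("pi", 20), rep("evalue", 30),
              rep("matchlen", 25), rep("similarity", 30),
              rep("cavity", 20), rep("charge", 25), rep("drastic", 20),
              rep("pass", 30))
  n <- length(groups)
  stage_of <- c(energy = "energy_top_n", pi = "isoelectric_point",
                evalue = "fold_recognition", matchlen = "fold_recognition",
                similarity = "similarity", cavity = "cavity",
                charge = "charge", drastic = "drastic_mutations",
                pass = NA_character_)

  sub_at <- function(s, pos, repl) {
    v <- seq_split(s)
    v[pos] <- repl
    paste(v, collapse = "")
  }
  g6_pattern <- sub_at(base, 5:13, "K")                    # +9 charge
  g7_pattern <- sub_at(sub_at(base, seq(18, 32, 2), "S"),  # 8 F->S
                       seq(19, 33, 2), "N")                # 8 L->N
  pi_pattern <- sub_at(base, 5:8, c("K", "K", "K", "H"))

  wiggle_codes <- c("V", "I", "L", "M")
  seqs <- character(n)
  withr::with_seed(seed, {
    wig <- expand.grid(w1 = 1:4, w2 = 1:4, w3 = 1:4, w4 = 1:4)
    wig <- wig[sample.int(nrow(wig), n), ]
    scramble_pool <- c("A", "S", "T", "N", "M", "W", "G")
    for (i in seq_len(n)) {
      s <- switch(groups[i],
                  pi = pi_pattern,
                  charge = g6_pattern,
                  drastic = g7_pattern,
                  similarity = {
                    pos <- sort(sample(c(5:14, 18:33), 25, replace = FALSE))
                    v <- seq_split(base)
                    v[pos] <- vapply(v[pos], function(orig) {
                      sample(setdiff(scramble_pool, orig), 1)
                    }, character(1))
                    paste(v, collapse = "")
                  },
                  base)
      seqs[i] <- sub_at(s, 1:4, wiggle_codes[as.integer(wig[i, ])])
    }
  })
  stopifnot(!anyDuplicated(seqs))
  ids <- sprintf("seq%05d", seq_len(n))
  energies <- ifelse(groups == "energy", 100 + seq_len(n),
                     0.01 * seq_len(n))
  archive <- tibble(id = ids, sequence = seqs, energy = energies)

  references <- tibble(id = c("ref_base", "ref_charge", "ref_drastic"),
                       seq = c(base, g6_pattern, g7_pattern))
  class(references) <- c("reference_alignment", class(references))
  records <- tibble(id = ids, family = "PDZ",
                    log10_evalue = ifelse(groups == "evalue", -20, -40),
                    match_length = ifelse(groups == "matchlen", 40L, 60L))

  shell <- sphere_points(120) * 6
  shell_tb <- tibble(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                     radius = 1.5)
  cluster <- tibble(x = c(0, 3, 0, 0, 3), y = c(0, 0, 3, 0, 3),
                    z = c(0, 0, 0, 3, 0), radius = 1.9)
  structures <- setNames(lapply(groups, function(g) {
    if (g == "cavity") shell_tb else cluster
  }), ids)

  config <- filter_config(top_n = 200)
  # verify the planted separations hold
  pis <- vapply(seqs[groups == "pi"], function(s) {
    suppressWarnings(isoelectric_point(s))
  }, numeric(1))
  stopifnot(all(pis >= config$pi_window[1] & pis <= config$pi_window[2]))
  stage4_groups <- c("similarity", "cavity", "charge", "drastic", "pass")
  s4 <- groups %in% stage4_groups
  scores <- vapply(seqs[s4], function(s) {
    blosum_similarity(s, references, config$similarity_matrix)$best
  }, numeric(1))
  m <- mean(scores)
  stopifnot(max(scores[groups[s4] == "similarity"]) < m,
            min(scores[groups[s4] != "similarity"]) >= m)

  list(archive = archive, structures = structures,
       references = references, records = records, wildtype = base,
       config = config,
       truth = tibble(id = ids, group = groups,
                      expected_stage = unname(stage_of[groups])))
}
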
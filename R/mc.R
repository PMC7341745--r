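# Metropolis Monte Carlo exploration of sequence-rotamer space.

#' Monte Carlo configuration
#'
#' @param n_steps number of proposals.
#' @param kT temperature(s) in kcal/mol; a vector sets up a replica ladder
#'   (nearest-neighbour swaps every `swap_interval` steps, archive fed by
#'   the first, coldest replica).
#' @param p_mutation probability that a move at a mutable position proposes
#'   a new (type, rotamer) pair rather than a rotamer-only re-draw.
#' @param seed integer RNG seed; the run is fully reproducible from it.
#' @param archive_size number of best sequences kept.
#' @param swap_interval steps between replica-swap attempts.
#' @param trace_thin if > 0, visit counts of full states are recorded every
#'   `trace_thin` steps (enumerable toy systems only).
#' @param check_every if > 0, the incrementally tracked energy is compared
#'   with a from-scratch matrix evaluation every that many accepted steps.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_steps, kT = 0.6, p_mutation = 0.3, seed = 1L,
                      archive_size = 2000L, swap_interval = 100L,
                      trace_thin = 0L, check_every = 0L) {
  if (any(kT <= 0)) abort("kT must be > 0")
  if (p_mutation < 0 || p_mutation > 1) abort("p_mutation must be in [0, 1]")
  if (archive_size < 1) abort("archive_size must be >= 1")
  if (n_steps < 0) abort("n_steps must be >= 0")
  structure(list(n_steps = as.integer(n_steps), kT = kT,
                 p_mutation = p_mutation, seed = as.integer(seed),
                 archive_size = as.integer(archive_size),
                 swap_interval = as.integer(swap_interval),
                 trace_thin = as.integer(trace_thin),
                 check_every = as.integer(check_every)),
            class = "mc_config")
}

#' Metropolis acceptance
#'
#' Accepts an energy change `delta_e` with probability
#' `min(1, exp(-delta_e / kT))`, consuming one uniform draw from the
#' current RNG stream when `delta_e > 0`.
#'
#' @param delta_e energy change, kcal/mol.
#' @param kT temperature, kcal/mol (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, kT) {
  if (kT <= 0) abort("kT must be > 0")
  delta_e <= 0 || runif(1) < exp(-delta_e / kT)
}

#' Propose a single Monte Carlo move
#'
#' Picks a position uniformly among non-frozen positions. At a mutable
#' position, with probability `p_mutation` a new (type, rotamer) pair is
#' drawn uniformly over all allowed combinations; otherwise (and always at
#' rotamer-only positions) a rotamer is re-drawn uniformly for the current
#' type. The proposal kernel is symmetric. The candidate differs from the
#' input at exactly one position (possibly by the identity draw).
#'
#' @param state a [system_state()].
#' @param config an [mc_config()] (for `p_mutation`).
#' @return list with `state` (candidate), `position` (res_idx), `kind`
#'   (`"mutation"` or `"rotamer"`).
#' @export
propose_move <- function(state, config = mc_config(1)) {
  spec <- state$spec
  free <- which(spec$class != "frozen")
  if (length(free) == 0) abort("no non-frozen positions: nothing to move")
  p <- free[sample.int(length(free), 1)]
  seq2 <- state$sequence
  rot2 <- state$rotamers
  kind <- "rotamer"
  if (spec$class[p] == "mutable" && runif(1) < config$p_mutation) {
    kind <- "mutation"
    types <- spec$allowed[[p]]
    counts <- vapply(types, function(t3) nrow(state$library[[t3]]),
                     integer(1))
    k <- sample.int(sum(counts), 1)
    ti <- findInterval(k - 1, cumsum(c(0, counts)), rightmost.closed = TRUE)
    seq2[p] <- types[ti]
    rot2[p] <- k - c(0, cumsum(counts))[ti]
  } else {
    nr <- nrow(state$library[[seq2[p]]])
    rot2[p] <- sample.int(nr, 1)
  }
  list(state = system_state(state$scaffold, spec, seq2, rot2,
                            state$library),
       position = spec$res_id[p], kind = kind)
}

#' Run a Monte Carlo sequence design
#'
#' Metropolis sampling of folding energy over sequence-rotamer space on the
#' fixed backbone. In NEA mode every energy change is an exact lookup in
#' the precomputed pair matrix; in FDB mode each proposal is evaluated from
#' scratch with current-state Born radii (restricted by default to small
#' systems, since every step is a full many-body evaluation). Every
#' distinct sequence's best folding energy is archived.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param spec a [make_design_spec()] result.
#' @param library rotamer library.
#' @param params force-field parameters.
#' @param model an [unfolded_model()].
#' @param mode `"NEA"` or `"FDB"`.
#' @param config an [mc_config()].
#' @param em optional precomputed [precompute_energy_matrix()] (NEA).
#' @param max_fdb_positions guard for FDB runs.
#' @return tibble of class `sequence_archive` (columns `rank`, `sequence`,
#'   `energy`, `rotamers` list-column, `step_first_seen`), with attributes
#'   `mode`, `config`, and (if traced) `trace`.
#' @export
run_design <- function(scaffold, spec, library = default_rotamer_library(),
                       params = design_params(), model = unfolded_model(),
                       mode = c("NEA", "FDB"), config = mc_config(1000),
                       em = NULL, max_fdb_positions = 30) {
  mode <- match.arg(mode)
  free <- which(spec$class != "frozen")
  if (length(free) == 0) abort("no non-frozen positions: nothing to design")
  if (mode == "FDB" && length(free) > max_fdb_positions) {
    abort(paste0("FDB per-step evaluation is many-body and O(N^2); ",
                 "refusing > ", max_fdb_positions, " designable positions"))
  }
  if (mode == "NEA" && is.null(em)) {
    em <- precompute_energy_matrix(scaffold, spec, library, params)
  }

  # choice bookkeeping shared by both modes
  positions <- spec$res_idx[spec$class != "frozen"]
  np <- length(positions)
  choices <- if (mode == "NEA") em$choices else {
    lapply(positions, function(i) {
      cls <- spec$class[spec$res_idx == i]
      types <- if (cls == "mutable") spec$allowed[[which(spec$res_idx == i)]]
               else spec$native_type[spec$res_idx == i]
      bind_rows(lapply(types, function(t3) {
        tibble(type = t3, rot = seq_len(nrow(library[[t3]])))
      }))
    })
  }
  nch <- vapply(choices, nrow, integer(1))
  mutable <- spec$class[match(positions, spec$res_idx)] == "mutable"
  # indices of same-type choices, per position and choice
  same_type <- lapply(seq_len(np), function(p) {
    ch <- choices[[p]]
    lapply(seq_len(nrow(ch)), function(k) which(ch$type == ch$type[k]))
  })
  # per-choice unfolded contribution
  u <- lapply(choices, function(ch) {
    model$e_ext[ch$type] + model$mu[ch$type]
  })
  # constant unfolded contribution of frozen positions
  frozen_types <- spec$native_type[spec$class == "frozen"]
  u_frozen <- if (length(frozen_types)) {
    sum(model$e_ext[frozen_types] + model$mu[frozen_types])
  } else 0

  # initial state: native type in its first rotamer where allowed,
  # otherwise the position's first choice
  native <- spec$native_type[match(positions, spec$res_idx)]
  cv <- vapply(seq_len(np), function(p) {
    k <- which(choices[[p]]$type == native[p] & choices[[p]]$rot == 1L)
    if (length(k)) k[1] else 1L
  }, integer(1))

  state_energy <- function(cvec) {
    if (mode == "NEA") {
      energy_from_matrix(em, cvec) -
        sum(vapply(seq_len(np), function(p) u[[p]][cvec[p]], numeric(1))) -
        u_frozen
    } else {
      st <- cv_to_state(cvec)
      folding_energy(st, model, params, mode = "FDB")$delta
    }
  }
  cv_to_state <- function(cvec) {
    s3 <- spec$native_type
    rt <- rep(1L, nrow(spec))
    for (p in seq_len(np)) {
      s3[positions[p]] <- choices[[p]]$type[cvec[p]]
      rt[positions[p]] <- choices[[p]]$rot[cvec[p]]
    }
    system_state(scaffold, spec, s3, rt, library)
  }

  kTs <- config$kT
  nrep <- length(kTs)
  reps <- lapply(seq_len(nrep), function(r) {
    list(cv = cv, E = state_energy(cv))
  })

  archive <- new.env(parent = emptyenv())
  arch_add <- function(cvec, E, step) {
    key <- paste(vapply(seq_len(np), function(p) choices[[p]]$type[cvec[p]],
                        character(1)), collapse = ".")
    cur <- archive[[key]]
    if (is.null(cur) || E < cur$energy) {
      first <- if (is.null(cur)) step else cur$first
      archive[[key]] <- list(energy = E, cv = cvec, first = first)
    }
  }

  # optional full-state visit trace (enumerable toys)
  do_trace <- config$trace_thin > 0
  if (do_trace) {
    if (prod(nch) > 1e6) abort("state space too large to trace")
    trace_counts <- numeric(prod(nch))
    mult <- cumprod(c(1, nch[-np]))
    state_id <- function(cvec) 1 + sum((cvec - 1) * mult)
  }

  withr::with_seed(config$seed, {
    arch_add(reps[[1]]$cv, reps[[1]]$E, 0L)
    step <- 0L
    accepted <- 0L
    while (step < config$n_steps) {
      step <- step + 1L
      for (r in seq_len(nrep)) {
        cvec <- reps[[r]]$cv
        p <- sample.int(np, 1)
        if (mutable[p] && runif(1) < config$p_mutation) {
          knew <- sample.int(nch[p], 1)
        } else {
          blk <- same_type[[p]][[cvec[p]]]
          knew <- blk[sample.int(length(blk), 1)]
        }
        if (mode == "NEA") {
          d <- matrix_delta(em, cvec, p, knew) -
            (u[[p]][knew] - u[[p]][cvec[p]])
        } else {
          cv2 <- cvec
          cv2[p] <- knew
          E2 <- state_energy(cv2)
          d <- E2 - reps[[r]]$E
        }
        if (d <= 0 || runif(1) < exp(-d / kTs[r])) {
          cvec[p] <- knew
          reps[[r]]$cv <- cvec
          reps[[r]]$E <- reps[[r]]$E + d
          if (r == 1) {
            accepted <- accepted + 1L
            arch_add(cvec, reps[[r]]$E, step)
            if (config$check_every > 0 &&
                accepted %% config$check_every == 0 && mode == "NEA") {
              ref <- state_energy(cvec)
              if (abs(ref - reps[[r]]$E) > 1e-6) {
                abort(sprintf(
                  "incremental energy drifted: %.9f vs %.9f at step %d",
                  reps[[r]]$E, ref, step))
              }
            }
          }
        }
      }
      if (nrep > 1 && step %% config$swap_interval == 0) {
        for (r in seq_len(nrep - 1)) {
          dE <- reps[[r + 1]]$E - reps[[r]]$E
          darg <- (1 / kTs[r] - 1 / kTs[r + 1]) * dE
          if (darg >= 0 || runif(1) < exp(darg)) {
            tmp <- reps[[r]]
            reps[[r]] <- reps[[r + 1]]
            reps[[r + 1]] <- tmp
          }
        }
      }
      if (do_trace && step %% config$trace_thin == 0) {
        id <- state_id(reps[[1]]$cv)
        trace_counts[id] <- trace_counts[id] + 1
      }
    }
  })

  keys <- ls(archive)
  entries <- lapply(keys, function(k) archive[[k]])
  ord <- order(vapply(entries, function(e) e$energy, numeric(1)),
               vapply(entries, function(e) e$first, numeric(1)))
  ord <- ord[seq_len(min(length(ord), config$archive_size))]
  out <- tibble(
    rank = seq_along(ord),
    sequence = vapply(entries[ord], function(e) {
      st <- full_sequence(spec, positions, choices, e$cv)
      paste(aa_one(st), collapse = "")
    }, character(1)),
    energy = vapply(entries[ord], function(e) e$energy, numeric(1)),
    rotamers = lapply(entries[ord], function(e) {
      vapply(seq_len(np), function(p) choices[[p]]$rot[e$cv[p]], integer(1))
    }),
    step_first_seen = vapply(entries[ord], function(e) as.integer(e$first),
                             integer(1)))
  class(out) <- c("sequence_archive", class(out))
  attr(out, "mode") <- mode
  attr(out, "config") <- config
  if (do_trace) {
    attr(out, "trace") <- trace_counts
    attr(out, "trace_choices") <- choices
  }
  out
}

full_sequence <- function(spec, positions, choices, cvec) {
  s3 <- spec$native_type
  for (p in seq_along(positions)) {
    s3[positions[p]] <- choices[[p]]$type[cvec[p]]
  }
  s3
}

#' Folding-energy window of the best sequences
#'
#' @param archive a `sequence_archive`.
#' @param top_n number of best entries considered.
#' @return `max - min` energy among the `top_n` best entries, kcal/mol.
#' @export
energy_window <- function(archive, top_n) {
  if (nrow(archive) == 0) abort("archive is empty")
  if (top_n < 1) abort("top_n must be >= 1")
  e <- head(sort(archive$energy), top_n)
  max(e) - min(e)
}
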
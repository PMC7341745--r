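# The seven-stage candidate-selection cascade with attrition reporting.

stage_names <- c("energy_top_n", "isoelectric_point", "fold_recognition",
                 "similarity", "cavity", "charge", "drastic_mutations")

#' Run the candidate-filtering cascade
#'
#' Applies, in order: (1) keep the `top_n` lowest folding energies;
#' (2) exclude sequences with isoelectric point inside the physiological
#' window; (3) keep sequences whose fold-recognition match length is above
#' the survivors' mean and whose log10 E-value is below the threshold;
#' (4) keep sequences whose best-hit similarity to the reference alignment
#' is at or above the survivors' mean (the mean is computed over the
#' sequences entering this stage); (5) exclude sequences whose structure
#' contains a buried cavity above the volume limit; (6) require unsigned
#' formal charge strictly below the limit; (7) allow at most the configured
#' number of drastic mutations relative to the wild type. Stages 3 and 4
#' depend on their input set through the mean, so the stage order matters
#' there; stages 5-7 are independent per-sequence predicates.
#'
#' @param archive `sequence_archive` tibble (columns `sequence`, `energy`;
#'   an `id` column is added from the rank when absent).
#' @param structures named list (id -> atom tibble with `x`, `y`, `z` and
#'   optionally `radius`) used by the cavity stage.
#' @param references a `reference_alignment`.
#' @param records fold-recognition tibble keyed by `id`.
#' @param wildtype one-letter wild-type sequence for the drastic-mutation
#'   stage.
#' @param config a [filter_config()].
#' @return object of class `filter_report`: `stages` (per-stage attrition
#'   tibble), `decisions` (per-sequence, per-stage value and pass flag),
#'   `survivors` (tibble of surviving sequences ranked by energy).
#' @export
run_cascade <- function(archive, structures, references, records, wildtype,
                        config = filter_config()) {
  arc <- as_tibble(archive)
  if (!"id" %in% names(arc)) {
    arc$id <- sprintf("seq%05d", seq_len(nrow(arc)))
  }
  decisions <- list()
  note <- function(ids, stage, values, pass) {
    decisions[[length(decisions) + 1]] <<-
      tibble(id = ids, stage = stage, value = as.numeric(values),
             pass = pass)
  }
  counts <- tibble(stage = stage_names, n_in = 0L, n_out = 0L)
  set_count <- function(stage, n_in, n_out) {
    counts[counts$stage == stage, c("n_in", "n_out")] <<-
      list(as.integer(n_in), as.integer(n_out))
  }

  if (nrow(arc) == 0) {
    return(new_filter_report(counts, bind_rows(decisions), arc))
  }

  # 1: energy cut
  arc <- arc[order(arc$energy), , drop = FALSE]
  keep <- seq_len(min(nrow(arc), config$top_n))
  note(arc$id, "energy_top_n", arc$energy,
       seq_len(nrow(arc)) %in% keep)
  set_count("energy_top_n", nrow(arc), length(keep))
  arc <- arc[keep, , drop = FALSE]

  # 2: isoelectric point exclusion window (inclusive)
  pis <- vapply(arc$sequence, function(s) {
    suppressWarnings(isoelectric_point(s))
  }, numeric(1))
  ok <- pis < config$pi_window[1] | pis > config$pi_window[2]
  note(arc$id, "isoelectric_point", pis, ok)
  set_count("isoelectric_point", nrow(arc), sum(ok))
  arc <- arc[ok, , drop = FALSE]

  # 3: fold recognition (mean over this stage's input set)
  rec <- records[match(arc$id, records$id), , drop = FALSE]
  if (anyNA(rec$id)) {
    abort(paste0("missing fold-recognition record(s) for: ",
                 paste(arc$id[is.na(rec$id)], collapse = ", ")))
  }
  if (nrow(arc) > 0) {
    mlen <- mean(rec$match_length)
    ok <- rec$match_length > mlen &
      rec$log10_evalue < config$log10E_threshold
    note(arc$id, "fold_recognition", rec$log10_evalue, ok)
    set_count("fold_recognition", nrow(arc), sum(ok))
    arc <- arc[ok, , drop = FALSE]
  }

  # 4: similarity at or above the survivors' mean
  if (nrow(arc) > 0) {
    scores <- vapply(arc$sequence, function(s) {
      blosum_similarity(s, references, config$similarity_matrix,
                        config$similarity_positions)$best
    }, numeric(1))
    ok <- scores >= mean(scores)
    note(arc$id, "similarity", scores, ok)
    set_count("similarity", nrow(arc), sum(ok))
    arc <- arc[ok, , drop = FALSE]
  }

  # 5: buried cavities
  if (nrow(arc) > 0) {
    vols <- vapply(arc$id, function(id) {
      st <- structures[[id]]
      if (is.null(st)) abort(paste0("missing structure for sequence ", id))
      coords <- as.matrix(st[, c("x", "y", "z")])
      radii <- if ("radius" %in% names(st)) st$radius else rep(1.9, nrow(st))
      v <- detect_cavities(coords, radii, spacing = config$cavity_spacing,
                           probe = config$cavity_probe)
      if (length(v)) max(v) else 0
    }, numeric(1))
    ok <- vols <= config$cavity_max_volume
    note(arc$id, "cavity", vols, ok)
    set_count("cavity", nrow(arc), sum(ok))
    arc <- arc[ok, , drop = FALSE]
  }

  # 6: unsigned formal charge, strict
  if (nrow(arc) > 0) {
    ch <- vapply(arc$sequence, formal_charge, integer(1))
    ok <- abs(ch) < config$charge_max
    note(arc$id, "charge", ch, ok)
    set_count("charge", nrow(arc), sum(ok))
    arc <- arc[ok, , drop = FALSE]
  }

  # 7: drastic mutations vs wild type
  if (nrow(arc) > 0) {
    dc <- vapply(arc$sequence, function(s) {
      drastic_mutation_count(s, wildtype, config$drastic_matrix,
                             config$drastic_threshold)
    }, integer(1))
    ok <- dc <= config$drastic_max
    note(arc$id, "drastic_mutations", dc, ok)
    set_count("drastic_mutations", nrow(arc), sum(ok))
    arc <- arc[ok, , drop = FALSE]
  }

  arc <- arc[order(arc$energy), , drop = FALSE]
  new_filter_report(counts, bind_rows(decisions), arc)
}

new_filter_report <- function(stages, decisions, survivors) {
  structure(list(stages = stages, decisions = decisions,
                 survivors = survivors),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %5d -> %5d\n", x$stages$stage[i],
                x$stages$n_in[i], x$stages$n_out[i]))
  }
  cat("  survivors:", nrow(x$survivors), "\n")
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  mutate(x$stages, eliminated = .data$n_in - .data$n_out)
}

#' @export
glance.filter_report <- function(x, ...) {
  tibble(n_input = if (nrow(x$stages)) max(x$stages$n_in) else 0L,
         n_survivors = nrow(x$survivors),
         n_stages = nrow(x$stages))
}

#' Stage that eliminated each sequence
#'
#' @param report a `filter_report`.
#' @return tibble with `id` and `eliminated_by` (NA for survivors).
#' @export
elimination_stage <- function(report) {
  d <- report$decisions
  if (is.null(d) || nrow(d) == 0) {
    return(tibble(id = character(), eliminated_by = character()))
  }
  d |>
    group_by(.data$id) |>
    summarise(eliminated_by = {
      fails <- .data$stage[!.data$pass]
      if (length(fails)) fails[1] else NA_character_
    }, .groups = "drop")
}
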
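# Seeded generators for reference alignments, fold-recognition tables, and
# melt curves, plus their plain-text readers/writers.

#' Configuration for a synthetic reference alignment
#'
#' @param consensus one-letter consensus sequence string.
#' @param n_sequences number of sequences to generate (>= 1).
#' @param substitution_rate per-position substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list of class `msa_config`.
#' @export
msa_config <- function(consensus, n_sequences, substitution_rate, seed = 1L) {
  if (nchar(consensus) == 0) abort("consensus must be non-empty")
  if (substitution_rate < 0 || substitution_rate > 1) {
    abort("substitution_rate must be in [0, 1]")
  }
  if (n_sequences < 1) abort("n_sequences must be >= 1")
  aa_three(seq_split(consensus))  # validate
  structure(list(consensus = consensus, n_sequences = as.integer(n_sequences),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "msa_config")
}

#' Generate a synthetic ungapped reference alignment
#'
#' Each sequence is the consensus with every position independently
#' substituted (probability `substitution_rate`) by a uniformly chosen
#' different amino acid. No indels: the alignment is template-anchored.
#'
#' @param config an [msa_config()].
#' @return tibble with columns `id`, `seq`, class `reference_alignment`.
#' @export
make_reference_msa <- function(config) {
  stopifnot(inherits(config, "msa_config"))
  cons <- seq_split(config$consensus)
  L <- length(cons)
  out <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_sequences), function(k) {
      s <- cons
      hit <- runif(L) < config$substitution_rate
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(orig) {
          sample(setdiff(AA1, orig), 1)
        }, character(1))
      }
      paste(s, collapse = "")
    }, character(1))
  })
  res <- tibble(id = sprintf("ref%04d", seq_along(out)), seq = out)
  class(res) <- c("reference_alignment", class(res))
  res
}

#' Write / read an alignment as FASTA
#'
#' @param msa tibble with `id`, `seq`.
#' @param path file path.
#' @return `path` / tibble.
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::AAStringSet(setNames(msa$seq, msa$id))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  res <- tibble(id = names(x), seq = as.character(x))
  class(res) <- c("reference_alignment", class(res))
  res
}

#' Generate a synthetic fold-recognition score table
#'
#' Emulates the output of an external fold-recognition tool: per-sequence
#' log10 E-values drawn from a two-component normal mixture (a "good hit"
#' component centred below the detection threshold with weight `frac_hits`
#' and a background component above it) and integer match lengths.
#'
#' @param n number of records (>= 0).
#' @param frac_hits probability a record comes from the hit component.
#' @param seed integer seed.
#' @param hit_mean,hit_sd hit-component parameters for log10 E.
#' @param bg_mean,bg_sd background-component parameters.
#' @param len_mean,len_sd match-length distribution (rounded to integers).
#' @return tibble with columns `id`, `family`, `log10_evalue`,
#'   `match_length`.
#' @export
make_fold_recognition_table <- function(n, frac_hits, seed = 1L,
                                        hit_mean = -40, hit_sd = 3,
                                        bg_mean = -10, bg_sd = 5,
                                        len_mean = 80, len_sd = 8) {
  if (n < 0) abort("n must be >= 0")
  if (frac_hits < 0 || frac_hits > 1) abort("frac_hits must be in [0, 1]")
  if (n == 0) {
    return(tibble(id = character(), family = character(),
                  log10_evalue = numeric(), match_length = integer()))
  }
  withr::with_seed(seed, {
    is_hit <- runif(n) < frac_hits
    le <- ifelse(is_hit, rnorm(n, hit_mean, hit_sd), rnorm(n, bg_mean, bg_sd))
    ml <- pmax(1L, as.integer(round(rnorm(n, len_mean, len_sd))))
    tibble(id = sprintf("seq%05d", seq_len(n)),
           family = ifelse(is_hit, "PDZ", "other"),
           log10_evalue = le, match_length = ml)
  })
}

#' Write / read a fold-recognition table as TSV
#'
#' @param records tibble from [make_fold_recognition_table()].
#' @param path file path.
#' @return `path` / tibble.
#' @export
write_fold_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_fold_table
#' @export
read_fold_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    family = readr::col_character(),
                    log10_evalue = readr::col_double(),
                    match_length = readr::col_integer()))
}

#' Configuration for a synthetic melt curve
#'
#' @param t_half transition midpoint, degrees C.
#' @param slope transition width parameter, degrees C (> 0).
#' @param f_min,f_max lower/upper fluorescence plateaus (`f_max > f_min`).
#' @param noise_sd Gaussian noise standard deviation, fluorescence units.
#' @param t_grid strictly increasing temperature grid, degrees C.
#' @param seed integer seed.
#' @return list of class `melt_config`.
#' @export
melt_config <- function(t_half, slope, f_min = 0, f_max = 1, noise_sd = 0,
                        t_grid = seq(25, 85, by = 0.5), seed = 1L) {
  if (slope <= 0) abort("slope must be > 0")
  if (f_max <= f_min) abort("f_max must exceed f_min")
  if (any(diff(t_grid) <= 0)) abort("t_grid must be strictly increasing")
  structure(list(t_half = t_half, slope = slope, f_min = f_min,
                 f_max = f_max, noise_sd = noise_sd, t_grid = t_grid,
                 seed = as.integer(seed)),
            class = "melt_config")
}

# noiseless rising Boltzmann sigmoid
melt_sigmoid <- function(T, t_half, slope, f_min, f_max) {
  f_min + (f_max - f_min) / (1 + exp((t_half - T) / slope))
}

#' Generate a synthetic melt curve
#'
#' Fluorescence follows a rising Boltzmann sigmoid
#' `f(T) = f_min + (f_max - f_min) / (1 + exp((t_half - T)/slope))`
#' with seeded Gaussian noise added on the temperature grid.
#'
#' @param config a [melt_config()].
#' @param replicate replicate label stored with the curve.
#' @return tibble with columns `temperature_C`, `fluorescence`,
#'   `replicate`, class `melt_curve`.
#' @export
make_melt_curve <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "melt_config"))
  f0 <- melt_sigmoid(config$t_grid, config$t_half, config$slope,
                     config$f_min, config$f_max)
  noise <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed, rnorm(length(f0), 0, config$noise_sd))
  } else {
    0
  }
  res <- tibble(temperature_C = config$t_grid, fluorescence = f0 + noise,
                replicate = replicate)
  class(res) <- c("melt_curve", class(res))
  res
}

#' Write / read melt curves as CSV
#'
#' @param curve tibble with `temperature_C`, `fluorescence` (and optionally
#'   `replicate`).
#' @param path file path.
#' @return `path` / tibble.
#' @export
write_melt_csv <- function(curve, path) {
  readr::write_csv(curve, path)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  res <- readr::read_csv(path, show_col_types = FALSE)
  class(res) <- c("melt_curve", class(res))
  res
}
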
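# Per-sequence selection criteria: isoelectric point, formal charge,
# BLOSUM similarity, drastic mutations, fold-recognition rule.

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains (D, E, C, Y, H, K,
#' R) and the free termini.
#'
#' @param sequence one-letter string or character vector.
#' @param pH pH value(s); vectorized.
#' @param pka_set named pKa list (see [default_pka_set()]).
#' @param termini include the terminal groups (default TRUE).
#' @return net charge (elementary charges).
#' @export
net_charge <- function(sequence, pH, pka_set = default_pka_set(),
                       termini = TRUE) {
  s <- seq_split(sequence)
  if (length(s) == 0) abort("sequence must be non-empty")
  aa_three(s)  # validates codes
  acids <- c("D", "E", "C", "Y")
  bases <- c("H", "K", "R")
  counts <- table(factor(s, levels = c(acids, bases)))
  vapply(pH, function(p) {
    pos <- sum(vapply(bases, function(a) {
      counts[[a]] / (1 + 10^(p - pka_set[[a]]))
    }, numeric(1)))
    neg <- sum(vapply(acids, function(a) {
      counts[[a]] / (1 + 10^(pka_set[[a]] - p))
    }, numeric(1)))
    if (termini) {
      pos <- pos + 1 / (1 + 10^(p - pka_set$nterm))
      neg <- neg + 1 / (1 + 10^(pka_set$cterm - p))
    }
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' Root of the Henderson-Hasselbalch net charge, found by bisection on
#' pH in [0, 14] to 1e-4. A sequence whose charge never changes sign
#' (e.g. poly-Asp with blocked termini) gets the boundary pH on the side
#' of its charge, with a warning.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units.
#' @return pI (pH units).
#' @export
isoelectric_point <- function(sequence, pka_set = default_pka_set(),
                              termini = TRUE, tol = 1e-4) {
  f <- function(p) net_charge(sequence, p, pka_set, termini)
  lo <- 0
  hi <- 14
  flo <- f(lo)
  fhi <- f(hi)
  if (flo <= 0) {
    warn("net charge never positive; reporting acidic boundary pI")
    return(lo)
  }
  if (fhi >= 0) {
    warn("net charge never negative; reporting basic boundary pI")
    return(hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Integer formal charge at neutral pH
#'
#' `+1` per Arg/Lys, `-1` per Asp/Glu, His and all others 0; the two free
#' termini cancel.
#'
#' @param sequence one-letter string or character vector.
#' @return signed integer.
#' @export
formal_charge <- function(sequence) {
  s <- seq_split(sequence)
  if (length(s) == 0) abort("sequence must be non-empty")
  aa_three(s)
  sum(s %in% c("K", "R")) - sum(s %in% c("D", "E"))
}

#' BLOSUM similarity of a sequence to a reference alignment
#'
#' Template-anchored, ungapped: for every reference sequence, sums the
#' substitution-matrix entries over the chosen positions; reports the
#' maximum over references (best hit) together with the full per-reference
#' score vector.
#'
#' @param sequence one-letter string, same length as the alignment width.
#' @param reference a `reference_alignment` tibble (`id`, `seq`).
#' @param matrix matrix name (`"BLOSUM40"` or `"BLOSUM62"`) or a numeric
#'   matrix with one-letter dimnames.
#' @param positions optional integer subset of alignment columns; an empty
#'   subset scores 0.
#' @return list with `best` (max score), `scores` (named per-reference
#'   vector).
#' @export
blosum_similarity <- function(sequence, reference, matrix = "BLOSUM40",
                              positions = NULL) {
  m <- if (is.character(matrix)) blosum_matrix(matrix) else matrix
  s <- seq_split(sequence)
  width <- nchar(reference$seq[1])
  if (length(s) != width) {
    abort(paste0("sequence length ", length(s),
                 " does not match alignment width ", width))
  }
  pos <- positions %||% seq_len(width)
  if (length(pos) == 0) {
    sc <- setNames(rep(0, nrow(reference)), reference$id)
    return(list(best = 0, scores = sc))
  }
  if (any(pos < 1 | pos > width)) abort("positions outside alignment width")
  sc <- vapply(reference$seq, function(ref) {
    r <- seq_split(ref)
    sum(m[cbind(s[pos], r[pos])])
  }, numeric(1))
  names(sc) <- reference$id
  list(best = max(sc), scores = sc)
}

#' Count drastic mutations relative to a wild type
#'
#' A substitution is drastic when the substitution-matrix score between
#' the wild-type and new residue is at or below `threshold` (inclusive).
#'
#' @param sequence,wildtype equal-length one-letter strings.
#' @param matrix matrix name or numeric matrix (default BLOSUM62).
#' @param threshold score threshold (default -2).
#' @return integer count.
#' @export
drastic_mutation_count <- function(sequence, wildtype, matrix = "BLOSUM62",
                                   threshold = -2) {
  m <- if (is.character(matrix)) blosum_matrix(matrix) else matrix
  s <- seq_split(sequence)
  w <- seq_split(wildtype)
  if (length(s) != length(w)) {
    abort("sequence and wildtype must have equal lengths")
  }
  diffpos <- which(s != w)
  if (length(diffpos) == 0) return(0L)
  sum(m[cbind(w[diffpos], s[diffpos])] <= threshold)
}

#' Fold-recognition filter
#'
#' Keeps records whose match length is strictly above the mean match
#' length of the input set and whose log10 E-value is below the threshold.
#'
#' @param records fold-recognition tibble (`id`, `log10_evalue`,
#'   `match_length`).
#' @param threshold_log10E keep `log10_evalue < threshold` (default -31).
#' @return character vector of surviving ids.
#' @export
apply_fold_recognition_filter <- function(records, threshold_log10E = -31) {
  if (nrow(records) == 0) abort("records must be non-empty")
  mlen <- mean(records$match_length)
  records$id[records$match_length > mlen &
               records$log10_evalue < threshold_log10E]
}

#' Filtering-cascade configuration
#'
#' Thresholds for the seven-stage selection cascade, with the defaults
#' used throughout the package: keep the `top_n` lowest folding energies,
#' exclude isoelectric points inside `[6.5, 8.5]` (inclusive), require
#' fold-recognition match length above the survivors' mean and
#' log10 E < -31, require best-hit BLOSUM40 similarity at or above the
#' survivors' mean, no buried cavity larger than `cavity_max_volume`,
#' unsigned formal charge strictly below 6, and at most 15 drastic
#' (BLOSUM62 <= -2) mutations.
#'
#' @param top_n energy cut size.
#' @param pi_window inclusive exclusion window for pI.
#' @param log10E_threshold fold-recognition E-value rule.
#' @param similarity_matrix matrix for the similarity stage.
#' @param similarity_positions optional column subset for the similarity
#'   stage (e.g. core positions).
#' @param cavity_max_volume maximum tolerated buried void, Angstrom^3.
#' @param cavity_spacing,cavity_probe cavity-grid parameters.
#' @param charge_max unsigned-charge strict upper bound.
#' @param drastic_matrix,drastic_threshold,drastic_max drastic-mutation
#'   rule.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(top_n = 2000, pi_window = c(6.5, 8.5),
                          log10E_threshold = -31,
                          similarity_matrix = "BLOSUM40",
                          similarity_positions = NULL,
                          cavity_max_volume = 30,
                          cavity_spacing = 1.0, cavity_probe = 1.4,
                          charge_max = 6,
                          drastic_matrix = "BLOSUM62",
                          drastic_threshold = -2, drastic_max = 15) {
  if (pi_window[1] > pi_window[2]) abort("pi_window must be ordered")
  structure(list(top_n = top_n, pi_window = pi_window,
                 log10E_threshold = log10E_threshold,
                 similarity_matrix = similarity_matrix,
                 similarity_positions = similarity_positions,
                 cavity_max_volume = cavity_max_volume,
                 cavity_spacing = cavity_spacing,
                 cavity_probe = cavity_probe,
                 charge_max = charge_max,
                 drastic_matrix = drastic_matrix,
                 drastic_threshold = drastic_threshold,
                 drastic_max = drastic_max),
            class = "filter_config")
}
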
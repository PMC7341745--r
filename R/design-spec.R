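# Design specification (mutability classes) and sequence-space bookkeeping.

#' Build a design specification for a scaffold
#'
#' Assigns every position one of three classes: positions natively occupied
#' by Gly or Pro are `frozen` (they never mutate and have no rotamers to
#' explore); positions in `interface_ids` keep their native type but may
#' explore rotamers (`rotamer_only`); every other position is `mutable` with
#' all twenty types allowed except Gly and Pro.
#'
#' @param scaffold a [backbone_scaffold()].
#' @param interface_ids residue ids (author numbering, `res_id`) that
#'   contact the peptide ligand and must keep wild-type identity.
#' @param extra_frozen residue ids to freeze completely.
#' @return tibble of class `design_spec` with columns `res_idx`, `res_id`,
#'   `native_type`, `class`, `allowed` (list-column of allowed types for
#'   mutable positions).
#' @export
make_design_spec <- function(scaffold, interface_ids = integer(),
                             extra_frozen = integer()) {
  res <- scaffold$residues
  unknown <- setdiff(c(interface_ids, extra_frozen), res$res_id)
  if (length(unknown)) {
    abort(paste0("residue id(s) not in scaffold: ",
                 paste(unknown, collapse = ", ")))
  }
  mutable_types <- setdiff(AA3, c("GLY", "PRO"))
  cls <- character(nrow(res))
  allowed <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    if (res$res_name[i] %in% c("GLY", "PRO") || res$res_id[i] %in% extra_frozen) {
      cls[i] <- "frozen"
      allowed[[i]] <- character()
    } else if (res$res_id[i] %in% interface_ids) {
      cls[i] <- "rotamer_only"
      allowed[[i]] <- character()
    } else {
      cls[i] <- "mutable"
      allowed[[i]] <- mutable_types
    }
  }
  out <- tibble(res_idx = res$res_idx, res_id = res$res_id,
                native_type = res$res_name, class = cls, allowed = allowed)
  class(out) <- c("design_spec", class(out))
  out
}

#' Size of the designable sequence space
#'
#' Product over mutable positions of the number of allowed types, computed
#' in exact integer arithmetic (arbitrary precision, base-10000 digits).
#'
#' @param spec a [make_design_spec()] result.
#' @return object of class `big_integer`; `as.character()` gives the exact
#'   decimal value, `log10()` its magnitude, and `signif_mantissa()` the
#'   leading mantissa at a chosen number of significant figures.
#' @export
sequence_space_size <- function(spec) {
  counts <- vapply(spec$allowed[spec$class == "mutable"], length, integer(1))
  x <- big_from_int(1)
  for (k in counts) x <- big_mul_small(x, k)
  x
}

# --- minimal exact big-integer arithmetic (base 1e4, little-endian) -------

big_from_int <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  d <- integer()
  n <- as.numeric(n)
  repeat {
    d <- c(d, n %% 10000)
    n <- n %/% 10000
    if (n == 0) break
  }
  structure(as.integer(d), class = "big_integer")
}

big_mul_small <- function(x, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^20)
  v <- as.numeric(unclass(x)) * m
  out <- numeric(0)
  cr <- 0
  for (i in seq_along(v)) {
    t <- v[i] + cr
    out[i] <- t %% 10000
    cr <- t %/% 10000
  }
  while (cr > 0) {
    out <- c(out, cr %% 10000)
    cr <- cr %/% 10000
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  structure(as.integer(out), class = "big_integer")
}

#' Multiply two exact big integers
#'
#' @param x,y `big_integer` objects.
#' @return `big_integer` product.
#' @export
big_mul <- function(x, y) {
  a <- as.numeric(unclass(x))
  b <- as.numeric(unclass(y))
  # schoolbook product; cells stay below 2^53 for the sizes used here
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    seg <- seq_along(b) + i - 1
    res[seg] <- res[seg] + a[i] * b
  }
  # carry pass
  cr <- 0
  for (i in seq_along(res)) {
    t <- res[i] + cr
    res[i] <- t %% 10000
    cr <- t %/% 10000
  }
  while (cr > 0) {
    res <- c(res, cr %% 10000)
    cr <- cr %/% 10000
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  structure(as.integer(res), class = "big_integer")
}

#' @export
as.character.big_integer <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.big_integer <- function(x, ...) {
  s <- as.character(x)
  cat("<big_integer>", s, sprintf("(10^%.4f)", big_log10(x)), "\n")
  invisible(x)
}

#' Decimal magnitude of a big integer
#'
#' @param x a `big_integer`.
#' @return `log10(x)` as a double.
#' @export
big_log10 <- function(x) {
  s <- as.character(x)
  nchar(s) - 1 + log10(as.numeric(paste0(substr(s, 1, 1), ".",
                                         substr(s, 2, min(16, nchar(s))))))
}

#' Leading mantissa of a big integer
#'
#' @param x a `big_integer`.
#' @param digits significant figures.
#' @return numeric mantissa in `[1, 10)` rounded to `digits` figures.
#' @export
signif_mantissa <- function(x, digits = 2) {
  s <- as.character(x)
  m <- as.numeric(paste0(substr(s, 1, 1), ".",
                         substr(s, 2, min(16, nchar(s)))))
  signif(m, digits)
}

#' @export
`==.big_integer` <- function(e1, e2) {
  as.character(e1) == as.character(e2)
}
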
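# Amino-acid code tables and small shared utilities.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_BY_1 <- setNames(AA3, AA1)

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes (all one-letter or all three-letter).
#' @return character vector in the other convention.
#' @export
aa_three <- function(x) {
  out <- AA3_BY_1[toupper(x)]
  if (anyNA(out)) {
    abort(paste0("unknown amino-acid code(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  out <- AA1[toupper(x)]
  if (anyNA(out)) {
    abort(paste0("unknown amino-acid code(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

# split a one-letter sequence string into a character vector
seq_split <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "cpdesign", mustWork = FALSE)
  if (p == "") {
    # during development (load_all) inst/ may be the source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) abort(paste0("packaged data file not found: ", file))
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
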
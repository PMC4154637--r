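#' @importFrom utils read.delim modifyList head
NULL

# one-letter <-> lower-case name maps for the 20 proteinogenic amino acids
.AA1 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys",
          Q = "gln", E = "glu", G = "gly", H = "his", I = "ile",
          L = "leu", K = "lys", M = "met", F = "phe", P = "pro",
          S = "ser", T = "thr", W = "trp", Y = "tyr", V = "val")
.AA3 <- structure(names(.AA1), names = unname(.AA1))

#' Monomer name helpers
#'
#' `oneLetterToMonomer()` and `monomerToOneLetter()` convert between
#' one-letter amino-acid codes and the lower-case monomer names used
#' throughout the package. Nonproteinogenic monomers (e.g. `"orn"`) have no
#' one-letter code and map to `NA`.
#'
#' @param x character vector of one-letter codes or monomer names.
#' @return character vector of the same length; `NA` where no mapping exists.
#' @examples
#' oneLetterToMonomer(c("V", "W"))
#' monomerToOneLetter(c("val", "orn"))
#' @export
oneLetterToMonomer <- function(x) unname(.AA1[toupper(x)])

#' @rdname oneLetterToMonomer
#' @export
monomerToOneLetter <- function(x) unname(.AA3[tolower(x)])

#' The default monomer alphabet
#'
#' The alphabet is the set of monomers carried by the shipped
#' NORINE-style frequency snapshot: the 20 proteinogenic amino acids plus
#' common nonproteinogenic NRP monomers (ornithine, diaminobutyrate,
#' hydroxyphenylglycines, homotyrosine, allo-threonine, valinol, ...).
#'
#' @return character vector of lower-case monomer names.
#' @seealso [defaultFrequencyTable()]
#' @export
defaultAlphabet <- function() {
  names(counts(defaultFrequencyTable()))
}

.normalizeMonomer <- function(x) tolower(trimws(x))
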
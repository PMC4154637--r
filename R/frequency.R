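.pkgCache <- new.env(parent = emptyenv())

#' Read a monomer frequency table
#'
#' Tab-separated file with comment lines starting `#` and columns
#' `monomer` and `count`; the alphabet is the set of monomers listed.
#'
#' @param path file path.
#' @param pseudocount additive smoothing constant k (default 1, correcting
#'   for the limited sample size of the background peptide set).
#' @return a [MonomerFrequencyTable-class] object.
#' @export
readFrequencyTable <- function(path, pseudocount = 1) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("monomer", "count") %in% names(df)))
    stop(sprintf("frequency table '%s' must have columns monomer, count",
                 path))
  monomerFrequencyTable(structure(as.numeric(df$count),
                                  names = df$monomer),
                        pseudocount = pseudocount)
}

#' The shipped background frequency table
#'
#' A NORINE-style synthetic snapshot of monomer occurrence counts in known
#' nonribosomal peptides (see
#' `system.file("extdata", "monomer_frequencies_synthetic.tsv",
#' package = "pep2path")`). It is a constructed stand-in with realistic
#' relative abundances, not an export of the live NORINE database; users
#' with access to curated counts can drop in their own file via
#' [readFrequencyTable()].
#'
#' @param pseudocount additive smoothing constant k (default 1).
#' @return a [MonomerFrequencyTable-class] object.
#' @export
defaultFrequencyTable <- function(pseudocount = 1) {
  key <- sprintf("freq_%g", pseudocount)
  if (is.null(.pkgCache[[key]])) {
    path <- system.file("extdata", "monomer_frequencies_synthetic.tsv",
                        package = "pep2path", mustWork = TRUE)
    .pkgCache[[key]] <- readFrequencyTable(path, pseudocount = pseudocount)
  }
  .pkgCache[[key]]
}

#' Background probability P(A) of a tag position
#'
#' For a singleton position (or a bare monomer name) the background
#' probability is the additively smoothed frequency
#' \deqn{P(A) = (n_A + k) / (N + k |\Sigma|),}
#' with `n_A` the monomer's occurrence count, `N` the total count, `k` the
#' pseudocount and \eqn{\Sigma} the alphabet. A degenerate position (more
#' than one candidate) gets the fixed baseline \eqn{1/|\Sigma|} instead:
#' treating a merely possible rare monomer as an actual observation would
#' bias scores towards matches to rare monomers.
#'
#' @param a a monomer name, a candidate character vector, or a
#'   [SequenceTag-class] position list element.
#' @param freq a [MonomerFrequencyTable-class] object.
#' @return probability in (0, 1).
#' @examples
#' f <- monomerFrequencyTable(c(ala = 3, gly = 1, ser = 0, val = 0))
#' baselineProbability("ala", f)   # (3+1)/(4+4) = 0.5
#' baselineProbability(c("thr", "ser"), defaultFrequencyTable())
#' @export
baselineProbability <- function(a, freq) {
  if (is(a, "SequenceTag")) {
    return(vapply(a@positions, baselineProbability, numeric(1L),
                  freq = freq))
  }
  a <- .normalizeMonomer(a)
  bad <- setdiff(a, freq@alphabet)
  if (length(bad))
    stop(sprintf("monomer(s) outside the alphabet: %s",
                 paste(bad, collapse = ", ")))
  sigma <- length(freq@alphabet)
  if (length(a) > 1L) return(1 / sigma)
  k <- freq@pseudocount
  unname((freq@counts[[a]] + k) / (sum(freq@counts) + k * sigma))
}

#' Write a frequency table to file
#'
#' @param freq a [MonomerFrequencyTable-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(freq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# monomer frequency table, %d-monomer alphabet",
                       length(freq@alphabet)),
               "monomer\tcount"), con)
  writeLines(sprintf("%s\t%d", names(freq@counts),
                     as.integer(freq@counts)), con)
  invisible(path)
}
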
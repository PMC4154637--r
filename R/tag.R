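## Tag grammar (EBNF):
##   tag       = token , { [ "-" ] , token } ;
##   token     = residue , [ "(" , alt , { "/" , alt } , ")" ] ;
##   residue   = one-letter code | monomer name ;
##   alt       = one-letter code | monomer name ;
## Dash separators are required between multi-letter monomer names; a
## dash-free string is read either as a single monomer name or as a run of
## one-letter codes, each optionally followed by its parenthesized
## alternatives (e.g. "VHFVGWI(L)").

.tokenToMonomer <- function(token, alphabet, context) {
  token <- trimws(token)
  if (nchar(token) == 1L) {
    m <- oneLetterToMonomer(token)
    if (is.na(m))
      stop(sprintf("unknown one-letter code '%s' in tag '%s'", token, context))
  } else {
    m <- .normalizeMonomer(token)
  }
  if (!m %in% alphabet)
    stop(sprintf("unknown monomer '%s' in tag '%s'", token, context))
  m
}

.splitTokens <- function(text, alphabet) {
  if (grepl("-", text, fixed = TRUE))
    return(strsplit(text, "-", fixed = TRUE)[[1L]])
  # dash-free: a bare monomer name, or a run of one-letter codes with
  # optional parenthesized alternatives
  if (grepl("^[A-Za-z]{2,}$", text) && .normalizeMonomer(text) %in% alphabet)
    return(text)
  m <- gregexpr("[A-Za-z](\\([^()]*\\))?", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop(sprintf("cannot tokenize tag '%s' (unbalanced parentheses?)", text))
  tokens
}

#' Parse a peptide sequence tag
#'
#' Accepts the tag notations in common use: dash-separated monomer names
#' (`"thr-pro-pro-arg"`), dash-separated one-letter codes with
#' parenthesized alternatives (`"V-V-T(S)-T(S)-A-I(L)-V-G"`), and compact
#' one-letter runs (`"VHFVGWI(L)"`). A parenthesized group lists
#' alternative candidates for the preceding residue; `"X(Y)"` yields the
#' candidate set \{X, Y\}.
#'
#' @param text the tag string.
#' @param kind `"nrp"` or `"ripp"`.
#' @param alphabet monomer alphabet the candidates must belong to.
#' @return a [SequenceTag-class] object.
#' @examples
#' parseTag("V-V-T(S)-T(S)-A-I(L)-V-G")
#' parseTag("VHFVGWI(L)")
#' @seealso [formatTag()], [massesToTag()]
#' @export
parseTag <- function(text, kind = c("nrp", "ripp"),
                     alphabet = defaultAlphabet()) {
  kind <- match.arg(kind)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("empty tag string")
  text <- trimws(text)
  if (lengths(regmatches(text, gregexpr("(", text, fixed = TRUE))) !=
      lengths(regmatches(text, gregexpr(")", text, fixed = TRUE))))
    stop(sprintf("unbalanced parentheses in tag '%s'", text))
  tokens <- .splitTokens(text, alphabet)
  tokens <- tokens[nzchar(trimws(tokens))]
  if (!length(tokens)) stop("empty tag string")
  positions <- lapply(tokens, function(tok) {
    hasAlt <- grepl("(", tok, fixed = TRUE)
    if (hasAlt) {
      if (!grepl("^[^()]+\\([^()]+\\)$", tok))
        stop(sprintf("malformed token '%s' in tag '%s'", tok, text))
      base <- sub("\\(.*$", "", tok)
      alts <- strsplit(sub("^[^(]*\\(([^)]*)\\)$", "\\1", tok), "[/,]")[[1L]]
      cands <- c(.tokenToMonomer(base, alphabet, text),
                 vapply(alts, .tokenToMonomer, character(1L),
                        alphabet = alphabet, context = text))
    } else {
      cands <- .tokenToMonomer(tok, alphabet, text)
    }
    unique(cands)
  })
  sequenceTag(positions, kind = kind, alphabet = alphabet)
}

#' Format a sequence tag as its canonical string
#'
#' Dash-separated monomer names with alternatives in parentheses, e.g.
#' `"val-val-thr(ser)"`. `parseTag(formatTag(tag))` reproduces `tag`.
#'
#' @param tag a [SequenceTag-class] object.
#' @return a single string.
#' @export
formatTag <- function(tag) {
  paste(vapply(tag@positions, function(p) {
    if (length(p) == 1L) p
    else sprintf("%s(%s)", p[1L], paste(p[-1L], collapse = "/"))
  }, character(1L)), collapse = "-")
}

#' Read a mass-shift conversion table
#'
#' Tab-separated file with comment lines starting `#` and columns `mass`
#' (Da), `candidates` ("/"-joined monomer names) and `label`.
#'
#' @param path file path.
#' @param tolerance matching tolerance in Da (default 0.02, typical
#'   high-resolution MS tag accuracy).
#' @return a [MassConversionTable-class] object.
#' @seealso [defaultMassTable()], [massesToTag()]
#' @export
readMassTable <- function(path, tolerance = 0.02) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("mass", "candidates", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("mass table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  new("MassConversionTable",
      masses = as.numeric(df$mass),
      candidates = lapply(strsplit(df$candidates, "/", fixed = TRUE),
                          .normalizeMonomer),
      labels = as.character(df$label),
      tolerance = tolerance)
}

#' Shipped mass-conversion tables
#'
#' `kind = "nrp"` covers proteinogenic plus common nonproteinogenic NRP
#' monomers; `kind = "ripp"` is PTM-aware (Ile/Leu; lanthionine-linked Cys
#' reading at Ala/Ser masses; Lys/Gln merging at low resolution through the
#' tolerance). Both are plain editable files under the package's `extdata`.
#'
#' @param kind `"nrp"` or `"ripp"`.
#' @param tolerance matching tolerance in Da.
#' @return a [MassConversionTable-class] object.
#' @export
defaultMassTable <- function(kind = c("nrp", "ripp"), tolerance = 0.02) {
  kind <- match.arg(kind)
  path <- system.file("extdata",
                      sprintf("residue_masses_%s.tsv", kind),
                      package = "pep2path", mustWork = TRUE)
  readMassTable(path, tolerance = tolerance)
}

#' Convert an ordered mass-shift list into a degenerate sequence tag
#'
#' Each mass shift collects the union of the candidate sets of every
#' conversion-table row within the table's tolerance, so isobaric residues
#' (Ile/Leu, Thr/allo-Thr, ...) naturally produce degenerate positions.
#'
#' @param shifts numeric vector of mass shifts (Da), all positive.
#' @param table a [MassConversionTable-class]; defaults to the shipped NRP
#'   table.
#' @param kind `"nrp"` or `"ripp"` (also selects the default table).
#' @return a [SequenceTag-class] with `sourceMass` recorded per position.
#' @examples
#' formatTag(massesToTag(c(99.068, 113.084)))
#' @export
massesToTag <- function(shifts, table = NULL, kind = c("nrp", "ripp")) {
  kind <- match.arg(kind)
  if (is.null(table)) table <- defaultMassTable(kind)
  if (!length(shifts)) stop("empty mass-shift list")
  if (any(!is.finite(shifts) | shifts <= 0))
    stop("mass shifts must be positive numbers")
  positions <- lapply(shifts, function(s) {
    hit <- abs(table@masses - s) <= table@tolerance
    if (!any(hit))
      stop(sprintf(
        "mass shift %.5f Da matches no conversion-table row within %.4g Da",
        s, table@tolerance))
    unique(unlist(table@candidates[hit], use.names = FALSE))
  })
  alphabet <- unique(c(defaultAlphabet(),
                       unlist(positions, use.names = FALSE)))
  sequenceTag(positions, kind = kind, alphabet = alphabet,
              sourceMass = as.numeric(shifts))
}

#' Expand a degenerate tag into all concrete sequences
#'
#' @param tag a [SequenceTag-class] object.
#' @param cap maximum number of sequences to generate (default 10000);
#'   exceeding it is an error naming the product size.
#' @param collapse separator joining monomer names (default `"-"`).
#' @return character vector of all concrete sequences, lexicographically
#'   ordered; its length is the product of per-position candidate counts.
#' @examples
#' expandTag(parseTag("V-V-T(S)-T(S)-A-I(L)-V-G"))
#' @export
expandTag <- function(tag, cap = 10000, collapse = "-") {
  sizes <- lengths(tag@positions)
  total <- prod(sizes)
  if (total > cap)
    stop(sprintf("tag expands to %.0f sequences, above the cap of %d",
                 total, as.integer(cap)))
  sorted <- lapply(tag@positions, sort)
  # later positions vary fastest => lexicographic order of the output
  grid <- expand.grid(rev(sorted), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(sorted)), drop = FALSE]
  out <- do.call(paste, c(unname(as.list(grid)), sep = collapse))
  sort(out)
}

#' Reverse a sequence tag
#'
#' MS fragmentation does not reveal the N-to-C reading direction of a tag;
#' scoring and matching therefore consider the reversed tag as well.
#' Candidates within each position are untouched.
#'
#' @param tag a [SequenceTag-class] object.
#' @return the reversed [SequenceTag-class].
#' @export
reverseTag <- function(tag) {
  new("SequenceTag", positions = rev(tag@positions),
      sourceMass = rev(tag@sourceMass), kind = tag@kind,
      alphabet = tag@alphabet)
}
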
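#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement translate getGeneticCode subseq
NULL

.asDNAStringSet <- function(genomes) {
  if (is(genomes, "DNAStringSet")) return(genomes)
  if (is(genomes, "DNAString")) return(DNAStringSet(list(genome = genomes)))
  if (is.character(genomes)) {
    if (is.null(names(genomes)))
      names(genomes) <- sprintf("record%d", seq_along(genomes))
    bad <- grepl("[^ACGTNacgtn]", genomes)
    if (any(bad))
      stop(sprintf("record '%s' contains non-nucleotide characters",
                   names(genomes)[which(bad)[1L]]))
    return(DNAStringSet(genomes))
  }
  stop("genomes must be a DNAStringSet or a named character vector")
}

#' Six-frame translation of a genome record
#'
#' Translates all three frames of both strands with the bacterial/archaeal
#' genetic code (translation table 11; identical codon assignments to the
#' standard code). Stop codons become `"*"` and codons containing `N`
#' become `"X"`; neither symbol matches any tag candidate, so matching
#' windows never span stops or ambiguous codons. Minus-strand frames
#' translate the reverse complement: frame `-f` is frame `+f` of the
#' reverse-complemented record.
#'
#' @param genomes a [Biostrings::DNAStringSet], single
#'   [Biostrings::DNAString], or named character vector of DNA sequences
#'   over `A,C,G,T,N` (each of length >= 3).
#' @return a data.frame with columns `record`, `frame` (+1..+3, -1..-3),
#'   `strand` and `peptide`, six rows per record.
#' @examples
#' sixFrameTranslate(c(x = "ATGAAAACC"))
#' @export
sixFrameTranslate <- function(genomes) {
  gset <- .asDNAStringSet(genomes)
  code <- getGeneticCode("11")
  out <- vector("list", length(gset))
  for (r in seq_along(gset)) {
    d <- gset[[r]]
    str <- as.character(d)
    if (grepl("[^ACGTNacgtn]", str))
      stop(sprintf("record '%s' contains non-nucleotide characters",
                   names(gset)[r]))
    n <- length(d)
    if (n < 3L)
      stop(sprintf("record '%s' is shorter than one codon", names(gset)[r]))
    # N-containing codons must read as the unknown symbol "X"; the
    # ambiguity-aware translation path is slow, so translate an N->A
    # substituted copy on the fast path and patch the affected residues
    nPosFwd <- which(strsplit(str, "", fixed = TRUE)[[1L]] %in% c("N", "n"))
    if (length(nPosFwd)) d <- DNAString(chartr("Nn", "AA", str))
    rc <- reverseComplement(d)
    nPosRev <- n + 1L - nPosFwd
    fs <- DNAStringSet(unlist(lapply(list(d, rc), function(s)
      lapply(1:3, function(f) {
        len <- 3L * ((n - f + 1L) %/% 3L)
        subseq(s, f, f + len - 1L)
      })), recursive = FALSE))
    peps <- as.character(translate(fs, genetic.code = code,
                                   no.init.codon = TRUE))
    if (length(nPosFwd)) {
      for (k in 1:6) {
        f <- c(1:3, 1:3)[k]
        np <- if (k <= 3L) nPosFwd else nPosRev
        nAa <- nchar(peps[k])
        aaIdx <- unique((np[np >= f] - f) %/% 3L + 1L)
        aaIdx <- aaIdx[aaIdx <= nAa]
        for (i in aaIdx) substr(peps[k], i, i) <- "X"
      }
    }
    out[[r]] <- data.frame(record = names(gset)[r],
                           frame = c(1L, 2L, 3L, -1L, -2L, -3L),
                           strand = rep(c("+", "-"), each = 3L),
                           peptide = peps,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# genomic 0-based half-open interval of an aa window in a frame
# aaOffset is 0-based within the frame's peptide
.windowToGenomic <- function(frame, recordLength, aaOffset, aaLen) {
  f <- abs(frame)
  s <- (f - 1L) + 3L * aaOffset
  e <- s + 3L * aaLen
  if (frame > 0L) c(start = s, end = e)
  else c(start = recordLength - e, end = recordLength - s)
}

.tagLetterSets <- function(tag) {
  lapply(tag@positions, function(p) {
    l <- monomerToOneLetter(p)
    unique(l[!is.na(l)])
  })
}

.emptyMatches <- function() {
  data.frame(record = character(), strand = character(),
             frame = integer(), start = integer(), end = integer(),
             peptide = character(), tag_orientation = character(),
             stringsAsFactors = FALSE)
}

#' Find precursor-peptide matches of a RiPP tag in genome sequences
#'
#' Slides a window of the tag's length along all six translation frames of
#' every record and reports each window where every residue belongs to the
#' corresponding tag position's candidate set. Candidates without a
#' one-letter code (nonproteinogenic monomers) can never match a
#' ribosomal translation. With `orientationMode = "both"` the reversed tag
#' is matched as well and loci found by both orientations are reported
#' once (as forward). Zero matches is a valid outcome.
#'
#' @param tag a [SequenceTag-class] object.
#' @param genomes a [Biostrings::DNAStringSet], single
#'   [Biostrings::DNAString], or named character vector of DNA sequences.
#' @param orientationMode `"forward"` (default, the conservative reading)
#'   or `"both"`.
#' @return a data.frame in deterministic (record, frame, offset) order
#'   with columns `record`, `strand`, `frame`, `start`, `end` (0-based
#'   half-open forward-strand genomic coordinates; `end - start` is three
#'   times the tag length), `peptide` (the matched translation) and
#'   `tag_orientation`.
#' @examples
#' g <- generateRippGenome(600, "MKTAYIA", seed = 1)
#' findPrepeptideMatches(parseTag("MKTAYIA", kind = "ripp"), g$genome)
#' @export
findPrepeptideMatches <- function(tag, genomes,
                                  orientationMode = c("forward", "both")) {
  orientationMode <- match.arg(orientationMode)
  gset <- .asDNAStringSet(genomes)
  L <- length(tag@positions)
  frames <- sixFrameTranslate(gset)
  lens <- structure(Biostrings::width(gset), names = names(gset))
  sets <- list(forward = .tagLetterSets(tag))
  if (orientationMode == "both")
    sets$reversed <- rev(sets$forward)
  rows <- list()
  # frames is ordered (record, +1,+2,+3,-1,-2,-3) already
  for (k in seq_len(nrow(frames))) {
    pep <- frames$peptide[k]
    n <- nchar(pep)
    if (n < L) next
    chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
    nWin <- n - L + 1L
    for (orient in names(sets)) {
      letters <- sets[[orient]]
      if (any(lengths(letters) == 0L)) next
      hit <- rep(TRUE, nWin)
      for (j in seq_len(L)) {
        hit <- hit & (chars[j:(j + nWin - 1L)] %in% letters[[j]])
        if (!any(hit)) break
      }
      for (i0 in which(hit) - 1L) {
        cc <- .windowToGenomic(frames$frame[k], lens[[frames$record[k]]],
                               i0, L)
        rows[[length(rows) + 1L]] <- data.frame(
          record = frames$record[k], strand = frames$strand[k],
          frame = frames$frame[k], start = unname(cc["start"]),
          end = unname(cc["end"]),
          peptide = substr(pep, i0 + 1L, i0 + L),
          tag_orientation = orient, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.emptyMatches())
  out <- do.call(rbind, rows)
  # a palindromic-in-tag locus found via both orientations is one locus
  key <- paste(out$record, out$frame, out$start, out$end)
  out$tag_orientation[key %in% key[duplicated(key)]] <- "forward"
  out <- out[!duplicated(key), , drop = FALSE]
  ordKey <- order(match(out$record, names(gset)),
                  match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L)),
                  out$start)
  out <- out[ordKey, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a RiPP match table
#'
#' Tab-separated export of [findPrepeptideMatches()] results. With
#' `coords = "halfopen"` (machine output) coordinates are 0-based
#' half-open; with `coords = "genbank"` (human-readable) they are 1-based
#' inclusive. The convention in use is stated in the header line.
#'
#' @param matches a [findPrepeptideMatches()] result.
#' @param path output file path.
#' @param coords `"halfopen"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
writeMatchTable <- function(matches, path,
                            coords = c("halfopen", "genbank")) {
  coords <- match.arg(coords)
  df <- matches
  if (coords == "genbank") df$start <- df$start + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coordinates: %s",
                     if (coords == "halfopen")
                       "0-based half-open, forward strand"
                     else "1-based inclusive, forward strand"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export RiPP matches as BED6
#'
#' @param matches a [findPrepeptideMatches()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(matches, path) {
  bed <- data.frame(matches$record, matches$start, matches$end,
                    matches$peptide, 0L, matches$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
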
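#' Construct a specificity prediction
#'
#' @param stachCode 10-character Stachelhaus code, or `NA`.
#' @param stachMatch monomer(s) loaded by the closest known code.
#' @param stachIdentity identity to the closest known code. Values in
#'   (1, 100] are interpreted as percent and divided by 100, since
#'   predictor output commonly reports percent of the 10-residue code.
#' @param svmSingle,svmSmall,svmLarge,svmThree SVM monomer sets (character
#'   vectors, possibly empty; `"nrp"` no-call tokens become empty sets).
#' @return a [SpecificityPrediction-class] object.
#' @examples
#' specificityPrediction(svmSingle = "val", svmSmall = c("val", "ile"),
#'                       stachMatch = "val", stachIdentity = 90)
#' @export
specificityPrediction <- function(stachCode = NA_character_,
                                  stachMatch = character(),
                                  stachIdentity = NA_real_,
                                  svmSingle = character(),
                                  svmSmall = character(),
                                  svmLarge = character(),
                                  svmThree = character()) {
  clean <- function(x) {
    x <- .normalizeMonomer(x[!is.na(x)])
    x <- x[nzchar(x) & x != "nrp"]
    unique(x)
  }
  stachIdentity <- as.numeric(stachIdentity)
  if (length(stachIdentity) != 1L)
    stop("stachIdentity must be a single number or NA")
  if (!is.na(stachIdentity) && stachIdentity > 1) {
    if (stachIdentity > 100)
      stop("stachIdentity must be a fraction in [0,1] or a percent in (1,100]")
    stachIdentity <- stachIdentity / 100
  }
  new("SpecificityPrediction",
      stachCode = as.character(stachCode)[1L],
      stachMatch = clean(stachMatch),
      stachIdentity = stachIdentity,
      svmSingle = clean(svmSingle),
      svmSmall = clean(svmSmall),
      svmLarge = clean(svmLarge),
      svmThree = clean(svmThree))
}

#' Construct a BGC entry
#'
#' @param clusterId unique cluster identifier.
#' @param genes named list: names are gene ids, each element a list of
#'   [SpecificityPrediction-class] objects in native module order.
#' @param accession source nucleotide record name.
#' @param lineage ordered taxonomy character vector, broadest rank first.
#' @return a [BGCEntry-class] object.
#' @export
bgcEntry <- function(clusterId, genes, accession = NA_character_,
                     lineage = character()) {
  new("BGCEntry", clusterId = as.character(clusterId),
      accession = as.character(accession)[1L],
      lineage = as.character(lineage), genes = genes)
}

#' Construct a BGC database
#'
#' @param entries list of [BGCEntry-class] objects.
#' @param alphabet monomer alphabet; defaults to [defaultAlphabet()].
#' @param provenance free-text metadata.
#' @return a [BGCDatabase-class] object.
#' @export
bgcDatabase <- function(entries = list(), alphabet = defaultAlphabet(),
                        provenance = "constructed in R") {
  new("BGCDatabase", entries = entries, alphabet = alphabet,
      provenance = as.character(provenance))
}

#' Construct a sequence tag from candidate sets
#'
#' Lower-level companion to [parseTag()] and [massesToTag()].
#'
#' @param positions list of character vectors of candidate monomer names
#'   (a plain character vector is taken as singleton positions).
#' @param kind `"nrp"` or `"ripp"`.
#' @param alphabet monomer alphabet; defaults to [defaultAlphabet()].
#' @param sourceMass optional per-position source mass shifts (Da).
#' @return a [SequenceTag-class] object.
#' @examples
#' sequenceTag(list("val", c("thr", "ser"), "gly"))
#' @export
sequenceTag <- function(positions, kind = "nrp",
                        alphabet = defaultAlphabet(), sourceMass = NULL) {
  if (is.character(positions)) positions <- as.list(positions)
  positions <- lapply(positions, .normalizeMonomer)
  if (is.null(sourceMass)) sourceMass <- rep(NA_real_, length(positions))
  new("SequenceTag", positions = positions, sourceMass = sourceMass,
      kind = match.arg(kind, c("nrp", "ripp")), alphabet = alphabet)
}

#' Construct a monomer frequency table
#'
#' @param counts named non-negative occurrence counts.
#' @param alphabet monomer alphabet; defaults to the count names. Alphabet
#'   members without a count get count 0.
#' @param pseudocount additive smoothing constant k (default 1).
#' @return a [MonomerFrequencyTable-class] object.
#' @examples
#' monomerFrequencyTable(c(ala = 3, gly = 1, ser = 0, val = 0))
#' @export
monomerFrequencyTable <- function(counts, alphabet = names(counts),
                                  pseudocount = 1) {
  names(counts) <- .normalizeMonomer(names(counts))
  alphabet <- .normalizeMonomer(alphabet)
  full <- structure(numeric(length(alphabet)), names = alphabet)
  full[names(counts)] <- counts
  new("MonomerFrequencyTable", counts = full, alphabet = alphabet,
      pseudocount = pseudocount)
}

#' Construct scoring parameters
#'
#' Defaults are the published defaults of the method: confidence c = 1,
#' pseudocount x = 0.01, mismatch exponent eta = 2; both tag orientations
#' are scored because MS tags do not reveal the N-to-C direction.
#'
#' @param c confidence factor (>= 0).
#' @param x pseudocount in (0, 1].
#' @param eta mismatch exponent (>= 1).
#' @param orientationMode `"both"` or `"forward"`.
#' @param maxOrderings cap on enumerated assembly-line configurations.
#' @param tieBreak `"colinearity"` or `"cluster_id"`.
#' @return a [ScoringParams-class] object.
#' @export
scoringParams <- function(c = 1, x = 0.01, eta = 2,
                          orientationMode = c("both", "forward"),
                          maxOrderings = 5040,
                          tieBreak = c("colinearity", "cluster_id")) {
  new("ScoringParams", c = c, x = x, eta = eta,
      orientationMode = match.arg(orientationMode),
      maxOrderings = maxOrderings, tieBreak = match.arg(tieBreak))
}
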
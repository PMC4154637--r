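#' @import methods
NULL

#' Adenylation-domain substrate specificity prediction
#'
#' Holds the two NRPSPredictor2-style prediction channels for one NRPS
#' module: the Stachelhaus-code channel (the 10-residue active-site code,
#' the monomer(s) of the most closely related known code, and the fractional
#' identity to it) and the nested SVM channel (single / small-class /
#' large-class / three-class monomer sets). "nrp"/no-call SVM predictions
#' are represented as empty sets and contribute a 0 tier.
#'
#' @slot stachCode 10-character residue string, or `NA` when absent.
#' @slot stachMatch monomer set the best-matching known code loads
#'   (empty when the channel is absent).
#' @slot stachIdentity fractional identity in `[0, 1]` to the closest known
#'   code, or `NA` when the channel is absent.
#' @slot svmSingle,svmSmall,svmLarge,svmThree nested monomer sets for the
#'   four SVM granularities; any may be empty.
#' @seealso [specificityPrediction()], [matchValue()]
#' @export
setClass("SpecificityPrediction",
  representation(
    stachCode = "character",
    stachMatch = "character",
    stachIdentity = "numeric",
    svmSingle = "character",
    svmSmall = "character",
    svmLarge = "character",
    svmThree = "character"
  )
)

setValidity("SpecificityPrediction", function(object) {
  msg <- character()
  id <- object@stachIdentity
  if (length(id) != 1L)
    msg <- c(msg, "stachIdentity must have length 1 (NA when absent)")
  else if (!is.na(id) && (id < 0 || id > 1))
    msg <- c(msg, "stachIdentity must lie in [0, 1]")
  stachPresent <- length(object@stachMatch) > 0L && !is.na(id)
  svm <- list(object@svmSingle, object@svmSmall, object@svmLarge,
              object@svmThree)
  svmPresent <- any(lengths(svm) > 0L)
  if (!stachPresent && !svmPresent)
    msg <- c(msg, "at least one prediction channel must be present")
  # nesting: single <= small <= large <= three, among non-empty tiers
  tiers <- c("svmSingle", "svmSmall", "svmLarge", "svmThree")
  for (i in seq_len(3L)) {
    a <- slot(object, tiers[i]); b <- slot(object, tiers[i + 1L])
    if (length(a) && length(b) && !all(a %in% b))
      msg <- c(msg, sprintf("SVM sets must be nested: %s is not a subset of %s",
                            tiers[i], tiers[i + 1L]))
  }
  if (length(msg)) msg else TRUE
})

#' A biosynthetic gene cluster entry
#'
#' One NRPS-encoding BGC: its identifier, the nucleotide accession it was
#' found on, the organism lineage (ordered, domain to strain), and the
#' ordered genes with their ordered module predictions. Module ordinals
#' within a gene are implicit list positions (0-based in all outputs), so
#' they are consecutive and unique by construction.
#'
#' @slot clusterId unique cluster identifier.
#' @slot accession source nucleotide record name.
#' @slot lineage ordered taxonomy, most inclusive rank first.
#' @slot genes named list (names are gene ids, unique, order meaningful);
#'   each element is a list of [SpecificityPrediction-class] objects, one
#'   per module in native encoded order.
#' @seealso [bgcEntry()], [scoreTagAgainstBgc()]
#' @export
setClass("BGCEntry",
  representation(
    clusterId = "character",
    accession = "character",
    lineage = "character",
    genes = "list"
  )
)

setValidity("BGCEntry", function(object) {
  msg <- character()
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  gid <- names(object@genes)
  if (is.null(gid) || any(!nzchar(gid)))
    msg <- c(msg, "genes must be a named list (names are gene ids)")
  else if (anyDuplicated(gid))
    msg <- c(msg, sprintf("duplicate gene_id in entry '%s': %s",
                          object@clusterId,
                          paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  nmod <- sum(lengths(object@genes))
  if (nmod < 1L)
    msg <- c(msg, sprintf("entry '%s' must contain at least one module",
                          object@clusterId))
  ok <- vapply(unlist(object@genes, recursive = FALSE, use.names = FALSE),
               is, logical(1L), "SpecificityPrediction")
  if (length(ok) && !all(ok))
    msg <- c(msg, "every module must be a SpecificityPrediction")
  if (length(msg)) msg else TRUE
})

#' A database of BGC entries
#'
#' @slot entries list of [BGCEntry-class] objects with unique cluster ids.
#' @slot alphabet the monomer alphabet the predictions are expressed in.
#' @slot provenance free-text metadata recorded at construction/merge time.
#' @seealso [loadDatabase()], [mergeDatabases()], [rankBgcs()]
#' @export
setClass("BGCDatabase",
  representation(
    entries = "list",
    alphabet = "character",
    provenance = "character"
  )
)

setValidity("BGCDatabase", function(object) {
  msg <- character()
  ok <- vapply(object@entries, is, logical(1L), "BGCEntry")
  if (length(ok) && !all(ok))
    msg <- c(msg, "entries must all be BGCEntry objects")
  ids <- vapply(object@entries, function(e) e@clusterId, character(1L))
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate cluster ids: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A peptide sequence tag
#'
#' An ordered list of tag positions, each a non-empty set of candidate
#' monomers. Degenerate positions (more than one candidate) arise from
#' isobaric residues or printed alternatives such as `"I(L)"`.
#'
#' @slot positions list of character vectors of candidate monomer names.
#' @slot sourceMass the mass shift (Da) each position was derived from, or
#'   `NA` when the tag was given as amino acids.
#' @slot kind `"nrp"` or `"ripp"`.
#' @slot alphabet the monomer alphabet the candidates are drawn from.
#' @seealso [parseTag()], [massesToTag()], [expandTag()]
#' @export
setClass("SequenceTag",
  representation(
    positions = "list",
    sourceMass = "numeric",
    kind = "character",
    alphabet = "character"
  )
)

setValidity("SequenceTag", function(object) {
  msg <- character()
  if (length(object@positions) < 1L)
    msg <- c(msg, "a tag must have at least one position")
  if (any(lengths(object@positions) == 0L))
    msg <- c(msg, "every tag position needs at least one candidate monomer")
  cand <- unlist(object@positions, use.names = FALSE)
  bad <- setdiff(cand, object@alphabet)
  if (length(bad))
    msg <- c(msg, sprintf("candidates outside the alphabet: %s",
                          paste(unique(bad), collapse = ", ")))
  if (length(object@sourceMass) != length(object@positions))
    msg <- c(msg, "sourceMass must have one value (possibly NA) per position")
  if (!identical(length(object@kind), 1L) ||
      !object@kind %in% c("nrp", "ripp"))
    msg <- c(msg, "kind must be \"nrp\" or \"ripp\"")
  if (length(msg)) msg else TRUE
})

#' Mass-shift conversion table
#'
#' Maps observed mass shifts (monoisotopic residue masses, Da) to candidate
#' monomer sets. A query shift collects the union of candidates of every
#' row within the tolerance, so isobaric and near-isobaric residues yield
#' degenerate tag positions.
#'
#' @slot masses residue masses (Da), all positive.
#' @slot candidates list of monomer-name character vectors, parallel to
#'   `masses`.
#' @slot labels human-readable row labels.
#' @slot tolerance matching tolerance in Da (non-negative).
#' @seealso [readMassTable()], [massesToTag()]
#' @export
setClass("MassConversionTable",
  representation(
    masses = "numeric",
    candidates = "list",
    labels = "character",
    tolerance = "numeric"
  )
)

setValidity("MassConversionTable", function(object) {
  msg <- character()
  if (any(object@masses <= 0)) msg <- c(msg, "masses must be positive")
  if (length(object@candidates) != length(object@masses) ||
      length(object@labels) != length(object@masses))
    msg <- c(msg, "masses, candidates and labels must be parallel")
  if (length(object@tolerance) != 1L || object@tolerance < 0)
    msg <- c(msg, "tolerance must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Background monomer frequencies
#'
#' NORINE-style occurrence counts of monomers in known nonribosomal
#' peptides, used as the background probability P(A) of observing a monomer
#' in a peptide. Queries are smoothed with an additive pseudocount `k`:
#' P(A) = (n_A + k) / (N + k * |alphabet|).
#'
#' @slot counts named non-negative counts, one per alphabet member.
#' @slot alphabet the monomer alphabet (equals `names(counts)`).
#' @slot pseudocount the additive smoothing constant k (default 1).
#' @seealso [readFrequencyTable()], [baselineProbability()]
#' @export
setClass("MonomerFrequencyTable",
  representation(
    counts = "numeric",
    alphabet = "character",
    pseudocount = "numeric"
  )
)

setValidity("MonomerFrequencyTable", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) ||
      !setequal(names(object@counts), object@alphabet) ||
      length(object@counts) != length(object@alphabet))
    msg <- c(msg, "counts must be named with exactly the alphabet members")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Scoring parameters
#'
#' Tunable parameters of the Bayesian tag-to-BGC scorer.
#'
#' @slot c confidence factor weighting the specificity predictions against
#'   the background probability (default 1; 0 makes every score 0).
#' @slot x pseudocount in (0, 1] preventing log(0) on complete mismatches
#'   (default 0.01).
#' @slot eta exponent penalizing prediction mismatches (default 2).
#' @slot orientationMode `"both"` (default) scores the tag in both reading
#'   directions; `"forward"` scores as given.
#' @slot maxOrderings cap on enumerated assembly-line configurations
#'   (default 5040 = 7!); beyond it enumeration truncates deterministically
#'   and results carry a `capped` flag.
#' @slot tieBreak tie policy id; `"colinearity"` breaks equal scores by the
#'   higher colinearity index, then lexicographic cluster id.
#' @seealso [scoringParams()], [positionScore()], [rankBgcs()]
#' @export
setClass("ScoringParams",
  representation(
    c = "numeric",
    x = "numeric",
    eta = "numeric",
    orientationMode = "character",
    maxOrderings = "numeric",
    tieBreak = "character"
  )
)

setValidity("ScoringParams", function(object) {
  msg <- character()
  if (object@c < 0) msg <- c(msg, "c must be >= 0")
  if (object@x <= 0 || object@x > 1) msg <- c(msg, "x must lie in (0, 1]")
  if (object@eta < 1) msg <- c(msg, "eta must be >= 1")
  if (!object@orientationMode %in% c("forward", "both"))
    msg <- c(msg, "orientationMode must be \"forward\" or \"both\"")
  if (object@maxOrderings < 1) msg <- c(msg, "maxOrderings must be >= 1")
  if (!object@tieBreak %in% c("colinearity", "cluster_id"))
    msg <- c(msg, "tieBreak must be \"colinearity\" or \"cluster_id\"")
  if (length(msg)) msg else TRUE
})
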
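#' @name accessors
#' @title Accessors for the core classes
#' @description Small accessor generics: `entries()` and `clusterIds()` for
#'   databases, `monomerAlphabet()` for any alphabet-carrying object,
#'   `tagPositions()`/`tagLength()`/`tagKind()` for tags, `counts()` and
#'   `totalCount()` for frequency tables, `moduleCount()` and `modules()`
#'   for entries. `modules()` flattens an entry's genes into one list of
#'   modules in native encoded order; each element carries `geneId`,
#'   `ordinal` (0-based within the gene) and the `prediction`.
#' @param x the object.
#' @return the extracted component; see Description.
#' @examples
#' tagLength(parseTag("VHFVGWI(L)"))
NULL

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "BGCDatabase", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setMethod("clusterIds", "BGCDatabase", function(x)
  vapply(x@entries, function(e) e@clusterId, character(1L)))

#' @rdname accessors
#' @export
setGeneric("monomerAlphabet", function(x) standardGeneric("monomerAlphabet"))
#' @rdname accessors
#' @export
setMethod("monomerAlphabet", "BGCDatabase", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("monomerAlphabet", "SequenceTag", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("monomerAlphabet", "MonomerFrequencyTable", function(x) x@alphabet)

#' @rdname accessors
#' @export
setGeneric("tagPositions", function(x) standardGeneric("tagPositions"))
#' @rdname accessors
#' @export
setMethod("tagPositions", "SequenceTag", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("tagLength", function(x) standardGeneric("tagLength"))
#' @rdname accessors
#' @export
setMethod("tagLength", "SequenceTag", function(x) length(x@positions))

#' @rdname accessors
#' @export
setGeneric("tagKind", function(x) standardGeneric("tagKind"))
#' @rdname accessors
#' @export
setMethod("tagKind", "SequenceTag", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "MonomerFrequencyTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))
#' @rdname accessors
#' @export
setMethod("totalCount", "MonomerFrequencyTable", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setGeneric("moduleCount", function(x) standardGeneric("moduleCount"))
#' @rdname accessors
#' @export
setMethod("moduleCount", "BGCEntry", function(x) sum(lengths(x@genes)))

#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname accessors
#' @export
setMethod("modules", "BGCEntry", function(x) {
  out <- list()
  for (g in names(x@genes)) {
    preds <- x@genes[[g]]
    for (i in seq_along(preds))
      out[[length(out) + 1L]] <- list(geneId = g, ordinal = i - 1L,
                                      prediction = preds[[i]])
  }
  out
})

setMethod("show", "SequenceTag", function(object) {
  cat(sprintf("SequenceTag (%s), %d positions, %d degenerate: %s\n",
              object@kind, length(object@positions),
              sum(lengths(object@positions) > 1L), formatTag(object)))
})

setMethod("show", "BGCEntry", function(object) {
  cat(sprintf("BGCEntry '%s' (%s): %d gene(s), %d module(s)\n",
              object@clusterId, object@accession, length(object@genes),
              moduleCount(object)))
})

setMethod("show", "BGCDatabase", function(object) {
  cat(sprintf("BGCDatabase: %d entries, alphabet of %d monomers\n",
              length(object@entries), length(object@alphabet)))
  if (length(object@entries)) {
    ids <- clusterIds(object)
    cat("  ", paste(head(ids, 5L), collapse = ", "),
        if (length(ids) > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "MonomerFrequencyTable", function(object) {
  cat(sprintf(
    "MonomerFrequencyTable: %d monomers, N = %d occurrences, k = %g\n",
    length(object@alphabet), as.integer(sum(object@counts)),
    object@pseudocount))
})

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(
    "ScoringParams: c = %g, x = %g, eta = %g, orientation = %s, cap = %d\n",
    object@c, object@x, object@eta, object@orientationMode,
    as.integer(object@maxOrderings)))
})

setMethod("show", "MassConversionTable", function(object) {
  cat(sprintf("MassConversionTable: %d rows, tolerance %.4g Da\n",
              length(object@masses), object@tolerance))
})
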
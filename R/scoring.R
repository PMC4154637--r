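#' Prediction match value of a tag position against a module
#'
#' For each candidate monomer `a` of the position, the SVM channel
#' contributes the innermost matching tier: 1.0 when `a` equals the single
#' amino-acid prediction, 0.75 for the small-class set, 0.5 for the
#' large-class set, 0.25 for the three-class set, 0.0 when none matches
#' (including no-call predictions stored as empty sets). The Stachelhaus
#' channel contributes the fractional code identity when `a` is among the
#' best-matching known code's monomers and 0 otherwise. `I(a)` is the mean
#' of the two channels, or the one present when the other channel is
#' absent from the prediction. The position's match value is the maximum
#' of `I(a)` over its candidates: a degenerate tag is compatible with its
#' best-matching reading.
#'
#' @param candidates character vector of candidate monomer names (one tag
#'   position), or a [SequenceTag-class] (then a matrix of match values,
#'   positions x modules of `prediction`, is returned).
#' @param prediction a [SpecificityPrediction-class], or a
#'   [BGCEntry-class] when `candidates` is a tag.
#' @return match value(s) in `[0, 1]`.
#' @examples
#' p <- specificityPrediction(svmSingle = "leu", svmSmall = "leu",
#'                            stachMatch = "leu", stachIdentity = 1)
#' matchValue(c("ile", "leu"), p)   # 1.0
#' @export
matchValue <- function(candidates, prediction) {
  if (is(candidates, "SequenceTag")) {
    stopifnot(is(prediction, "BGCEntry"))
    mods <- modules(prediction)
    return(vapply(mods, function(m)
      vapply(candidates@positions, matchValue, numeric(1L),
             prediction = m$prediction),
      numeric(length(candidates@positions))))
  }
  p <- prediction
  iSvm <- numeric(length(candidates))
  iSvm[candidates %in% p@svmThree] <- 0.25
  iSvm[candidates %in% p@svmLarge] <- 0.5
  iSvm[candidates %in% p@svmSmall] <- 0.75
  iSvm[candidates %in% p@svmSingle] <- 1.0
  stachPresent <- !is.na(p@stachIdentity) && length(p@stachMatch) > 0L
  svmPresent <- length(p@svmSingle) > 0L || length(p@svmSmall) > 0L ||
    length(p@svmLarge) > 0L || length(p@svmThree) > 0L
  if (stachPresent) {
    iStach <- ifelse(candidates %in% p@stachMatch, p@stachIdentity, 0)
    i <- if (svmPresent) (iSvm + iStach) / 2 else iStach
  } else {
    i <- iSvm
  }
  max(i)
}

#' Per-position log-likelihood score
#'
#' The contribution of one aligned tag position, the log-likelihood ratio
#' \deqn{\ln \frac{P(A \mid M)}{P(A)}, \qquad
#'       P(A \mid M) = \frac{c\,\bar I^{\eta} + x\,P(A)}{c + x},}
#' where \eqn{\bar I} is the prediction [matchValue()], `P(A)` the
#' [baselineProbability()], `c` the confidence factor weighting the
#' predictions against the background, `x` a small pseudocount preventing
#' \eqn{\log 0} on complete mismatches, and \eqn{\eta} the exponent that
#' makes multi-position mismatch penalties exponential in the mismatch
#' count through log-additivity. At `c = 0` the term is exactly 0
#' (baseline-neutral); at \eqn{\bar I = 0} it is \eqn{\ln(x / (c + x))}.
#'
#' @param iBar match value(s) in `[0, 1]`.
#' @param pA baseline probability or probabilities in `(0, 1)`, recycled
#'   against `iBar`.
#' @param params a [ScoringParams-class] object.
#' @return log-likelihood term(s), natural log.
#' @examples
#' positionScore(1, 0.05, scoringParams())    # ~ 2.9863
#' positionScore(0, 0.05, scoringParams())    # ln(0.01/1.01) ~ -4.6151
#' @export
positionScore <- function(iBar, pA, params = scoringParams()) {
  if (any(pA <= 0) || any(pA >= 1))
    stop("baseline probabilities must lie in (0, 1)")
  if (any(iBar < 0 | iBar > 1)) stop("match values must lie in [0, 1]")
  log((params@c * iBar^params@eta + params@x * pA) /
        ((params@c + params@x) * pA))
}

# lexicographic permutation enumeration, truncated at cap
.permutations <- function(n, cap = Inf) {
  perm <- seq_len(n)
  out <- list(perm)
  total <- factorial(n)
  capped <- total > cap
  while (length(out) < min(total, cap)) {
    # next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    perm[c(i, j)] <- perm[c(j, i)]
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
    out[[length(out) + 1L]] <- perm
  }
  attr(out, "capped") <- capped
  out
}

#' Enumerate assembly-line configurations of a BGC
#'
#' A BGC encoding several NRPS genes may assemble its product with the
#' gene products in any order, while the modules within one gene keep
#' their native order. Each configuration is the concatenation of the
#' genes' module lists under one gene permutation. Permutations are
#' generated in lexicographic order of gene positions; beyond `cap` the
#' enumeration truncates deterministically and the result is flagged.
#'
#' @param entry a [BGCEntry-class] object.
#' @param cap maximum number of configurations (default 5040 = 7!).
#' @return list of configurations, each a list with `genePerm` (gene index
#'   permutation) and `moduleIdx` (global module indices, native flat
#'   order, concatenated under the permutation); attribute `capped` says
#'   whether enumeration was truncated.
#' @export
enumerateOrderings <- function(entry, cap = 5040) {
  nGenes <- length(entry@genes)
  sizes <- lengths(entry@genes)
  offsets <- c(0L, cumsum(sizes))  # global index of gene g starts here
  perms <- .permutations(nGenes, cap)
  out <- lapply(perms, function(p) {
    idx <- unlist(lapply(p, function(g)
      offsets[g] + seq_len(sizes[g])), use.names = FALSE)
    list(genePerm = p, moduleIdx = idx)
  })
  attr(out, "capped") <- attr(perms, "capped")
  out
}

#' Colinearity index of an alignment
#'
#' The fraction of adjacent tag-position pairs whose matched modules
#' follow the encoded assembly-line order: same gene, consecutive module
#' ordinals, ascending. Length-1 alignments return 1 by convention. A
#' reversed-orientation alignment within one gene maps tag positions to
#' descending ordinals and scores 0.
#'
#' @param alignment the alignment component of a [scoreTagAgainstBgc()]
#'   result (uses its `geneIds` and `ordinals` fields), or a list with
#'   those two fields.
#' @return colinearity index in `[0, 1]`.
#' @export
colinearityIndex <- function(alignment) {
  g <- alignment$geneIds
  o <- alignment$ordinals
  n <- length(g)
  stopifnot(length(o) == n, n >= 1L)
  if (n == 1L) return(1)
  ok <- g[-n] == g[-1L] & o[-1L] == o[-n] + 1L
  mean(ok)
}

.alignmentString <- function(alignment) {
  if (is.null(alignment)) return(NA_character_)
  paste0(substr(alignment$orientation, 1, 3), ":",
         paste0(alignment$geneIds, "/", alignment$ordinals,
                collapse = ","))
}

#' Score a sequence tag against one BGC
#'
#' The cluster score `S` is the maximum over all admissible alignments of
#' the sum of per-position log-likelihood terms
#' ([positionScore()] of [matchValue()] and [baselineProbability()]):
#' all assembly-line configurations ([enumerateOrderings()]), all
#' contiguous, gap-free offsets of the tag along the configuration's
#' module sequence, and both tag orientations when
#' `params@orientationMode == "both"`. Enumeration order (configurations,
#' then offsets, then forward before reversed) breaks exact score ties,
#' after preferring the higher colinearity index. A tag longer than the
#' module chain has no admissible alignment and yields the sentinel score
#' `-Inf`, which always ranks last.
#'
#' @param tag a [SequenceTag-class] object.
#' @param entry a [BGCEntry-class] object.
#' @param freq a [MonomerFrequencyTable-class] object.
#' @param params a [ScoringParams-class] object.
#' @return a list with `clusterId`, `accession`, `S`, `colinearity`,
#'   `capped`, and `alignment` (itself a list: `genePerm`, `offset`
#'   (0-based), `orientation`, `moduleIdx`, `geneIds`, `ordinals`, one
#'   entry per tag position in tag order), or `alignment = NULL` for the
#'   sentinel.
#' @export
scoreTagAgainstBgc <- function(tag, entry, freq = defaultFrequencyTable(),
                               params = scoringParams()) {
  L <- length(tag@positions)
  mods <- modules(entry)
  M <- length(mods)
  if (L > M) {
    return(list(clusterId = entry@clusterId, accession = entry@accession,
                S = -Inf, colinearity = NA_real_, capped = FALSE,
                alignment = NULL))
  }
  pA <- vapply(tag@positions, baselineProbability, numeric(1L), freq = freq)
  # term[l, m]: score of tag position l on module m
  term <- matrix(0, nrow = L, ncol = M)
  for (m in seq_len(M)) {
    iB <- vapply(tag@positions, matchValue, numeric(1L),
                 prediction = mods[[m]]$prediction)
    term[, m] <- positionScore(iB, pA, params)
  }
  orderings <- enumerateOrderings(entry, cap = params@maxOrderings)
  orientations <- if (params@orientationMode == "both")
    c("forward", "reversed") else "forward"
  best <- NULL
  bestS <- -Inf
  bestCI <- -Inf
  li <- seq_len(L)
  for (ord in orderings) {
    seqIdx <- ord$moduleIdx
    for (off in 0:(M - L)) {
      for (orient in orientations) {
        slots <- if (orient == "forward") seqIdx[off + li]
                 else seqIdx[off + L + 1L - li]
        s <- sum(term[cbind(li, slots)])
        if (s > bestS ||
            (s == bestS && {
              ci <- colinearityIndex(list(
                geneIds = vapply(mods[slots], `[[`, character(1L), "geneId"),
                ordinals = vapply(mods[slots], `[[`, integer(1L), "ordinal")))
              ci > bestCI
            })) {
          geneIds <- vapply(mods[slots], `[[`, character(1L), "geneId")
          ordinals <- vapply(mods[slots], `[[`, integer(1L), "ordinal")
          bestS <- s
          bestCI <- colinearityIndex(list(geneIds = geneIds,
                                          ordinals = ordinals))
          best <- list(genePerm = ord$genePerm, offset = off,
                       orientation = orient, moduleIdx = slots,
                       geneIds = geneIds, ordinals = ordinals)
        }
      }
    }
  }
  list(clusterId = entry@clusterId, accession = entry@accession,
       S = bestS, colinearity = bestCI,
       capped = isTRUE(attr(orderings, "capped")), alignment = best)
}

#' Rank every BGC in a database against a sequence tag
#'
#' Scores each entry with [scoreTagAgainstBgc()] (after optional
#' [filterByTaxonomy()]) and sorts descending by score, breaking ties by
#' higher colinearity index and then lexicographic cluster id. Entries
#' with equal score and colinearity share a rank (shared best hits:
#' orthologous clusters in related genomes frequently tie).
#'
#' @param tag a [SequenceTag-class] object.
#' @param db a [BGCDatabase-class] object.
#' @param freq a [MonomerFrequencyTable-class] object.
#' @param params a [ScoringParams-class] object.
#' @param taxonValue,taxonRank optional taxonomic range restriction,
#'   passed to [filterByTaxonomy()].
#' @return an [S4Vectors::DataFrame] with columns `rank`, `clusterId`,
#'   `accession`, `organism`, `score`, `colinearity`, `capped`,
#'   `alignmentString` and a list column `alignment`.
#' @examples
#' sim <- generateNrpDatabase(5, parseTag("V-A-L-S"), seed = 1)
#' rankBgcs(parseTag("V-A-L-S"), sim$db)[, 1:5]
#' @export
rankBgcs <- function(tag, db, freq = defaultFrequencyTable(),
                     params = scoringParams(),
                     taxonValue = NULL, taxonRank = NULL) {
  if (!is.null(taxonValue))
    db <- filterByTaxonomy(db, taxonValue, rank = taxonRank)
  if (!length(db@entries))
    stop("no BGC entries to rank (empty database after taxonomic filtering)")
  scores <- lapply(db@entries, scoreTagAgainstBgc, tag = tag, freq = freq,
                   params = params)
  S <- vapply(scores, `[[`, numeric(1L), "S")
  CI <- vapply(scores, `[[`, numeric(1L), "colinearity")
  ids <- vapply(scores, `[[`, character(1L), "clusterId")
  ciKey <- ifelse(is.na(CI), -Inf, CI)
  ord <- order(-S, -ciKey, ids, method = "radix")
  S <- S[ord]; CI <- CI[ord]; ids <- ids[ord]; scores <- scores[ord]
  ciKey <- ciKey[ord]
  n <- length(scores)
  rank <- integer(n)
  rank[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    rank[i] <- if (S[i] == S[i - 1L] && ciKey[i] == ciKey[i - 1L])
      rank[i - 1L] else i
  }
  organism <- vapply(db@entries[ord], function(e) {
    if (length(e@lineage)) e@lineage[length(e@lineage)] else NA_character_
  }, character(1L))
  S4Vectors::DataFrame(
    rank = rank,
    clusterId = ids,
    accession = vapply(scores, `[[`, character(1L), "accession"),
    organism = organism,
    score = S,
    colinearity = CI,
    capped = vapply(scores, `[[`, logical(1L), "capped"),
    alignmentString = vapply(scores, function(s)
      .alignmentString(s$alignment), character(1L)),
    alignment = I(lapply(scores, `[[`, "alignment")))
}

#' Write a ranked result table
#'
#' `writeResultTable()` writes the human-readable tab-separated ranking
#' (scores to 2 decimals); `writeResultJson()` writes the machine-readable
#' variant at full precision, including the alignments.
#'
#' @param res a [rankBgcs()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(res, path) {
  df <- data.frame(rank = res$rank, cluster_id = res$clusterId,
                   accession = res$accession, organism = res$organism,
                   S = sprintf("%.2f", res$score),
                   CI = sprintf("%.2f", res$colinearity),
                   capped = res$capped,
                   alignment = res$alignmentString,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
writeResultJson <- function(res, path) {
  out <- lapply(seq_len(nrow(res)), function(i)
    list(rank = res$rank[i], cluster_id = res$clusterId[i],
         accession = res$accession[i], organism = res$organism[i],
         S = res$score[i], CI = res$colinearity[i],
         capped = res$capped[i], alignment = res$alignment[[i]]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
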
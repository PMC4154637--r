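# run code under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, fn) {
  gl <- globalenv()
  old <- if (exists(".Random.seed", envir = gl, inherits = FALSE))
    get(".Random.seed", envir = gl) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = gl, inherits = FALSE))
        rm(".Random.seed", envir = gl)
    } else assign(".Random.seed", old, envir = gl)
  })
  set.seed(as.integer(seed))
  fn()
}

.fullConfidencePrediction <- function(monomer) {
  specificityPrediction(svmSingle = monomer, svmSmall = monomer,
                        svmLarge = monomer, svmThree = monomer,
                        stachMatch = monomer, stachIdentity = 1)
}

# a decoy BGC whose module substrates are drawn from the background
# frequencies, so decoys are realistically confusable with the planted
# cluster rather than uniform noise
.randomDecoy <- function(j, tagLen, freq) {
  lo <- max(2L, tagLen - 2L)
  m <- sample(seq(lo, tagLen + 4L), 1L)
  nGenes <- sample.int(min(3L, m), 1L)
  cuts <- if (nGenes > 1L) sort(sample(m - 1L, nGenes - 1L)) else integer()
  sizes <- diff(c(0L, cuts, m))
  monomers <- sample(freq@alphabet, m, replace = TRUE,
                     prob = freq@counts + freq@pseudocount)
  genes <- list()
  at <- 0L
  for (g in seq_len(nGenes)) {
    genes[[sprintf("decoy%04d_g%d", j, g)]] <-
      lapply(monomers[at + seq_len(sizes[g])], .fullConfidencePrediction)
    at <- at + sizes[g]
  }
  bgcEntry(sprintf("decoy%04d", j), genes,
           accession = sprintf("SYN%06d", j),
           lineage = c("Bacteria", "Simulibacterota", "Simulia",
                       sprintf("Simulia species %d", j)))
}

#' Generate a synthetic NRP database with a planted ground truth
#'
#' Builds a database of `nBgcs` entries: one planted cluster whose module
#' predictions match the tag exactly (full-confidence prediction of each
#' position's first candidate), except at `mispredictions` seeded
#' positions where the prediction is forced to a monomer outside the
#' candidate set (match value exactly 0, emulating a completely wrong
#' substrate call); and `nBgcs - 1` decoys whose module substrates are
#' drawn from the background frequency table. For a fixed seed the decoys
#' and the misprediction position order are identical across
#' `mispredictions` values (the mispredicted sets are nested), and decoy
#' `j` is identical across database sizes, so recovery comparisons across
#' those knobs are paired.
#'
#' @param nBgcs database size (>= 1).
#' @param tag the [SequenceTag-class] the planted cluster encodes.
#' @param mispredictions number of forced-zero positions (0..tag length).
#' @param seed integer seed; identical inputs and seed give identical
#'   databases.
#' @param freq background [MonomerFrequencyTable-class].
#' @return list with `db` (a [BGCDatabase-class]; the planted entry is
#'   `"planted"`) and `truth` (planted cluster id, the tag string,
#'   misprediction count and 1-based mispredicted positions, seed).
#' @examples
#' sim <- generateNrpDatabase(10, parseTag("V-A-L-S-G-T"), seed = 7)
#' rankBgcs(parseTag("V-A-L-S-G-T"), sim$db)[1, "clusterId"]
#' @export
generateNrpDatabase <- function(nBgcs, tag, mispredictions = 0, seed = 1,
                                freq = defaultFrequencyTable()) {
  L <- length(tag@positions)
  if (nBgcs < 1L) stop("nBgcs must be >= 1")
  if (mispredictions < 0L || mispredictions > L)
    stop("mispredictions must lie between 0 and the tag length")
  .withSeed(seed, function() {
    decoys <- lapply(seq_len(nBgcs - 1L), .randomDecoy, tagLen = L,
                     freq = freq)
    posOrder <- sample.int(L)
    wrongAt <- sort(posOrder[seq_len(mispredictions)])
    preds <- lapply(seq_len(L), function(i) {
      cands <- tag@positions[[i]]
      if (i %in% wrongAt) {
        wrong <- setdiff(freq@alphabet, cands)[1L]
        .fullConfidencePrediction(wrong)
      } else {
        .fullConfidencePrediction(cands[1L])
      }
    })
    planted <- bgcEntry("planted", list(planted_nrps = preds),
                        accession = "SYN000000",
                        lineage = c("Bacteria", "Simulibacterota",
                                    "Simulia", "Simulia species 0"))
    db <- bgcDatabase(c(list(planted), decoys), alphabet = freq@alphabet,
                      provenance = sprintf(
                        "synthetic: %d entries, planted tag %s, %d misprediction(s), seed %d",
                        nBgcs, formatTag(tag), mispredictions,
                        as.integer(seed)))
    list(db = db,
         truth = list(plantedClusterId = "planted", tag = formatTag(tag),
                      mispredictionCount = as.integer(mispredictions),
                      mispredictedPositions = wrongAt,
                      seed = as.integer(seed)))
  })
}

#' Generate a random genome with one planted precursor peptide
#'
#' Random background DNA of `lengthNt` nucleotides with the peptide's
#' codons (synonymous codons drawn under the seed) planted once at a
#' seeded offset on the requested strand. Backgrounds in which the exact
#' peptide occurs anywhere else in the six translation frames are
#' rejected and redrawn, so the planted locus is the unique match by
#' construction.
#'
#' @param lengthNt genome length (>= 3 x peptide length).
#' @param peptide concrete amino-acid string (one-letter, no stops).
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed; identical inputs and seed give identical
#'   sequences.
#' @return list with `genome` (a single-record
#'   [Biostrings::DNAStringSet]) and `truth` (record, strand, frame,
#'   0-based half-open start/end, peptide, seed).
#' @export
generateRippGenome <- function(lengthNt, peptide, strand = c("+", "-"),
                               seed = 1) {
  strand <- match.arg(strand)
  peptide <- toupper(peptide)
  lp <- nchar(peptide)
  if (3L * lp > lengthNt)
    stop("genome too short for the peptide (need 3 x peptide length)")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (!all(aa %in% names(.AA1)))
    stop("peptide must use the 20 proteinogenic one-letter codes")
  code <- getGeneticCode("11")
  codonsFor <- split(names(code), unname(code))
  .withSeed(seed, function() {
    for (attempt in seq_len(200L)) {
      codons <- vapply(aa, function(a)
        sample(codonsFor[[a]], 1L), character(1L))
      insertNt <- paste(codons, collapse = "")
      if (strand == "-")
        insertNt <- as.character(reverseComplement(DNAString(insertNt)))
      pos <- sample.int(lengthNt - 3L * lp + 1L, 1L) - 1L  # 0-based
      bg <- sample(c("A", "C", "G", "T"), lengthNt, replace = TRUE)
      bg[pos + seq_len(3L * lp)] <- strsplit(insertNt, "")[[1L]]
      genome <- DNAStringSet(structure(paste(bg, collapse = ""),
                                       names = "synthetic_genome"))
      # unique-by-construction: the exact peptide must occur exactly once
      # across the six frames
      frames <- sixFrameTranslate(genome)
      nOcc <- sum(vapply(frames$peptide, function(p)
        length(gregexpr(peptide, p, fixed = TRUE)[[1L]]) *
          (gregexpr(peptide, p, fixed = TRUE)[[1L]][1L] != -1L),
        numeric(1L)))
      if (nOcc != 1L) next
      if (strand == "+") {
        frame <- (pos %% 3L) + 1L
      } else {
        startRc <- lengthNt - (pos + 3L * lp)
        frame <- -((startRc %% 3L) + 1L)
      }
      return(list(genome = genome,
                  truth = list(record = "synthetic_genome",
                               strand = strand, frame = frame,
                               start = pos, end = pos + 3L * lp,
                               peptide = peptide,
                               seed = as.integer(seed))))
    }
    stop("could not generate a background without spurious matches")
  })
}

#' Rank-1 recovery over synthetic databases
#'
#' For each (tag length, database size) cell, generates `replicates`
#' planted databases ([generateNrpDatabase()]; tags are drawn
#' position-wise from the background frequencies) and reports the
#' fraction of replicates in which the planted cluster is the (shared)
#' best hit of [rankBgcs()]. Shared best hits count as successes, since
#' orthologous clusters encoding the same molecule legitimately tie.
#' Within a replicate the decoy pool is generated once at the largest
#' database size and smaller sizes use its prefixes, so recovery is
#' exactly paired (and monotone non-increasing) across database sizes;
#' likewise the `mispredictions` positions are nested under the seed.
#'
#' @param tagLengths integer vector of tag lengths.
#' @param dbSizes integer vector of database sizes.
#' @param replicates replicates per cell (>= 1).
#' @param seed integer seed.
#' @param mispredictions forced-zero positions in the planted cluster.
#' @param freq background [MonomerFrequencyTable-class].
#' @param params [ScoringParams-class] used for ranking.
#' @return data.frame with columns `tag_length`, `db_size`,
#'   `mispredictions` and `recovery` (fraction in `[0, 1]`).
#' @export
recoveryCurve <- function(tagLengths, dbSizes, replicates = 50, seed = 1,
                          mispredictions = 0,
                          freq = defaultFrequencyTable(),
                          params = scoringParams()) {
  stopifnot(replicates >= 1L, all(dbSizes >= 1L), all(tagLengths >= 1L))
  maxSize <- max(dbSizes)
  grid <- expand.grid(tag_length = sort(tagLengths),
                      db_size = sort(dbSizes),
                      KEEP.OUT.ATTRS = FALSE)
  hits <- matrix(0L, nrow = length(tagLengths), ncol = length(dbSizes),
                 dimnames = list(sort(tagLengths), sort(dbSizes)))
  lens <- sort(tagLengths)
  sizes <- sort(dbSizes)
  for (r in seq_len(replicates)) {
    for (li in seq_along(lens)) {
      L <- lens[li]
      subSeed <- (as.integer(seed) * 797L + r * 131L + L * 17L) %%
        2147483647L
      tag <- .withSeed(subSeed + 1L, function()
        sequenceTag(sample(freq@alphabet, L, replace = TRUE,
                           prob = freq@counts + freq@pseudocount),
                    alphabet = freq@alphabet))
      k <- min(mispredictions, L)
      sim <- generateNrpDatabase(maxSize, tag, mispredictions = k,
                                 seed = subSeed, freq = freq)
      for (si in seq_along(sizes)) {
        db <- bgcDatabase(sim$db@entries[seq_len(sizes[si])],
                          alphabet = sim$db@alphabet)
        res <- rankBgcs(tag, db, freq = freq, params = params)
        if (res$rank[match("planted", res$clusterId)] == 1L)
          hits[li, si] <- hits[li, si] + 1L
      }
    }
  }
  grid$mispredictions <- mispredictions
  grid$recovery <- vapply(seq_len(nrow(grid)), function(i)
    hits[as.character(grid$tag_length[i]),
         as.character(grid$db_size[i])] / replicates, numeric(1L))
  grid
}
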
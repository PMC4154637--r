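# Independent brute-force oracles. Everything here is written as plain
# scalar loops from the model definitions, deliberately sharing no code
# with the package internals, so agreement is evidence and not tautology.

# all permutations of 1..n in lexicographic order, by recursion
oraclePerms <- function(n) {
  recurse <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in recurse(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  recurse(seq_len(n))
}

oracleBaseline <- function(cands, freq) {
  sigma <- monomerAlphabet(freq)
  if (length(cands) > 1L) return(1 / length(sigma))
  k <- freq@pseudocount
  n <- 0
  for (m in names(counts(freq))) if (m == cands) n <- counts(freq)[[m]]
  (n + k) / (sum(counts(freq)) + k * length(sigma))
}

oracleMatchValue <- function(cands, pred) {
  best <- 0
  for (a in cands) {
    iSvm <- 0
    if (a %in% pred@svmThree) iSvm <- 0.25
    if (a %in% pred@svmLarge) iSvm <- 0.5
    if (a %in% pred@svmSmall) iSvm <- 0.75
    if (a %in% pred@svmSingle) iSvm <- 1.0
    stachOn <- !is.na(pred@stachIdentity) && length(pred@stachMatch) > 0
    svmOn <- length(pred@svmSingle) + length(pred@svmSmall) +
      length(pred@svmLarge) + length(pred@svmThree) > 0
    iStach <- if (stachOn && a %in% pred@stachMatch) pred@stachIdentity
              else 0
    i <- if (stachOn && svmOn) (iSvm + iStach) / 2
         else if (stachOn) iStach
         else iSvm
    if (i > best) best <- i
  }
  best
}

oracleColinearity <- function(geneIds, ordinals) {
  n <- length(geneIds)
  if (n == 1L) return(1)
  hits <- 0
  for (i in seq_len(n - 1L))
    if (geneIds[i] == geneIds[i + 1L] &&
        ordinals[i + 1L] == ordinals[i] + 1L)
      hits <- hits + 1
  hits / (n - 1L)
}

# exhaustive maximum over gene permutations x offsets x orientations,
# with the same preference order as the scorer: higher S, then higher
# colinearity, then first in enumeration order
oracleScore <- function(tag, entry, freq, params) {
  pos <- tagPositions(tag)
  L <- length(pos)
  flat <- list()
  for (g in names(entry@genes))
    for (j in seq_along(entry@genes[[g]]))
      flat[[length(flat) + 1L]] <- list(gene = g, ord = j - 1L,
                                        pred = entry@genes[[g]][[j]])
  geneSizes <- lengths(entry@genes)
  geneStart <- cumsum(c(0L, geneSizes))
  M <- length(flat)
  if (L > M) return(list(S = -Inf, alignment = NULL, colinearity = NA_real_))
  orientations <- if (params@orientationMode == "both")
    c("forward", "reversed") else "forward"
  bestS <- -Inf; bestCI <- -Inf; best <- NULL
  for (perm in oraclePerms(length(geneSizes))) {
    idx <- integer()
    for (g in perm) idx <- c(idx, geneStart[g] + seq_len(geneSizes[g]))
    for (off in 0:(M - L)) {
      for (orient in orientations) {
        slots <- integer(L)
        for (l in seq_len(L))
          slots[l] <- if (orient == "forward") idx[off + l]
                      else idx[off + L + 1L - l]
        s <- 0
        for (l in seq_len(L)) {
          iB <- oracleMatchValue(pos[[l]], flat[[slots[l]]]$pred)
          pA <- oracleBaseline(pos[[l]], freq)
          s <- s + log((params@c * iB^params@eta + params@x * pA) /
                         ((params@c + params@x) * pA))
        }
        gids <- vapply(slots, function(m) flat[[m]]$gene, character(1L))
        ords <- vapply(slots, function(m) flat[[m]]$ord, integer(1L))
        ci <- oracleColinearity(gids, ords)
        if (s > bestS || (s == bestS && ci > bestCI)) {
          bestS <- s; bestCI <- ci
          best <- list(moduleIdx = slots, offset = off,
                       orientation = orient, genePerm = perm)
        }
      }
    }
  }
  list(S = bestS, colinearity = bestCI, alignment = best)
}

# --- RiPP side: independent translation and window membership test ------

oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

oracleTranslateFrame <- function(s, f) {
  code <- Biostrings::getGeneticCode("11")
  n <- nchar(s)
  aa <- character()
  i <- f
  while (i + 2L <= n) {
    codon <- substr(s, i, i + 2L)
    aa <- c(aa, if (grepl("N", codon)) "X"
                else unname(code[codon]))
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

# every window of every frame tested against expandTag membership;
# coordinates recomputed from scratch
oracleRippMatches <- function(tag, genomeStr, orientationMode = "forward") {
  tags <- list(forward = tag)
  if (orientationMode == "both") tags$reversed <- reverseTag(tag)
  L <- tagLength(tag)
  out <- list()
  for (orient in names(tags)) {
    concrete <- tryCatch(expandTag(tags[[orient]], cap = 1e6),
                         error = function(e) NULL)
    pepSet <- character()
    for (seqStr in concrete) {
      letters <- monomerToOneLetter(strsplit(seqStr, "-", fixed = TRUE)[[1L]])
      if (!any(is.na(letters)))
        pepSet <- c(pepSet, paste(letters, collapse = ""))
    }
    n <- nchar(genomeStr)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genomeStr else oracleRevComp(genomeStr)
      for (f in 1:3) {
        pep <- oracleTranslateFrame(s, f)
        if (nchar(pep) < L) next
        for (i0 in 0:(nchar(pep) - L)) {
          win <- substr(pep, i0 + 1L, i0 + L)
          if (win %in% pepSet) {
            sNt <- (f - 1L) + 3L * i0
            eNt <- sNt + 3L * L
            if (strand == "-") { tmp <- sNt; sNt <- n - eNt; eNt <- n - tmp }
            out[[length(out) + 1L]] <- data.frame(
              strand = strand, frame = if (strand == "+") f else -f,
              start = sNt, end = eNt, peptide = win,
              tag_orientation = orient, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      peptide = character(),
                      tag_orientation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$frame, res$start)), , drop = FALSE]
  res[order(match(res$frame, c(1L, 2L, 3L, -1L, -2L, -3L)), res$start), ,
      drop = FALSE]
}
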
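# fixture builders used across test files

fullPred <- function(m) {
  specificityPrediction(svmSingle = m, svmSmall = m, svmLarge = m,
                        svmThree = m, stachMatch = m, stachIdentity = 1)
}

# entry whose single gene encodes exactly `monomers`, full confidence
perfectEntry <- function(id, monomers, lineage = character(),
                         accession = NA_character_) {
  bgcEntry(id, setNames(list(lapply(monomers, fullPred)),
                        paste0(id, "_g1")),
           accession = accession, lineage = lineage)
}

# a small mixed-taxonomy fixture database
taxonomyFixtureDb <- function() {
  bgcDatabase(list(
    perfectEntry("str1", c("val", "ala"),
                 lineage = c("Bacteria", "Actinomycetota", "Actinomycetes",
                             "Kitasatosporales", "Streptomycetaceae",
                             "Streptomyces", "Streptomyces coelicolor",
                             "Streptomyces coelicolor A3(2)"),
                 accession = "FIX001"),
    perfectEntry("str2", c("leu", "gly"),
                 lineage = c("Bacteria", "Actinomycetota", "Actinomycetes",
                             "Kitasatosporales", "Streptomycetaceae",
                             "Streptomyces", "Streptomyces griseus"),
                 accession = "FIX002"),
    perfectEntry("bac1", c("ser", "thr"),
                 lineage = c("Bacteria", "Bacillota", "Bacilli",
                             "Bacillales", "Bacillaceae", "Bacillus",
                             "Bacillus subtilis"),
                 accession = "FIX003")))
}

# seeded random small BGC entry for oracle-equivalence sweeps:
# <= maxGenes genes, <= maxModules modules total, mixed prediction styles
randomSmallEntry <- function(id, alphabet, maxGenes = 3, maxModules = 8) {
  m <- sample(2:maxModules, 1L)
  ng <- sample(seq_len(min(maxGenes, m)), 1L)
  cuts <- if (ng > 1L) sort(sample(m - 1L, ng - 1L)) else integer()
  sizes <- diff(c(0L, cuts, m))
  makePred <- function() {
    a <- sample(alphabet, 1L)
    style <- sample(3L, 1L)
    pool <- unique(c(a, sample(alphabet, 4L)))[1:4]
    if (style == 1L) {            # both channels, tiered nested sets
      specificityPrediction(svmSingle = a, svmSmall = pool[1:2],
                            svmLarge = pool[1:3], svmThree = pool,
                            stachMatch = sample(alphabet, 1L),
                            stachIdentity = round(runif(1L), 2))
    } else if (style == 2L) {     # Stachelhaus channel only
      specificityPrediction(stachMatch = a,
                            stachIdentity = round(runif(1L, 0.3, 1), 2))
    } else {                      # SVM channel only, no-call single
      specificityPrediction(svmSmall = pool[1:2], svmLarge = pool[1:3],
                            svmThree = pool)
    }
  }
  genes <- list()
  for (g in seq_len(ng))
    genes[[sprintf("%s_g%d", id, g)]] <-
      replicate(sizes[g], makePred(), simplify = FALSE)
  bgcEntry(id, genes, accession = sprintf("RND%04d", sample(9999L, 1L)))
}

randomTestTag <- function(len, alphabet, pDegenerate = 0.3) {
  sequenceTag(lapply(seq_len(len), function(i) {
    if (runif(1L) < pDegenerate) sample(alphabet, 2L)
    else sample(alphabet, 1L)
  }), alphabet = alphabet)
}

# 20-monomer alphabet with equal counts: every singleton baseline is 1/20
uniformFreq20 <- function() {
  aa20 <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly",
            "his", "ile", "leu", "lys", "met", "phe", "pro", "ser",
            "thr", "trp", "tyr", "val")
  monomerFrequencyTable(setNames(rep(50, 20L), aa20))
}
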
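test_that("six-frame translation follows the genetic code and strand symmetry", {
  fr <- sixFrameTranslate(c(x = "ATGAAAACC"))
  expect_equal(nrow(fr), 6L)
  expect_equal(fr$peptide[fr$frame == 1L], "MKT")
  expect_equal(sixFrameTranslate(c(x = "ATGTAAACC"))$peptide[1], "M*T")
  # alternative initiation codons are NOT forced to Met: frames are not ORFs
  expect_equal(sixFrameTranslate(c(x = "TTGAAA"))$peptide[1], "LK")
  # N-containing codons read as X on both strands
  frN <- sixFrameTranslate(c(x = "ATGNNNACC"))
  expect_equal(frN$peptide[frN$frame == 1L], "MXT")
  expect_equal(frN$peptide[frN$frame == -1L], "GXH")
  # frame -1 of a record is frame +1 of its reverse complement
  s <- "ATGGCATTAGCCTGAACT"
  rc <- oracleRevComp(s)
  expect_equal(sixFrameTranslate(c(x = s))$peptide[4],
               sixFrameTranslate(c(x = rc))$peptide[1])
  expect_error(sixFrameTranslate(c(x = "ATGXQA")), "non-nucleotide")
  expect_error(sixFrameTranslate(c(x = "AT")), "shorter than one codon")
})

test_that("planted windows are found at exact genomic coordinates", {
  # hand-built: pad 4 nt, then codons for "GT" at nt 4..10 (frame +2)
  g <- c(toy = paste0("ACGC", "GGTACT", "AGGA"))
  m <- findPrepeptideMatches(parseTag("G-T", kind = "ripp"), g)
  expect_equal(nrow(m), 1L)
  expect_equal(m$frame, 2L)
  expect_equal(c(m$start, m$end), c(4L, 10L))
  expect_equal(m$peptide, "GT")
  expect_equal(m$end - m$start, 3L * 2L)

  # degenerate position: I(L) accepts a genomic Leu
  gl <- c(toy = paste0("ACGC", "CTTGCC", "AGGA"))   # "LA" at frame +2
  ml <- findPrepeptideMatches(parseTag("I(L)A", kind = "ripp"), gl)
  expect_true(any(ml$frame == 2L & ml$start == 4L & ml$peptide == "LA"))

  # minus-strand plant, coordinates checked by manual arithmetic
  fwd <- paste0("ACGC", "GGTACT", "AGGA")
  flipped <- c(toy = oracleRevComp(fwd))
  mm <- findPrepeptideMatches(parseTag("G-T", kind = "ripp"), flipped)
  expect_equal(mm$strand, "-")
  expect_equal(c(mm$start, mm$end), c(nchar(fwd) - 10L, nchar(fwd) - 4L))
  # nonproteinogenic candidates can never match a ribosomal frame
  none <- findPrepeptideMatches(sequenceTag(list("orn", "ser"),
                                            kind = "ripp"), g)
  expect_equal(nrow(none), 0L)
})

test_that("every reported match re-validates against the tag and genome", {
  set.seed(21)
  tag <- parseTag("AS(C)ATVTI(L)", kind = "ripp")
  concrete <- expandTag(tag)
  for (i in 1:10) {
    pep <- sample(c("ASATVTI", "ACATVTL"), 1L)
    sim <- generateRippGenome(1200, pep,
                              strand = sample(c("+", "-"), 1L),
                              seed = 100 + i)
    m <- findPrepeptideMatches(tag, sim$genome, orientationMode = "forward")
    expect_gte(nrow(m), 1L)
    fr <- sixFrameTranslate(sim$genome)
    for (j in seq_len(nrow(m))) {
      expect_equal(m$end[j] - m$start[j], 3L * tagLength(tag))
      # re-translate the reported interval on the reported strand
      gstr <- as.character(sim$genome[[1]])
      nt <- substr(gstr, m$start[j] + 1L, m$end[j])
      if (m$strand[j] == "-") nt <- oracleRevComp(nt)
      expect_equal(oracleTranslateFrame(nt, 1L), m$peptide[j])
      # and the matched peptide is one of the tag's concrete readings
      named <- paste(oneLetterToMonomer(strsplit(m$peptide[j], "")[[1]]),
                     collapse = "-")
      expect_true(named %in% concrete)
    }
  }
})

test_that("match counts are invariant under reverse complementation", {
  set.seed(31)
  tag <- parseTag("VVI(L)S(C)T", kind = "ripp")
  for (i in 1:5) {
    sim <- generateRippGenome(900, "VVLST", strand = "+", seed = 200 + i)
    g1 <- as.character(sim$genome[[1]])
    m1 <- findPrepeptideMatches(tag, c(r = g1))
    m2 <- findPrepeptideMatches(tag, c(r = oracleRevComp(g1)))
    expect_equal(nrow(m1), nrow(m2))
    expect_equal(sort(m1$start), sort(nchar(g1) - m2$end))
    expect_equal(table(m1$strand)[["+"]], table(m2$strand)[["-"]])
  }
})

test_that("window containment: prefix tags match at least as often", {
  set.seed(41)
  full <- parseTag("VHFVGWI(L)", kind = "ripp")
  for (i in 1:5) {
    sim <- generateRippGenome(1500, "VHFVGWL",
                              strand = sample(c("+", "-"), 1L),
                              seed = 300 + i)
    nFull <- nrow(findPrepeptideMatches(full, sim$genome))
    for (L in c(2, 4, 6)) {
      prefix <- sequenceTag(tagPositions(full)[1:L], kind = "ripp",
                            alphabet = monomerAlphabet(full))
      expect_gte(nrow(findPrepeptideMatches(prefix, sim$genome)), nFull)
    }
  }
})

test_that("matcher agrees with the naive expand-and-test oracle", {
  set.seed(51)
  tags <- list(parseTag("VTI(L)S(C)T", kind = "ripp"),
               parseTag("A-G", kind = "ripp"),
               parseTag("I(L)AGI(L)", kind = "ripp"))
  for (i in 1:8) {
    gstr <- paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
    for (tag in tags) {
      for (mode in c("forward", "both")) {
        got <- findPrepeptideMatches(tag, c(g = gstr),
                                     orientationMode = mode)
        want <- oracleRippMatches(tag, gstr, orientationMode = mode)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$start, want$start)
        expect_equal(got$frame, want$frame)
        expect_equal(got$peptide, want$peptide)
      }
    }
  }
})

test_that("orientation mode both finds reversed loci and deduplicates", {
  # plant the REVERSE of the tag reading: forward-only must miss it
  sim <- generateRippGenome(900, "TSLVV", strand = "+", seed = 77)
  tag <- parseTag("VVI(L)S(C)T", kind = "ripp")
  expect_equal(nrow(findPrepeptideMatches(tag, sim$genome, "forward")), 0L)
  both <- findPrepeptideMatches(tag, sim$genome, "both")
  expect_equal(nrow(both), 1L)
  expect_equal(both$tag_orientation, "reversed")
  # a tag-palindromic locus is reported once
  simP <- generateRippGenome(900, "VAV", strand = "+", seed = 78)
  pal <- parseTag("V-A-V", kind = "ripp")
  m <- findPrepeptideMatches(pal, simP$genome, "both")
  expect_equal(nrow(m), 1L)
  expect_equal(m$tag_orientation, "forward")
})

test_that("match tables and BED export write the stated conventions", {
  g <- c(toy = paste0("ACGC", "GGTACT", "AGGA"))
  m <- findPrepeptideMatches(parseTag("G-T", kind = "ripp"), g)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeMatchTable(m, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "0-based half-open")
  back <- read.delim(tsv, comment.char = "#")
  expect_equal(back$start, 4L)
  writeMatchTable(m, tsv, coords = "genbank")
  gb <- read.delim(tsv, comment.char = "#")
  expect_equal(c(gb$start, gb$end), c(5L, 10L))  # 1-based inclusive
  bed <- withr::local_tempfile(fileext = ".bed")
  writeBed(m, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields, c("toy", "4", "10", "GT", "0", "+"))
})
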
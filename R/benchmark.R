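#' The nine Streptomyces RiPP benchmark tags
#'
#' The benchmark set of nine RiPP sequence tags with the genomes they were
#' identified in. `genome_slug` is the file stem [rippBenchmark()] expects
#' in its genome directory.
#'
#' @return data.frame with columns `peptide`, `tag`, `genome` and
#'   `genome_slug`.
#' @export
rippBenchmarkTags <- function() {
  data.frame(
    peptide = c("SSV-2083", "SGR-1832", "SCO-2138", "SLI-2138",
                "SWA-2138", "SRO15-2005", "SRO15-2212", "SRO15-3108",
                "SAL-2242"),
    tag = c("I(L)GA(C)GTA(C)WI(L)A(C)V", "AVAQ(K)FVI(L)Q(K)GSTI(L)",
            "VHFVGWI(L)", "GI(L)VHFVGWI(L)", "I(L)AGI(L)VHFI(L)GWI(L)",
            "YWSRRI(L)I(L)", "VVI(L)S(C)T", "AS(C)ATVTI(L)",
            "VTI(L)S(C)T"),
    genome = c("Streptomyces sviceus ATCC 20983",
               "Streptomyces griseus IFO 13350",
               "Streptomyces coelicolor A3(2)",
               "Streptomyces lividans TK24",
               "Streptomyces sp. E14",
               "Streptomyces roseosporus NRRL 15998",
               "Streptomyces roseosporus NRRL 15998",
               "Streptomyces roseosporus NRRL 15998",
               "Streptomyces albus J1074"),
    genome_slug = c("S_sviceus_ATCC20983", "S_griseus_IFO13350",
                    "S_coelicolor_A3_2", "S_lividans_TK24",
                    "S_sp_E14", "S_roseosporus_NRRL15998",
                    "S_roseosporus_NRRL15998", "S_roseosporus_NRRL15998",
                    "S_albus_J1074"),
    stringsAsFactors = FALSE)
}

#' Run the RiPP tag benchmark against local genome sequences
#'
#' Scans each benchmark tag ([rippBenchmarkTags()]) against its genome and
#' reports per-genome match counts. Genome sequences are multi-Mb public
#' records and are not shipped with the package: download each genome
#' (all replicons/contigs in one FASTA, plain or gzip) into `genomeDir`
#' under its `genome_slug` file stem (e.g. `S_coelicolor_A3_2.fasta`).
#' Tags whose genome file is absent get `NA` counts.
#'
#' @param genomeDir directory holding the genome FASTA files.
#' @param orientationMode `"forward"` (default) or `"both"`, passed to
#'   [findPrepeptideMatches()].
#' @return the [rippBenchmarkTags()] table with extra columns `file`
#'   (path found or `NA`), `n_matches` and `unique`.
#' @export
rippBenchmark <- function(genomeDir,
                          orientationMode = c("forward", "both")) {
  orientationMode <- match.arg(orientationMode)
  tab <- rippBenchmarkTags()
  tab$file <- NA_character_
  tab$n_matches <- NA_integer_
  for (i in seq_len(nrow(tab))) {
    hits <- list.files(genomeDir,
                       pattern = sprintf("^%s\\.(fa|fna|fasta)(\\.gz)?$",
                                         tab$genome_slug[i]),
                       full.names = TRUE)
    if (!length(hits)) next
    tab$file[i] <- hits[1L]
    genome <- readDNAStringSet(hits[1L])
    tag <- parseTag(tab$tag[i], kind = "ripp")
    tab$n_matches[i] <- nrow(findPrepeptideMatches(
      tag, genome, orientationMode = orientationMode))
  }
  tab$unique <- tab$n_matches == 1L
  tab
}
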
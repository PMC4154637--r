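.DB_SCHEMA <- "pep2path-bgcdb/1"
.RANKS <- c("domain", "phylum", "class", "order", "family",
            "genus", "species", "strain")

.predAsList <- function(p) {
  list(stachelhaus_code = if (is.na(p@stachCode)) NULL else p@stachCode,
       stachelhaus_match = as.list(p@stachMatch),
       stachelhaus_identity = if (is.na(p@stachIdentity)) NULL
                              else p@stachIdentity,
       svm_single = as.list(p@svmSingle),
       svm_small = as.list(p@svmSmall),
       svm_large = as.list(p@svmLarge),
       svm_three = as.list(p@svmThree))
}

.entryAsList <- function(e) {
  list(cluster_id = e@clusterId,
       accession = if (is.na(e@accession)) NULL else e@accession,
       lineage = as.list(e@lineage),
       genes = lapply(names(e@genes), function(g) {
         list(gene_id = g, modules = lapply(e@genes[[g]], .predAsList))
       }))
}

.chr <- function(x) as.character(unlist(x, use.names = FALSE))

.predFromList <- function(m, where) {
  tryCatch(
    specificityPrediction(
      stachCode = if (is.null(m$stachelhaus_code)) NA_character_
                  else m$stachelhaus_code,
      stachMatch = .chr(m$stachelhaus_match),
      stachIdentity = if (is.null(m$stachelhaus_identity)) NA_real_
                      else m$stachelhaus_identity,
      svmSingle = .chr(m$svm_single),
      svmSmall = .chr(m$svm_small),
      svmLarge = .chr(m$svm_large),
      svmThree = .chr(m$svm_three)),
    error = function(e)
      stop(sprintf("invalid module in %s: %s", where, conditionMessage(e)),
           call. = FALSE))
}

.entryFromList <- function(x) {
  id <- x$cluster_id
  if (is.null(id) || !nzchar(id))
    stop("database entry without a cluster_id", call. = FALSE)
  genes <- list()
  for (g in x$genes) {
    if (is.null(g$gene_id))
      stop(sprintf("entry '%s': gene without a gene_id", id), call. = FALSE)
    if (g$gene_id %in% names(genes))
      stop(sprintf("entry '%s': duplicate gene_id '%s'", id, g$gene_id),
           call. = FALSE)
    genes[[g$gene_id]] <- lapply(seq_along(g$modules), function(i)
      .predFromList(g$modules[[i]],
                    sprintf("entry '%s', gene '%s', module %d",
                            id, g$gene_id, i - 1L)))
  }
  e <- tryCatch(
    bgcEntry(id, genes,
             accession = if (is.null(x$accession)) NA_character_
                         else x$accession,
             lineage = .chr(x$lineage)),
    error = function(err)
      stop(sprintf("invalid entry '%s': %s", id, conditionMessage(err)),
           call. = FALSE))
  e
}

#' Load a BGC database from its JSON document
#'
#' The on-disk format is a single self-describing UTF-8 JSON document with
#' an embedded schema version (`"pep2path-bgcdb/1"`), the monomer
#' alphabet, free-text provenance and the entry list. Stachelhaus
#' identities given as percent (1, 100] are normalized to fractions on
#' load. Files violating the schema or the entry invariants are rejected
#' with an error naming the failing entry and field.
#'
#' @param path file path.
#' @return a [BGCDatabase-class] object.
#' @seealso [saveDatabase()], [mergeDatabases()], [readPredictionTable()]
#' @export
loadDatabase <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such database file: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$schema, .DB_SCHEMA))
    stop(sprintf("'%s' is not a %s document (schema: %s)",
                 path, .DB_SCHEMA, if (is.null(x$schema)) "missing"
                                   else x$schema))
  entries <- lapply(x$entries, .entryFromList)
  db <- bgcDatabase(entries,
                    alphabet = .normalizeMonomer(.chr(x$alphabet)),
                    provenance = if (is.null(x$provenance)) ""
                                 else x$provenance)
  validObject(db)
  db
}

#' Save a BGC database to its JSON document
#'
#' @param db a [BGCDatabase-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveDatabase <- function(db, path) {
  doc <- list(schema = .DB_SCHEMA,
              alphabet = as.list(db@alphabet),
              provenance = db@provenance,
              entries = lapply(db@entries, .entryAsList))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Merge two BGC databases
#'
#' The union of the two entry lists. Alphabets must be identical or one a
#' declared superset of the other (the union alphabet is kept). Entries
#' sharing a cluster id are deduplicated when their content is identical
#' and are a merge conflict otherwise.
#'
#' @param a,b [BGCDatabase-class] objects.
#' @return the merged [BGCDatabase-class].
#' @export
mergeDatabases <- function(a, b) {
  supA <- all(b@alphabet %in% a@alphabet)
  supB <- all(a@alphabet %in% b@alphabet)
  if (!supA && !supB)
    stop("incompatible alphabets: neither database's alphabet contains the other's")
  alphabet <- if (supA) a@alphabet else b@alphabet
  entries <- a@entries
  ids <- vapply(entries, function(e) e@clusterId, character(1L))
  for (e in b@entries) {
    i <- match(e@clusterId, ids)
    if (is.na(i)) {
      entries[[length(entries) + 1L]] <- e
      ids <- c(ids, e@clusterId)
    } else if (!identical(.entryAsList(entries[[i]]), .entryAsList(e))) {
      stop(sprintf(
        "merge conflict: cluster id '%s' occurs in both databases with different content",
        e@clusterId))
    }
  }
  bgcDatabase(entries, alphabet = alphabet,
              provenance = sprintf("merge of [%s] and [%s]",
                                   a@provenance, b@provenance))
}

#' Filter a database by taxonomic range
#'
#' Keeps the entries whose lineage carries `value` (case-insensitive) at
#' the requested rank, or at any lineage position when `rank` is `NULL`.
#' Rank keywords index into the declared rank order (domain, phylum,
#' class, order, family, genus, species, strain); lineages shorter
#' than the requested rank simply never match. Entry order is preserved
#' and an empty result is valid.
#'
#' @param db a [BGCDatabase-class] object.
#' @param value taxon name to match (non-empty).
#' @param rank one of the rank keywords above, or `NULL` for any position.
#' @return the filtered [BGCDatabase-class].
#' @export
filterByTaxonomy <- function(db, value, rank = NULL) {
  if (!nzchar(trimws(value))) stop("taxon value must be non-empty")
  value <- tolower(trimws(value))
  keep <- vapply(db@entries, function(e) {
    lin <- tolower(e@lineage)
    if (is.null(rank)) value %in% lin
    else {
      i <- match(tolower(rank), .RANKS)
      if (is.na(i)) stop(sprintf("unknown rank keyword '%s'", rank))
      length(lin) >= i && lin[i] == value
    }
  }, logical(1L))
  bgcDatabase(db@entries[keep], alphabet = db@alphabet,
              provenance = db@provenance)
}

#' Build a database from a tab-separated prediction table
#'
#' The importer behind the `makedb` command. One row per NRPS module with
#' columns `cluster_id`, `accession`, `lineage` (";"-joined, broadest rank
#' first), `gene_id`, `module_index` (0-based, consecutive within a gene),
#' `stachelhaus_code`, `stachelhaus_identity` (fraction or percent),
#' `stachelhaus_match`, `svm_single`, `svm_small`, `svm_large`,
#' `svm_three`; set-valued cells are "/"-joined, empty or `nrp` cells mean
#' no call.
#'
#' @param path TSV file path.
#' @param alphabet monomer alphabet for the resulting database.
#' @return a [BGCDatabase-class] object.
#' @export
readPredictionTable <- function(path, alphabet = defaultAlphabet()) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("cluster_id", "accession", "lineage", "gene_id", "module_index",
            "stachelhaus_code", "stachelhaus_identity",
            "svm_single", "svm_small", "svm_large", "svm_three")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("prediction table '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!"stachelhaus_match" %in% names(df))
    df$stachelhaus_match <- NA_character_
  splitSet <- function(x) {
    if (is.na(x)) character() else strsplit(x, "/", fixed = TRUE)[[1L]]
  }
  entries <- lapply(split(df, factor(df$cluster_id,
                                     levels = unique(df$cluster_id))),
                    function(rows) {
    genes <- list()
    for (g in unique(rows$gene_id)) {
      sub <- rows[rows$gene_id == g, , drop = FALSE]
      sub <- sub[order(sub$module_index), , drop = FALSE]
      if (!identical(as.integer(sub$module_index),
                     seq_len(nrow(sub)) - 1L))
        stop(sprintf(
          "entry '%s', gene '%s': module_index must be consecutive from 0",
          rows$cluster_id[1L], g))
      genes[[g]] <- lapply(seq_len(nrow(sub)), function(i)
        specificityPrediction(
          stachCode = sub$stachelhaus_code[i],
          stachMatch = splitSet(sub$stachelhaus_match[i]),
          stachIdentity = sub$stachelhaus_identity[i],
          svmSingle = splitSet(sub$svm_single[i]),
          svmSmall = splitSet(sub$svm_small[i]),
          svmLarge = splitSet(sub$svm_large[i]),
          svmThree = splitSet(sub$svm_three[i])))
    }
    bgcEntry(rows$cluster_id[1L], genes,
             accession = rows$accession[1L],
             lineage = if (is.na(rows$lineage[1L])) character()
                       else trimws(strsplit(rows$lineage[1L], ";",
                                            fixed = TRUE)[[1L]]))
  })
  bgcDatabase(unname(entries), alphabet = alphabet,
              provenance = sprintf("imported from %s", basename(path)))
}
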
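#' Construct an annotation table
#'
#' The central container of the package: a set of protein records plus their
#' InterPro domain hits, as produced by InterProScan. Every hit must resolve
#' to a protein record.
#'
#' @param proteins data.frame with columns `protein_id`, `species`,
#'   `gene_id`, and optionally `transcript_id` and `sequence`.
#' @param hits data.frame with columns `protein_id`, `interpro_id`
#'   (`"IPR"` + 6 digits, or `""` for signature-only hits), `signature_id`,
#'   `start`, `end` (1-based inclusive residue positions) and optionally
#'   `score`.
#' @return An object of class `nlr_annotation`: a list with elements
#'   `proteins` and `hits`.
#' @export
annotation_table <- function(proteins, hits) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  for (col in c("protein_id", "species", "gene_id")) {
    if (is.null(proteins[[col]])) proteins[[col]] <- character(nrow(proteins))
  }
  if (is.null(proteins$transcript_id)) {
    proteins$transcript_id <- rep(NA_character_, nrow(proteins))
  }
  if (is.null(proteins$sequence)) {
    proteins$sequence <- rep(NA_character_, nrow(proteins))
  }
  for (col in c("protein_id", "interpro_id", "signature_id")) {
    if (is.null(hits[[col]])) hits[[col]] <- character(nrow(hits))
  }
  if (is.null(hits$start)) hits$start <- integer(nrow(hits))
  if (is.null(hits$end)) hits$end <- integer(nrow(hits))
  if (is.null(hits$score)) hits$score <- rep(NA_real_, nrow(hits))
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein_id in protein records: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  }
  bad <- nzchar(hits$interpro_id) & !grepl("^IPR[0-9]{6}$", hits$interpro_id)
  if (any(bad)) {
    stop("malformed InterPro accession(s): ",
         paste(unique(hits$interpro_id[bad]), collapse = ", "))
  }
  if (nrow(hits) && any(hits$start < 1 | hits$end < hits$start)) {
    stop("domain hit coordinates must satisfy 1 <= start <= end")
  }
  orphan <- setdiff(hits$protein_id, proteins$protein_id)
  if (length(orphan)) {
    stop("hits reference unknown protein_id(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  proteins$species <- normalize_species(proteins$species)
  structure(list(proteins = proteins, hits = hits), class = "nlr_annotation")
}

#' @export
print.nlr_annotation <- function(x, ...) {
  cat(sprintf("<nlr_annotation> %d proteins, %d domain hits, %d species\n",
              nrow(x$proteins), nrow(x$hits),
              length(unique(x$proteins$species))))
  invisible(x)
}

# Collapse whitespace so "Genus  species" keys group identically everywhere.
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

#' Combine annotation tables
#'
#' @param ... `nlr_annotation` objects.
#' @return A single `nlr_annotation` containing all records.
#' @export
bind_annotations <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "nlr_annotation")) {
    tabs <- tabs[[1]]
  }
  annotation_table(
    do.call(rbind, lapply(tabs, `[[`, "proteins")),
    do.call(rbind, lapply(tabs, `[[`, "hits"))
  )
}

#' Read an InterProScan tab-separated output file
#'
#' Accepts the standard InterProScan TSV layout of 11 to 15 columns (protein
#' accession, md5, length, analysis, signature accession, signature
#' description, start, stop, score, status, date, and optionally InterPro
#' accession, InterPro description, GO terms and pathways). `"-"` marks a
#' missing field. Rows without an InterPro accession are retained as
#' signature-level hits with an empty `interpro_id`.
#'
#' @param path Path to the TSV file.
#' @param species Binomial species name attached to every protein record.
#' @return An [annotation_table()] with one protein record per distinct
#'   sequence identifier and one hit per row.
#' @export
read_interproscan_tsv <- function(path, species) {
  if (!file.exists(path)) stop("cannot read InterProScan file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(annotation_table(
      data.frame(protein_id = character(), species = character(),
                 gene_id = character(), stringsAsFactors = FALSE),
      data.frame(protein_id = character(), interpro_id = character(),
                 signature_id = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 11L | nf > 15L)
  if (length(bad)) {
    stop(sprintf("malformed InterProScan row: line %d has %d columns (expected 11-15)",
                 bad[1], nf[bad[1]]))
  }
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else "-", character(1))
  }
  blank <- function(x) ifelse(x == "-" | is.na(x), "", x)
  protein_id <- get_col(1)
  signature_id <- blank(get_col(5))
  start <- suppressWarnings(as.integer(get_col(7)))
  end <- suppressWarnings(as.integer(get_col(8)))
  score <- suppressWarnings(as.numeric(blank(get_col(9))))
  interpro_id <- blank(get_col(12))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed InterProScan row: non-integer coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  }
  hits <- data.frame(protein_id = protein_id, interpro_id = interpro_id,
                     signature_id = signature_id, start = start, end = end,
                     score = score, stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = unique(protein_id),
                         species = species,
                         gene_id = unique(protein_id),
                         stringsAsFactors = FALSE)
  annotation_table(proteins, hits)
}

#' Read a multi-FASTA protein file
#'
#' The first whitespace-delimited token of each header is taken as the
#' protein identifier. Sequences are uppercased; line wrapping is ignored.
#'
#' @param path Path to a FASTA file.
#' @param species Binomial species name attached to every record.
#' @return data.frame with columns `protein_id`, `species`, `sequence`.
#' @export
read_fasta <- function(path, species) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(protein_id = ids, species = normalize_species(species),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences as multi-FASTA
#'
#' @param seqs data.frame with columns `protein_id` and `sequence`, or a
#'   named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    v <- seqs$sequence
    names(v) <- seqs$protein_id
  } else {
    v <- seqs
  }
  set <- Biostrings::AAStringSet(v)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED-like gene coordinate table
#'
#' Four tab-separated columns: chromosome, start, end, gene identifier, with
#' an optional fifth species column. Coordinates are stored 0-based
#' half-open; set `one_based = TRUE` for tables in the 1-based inclusive
#' dialect.
#'
#' @param path Path to the TSV file.
#' @param one_based Logical; input uses 1-based inclusive coordinates.
#' @param species Species applied when no fifth column is present.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `species`, sorted by (chromosome, start).
#' @export
read_gene_coordinates <- function(path, one_based = FALSE, species = NA_character_) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chromosome", "start", "end",
                                         "gene_id", "species")[1:5],
                           fill = TRUE)
  if (!nrow(raw)) {
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      species = character(), stringsAsFactors = FALSE))
  }
  if (all(is.na(raw$species)) || all(raw$species == "")) raw$species <- species
  start <- as.numeric(raw$start)
  end <- as.numeric(raw$end)
  if (one_based) start <- start - 1
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid gene interval at row %d: start >= end", bad[1]))
  }
  out <- data.frame(gene_id = as.character(raw$gene_id),
                    chromosome = as.character(raw$chromosome),
                    start = start, end = end,
                    species = normalize_species(raw$species),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a result table deterministically
#'
#' Output is byte-stable for a fixed input: columns keep their order, rows
#' are sorted lexicographically over all columns, and numbers are formatted
#' locale-independently.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) > 1L) {
    ord <- do.call(order, c(unname(as.list(x)), list(method = "radix")))
    x <- x[ord, , drop = FALSE]
  }
  rownames(x) <- NULL
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(x), collapse = "\t"), con)
    if (nrow(x)) {
      cells <- vapply(x, function(col) {
        if (is.numeric(col)) formatC(col, format = "g", digits = 15) else as.character(col)
      }, character(nrow(x)))
      if (nrow(x) == 1L) cells <- matrix(cells, nrow = 1)
      writeLines(apply(cells, 1, paste, collapse = "\t"), con)
    }
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = NA,
                      check.names = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
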
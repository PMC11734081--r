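#' Per-group unique InterPro domain sets
#'
#' Collapses domain hits to the set of distinct InterPro accessions per
#' group (species or class), keeping the pre-deduplication hit count as
#' provenance. Accepts either an [annotation_table()] (grouped by species)
#' or a long data.frame with a group column and an `interpro_id` column.
#'
#' @param x `nlr_annotation` or data.frame.
#' @param group Name of the grouping column when `x` is a data.frame
#'   (default `"species"`).
#' @return An object of class `nlr_domain_sets`: list with `sets` (named
#'   list of sorted accession vectors) and `provenance` (named integer
#'   total-hit counts).
#' @export
unique_domains <- function(x, group = "species") {
  if (inherits(x, "nlr_annotation")) {
    h <- x$hits[nzchar(x$hits$interpro_id), , drop = FALSE]
    sp <- x$proteins$species[match(h$protein_id, x$proteins$protein_id)]
    df <- data.frame(group = sp, interpro_id = h$interpro_id,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(group = as.character(x[[group]]),
                     interpro_id = as.character(x$interpro_id),
                     stringsAsFactors = FALSE)
  }
  bad <- df$interpro_id[!grepl("^IPR[0-9]{6}$", df$interpro_id)]
  if (length(bad)) {
    stop("malformed InterPro accession(s): ",
         paste(unique(bad), collapse = ", "))
  }
  groups <- sort(unique(df$group))
  sets <- lapply(groups, function(g) sort(unique(df$interpro_id[df$group == g])))
  names(sets) <- groups
  prov <- vapply(groups, function(g) sum(df$group == g), integer(1))
  structure(list(sets = sets, provenance = prov), class = "nlr_domain_sets")
}

#' @export
print.nlr_domain_sets <- function(x, ...) {
  cat(sprintf("<nlr_domain_sets> %d groups; set sizes: %s\n",
              length(x$sets),
              paste(lengths(x$sets), collapse = ", ")))
  invisible(x)
}

as_sets <- function(collection) {
  if (inherits(collection, "nlr_domain_sets")) collection$sets else collection
}

#' Union of all group domain sets
#'
#' @param collection `nlr_domain_sets` or a named list of accession vectors.
#' @return Sorted character vector of accessions.
#' @export
union_all <- function(collection) {
  sort(unique(unlist(as_sets(collection), use.names = FALSE)))
}

#' Intersection across all groups
#'
#' @inheritParams union_all
#' @return Sorted character vector of accessions present in every group.
#' @export
intersect_all <- function(collection) {
  sets <- as_sets(collection)
  if (!length(sets)) return(character())
  out <- sets[[1]]
  for (s in sets[-1]) out <- intersect(out, s)
  sort(out)
}

#' Group-exclusive domains
#'
#' Accessions present in exactly one group, keyed by that group.
#'
#' @inheritParams union_all
#' @return Named list of sorted accession vectors, one per group.
#' @export
exclusive_domains <- function(collection) {
  sets <- as_sets(collection)
  m <- membership_matrix(sets)
  deg <- rowSums(m)
  lapply(stats::setNames(names(sets), names(sets)), function(g) {
    sort(rownames(m)[deg == 1L & m[, g]])
  })
}

#' Boolean membership matrix
#'
#' Rows are the union of accessions (sorted), columns the groups; a cell is
#' TRUE when the accession occurs in the group.
#'
#' @inheritParams union_all
#' @return Logical matrix.
#' @export
membership_matrix <- function(collection) {
  sets <- as_sets(collection)
  u <- union_all(sets)
  m <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) m <- matrix(m, nrow = 1, dimnames = list(u, names(sets)))
  rownames(m) <- u
  m
}

#' Domain counts by sharing degree
#'
#' For each k, the number of accessions present in exactly k groups. The
#' counts over all k sum to the union size.
#'
#' @param x `nlr_domain_sets`, a named list of sets, or a membership
#'   matrix from [membership_matrix()].
#' @return data.frame with columns `k` and `n_domains`.
#' @export
intersection_degrees <- function(x) {
  m <- if (is.matrix(x)) x else membership_matrix(x)
  deg <- rowSums(m)
  ks <- seq_len(ncol(m))
  data.frame(k = ks,
             n_domains = vapply(ks, function(k) sum(deg == k), integer(1)))
}

#' Packaged per-species domain lists for nine Fabaceae species
#'
#' The published per-species unique InterPro domain lists for the nine
#' Fabaceae species, as a domain-set collection ready for the set
#' operations. Provenance carries the published total (pre-deduplication)
#' domain-hit counts.
#'
#' @return `nlr_domain_sets` with nine groups.
#' @export
fabaceae_domain_sets <- function() {
  path <- system.file("extdata", "fabaceae_domain_lists.tsv",
                      package = "nlrarch", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- unique_domains(df, group = "species")
  totals <- c("Glycine max" = 4661L, "Lupinus angustifolius" = 1516L,
              "Medicago truncatula" = 4403L, "Pisum sativum" = 1701L,
              "Phaseolus vulgaris" = 2083L, "Trifolium pratense" = 2411L,
              "Vigna angularis" = 1631L, "Vigna radiata" = 1195L,
              "Vigna unguiculata" = 3740L)
  out$provenance <- totals[names(out$sets)]
  out
}

#' Packaged per-species NLR count summary for nine Fabaceae species
#'
#' Genome size, annotated-gene count, and NLR gene/protein counts for the
#' nine Fabaceae species.
#'
#' @return data.frame with columns `species`, `common_name`,
#'   `genome_size_mb`, `n_annotated_genes`, `n_nlr_genes`,
#'   `n_nlr_proteins`.
#' @export
fabaceae_species_summary <- function() {
  path <- system.file("extdata", "fabaceae_species_summary.tsv",
                      package = "nlrarch", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Packaged per-species architecture class counts
#'
#' Counts of the L, N, CN, TN, NL, CNL and TNL classes per species for the
#' nine Fabaceae species.
#'
#' @return data.frame with a `species` column and one column per class.
#' @export
fabaceae_class_counts <- function() {
  path <- system.file("extdata", "fabaceae_class_counts.tsv",
                      package = "nlrarch", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
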
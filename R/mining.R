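#' Select NLR candidate proteins
#'
#' A protein is a candidate when at least one of its hits carries a tracked
#' InterPro accession (the NB-ARC role N or any of the four LRR roles
#' L1-L4). Selection is by accession only; hit coordinates are ignored.
#'
#' @param annotations An [annotation_table()].
#' @param roles Role map; defaults to [default_role_map()].
#' @return An `nlr_annotation` restricted to candidate proteins (all their
#'   hits are retained, including untracked decoy domains).
#' @export
select_candidates <- function(annotations, roles = default_role_map()) {
  acc <- tracked_accessions(roles)
  keep_ids <- unique(annotations$hits$protein_id[
    annotations$hits$interpro_id %in% acc])
  subset_annotation(annotations, keep_ids)
}

subset_annotation <- function(annotations, protein_ids) {
  annotation_table(
    annotations$proteins[annotations$proteins$protein_id %in% protein_ids, ,
                         drop = FALSE],
    annotations$hits[annotations$hits$protein_id %in% protein_ids, ,
                     drop = FALSE]
  )
}

#' Remove duplicate sequences within each species
#'
#' Within each species at most one protein per distinct amino-acid sequence
#' is retained; the survivor is the lexicographically smallest protein
#' identifier, making the operation deterministic and idempotent. Proteins
#' without a sequence fall back to protein-identifier identity (i.e. are
#' always retained).
#'
#' @param candidates An `nlr_annotation`.
#' @return The deduplicated `nlr_annotation`.
#' @export
deduplicate_candidates <- function(candidates) {
  p <- candidates$proteins
  if (!nrow(p)) return(candidates)
  key <- ifelse(is.na(p$sequence) | !nzchar(p$sequence),
                paste0("\x01id:", p$protein_id),
                p$sequence)
  key <- paste(p$species, key, sep = "\x01")
  ord <- order(key, p$protein_id, method = "radix")
  keep <- !duplicated(key[ord])
  subset_annotation(candidates, p$protein_id[ord][keep])
}

#' Per-species candidate counts
#'
#' Counts distinct proteins and distinct genes per species, with a totals
#' row appended. Proteins with a missing gene identifier are counted under
#' a sentinel gene bucket with a warning.
#'
#' @param candidates An `nlr_annotation`.
#' @param genome_metadata Optional data.frame with columns `species` and any
#'   of `genome_size_mb`, `n_annotated_genes`, merged onto the summary.
#' @return data.frame with columns `species`, `n_genes`, `n_proteins` (plus
#'   merged metadata columns), last row `species == "Total"`.
#' @export
summarize_counts <- function(candidates, genome_metadata = NULL) {
  p <- candidates$proteins
  gene <- p$gene_id
  missing_gene <- is.na(gene) | !nzchar(gene)
  if (any(missing_gene)) {
    warning(sum(missing_gene), " protein(s) without gene_id counted under <no_gene>")
    gene[missing_gene] <- "<no_gene>"
  }
  if (nrow(p)) {
    sp <- sort(unique(p$species))
    n_proteins <- vapply(sp, function(s) length(unique(p$protein_id[p$species == s])), integer(1))
    n_genes <- vapply(sp, function(s) length(unique(gene[p$species == s])), integer(1))
  } else {
    sp <- character()
    n_proteins <- n_genes <- integer()
  }
  out <- data.frame(species = sp, n_genes = n_genes, n_proteins = n_proteins,
                    stringsAsFactors = FALSE)
  if (!is.null(genome_metadata)) {
    meta_cols <- intersect(c("genome_size_mb", "n_annotated_genes"),
                           names(genome_metadata))
    out <- merge(out, genome_metadata[, c("species", meta_cols), drop = FALSE],
                 by = "species", all.x = TRUE, sort = TRUE)
  }
  total <- out[1, , drop = FALSE][0, ]
  total[1, "species"] <- "Total"
  total[1, "n_genes"] <- sum(out$n_genes)
  total[1, "n_proteins"] <- sum(out$n_proteins)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
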
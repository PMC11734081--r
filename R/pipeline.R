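#' Run the full analysis pipeline
#'
#' Orchestrates mining, deduplication, classification, co-occurrence
#' counting, domain set operations, per-class MDS, window density and the
#' genome-size correlation over a set of annotation tables, writing every
#' stage's table plus a JSON manifest (configuration hash, package
#' version, per-stage row counts) to `out_dir`.
#'
#' @param annotations An [annotation_table()] covering all species (use
#'   [bind_annotations()] to combine per-species tables).
#' @param coordinates Optional gene coordinate table for the density stage.
#' @param genome_metadata Optional data.frame (`species`,
#'   `genome_size_mb`, `n_annotated_genes`) merged into the count summary
#'   and used for the correlation stage.
#' @param roles Role map.
#' @param out_dir Output directory (created if absent).
#' @param window_size Density window in bp.
#' @param mds_k Embedding dimensions.
#' @param mds_max_n Per-class cap on sequences entering the center-star
#'   alignment (larger classes are subsampled deterministically).
#' @param mds_min_n Minimum class size for the MDS stage.
#' @param seed Seed for the (only) stochastic step, MDS subsampling.
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_all <- function(annotations, coordinates = NULL, genome_metadata = NULL,
                    roles = default_role_map(), out_dir = tempfile("nlrarch_"),
                    window_size = 1e6, mds_k = 2, mds_max_n = 80,
                    mds_min_n = 4, seed = 1) {
  roles <- validate_role_map(roles)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()

  candidates <- select_candidates(annotations, roles)
  stage_counts$candidates <- nrow(candidates$proteins)
  candidates <- deduplicate_candidates(candidates)
  stage_counts$deduplicated <- nrow(candidates$proteins)

  summary <- summarize_counts(candidates, genome_metadata)
  write_table(summary, file.path(out_dir, "summary.tsv"))

  classes <- classify_all(candidates, roles)
  stopifnot(nrow(classes) == stage_counts$deduplicated)
  stage_counts$classified <- nrow(classes)
  write_table(classes, file.path(out_dir, "classes.tsv"))
  write_table(class_counts(classes), file.path(out_dir, "class_counts.tsv"))

  profiles <- suppressMessages(presence_profiles(candidates, roles))
  counts_pooled <- combination_counts(profiles, "pooled")
  counts_species <- combination_counts(profiles, "per-species")
  write_table(counts_pooled, file.path(out_dir, "cooccurrence_pooled.tsv"))
  write_table(counts_species, file.path(out_dir, "cooccurrence_species.tsv"))
  stage_counts$profiled <- nrow(profiles)

  sets <- unique_domains(candidates)
  membership <- membership_matrix(sets)
  write_table(data.frame(interpro_id = rownames(membership), membership,
                         check.names = FALSE),
              file.path(out_dir, "membership.tsv"))

  mds <- list()
  seqs_ok <- !is.na(candidates$proteins$sequence) &
    nzchar(candidates$proteins$sequence)
  if (any(seqs_ok)) {
    with_seed(seed, {
      for (cl in setdiff(unique(classes$class), "UNCLASSIFIED")) {
        ids <- classes$protein_id[classes$class == cl]
        ids <- intersect(ids, candidates$proteins$protein_id[seqs_ok])
        if (length(ids) < mds_min_n) next
        if (length(ids) > mds_max_n) ids <- sort(sample(ids, mds_max_n))
        p <- candidates$proteins
        seqs <- stats::setNames(p$sequence[match(ids, p$protein_id)], ids)
        aln <- center_star_align(seqs)
        emb <- classical_mds(difference_matrix(aln), k = mds_k)
        mds[[cl]] <- emb
        write_table(data.frame(protein_id = rownames(emb$points),
                               emb$points, check.names = FALSE),
                    file.path(out_dir, paste0("mds_", cl, ".tsv")))
      }
    })
  }
  stage_counts$mds_classes <- length(mds)

  density <- NULL
  if (!is.null(coordinates) && nrow(coordinates)) {
    density <- window_density(coordinates, window_size)
    write_table(density, file.path(out_dir, "density.tsv"))
  }

  correlation <- NULL
  if (!is.null(genome_metadata) &&
      all(c("genome_size_mb") %in% names(genome_metadata))) {
    per_species <- summary[summary$species != "Total", ]
    m <- merge(per_species, genome_metadata, by = "species")
    if (nrow(m) >= 3) {
      correlation <- pearson_cor(m$genome_size_mb.y %||% m$genome_size_mb,
                                 m$n_proteins)
    }
  }

  manifest <- list(package = "nlrarch",
                   version = as.character(utils::packageVersion("nlrarch")),
                   role_map_hash = role_map_hash(roles),
                   seed = seed, window_size = window_size, mds_k = mds_k,
                   stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, classes = classes,
                 cooccurrence_pooled = counts_pooled,
                 cooccurrence_species = counts_species,
                 domain_sets = sets, mds = mds, density = density,
                 correlation = correlation, manifest = manifest,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
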
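AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

LABEL_ROLES <- list(
  N = "N", CN = c("C", "N"), TN = c("T", "N"),
  L = "L", CL = c("C", "L"), TL = c("T", "L"),
  NL = c("N", "L"), CNL = c("C", "N", "L"), TNL = c("T", "N", "L"),
  UNCLASSIFIED = character()
)

#' Largest-remainder apportionment
#'
#' Deterministically allocates `n` items to categories in proportion to
#' `props`: floors of `props * n` first, then one extra item per category
#' in decreasing order of fractional remainder (ties broken by category
#' order).
#'
#' @param props Non-negative weights summing to 1.
#' @param n Total count to allocate.
#' @return Integer vector summing to `n`, same names as `props`.
#' @export
largest_remainder <- function(props, n) {
  if (abs(sum(props) - 1) > 1e-8) stop("proportions must sum to 1")
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra_order <- order(-(raw - base), seq_along(props))
    base[extra_order[seq_len(rem)]] <- base[extra_order[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Describe one synthetic species
#'
#' @param species Binomial species name.
#' @param n_genes Number of genes.
#' @param n_proteins Number of proteins (transcripts); defaults to
#'   `n_genes` (one transcript per gene). Extra transcripts beyond one per
#'   gene are assigned to genes round-robin, deterministically. Must not
#'   exceed `2 * n_genes`... larger fan-out wraps around further.
#' @param class_props Named proportions over architecture class labels
#'   (subset of the nine classes), summing to 1.
#' @param decoy_pool InterPro accessions usable as decoy domains; must not
#'   overlap any role accession.
#' @param decoy_prob Per-protein probability of carrying one decoy domain.
#' @param motif_length Length of the class- and species-specific conserved
#'   motifs embedded in each sequence.
#' @param divergence Per-site substitution probability applied to each
#'   motif copy.
#' @param base_length Length of the random (i.i.d. uniform residue)
#'   background on each side of the motifs.
#' @param n_chromosomes,chromosome_length Chromosome count and length (bp)
#'   for uniform gene placement.
#' @return List of class `nlr_species_block`.
#' @export
species_block <- function(species, n_genes, n_proteins = n_genes,
                          class_props = c(TNL = 1),
                          decoy_pool = character(), decoy_prob = 0,
                          motif_length = 120, divergence = 0.05,
                          base_length = 20,
                          n_chromosomes = 8, chromosome_length = 5e7) {
  if (abs(sum(class_props) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (!all(names(class_props) %in% CLASS_LABELS)) {
    stop("unknown class label(s): ",
         paste(setdiff(names(class_props), CLASS_LABELS), collapse = ", "))
  }
  if (decoy_prob < 0 || decoy_prob > 1) stop("decoy_prob must be in [0, 1]")
  if (n_proteins < n_genes) stop("n_proteins must be >= n_genes")
  structure(list(species = species, n_genes = as.integer(n_genes),
                 n_proteins = as.integer(n_proteins),
                 class_props = class_props, decoy_pool = decoy_pool,
                 decoy_prob = decoy_prob, motif_length = motif_length,
                 divergence = divergence, base_length = base_length,
                 n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length),
            class = "nlr_species_block")
}

#' Assemble a synthetic proteome specification
#'
#' @param blocks List of [species_block()]s.
#' @param seed Integer seed; mandatory, all sampling flows from it.
#' @param roles Role map used to plant role accessions.
#' @param sample_classes If TRUE, class labels are drawn multinomially from
#'   the proportions instead of the deterministic largest-remainder
#'   allocation.
#' @return List of class `nlr_synthetic_spec`.
#' @export
synthetic_spec <- function(blocks, seed, roles = default_role_map(),
                           sample_classes = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  roles <- validate_role_map(roles)
  role_acc <- unlist(roles, use.names = FALSE)
  for (b in blocks) {
    stopifnot(inherits(b, "nlr_species_block"))
    clash <- intersect(b$decoy_pool, role_acc)
    if (length(clash)) {
      stop("decoy pool overlaps role accessions: ",
           paste(clash, collapse = ", "))
    }
  }
  structure(list(blocks = blocks, seed = as.integer(seed), roles = roles,
                 sample_classes = isTRUE(sample_classes)),
            class = "nlr_synthetic_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_residues <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  ch <- strsplit(motif, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

#' Generate a synthetic multi-species proteome
#'
#' Emits an annotation table, protein sequences, gene coordinates and
#' ground-truth labels with the structure the analysis assumes: per-species
#' class counts follow the spec's proportions (largest-remainder rounding
#' by default), each protein carries exactly the role accessions implied by
#' its planted class (one accession per role, the L role drawing one of the
#' four LRR subtypes) plus optional decoy domains, and each sequence embeds
#' a class-specific and a species-specific conserved motif in an otherwise
#' i.i.d.-uniform residue background, with per-site substitution at the
#' stated divergence rate. Genes are placed uniformly on chromosomes. The
#' whole generation is deterministic given the spec's seed.
#'
#' @param spec [synthetic_spec()].
#' @return List with `annotations` (an [annotation_table()] whose protein
#'   records carry sequences), `sequences` (named character vector),
#'   `coordinates` (gene coordinate table) and `truth` (data.frame with
#'   `protein_id`, `species`, `class`, `roles`, `gene_id`, `cluster`).
#' @export
generate_proteomes <- function(spec) {
  stopifnot(inherits(spec, "nlr_synthetic_spec"))
  with_seed(spec$seed, {
    roles <- spec$roles
    all_species <- vapply(spec$blocks, `[[`, character(1), "species")
    all_classes <- CLASS_LABELS
    motif_len <- max(c(6, vapply(spec$blocks, `[[`, numeric(1), "motif_length")))
    class_motifs <- stats::setNames(
      vapply(all_classes, function(cl) random_residues(motif_len), character(1)),
      all_classes)
    species_motifs <- stats::setNames(
      vapply(all_species, function(s) random_residues(motif_len), character(1)),
      all_species)

    proteins <- hits <- coords <- truth <- list()
    for (bi in seq_along(spec$blocks)) {
      b <- spec$blocks[[bi]]
      if (b$n_proteins == 0L) next
      prefix <- paste0("S", bi)
      gene_ids <- sprintf("%s_g%05d", prefix, seq_len(b$n_genes))
      # transcripts: one per gene, extras assigned round-robin
      gene_of <- gene_ids[1 + (seq_len(b$n_proteins) - 1) %% b$n_genes]
      gene_of <- sort(gene_of)
      protein_ids <- sprintf("%s_p%05d", prefix, seq_len(b$n_proteins))
      transcript_ids <- sprintf("%s_t%05d", prefix, seq_len(b$n_proteins))

      props <- b$class_props
      if (spec$sample_classes) {
        labels <- sample(names(props), b$n_proteins, replace = TRUE, prob = props)
      } else {
        counts <- largest_remainder(props, b$n_proteins)
        labels <- rep(names(counts), counts)
      }

      block_hits <- list()
      seqs <- character(b$n_proteins)
      planted_roles <- character(b$n_proteins)
      for (i in seq_len(b$n_proteins)) {
        rs <- LABEL_ROLES[[labels[i]]]
        accs <- character()
        concrete <- character()
        for (r in rs) {
          role_key <- if (r == "L") sample(c("L1", "L2", "L3", "L4"), 1) else r
          concrete <- c(concrete, role_key)
          pool <- roles[[role_key]]
          accs <- c(accs, if (length(pool) == 1L) pool else sample(pool, 1))
        }
        if (length(b$decoy_pool) && stats::runif(1) < b$decoy_prob) {
          accs <- c(accs, if (length(b$decoy_pool) == 1L) b$decoy_pool
                    else sample(b$decoy_pool, 1))
        }
        planted_roles[i] <- paste(concrete, collapse = ",")
        seqs[i] <- paste0(
          random_residues(b$base_length),
          mutate_motif(species_motifs[[b$species]], b$divergence),
          random_residues(b$base_length),
          mutate_motif(class_motifs[[labels[i]]], b$divergence),
          random_residues(b$base_length))
        if (length(accs)) {
          pos <- 10L + 40L * (seq_along(accs) - 1L)
          block_hits[[i]] <- data.frame(
            protein_id = protein_ids[i], interpro_id = accs,
            signature_id = paste0("SYN_", accs),
            start = pos, end = pos + 30L, score = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
      proteins[[bi]] <- data.frame(
        protein_id = protein_ids, species = b$species, gene_id = gene_of,
        transcript_id = transcript_ids, sequence = seqs,
        stringsAsFactors = FALSE)
      hits[[bi]] <- do.call(rbind, block_hits)
      gene_len <- 3000
      chrom <- sample(b$n_chromosomes, b$n_genes, replace = TRUE)
      start <- floor(stats::runif(b$n_genes, 0, b$chromosome_length - gene_len))
      coords[[bi]] <- data.frame(
        gene_id = gene_ids, chromosome = sprintf("chr%02d", chrom),
        start = start, end = start + gene_len, species = b$species,
        stringsAsFactors = FALSE)
      truth[[bi]] <- data.frame(
        protein_id = protein_ids, species = b$species, class = labels,
        roles = planted_roles, gene_id = gene_of,
        cluster = paste(b$species, labels, sep = "/"),
        stringsAsFactors = FALSE)
    }
    proteins <- do.call(rbind, proteins)
    hits <- do.call(rbind, hits)
    if (is.null(proteins)) {
      proteins <- data.frame(protein_id = character(), species = character(),
                             gene_id = character(), transcript_id = character(),
                             sequence = character(), stringsAsFactors = FALSE)
    }
    if (is.null(hits)) {
      hits <- data.frame(protein_id = character(), interpro_id = character(),
                         signature_id = character(), start = integer(),
                         end = integer(), score = numeric(),
                         stringsAsFactors = FALSE)
    }
    coords <- if (length(coords)) do.call(rbind, coords) else
      data.frame(gene_id = character(), chromosome = character(),
                 start = numeric(), end = numeric(), species = character(),
                 stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(protein_id = character(), species = character(),
                 class = character(), roles = character(),
                 gene_id = character(), cluster = character(),
                 stringsAsFactors = FALSE)
    rownames(coords) <- rownames(truth) <- NULL
    annotations <- annotation_table(proteins, hits)
    list(annotations = annotations,
         sequences = stats::setNames(proteins$sequence, proteins$protein_id),
         coordinates = coords, truth = truth)
  })
}

#' Preset spec mirroring the nine-species Fabaceae study shape
#'
#' Builds a nine-species synthetic spec whose per-species gene and protein
#' totals mirror the packaged Fabaceae summary table (scaled by `factor`)
#' and whose class proportions follow the packaged per-species class-count
#' table. Decoy accessions are drawn from the packaged per-species domain
#' lists (minus the role accessions) so set-operation outputs look
#' realistic.
#'
#' @param preset Currently only `"fabaceae9"`.
#' @param factor Scale applied to the published per-species totals
#'   (default 0.1).
#' @param seed Integer seed (mandatory).
#' @param decoy_prob Per-protein decoy inclusion probability.
#' @param divergence Motif per-site substitution rate.
#' @return [synthetic_spec()].
#' @export
emulate_survey_shape <- function(preset = "fabaceae9", factor = 0.1, seed,
                                decoy_prob = 0.25, divergence = 0.05) {
  if (!identical(preset, "fabaceae9")) stop("unknown preset: ", preset)
  if (missing(seed)) stop("a seed is mandatory")
  summary <- fabaceae_species_summary()
  classes <- fabaceae_class_counts()
  roles <- default_role_map()
  sets <- fabaceae_domain_sets()
  decoys <- setdiff(union_all(sets), unlist(roles, use.names = FALSE))
  class_cols <- setdiff(names(classes), "species")
  blocks <- lapply(seq_len(nrow(summary)), function(i) {
    sp <- summary$species[i]
    n_prot <- as.integer(round(factor * summary$n_nlr_proteins[i]))
    n_gene <- min(as.integer(round(factor * summary$n_nlr_genes[i])),
                  max(n_prot, 1L))
    cc <- as.numeric(classes[classes$species == sp, class_cols])
    props <- stats::setNames(cc / sum(cc), class_cols)
    props <- props[props > 0]
    species_block(sp, n_genes = max(n_gene, 1L),
                  n_proteins = max(n_prot, 1L),
                  class_props = props, decoy_pool = decoys,
                  decoy_prob = decoy_prob, divergence = divergence)
  })
  synthetic_spec(blocks, seed = seed, roles = roles)
}
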
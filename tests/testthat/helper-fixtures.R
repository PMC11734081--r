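# Builders and independent brute-force oracles shared across the suite.

# Annotation table from a named list: protein_id -> character vector of
# InterPro accessions (possibly empty).
make_annotation <- function(hits_by_protein, species = "Testus species",
                            sequences = NULL, gene_ids = NULL) {
  ids <- names(hits_by_protein)
  if (is.null(ids)) ids <- character()
  proteins <- data.frame(
    protein_id = ids, species = rep_len(species, length(ids)),
    gene_id = if (is.null(gene_ids)) ids else gene_ids,
    stringsAsFactors = FALSE)
  if (!is.null(sequences)) proteins$sequence <- sequences[ids]
  hit_rows <- lapply(ids, function(p) {
    accs <- hits_by_protein[[p]]
    if (!length(accs)) return(NULL)
    data.frame(protein_id = p, interpro_id = accs,
               signature_id = paste0("SIG_", accs),
               start = 1L, end = 50L, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(), interpro_id = character(),
                       signature_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  annotation_table(proteins, hits)
}

# One InterProScan TSV row (13 columns).
ipscan_line <- function(protein, signature, start, end, interpro = "-",
                        score = "1e-10") {
  paste(protein, "md5", "500", "Pfam", signature, "desc", start, end,
        score, "T", "01-01-2024", interpro, "desc2", sep = "\t")
}

# Independent truth-table oracle for the nine-class assignment.
classify_oracle <- function(has_N, has_L, has_C, has_T) {
  if (has_N && has_L) {
    if (has_T) "TNL" else if (has_C) "CNL" else "NL"
  } else if (has_N) {
    if (has_T) "TN" else if (has_C) "CN" else "N"
  } else if (has_L) {
    if (has_T) "TL" else if (has_C) "CL" else "L"
  } else {
    "UNCLASSIFIED"
  }
}

# Brute-force combination counting: enumerate all 2^5 - 1 role subsets and
# count profiles matching each exactly.
brute_combination_counts <- function(profiles) {
  roles <- c("N", "L1", "L2", "L3", "L4")
  out <- list()
  for (mask in 1:31) {
    sel <- as.logical(bitwAnd(mask, 2^(0:4)))
    key <- paste(roles[sel], collapse = "")
    m <- as.matrix(profiles[, roles, drop = FALSE])
    n <- sum(rowSums(m == matrix(sel, nrow(m), 5, byrow = TRUE)) == 5L)
    if (n > 0) out[[key]] <- n
  }
  out
}

# Exhaustive global-alignment score by recursive enumeration (tiny inputs).
align_score_oracle <- function(a, b, match, mismatch, gap) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Pearson r and two-sided t-based p from the raw formulas.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

random_sequences <- function(n, len_range = c(8, 20)) {
  vapply(seq_len(n), function(i) {
    paste(sample(nlrarch:::AA_ALPHABET, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# A small random annotation table mixing tracked and decoy accessions.
random_annotation <- function(n = 20, species = "Testus species",
                              prefix = abbreviate(species, 2)) {
  roles <- default_role_map()
  tracked <- unlist(roles[c("N", "L1", "L2", "L3", "L4")], use.names = FALSE)
  decoys <- c("IPR000001", "IPR000002", "IPR000003")
  hits <- lapply(seq_len(n), function(i) {
    n_hit <- sample(0:3, 1)
    if (!n_hit) return(character())
    sample(c(tracked, decoys), n_hit)
  })
  names(hits) <- sprintf("%s_rp%03d", prefix, seq_len(n))
  make_annotation(hits, species = species)
}
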
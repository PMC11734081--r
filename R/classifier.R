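#' Architecture class labels
#'
#' The nine architecture classes plus UNCLASSIFIED, in the reporting order
#' used throughout the package.
#' @export
CLASS_LABELS <- c("N", "CN", "TN", "L", "CL", "TL", "NL", "CNL", "TNL",
                  "UNCLASSIFIED")

#' The 12 reference R-gene classes
#'
#' Closed vocabulary for asserted classes in reference R-gene tables
#' (PRGdb-style exports).
#' @export
REFERENCE_CLASSES <- c("CN", "CNL", "LECRK", "LYK", "LYP", "N", "NL",
                       "Other", "RLK", "RLP", "T", "TNL")

#' Derive per-protein domain-presence flags
#'
#' For every protein in the table, reports whether any hit maps to the
#' NB-ARC (N), coiled-coil (C) or TIR (T) role, and which of the four LRR
#' subtypes L1-L4 are present. `has_L` is true iff any L subtype is.
#'
#' @param annotations An [annotation_table()] (typically a candidate set).
#' @param roles Role map.
#' @return data.frame with columns `protein_id`, `species`, `has_N`,
#'   `has_C`, `has_T`, `L1` .. `L4`, `has_L`, one row per protein.
#' @export
derive_flags <- function(annotations, roles = default_role_map()) {
  roles <- validate_role_map(roles)
  p <- annotations$proteins
  h <- annotations$hits
  role_of_protein <- function(accs) {
    unique(h$protein_id[h$interpro_id %in% accs])
  }
  out <- data.frame(protein_id = p$protein_id, species = p$species,
                    stringsAsFactors = FALSE)
  out$has_N <- out$protein_id %in% role_of_protein(roles$N)
  out$has_C <- out$protein_id %in% role_of_protein(roles$C)
  out$has_T <- out$protein_id %in% role_of_protein(roles[["T"]])
  for (l in c("L1", "L2", "L3", "L4")) {
    out[[l]] <- out$protein_id %in% role_of_protein(roles[[l]])
  }
  out$has_L <- out$L1 | out$L2 | out$L3 | out$L4
  out
}

#' Assign an architecture class from presence flags
#'
#' Proteins with both NB-ARC and LRR fall in the NL group (NL, CNL, TNL),
#' NB-ARC only in the N group (N, CN, TN), LRR only in the L group
#' (L, CL, TL); neither gives UNCLASSIFIED. Within a group the TIR flag
#' picks the T-variant and the coiled-coil flag the C-variant; when both
#' are present the T-variant wins and the ambiguity flag is set.
#'
#' @param flags data.frame with logical columns `has_N`, `has_L`, `has_C`,
#'   `has_T` (extra columns are ignored), or a single named logical vector.
#' @return data.frame with columns `class` (one of [CLASS_LABELS]) and
#'   `ambiguous` (both C and T present).
#' @export
classify <- function(flags) {
  if (!is.data.frame(flags)) flags <- as.data.frame(as.list(flags))
  n <- as.logical(flags$has_N)
  l <- as.logical(flags$has_L)
  c_ <- as.logical(flags$has_C)
  t_ <- as.logical(flags$has_T)
  base <- ifelse(n & l, "NL", ifelse(n, "N", ifelse(l, "L", "")))
  prefix <- ifelse(t_, "T", ifelse(c_, "C", ""))
  label <- ifelse(base == "", "UNCLASSIFIED", paste0(prefix, base))
  data.frame(class = label, ambiguous = c_ & t_, stringsAsFactors = FALSE)
}

#' Classify every candidate protein
#'
#' Combines [derive_flags()] and [classify()] into a classification table;
#' each input protein appears exactly once. The role-map hash is attached
#' as attribute `role_map_hash` so results are attributable to an explicit
#' configuration.
#'
#' @inheritParams derive_flags
#' @return data.frame with flag columns, `class` and `ambiguous`.
#' @export
classify_all <- function(annotations, roles = default_role_map()) {
  flags <- derive_flags(annotations, roles)
  cls <- classify(flags)
  out <- cbind(flags, cls)
  attr(out, "role_map_hash") <- role_map_hash(roles)
  out
}

#' Per-species class count matrix
#'
#' @param classes Classification table from [classify_all()].
#' @return data.frame with one row per species and one column per class
#'   label, plus a `Total` row.
#' @export
class_counts <- function(classes) {
  sp <- sort(unique(classes$species))
  m <- sapply(CLASS_LABELS, function(cl) {
    vapply(sp, function(s) sum(classes$species == s & classes$class == cl),
           integer(1))
  })
  if (length(sp) == 1L) m <- matrix(m, nrow = 1, dimnames = list(sp, CLASS_LABELS))
  out <- data.frame(species = sp, m, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  total <- data.frame(species = "Total",
                      t(colSums(out[, CLASS_LABELS, drop = FALSE])),
                      stringsAsFactors = FALSE, check.names = FALSE)
  rbind(out, total)
}

default_audit_vocabulary <- function() {
  # asserted reference class -> derived label it should match; NA = cannot be
  # audited from domain architecture alone (kinase/lectin receptor classes).
  c(CN = "CN", CNL = "CNL", N = "N", NL = "NL", TNL = "TNL", TN = "TN",
    "T" = "T*", LECRK = NA, LYK = NA, LYP = NA, RLK = NA, RLP = NA,
    Other = NA)
}

#' Audit asserted reference classes against derived classes
#'
#' Compares the class asserted for each reference R-gene against the class
#' derived from its domain architecture. Classes outside the
#' architecture-derivable subset (kinase- and lectin-receptor families) are
#' flagged "not auditable"; the asserted class `T` is audited against the
#' TIR flag alone. Reference accessions absent from the derived table are
#' flagged "unscored".
#'
#' @param reference data.frame with columns `accession`, `asserted_class`
#'   (from [REFERENCE_CLASSES]) and optionally `gene_name`, `species`.
#' @param classes Classification table from [classify_all()] (accession
#'   matched against `protein_id`).
#' @param vocabulary Named vector mapping asserted classes to derived
#'   labels; `NA` marks non-auditable classes.
#' @return data.frame with columns `accession`, `asserted_class`,
#'   `derived_class`, `concordant`, `note`.
#' @export
audit_classes <- function(reference, classes,
                          vocabulary = default_audit_vocabulary()) {
  bad <- setdiff(reference$asserted_class, names(vocabulary))
  if (length(bad)) {
    stop("asserted class(es) outside the declared vocabulary: ",
         paste(unique(bad), collapse = ", "))
  }
  idx <- match(reference$accession, classes$protein_id)
  n <- nrow(reference)
  out <- data.frame(accession = reference$accession,
                    asserted_class = reference$asserted_class,
                    derived_class = NA_character_,
                    concordant = NA,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    expected <- vocabulary[[reference$asserted_class[i]]]
    if (is.na(idx[i])) {
      out$note[i] <- "unscored: accession absent from derived set"
      next
    }
    row <- classes[idx[i], ]
    out$derived_class[i] <- row$class
    if (is.na(expected)) {
      out$note[i] <- "not auditable from domain architecture"
      next
    }
    if (identical(expected, "T*")) {
      out$concordant[i] <- isTRUE(row$has_T)
      out$note[i] <- if (out$concordant[i]) "TIR flag present" else "TIR flag missing"
      next
    }
    out$concordant[i] <- identical(row$class, expected)
    if (!out$concordant[i]) {
      have <- c("N", "L", "C", "T")[c(row$has_N, row$has_L, row$has_C, row$has_T)]
      want <- strsplit(chartr("CNTL", "CNTL", expected), "")[[1]]
      want <- intersect(c("C", "T", "N", "L"), want)
      miss <- setdiff(want, have)
      extra <- setdiff(have, want)
      out$note[i] <- trimws(paste0(
        if (length(miss)) paste0("missing role(s): ", paste(miss, collapse = ","), " ") else "",
        if (length(extra)) paste0("extra role(s): ", paste(extra, collapse = ",")) else ""))
      if (!nzchar(out$note[i])) out$note[i] <- "class mismatch"
    }
  }
  out
}
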
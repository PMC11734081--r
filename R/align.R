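#' Pairwise global alignment
#'
#' Needleman-Wunsch global alignment of two residue strings under a simple
#' match/mismatch/linear-gap scoring scheme, with a deterministic traceback
#' (diagonal preferred over gap-in-second over gap-in-first on ties).
#'
#' @param a,b Residue strings.
#' @param match,mismatch,gap Integer scores; `gap` must be negative.
#' @return List with `score`, `aligned_a`, `aligned_b`.
#' @export
pairwise_global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(gap < 0)
  .nw_align(as.character(a), as.character(b), match, mismatch, gap)
}

#' Center-star multiple sequence alignment
#'
#' A desk-scale progressive aligner: the center sequence is the one
#' maximizing the summed pairwise global-alignment score against all
#' others (ties broken by the lexicographically smallest identifier); every
#' other sequence is aligned to the center and the pairwise alignments are
#' merged under the "once a gap, always a gap" rule. Intended for the
#' moderate per-class sequence sets of this analysis; an external aligner's
#' aligned FASTA can be supplied anywhere an alignment is expected.
#'
#' @param sequences Named character vector of residue strings (names are
#'   protein identifiers), or a data.frame with `protein_id` and
#'   `sequence`.
#' @inheritParams pairwise_global_align
#' @return Named character vector of equal-length aligned rows (gap `"-"`),
#'   in the input order, with class `nlr_alignment`.
#' @export
center_star_align <- function(sequences, match = 1, mismatch = -1, gap = -2) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$protein_id)
  }
  n <- length(sequences)
  if (!n) stop("center_star_align requires at least one sequence")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by protein identifier")
  }
  sequences <- vapply(sequences, toupper, character(1))
  if (n == 1L) {
    return(structure(sequences, class = "nlr_alignment"))
  }
  # choose the center by summed pairwise score
  total <- stats::setNames(numeric(n), names(sequences))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- .nw_align(sequences[[i]], sequences[[j]], match, mismatch, gap)$score
      total[i] <- total[i] + s
      total[j] <- total[j] + s
    }
  }
  best <- max(total)
  center_idx <- which(total == best)
  center_idx <- center_idx[order(names(sequences)[center_idx])][1]
  center <- sequences[[center_idx]]
  others <- setdiff(seq_len(n), center_idx)

  pairs <- lapply(others, function(i) {
    .nw_align(center, sequences[[i]], match, mismatch, gap)
  })
  nc <- nchar(center)
  # insertions relative to the center: gaps in the aligned center row,
  # bucketed by how many center residues precede them (slots 0..nc)
  ins_counts <- function(aligned_center) {
    ch <- strsplit(aligned_center, "")[[1]]
    slot <- integer(nc + 1)
    consumed <- 0L
    for (x in ch) {
      if (x == "-") slot[consumed + 1L] <- slot[consumed + 1L] + 1L
      else consumed <- consumed + 1L
    }
    slot
  }
  master <- integer(nc + 1)
  slots <- lapply(pairs, function(p) ins_counts(p$aligned_a))
  for (s in slots) master <- pmax(master, s)

  center_chars <- strsplit(center, "")[[1]]
  build_center <- function() {
    out <- character(0)
    for (k in 0:nc) {
      out <- c(out, rep("-", master[k + 1L]))
      if (k < nc) out <- c(out, center_chars[k + 1L])
    }
    paste(out, collapse = "")
  }
  # thread one pairwise alignment into the master coordinates; extra master
  # insertions are padded with gaps after the row's own insertion block
  build_row <- function(p) {
    ca <- strsplit(p$aligned_a, "")[[1]]
    sa <- strsplit(p$aligned_b, "")[[1]]
    out <- character(0)
    consumed <- 0L
    pending <- character(0)
    flush <- function(out, pending, slot_idx) {
      pad <- master[slot_idx] - length(pending)
      c(out, pending, rep("-", pad))
    }
    for (idx in seq_along(ca)) {
      if (ca[idx] == "-") {
        pending <- c(pending, sa[idx])
      } else {
        out <- flush(out, pending, consumed + 1L)
        pending <- character(0)
        out <- c(out, sa[idx])
        consumed <- consumed + 1L
      }
    }
    out <- flush(out, pending, consumed + 1L)
    paste(out, collapse = "")
  }
  rows <- stats::setNames(character(n), names(sequences))
  rows[center_idx] <- build_center()
  for (k in seq_along(others)) rows[others[k]] <- build_row(pairs[[k]])
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(rows, class = "nlr_alignment")
}

#' Read / write an aligned FASTA file
#'
#' Adapter for alignments produced by an external aligner (e.g. MUSCLE or
#' MAFFT): all records must have equal length.
#'
#' @param path Aligned FASTA path.
#' @return Named character vector of class `nlr_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (length(unique(nchar(rows))) > 1L) {
    stop("aligned FASTA rows have unequal lengths")
  }
  structure(rows, class = "nlr_alignment")
}

#' @rdname read_alignment_fasta
#' @param alignment `nlr_alignment`.
#' @export
write_alignment_fasta <- function(alignment, path) {
  write_fasta(unclass(alignment), path)
}

#' Pairwise difference-score matrix
#'
#' For every pair of aligned rows, the proportion of columns at which the
#' two symbols differ among the columns where not both are gaps
#' (gap-versus-residue counts as a difference; both-gap columns are
#' excluded). A pair with no eligible column scores 0 with a warning.
#'
#' @param alignment `nlr_alignment` (equal-length rows).
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal and the
#'   row names of the alignment.
#' @export
difference_matrix <- function(alignment) {
  rows <- unclass(alignment)
  if (length(unique(nchar(rows))) > 1L) {
    stop("alignment rows have unequal lengths")
  }
  all_gap <- !grepl("[^-]", rows)
  if (sum(all_gap) >= 2L || (any(all_gap) && length(rows) >= 2L)) {
    warning("pair(s) with zero eligible columns scored 0")
  }
  d <- .diff_scores(unname(rows))
  dimnames(d) <- list(names(rows), names(rows))
  d
}
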
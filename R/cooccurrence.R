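ROLE_ORDER <- c("N", "L1", "L2", "L3", "L4")

#' Per-protein presence profiles over the tracked roles
#'
#' One profile per candidate protein, recording which of the tracked roles
#' N, L1-L4 are present. Proteins with no tracked role are excluded and the
#' excluded count reported via a message.
#'
#' @param candidates An [annotation_table()], ideally deduplicated.
#' @param roles Role map.
#' @return data.frame with columns `protein_id`, `species`, logical columns
#'   `N`, `L1` .. `L4`, and `combination` (fixed-order key such as "NL1L2").
#' @export
presence_profiles <- function(candidates, roles = default_role_map()) {
  flags <- derive_flags(candidates, roles)
  out <- data.frame(protein_id = flags$protein_id, species = flags$species,
                    N = flags$has_N, L1 = flags$L1, L2 = flags$L2,
                    L3 = flags$L3, L4 = flags$L4, stringsAsFactors = FALSE)
  present <- out$N | out$L1 | out$L2 | out$L3 | out$L4
  if (any(!present)) {
    message(sum(!present), " protein(s) without tracked roles excluded from profiles")
  }
  out <- out[present, , drop = FALSE]
  out$combination <- combination_key(as.matrix(out[, ROLE_ORDER, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Combination key from a role-presence matrix
#'
#' Concatenates the present roles in the fixed order N, L1, L2, L3, L4
#' ("N", "L1L3", "NL1L2", ...).
#'
#' @param m Logical matrix with columns named as in `ROLE_ORDER`.
#' @return Character vector of keys.
#' @export
combination_key <- function(m) {
  m <- m[, ROLE_ORDER, drop = FALSE]
  apply(m, 1, function(r) paste(ROLE_ORDER[as.logical(r)], collapse = ""))
}

#' Exact presence-combination counts (UpSet-style)
#'
#' Counts every distinct subset of tracked roles observed among the
#' profiles. Percentages are relative to the universe: all profiled
#' proteins (pooled), or the species' profiled proteins (per species).
#' Rows are sorted by count descending, ties broken lexicographically by
#' key.
#'
#' @param profiles Output of [presence_profiles()].
#' @param universe `"pooled"` for one table over all species, or
#'   `"per-species"`.
#' @return data.frame with columns (`species`,) `combination`, `count`,
#'   `percent`.
#' @export
combination_counts <- function(profiles, universe = c("pooled", "per-species")) {
  universe <- match.arg(universe)
  count_one <- function(df) {
    if (!nrow(df)) {
      return(data.frame(combination = character(), count = integer(),
                        percent = numeric(), stringsAsFactors = FALSE))
    }
    tab <- table(df$combination)
    out <- data.frame(combination = names(tab),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out$percent <- 100 * out$count / nrow(df)
    out <- out[order(-out$count, out$combination, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (universe == "pooled") return(count_one(profiles))
  sp <- sort(unique(profiles$species))
  parts <- lapply(sp, function(s) {
    one <- count_one(profiles[profiles$species == s, , drop = FALSE])
    if (nrow(one)) cbind(species = s, one, stringsAsFactors = FALSE) else
      cbind(species = character(), one)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Check declared forbidden role co-occurrences
#'
#' For each declared role pair, reports whether any observed combination
#' contains both roles (e.g. the finding that NB-ARC never co-occurs with
#' the L3 entry in legume NLR candidates).
#'
#' @param counts Combination count table from [combination_counts()].
#' @param forbidden_pairs List of length-2 character vectors of roles, e.g.
#'   `list(c("N", "L3"), c("L2", "L3"))`.
#' @return data.frame with columns `pair`, `holds` (TRUE when no observed
#'   combination contains both roles) and `violations` (offending keys,
#'   comma-separated).
#' @export
absence_assertions <- function(counts,
                               forbidden_pairs = list(c("N", "L3"))) {
  keys <- unique(counts$combination[counts$count > 0])
  roles_in_key <- lapply(keys, key_roles)
  rows <- lapply(forbidden_pairs, function(pair) {
    stopifnot(length(pair) == 2L, all(pair %in% ROLE_ORDER))
    bad <- keys[vapply(roles_in_key, function(r) all(pair %in% r), logical(1))]
    data.frame(pair = paste(pair, collapse = "+"),
               holds = length(bad) == 0L,
               violations = paste(bad, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Decompose a fixed-order combination key back into its roles.
key_roles <- function(key) {
  found <- character()
  rest <- key
  for (r in c("L1", "L2", "L3", "L4", "N")) {
    if (grepl(r, rest, fixed = TRUE)) {
      found <- c(found, r)
      rest <- sub(r, "", rest, fixed = TRUE)
    }
  }
  intersect(ROLE_ORDER, found)
}
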
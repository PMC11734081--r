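#' Fixed-window gene density per chromosome
#'
#' Counts genes per non-overlapping window of `window_size` bp on each
#' chromosome. A gene is assigned to the window containing its start
#' coordinate (0-based); the trailing partial window is included.
#'
#' @param coords Gene coordinate table from [read_gene_coordinates()]
#'   (0-based half-open `start`/`end`, plus `chromosome`, `species`).
#' @param window_size Window width in bp (default 1 Mb).
#' @return data.frame with columns `species`, `chromosome`, `window`
#'   (0-based index), `window_start` and `count`; all windows from 0 to
#'   the last gene-bearing window are present, including empty ones.
#' @export
window_density <- function(coords, window_size = 1e6) {
  if (window_size <= 0) stop("window_size must be positive")
  if (!nrow(coords)) {
    return(data.frame(species = character(), chromosome = character(),
                      window = integer(), window_start = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  key <- unique(coords[, c("species", "chromosome")])
  key <- key[order(key$species, key$chromosome), , drop = FALSE]
  parts <- lapply(seq_len(nrow(key)), function(i) {
    sel <- coords$species == key$species[i] & coords$chromosome == key$chromosome[i]
    w <- floor(coords$start[sel] / window_size)
    n_win <- max(w) + 1L
    counts <- tabulate(w + 1L, nbins = n_win)
    data.frame(species = key$species[i], chromosome = key$chromosome[i],
               window = seq_len(n_win) - 1L,
               window_start = (seq_len(n_win) - 1) * window_size,
               count = counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with a t-based p-value
#'
#' Standard Pearson r with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x has zero variance")
  if (stats::sd(y) == 0) stop("y has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
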
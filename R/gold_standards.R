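#' Build the Gold Standard Positive (GSP) interaction set
#'
#' Unions curated interaction pair lists from several source databases into a
#' single set of unique canonical pairs. Reversed duplicates collapse to one
#' pair, self-interactions are dropped, and heterogeneous identifiers can be
#' resolved through an alias table before deduplication.
#'
#' @param sources Named list; each element a two-column data frame (or matrix)
#'   of protein identifier pairs as reported by one source database.
#'   Duplicates, reversed pairs and self-pairs are allowed in the input.
#' @param aliases Optional data frame with columns `alias` and `canonical`;
#'   identifiers matching `alias` are rewritten to `canonical` before
#'   deduplication.
#' @return Data frame of unique canonical pairs (columns `a`, `b`) with
#'   attributes `per_source_raw` (input row counts), `per_source_unique`
#'   (unique canonical pairs contributed by each source) and `n_unique`.
#' @export
build_gsp <- function(sources, aliases = NULL) {
  stopifnot(is.list(sources), length(sources) >= 1)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  resolve <- function(x) {
    x <- as.character(x)
    if (is.null(aliases)) return(x)
    i <- match(x, as.character(aliases$alias))
    ifelse(is.na(i), x, as.character(aliases$canonical)[i])
  }
  per_raw <- integer(length(sources))
  per_unique <- integer(length(sources))
  parts <- vector("list", length(sources))
  for (s in seq_along(sources)) {
    src <- as.data.frame(sources[[s]], stringsAsFactors = FALSE)
    stopifnot(ncol(src) >= 2)
    per_raw[s] <- nrow(src)
    p <- canonical_pairs(resolve(src[[1]]), resolve(src[[2]]))
    per_unique[s] <- nrow(p)
    parts[[s]] <- p
  }
  all <- do.call(rbind, parts)
  gsp <- canonical_pairs(all$a, all$b)
  if (nrow(gsp) == 0L) {
    stop("GSP is empty after canonicalization; cannot train on an empty positive set")
  }
  names(per_raw) <- names(per_unique) <- names(sources)
  attr(gsp, "per_source_raw") <- per_raw
  attr(gsp, "per_source_unique") <- per_unique
  attr(gsp, "n_unique") <- nrow(gsp)
  gsp
}

#' Build the Gold Standard Negative (GSN) interaction set
#'
#' Negative pairs are formed across incompatible cellular compartments: every
#' pair with one protein annotated to the plasma membrane and the other to the
#' nucleus. Proteins in `removed` are excluded up front; pairs whose members
#' are *both* dual-localized (annotated to both compartments) are excluded
#' because such a pair is not a confident negative; pairs present in the GSP
#' are subtracted and counted.
#'
#' @param membrane,nuclear Character vectors of protein identifiers annotated
#'   to the plasma-membrane and nuclear compartments.
#' @param removed Protein identifiers to drop from both compartments before
#'   pair formation.
#' @param gsp Optional GSP pair data frame (columns `a`, `b`); overlapping
#'   pairs are removed and the overlap count reported.
#' @return Data frame of canonical negative pairs with attributes
#'   `n_gsp_overlap_removed`, `n_dual_excluded` and `n_unique`.
#' @export
build_gsn <- function(membrane, nuclear, removed = character(), gsp = NULL) {
  m <- setdiff(unique(as.character(membrane)), as.character(removed))
  n <- setdiff(unique(as.character(nuclear)), as.character(removed))
  if (!length(m) || !length(n)) {
    stop("a compartment set is empty after removals; cannot build GSN")
  }
  grid <- expand.grid(a = m, b = n, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  pairs <- canonical_pairs(grid$a, grid$b)
  dual <- intersect(m, n)
  both_dual <- pairs$a %in% dual & pairs$b %in% dual
  n_dual <- sum(both_dual)
  pairs <- pairs[!both_dual, , drop = FALSE]
  n_overlap <- 0L
  if (!is.null(gsp) && nrow(gsp)) {
    hit <- pair_key(pairs$a, pairs$b) %in% pair_key(gsp$a, gsp$b)
    n_overlap <- sum(hit)
    pairs <- pairs[!hit, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("GSN is empty after subtractions")
  rownames(pairs) <- NULL
  attr(pairs, "n_gsp_overlap_removed") <- n_overlap
  attr(pairs, "n_dual_excluded") <- n_dual
  attr(pairs, "n_unique") <- nrow(pairs)
  pairs
}

#' Ratio of gold-standard positive to negative set sizes
#'
#' @param gsp_size,gsn_size Set sizes (counts).
#' @return `gsp_size / gsn_size` rounded (half-even) to 5 decimal places.
#' @examples
#' gsp_gsn_ratio(85083, 23169177)  # 0.00367
#' @export
gsp_gsn_ratio <- function(gsp_size, gsn_size) {
  stopifnot(length(gsp_size) == 1, length(gsn_size) == 1)
  if (gsn_size <= 0) stop("gsn_size must be positive")
  round(gsp_size / gsn_size, 5)
}

#' Split gold standards into training and Standard Test (STS) partitions
#'
#' Samples `n_pos` positives and `n_neg` negatives without replacement into a
#' held-out test set; the remainder forms the training partition used for
#' likelihood-ratio estimation. The test pairs never enter training.
#'
#' @param gsp,gsn Canonical pair data frames (columns `a`, `b`).
#' @param n_pos,n_neg Number of positive/negative pairs for the test set.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list of class `sts_split` with elements `train` and `test`, each
#'   a list with `gsp` and `gsn` pair data frames.
#' @export
split_sts <- function(gsp, gsn, n_pos, n_neg, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos > nrow(gsp) || n_neg > nrow(gsn)) {
    stop("requested test-set sizes exceed available gold-standard pairs")
  }
  set.seed(seed)
  ip <- sample.int(nrow(gsp), n_pos)
  ineg <- sample.int(nrow(gsn), n_neg)
  reset_rows <- function(d) { rownames(d) <- NULL; d }
  out <- list(
    train = list(gsp = reset_rows(gsp[setdiff(seq_len(nrow(gsp)), ip), , drop = FALSE]),
                 gsn = reset_rows(gsn[setdiff(seq_len(nrow(gsn)), ineg), , drop = FALSE])),
    test = list(gsp = reset_rows(gsp[ip, , drop = FALSE]),
                gsn = reset_rows(gsn[ineg, , drop = FALSE]))
  )
  class(out) <- "sts_split"
  out
}
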
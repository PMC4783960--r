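#' Canonicalize unordered protein pairs
#'
#' Protein pairs are unordered throughout the package. The canonical form
#' places the lexicographically smaller identifier first; self-pairs are
#' dropped and duplicates (including reversed duplicates) collapsed.
#'
#' @param a,b Character vectors of protein identifiers, same length.
#' @param drop_self Drop pairs with `a == b` (default `TRUE`).
#' @param dedupe Collapse duplicate pairs after canonicalization
#'   (default `TRUE`).
#' @return A data frame with character columns `a` and `b`, `a < b` rowwise.
#' @examples
#' canonical_pairs(c("B", "A", "C"), c("A", "B", "C"))
#' @export
canonical_pairs <- function(a, b, drop_self = TRUE, dedupe = TRUE) {
  stopifnot(length(a) == length(b))
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  keep <- if (drop_self) a != b else rep(TRUE, length(a))
  out <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  if (dedupe && nrow(out)) {
    out <- out[!duplicated(pair_key(out$a, out$b)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Order-independent key for an unordered pair
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Character vector of keys; `pair_key(x, y) == pair_key(y, x)`.
#' @export
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Map linear indices 1..n*(n-1)/2 onto the upper triangle (i < j) of an
# n x n pair space. Used to sample distinct unordered pairs without
# materializing the full candidate space.
pair_index_to_ij <- function(k, n) {
  stopifnot(n >= 2, all(k >= 1), all(k <= n * (n - 1) / 2))
  cum <- cumsum((n - 1):1)              # pairs with first index <= i
  i <- findInterval(k - 0.5, c(0, cum))
  before <- c(0, cum)[i]
  j <- i + (k - before)
  cbind(i = i, j = j)
}
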
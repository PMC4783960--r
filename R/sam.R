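#' Collapse probe-level values to a gene-level value
#'
#' One probe reports its value unchanged; exactly two probes are averaged;
#' three or more probes take the median.
#'
#' @param values Numeric vector of probe-level values for one gene (one
#'   sample).
#' @return A single numeric value.
#' @examples
#' aggregate_probes(c(2, 4))     # 3
#' aggregate_probes(c(1, 2, 9))  # 2
#' @export
aggregate_probes <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) stop("no probe values supplied")
  if (n == 1) return(values)
  if (n == 2) return(mean(values))
  stats::median(values)
}

#' Collapse a probe-level expression matrix to gene level
#'
#' Applies the [aggregate_probes()] rule per gene and sample.
#'
#' @param probe_matrix Numeric matrix, probes in rows.
#' @param genes Character vector mapping each probe row to its gene.
#' @return Numeric matrix with one row per gene (rownames = gene IDs, sorted).
#' @export
aggregate_probes_matrix <- function(probe_matrix, genes) {
  stopifnot(is.matrix(probe_matrix), length(genes) == nrow(probe_matrix))
  genes <- as.character(genes)
  ids <- sort(unique(genes))
  out <- matrix(NA_real_, length(ids), ncol(probe_matrix),
                dimnames = list(ids, colnames(probe_matrix)))
  rows <- split(seq_along(genes), genes)
  for (g in ids) {
    sub <- probe_matrix[rows[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, aggregate_probes)
  }
  out
}

#' Log2 transform and per-sample median normalization
#'
#' Applies `log2(x + offset)` and centers each sample (column) at median
#' zero, the preprocessing expected before co-expression and SAM analysis.
#'
#' @param x Numeric matrix of raw (positive) expression values.
#' @param offset Added before the log; values `<= -offset` are an error.
#' @return The transformed matrix with attribute `log2_transformed = TRUE`.
#' @export
log2_normalize <- function(x, offset = 0) {
  stopifnot(is.matrix(x))
  if (any(x + offset <= 0)) {
    stop("non-positive values; supply a positive `offset` or pre-clean the matrix")
  }
  l <- log2(x + offset)
  l <- sweep(l, 2, apply(l, 2, stats::median), `-`)
  attr(l, "log2_transformed") <- TRUE
  l
}

# Moderated d-statistic for a two-class comparison:
# d = (mean2 - mean1) / (s + s0), with s the pooled standard error.
sam_d_stat <- function(x, i1, i2, s0 = 0) {
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(r = m2 - m1, s = s, d = (m2 - m1) / (s + s0))
}

# Exchangeability factor s0: the percentile of the gene-wise standard errors
# that minimizes the coefficient of variation of the median absolute d
# across windows of s (the original SAM recipe).
sam_s0 <- function(r, s, n_windows = 100) {
  if (length(s) < 25) return(unname(stats::quantile(s, 0.5)))
  alphas <- seq(0, 1, by = 0.05)
  salpha <- stats::quantile(s, alphas)
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_windows + 1)))
  if (length(br) < 3) return(unname(stats::quantile(s, 0.5)))
  grp <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(seq_along(alphas), function(i) {
    dal <- r / (s + salpha[i])
    v <- tapply(dal, grp, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)
  structure(unname(salpha[best]), percentile = alphas[best])
}

#' Significance analysis of microarrays, two-class unpaired
#'
#' Per gene, the moderated statistic `d = (mean_treated - mean_control) /
#' (s + s0)` is compared against its expected order statistic `dbar` under a
#' permutation null (class labels permuted, `d` recomputed and sorted, then
#' averaged across permutations rank by rank). Genes with
#' `|d_(i) - dbar_(i)| > delta` are called, signed by `d`. The false
#' discovery rate at a given `delta` is estimated as the median number of
#' permuted genes falling beyond the least extreme called `d` values, divided
#' by the number of observed calls. When `delta` is `NULL` it is auto-tuned
#' to the smallest value whose estimated FDR does not exceed `fdr_ceiling`.
#'
#' @param x Log2-scale expression matrix, genes in rows (rownames required).
#' @param classes Two-level factor (or coercible) over the columns; the
#'   *second* level is treated as the treated/experiment group. At least two
#'   replicates per class are required.
#' @param n_permutations Number of label permutations (default 1000). When
#'   fewer distinct assignments exist (e.g. 20 for a 3 vs 3 design) the
#'   exhaustive set is used with a warning.
#' @param seed Integer seed for the permutation sample.
#' @param fdr_ceiling Target FDR for delta auto-tuning (default 0.05).
#' @param delta Fixed delta; `NULL` (default) auto-tunes.
#' @param s0 Fixed exchangeability factor; `NULL` (default) selects it by the
#'   coefficient-of-variation rule across standard-error windows.
#' @return Object of class `sam_result`: `genes` data frame (`gene`, `d`,
#'   `dbar`, `s`, `mean_diff` log2 fold change, `fold_change`, Welch `t` and
#'   `p` for transparency, `call` in up/down/none), and `tuning` (s0, delta,
#'   estimated FDR, permutation count, exhaustive flag, seed).
#' @export
sam_two_class <- function(x, classes, n_permutations = 1000, seed = 1L,
                          fdr_ceiling = 0.05, delta = NULL, s0 = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), all(is.finite(x)))
  classes <- factor(classes)
  stopifnot(nlevels(classes) == 2, length(classes) == ncol(x))
  i1 <- which(classes == levels(classes)[1])
  i2 <- which(classes == levels(classes)[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("at least two replicates per class are required")
  }
  n <- ncol(x)
  obs <- sam_d_stat(x, i1, i2, s0 = 0)
  if (is.null(s0)) s0 <- sam_s0(obs$r, obs$s)
  s0_percentile <- attr(s0, "percentile")
  s0 <- as.numeric(s0)
  d <- obs$r / (obs$s + s0)

  # permutation null: all distinct assignments of n2 columns to group 2,
  # or a seeded sample when too many exist
  n2 <- length(i2)
  n_avail <- choose(n, n2)
  exhaustive <- n_avail <= n_permutations
  if (exhaustive) {
    if (n_avail < n_permutations) {
      warning("only ", n_avail, " distinct label assignments exist; ",
              "using the exhaustive set instead of ", n_permutations,
              " permutations")
    }
    assign2 <- utils::combn(n, n2)
  } else {
    set.seed(seed)
    assign2 <- replicate(n_permutations, sample.int(n, n2))
  }
  B <- ncol(assign2)
  dstar <- matrix(0, nrow(x), B)
  for (b in seq_len(B)) {
    g2 <- assign2[, b]
    g1 <- setdiff(seq_len(n), g2)
    dstar[, b] <- sort(sam_d_stat(x, g1, g2, s0 = s0)$d)
  }
  ord <- order(d)
  dsort <- d[ord]
  dbar <- rowMeans(dstar)
  diff_i <- dsort - dbar

  fdr_at <- function(dl) {
    called <- abs(diff_i) > dl
    k <- sum(called)
    if (k == 0) return(list(fdr = 0, k = 0L))
    up <- called & dsort > 0
    down <- called & dsort <= 0
    cutup <- if (any(up)) min(dsort[up]) else Inf
    cutlow <- if (any(down)) max(dsort[down]) else -Inf
    false_b <- colSums(dstar >= cutup) + colSums(dstar <= cutlow)
    list(fdr = stats::median(false_b) / k, k = k)
  }
  if (is.null(delta)) {
    grid <- sort(unique(c(0, abs(diff_i))))
    delta <- grid[length(grid)]
    est <- list(fdr = 0, k = 0L)
    for (dl in grid) {
      cand <- fdr_at(dl)
      if (cand$fdr <= fdr_ceiling) {
        delta <- dl
        est <- cand
        break
      }
    }
  } else {
    est <- fdr_at(delta)
  }
  called_sorted <- abs(diff_i) > delta
  called <- logical(length(d))
  called[ord] <- called_sorted
  call <- rep("none", length(d))
  call[called & d > 0] <- "up"
  call[called & d <= 0] <- "down"

  # plain Welch t-test per gene, reported alongside the moderated statistic
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  se <- sqrt(v1 / length(i1) + v2 / length(i2))
  tw <- obs$r / se
  df <- se^4 / ((v1 / length(i1))^2 / (length(i1) - 1) +
                (v2 / length(i2))^2 / (length(i2) - 1))
  pw <- 2 * stats::pt(-abs(tw), df)

  genes <- data.frame(
    gene = rownames(x),
    d = d,
    dbar = dbar[match(seq_along(d), ord)],
    s = obs$s,
    mean_diff = obs$r,
    fold_change = 2^obs$r,
    t_welch = tw,
    p_welch = pw,
    call = call,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  structure(list(
    genes = genes,
    tuning = list(s0 = s0, s0_percentile = s0_percentile, delta = delta,
                  fdr = est$fdr, n_called = est$k, n_permutations = B,
                  exhaustive = exhaustive, fdr_ceiling = fdr_ceiling,
                  seed = seed)
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  tu <- x$tuning
  cat(sprintf(
    "SAM two-class (unpaired): %d genes, %d permutations%s\n",
    nrow(x$genes), tu$n_permutations,
    if (tu$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  s0 = %.4g, delta = %.4g, estimated FDR = %.4g\n",
              tu$s0, tu$delta, tu$fdr))
  cat(sprintf("  calls: %d up, %d down\n",
              sum(x$genes$call == "up"), sum(x$genes$call == "down")))
  invisible(x)
}

#' Significant up- and down-regulated gene lists from a SAM result
#' @param sam A `sam_result`.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
sam_calls <- function(sam) {
  stopifnot(inherits(sam, "sam_result"))
  list(up = sam$genes$gene[sam$genes$call == "up"],
       down = sam$genes$gene[sam$genes$call == "down"])
}

#' Hierarchically cluster significant genes
#'
#' Clusters genes and samples with correlation distance (`1 - Pearson r`)
#' and complete linkage. Rows are sorted by gene ID before clustering so leaf
#' ordering is deterministic; zero-variance profiles get correlation 0
#' (distance 1) against everything.
#'
#' @param x Expression matrix restricted to called genes (>= 2 rows).
#' @return List of class `sam_clustering`: `gene_hclust`, `sample_hclust`,
#'   `gene_order`, `sample_order`, and the reordered `matrix`; or `NULL`
#'   (with a message) when fewer than 2 genes are supplied.
#' @export
cluster_significant <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (nrow(x) < 2) {
    message("fewer than 2 significant genes; clustering skipped")
    return(NULL)
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  cor0 <- function(m) {
    cc <- suppressWarnings(stats::cor(m))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    cc
  }
  gd <- stats::as.dist(1 - cor0(t(x)))
  gh <- stats::hclust(gd, method = "complete")
  sh <- NULL
  sample_order <- seq_len(ncol(x))
  if (ncol(x) >= 2) {
    sd_ <- stats::as.dist(1 - cor0(x))
    sh <- stats::hclust(sd_, method = "complete")
    sample_order <- sh$order
  }
  structure(list(gene_hclust = gh, sample_hclust = sh,
                 gene_order = rownames(x)[gh$order],
                 sample_order = colnames(x)[sample_order],
                 matrix = x[gh$order, sample_order, drop = FALSE]),
            class = "sam_clustering")
}
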
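#' Estimate per-channel likelihood ratios from gold standards
#'
#' For every evidence channel and bin, the likelihood ratio is the smoothed
#' frequency of the bin among gold-standard positives divided by its smoothed
#' frequency among negatives:
#' \deqn{LR(bin) = \frac{(n^{+}_{bin} + c) / (N^{+} + cB)}{(n^{-}_{bin} + c) / (N^{-} + cB)}}
#' with pseudo-count `c` and `B` the number of bins in the channel. The
#' pseudo-count keeps empty bins at a finite positive ratio.
#'
#' @param profiles Evidence-profile data frame from [evidence_profiles()]
#'   covering both training sets (any `a`/`b` columns are ignored).
#' @param labels Logical (or `"pos"`/`"neg"`) vector: `TRUE` for gold-standard
#'   positive pairs, `FALSE` for negatives.
#' @param binning Binning configuration declaring the full bin set per
#'   channel; observed values must be a subset.
#' @param pseudo Additive pseudo-count per bin (default 1).
#' @return Object of class `likelihood_table`: per channel a data frame with
#'   `bin`, `n_pos`, `n_neg`, `p_pos`, `p_neg` (unsmoothed frequencies) and
#'   `lr`, plus the training-set sizes and pseudo-count used.
#' @export
estimate_lrs <- function(profiles, labels, binning = default_binning(),
                         pseudo = 1) {
  if (is.character(labels)) labels <- labels %in% c("pos", "positive", "TRUE")
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(profiles), pseudo >= 0)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both gold-standard classes must be represented in training profiles")
  }
  bins <- channel_bins(binning)
  chans <- intersect(names(bins), names(profiles))
  if (!length(chans)) stop("no declared evidence channels found in profiles")
  tables <- lapply(chans, function(ch) {
    lv <- bins[[ch]]
    if (length(lv) < 2) {
      warning("channel '", ch, "' has a single bin and is uninformative (LR = 1)")
    }
    x <- profiles[[ch]]
    bad <- setdiff(unique(x), lv)
    if (length(bad)) {
      stop("channel '", ch, "' contains undeclared bins: ",
           paste(bad, collapse = ", "))
    }
    f <- factor(x, levels = lv)
    np <- as.integer(table(f[labels]))
    nn <- as.integer(table(f[!labels]))
    B <- length(lv)
    data.frame(
      bin = lv,
      n_pos = np, n_neg = nn,
      p_pos = np / n_pos, p_neg = nn / n_neg,
      lr = ((np + pseudo) / (n_pos + pseudo * B)) /
           ((nn + pseudo) / (n_neg + pseudo * B)),
      stringsAsFactors = FALSE
    )
  })
  names(tables) <- chans
  structure(list(channels = tables, n_pos = n_pos, n_neg = n_neg,
                 pseudo = pseudo),
            class = "likelihood_table")
}

#' @export
print.likelihood_table <- function(x, ...) {
  cat("Likelihood table:", length(x$channels), "channels, trained on",
      x$n_pos, "positives /", x$n_neg, "negatives (pseudo-count ",
      x$pseudo, ")\n", sep = " ")
  for (ch in names(x$channels)) {
    tab <- x$channels[[ch]]
    cat("  ", ch, ": LR ",
        paste(sprintf("%s=%.3g", tab$bin, tab$lr), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Composite likelihood ratio under naive Bayes
#'
#' Multiplies the per-channel likelihood ratios of each profile's bins,
#' assuming the evidence channels are conditionally independent given the
#' interaction class. The absent bin contributes its own estimated ratio
#' (absence of evidence is evidence) unless `skip_absent` is set.
#'
#' @param profiles Evidence-profile data frame.
#' @param table A `likelihood_table` from [estimate_lrs()].
#' @param skip_absent If `TRUE`, channels sitting in their absent bin are
#'   skipped (contribute a factor of 1) instead of their estimated ratio.
#' @param absent_label Bin label treated as absent when skipping.
#' @return Numeric vector of composite likelihood ratios (> 0).
#' @export
composite_lr <- function(profiles, table, skip_absent = FALSE,
                         absent_label = "absent") {
  stopifnot(inherits(table, "likelihood_table"))
  chans <- names(table$channels)
  missing_ch <- setdiff(chans, names(profiles))
  if (length(missing_ch)) {
    stop("profiles lack channels present in the likelihood table: ",
         paste(missing_ch, collapse = ", "))
  }
  out <- rep(1, nrow(profiles))
  for (ch in chans) {
    tab <- table$channels[[ch]]
    lr <- tab$lr[match(profiles[[ch]], tab$bin)]
    if (anyNA(lr)) {
      stop("channel '", ch, "' contains bins unmapped in the likelihood table")
    }
    if (skip_absent) lr[profiles[[ch]] == absent_label] <- 1
    out <- out * lr
  }
  out
}

#' Score candidate pairs and filter on the composite likelihood ratio
#'
#' Computes composite likelihood ratios for candidate pairs, converts them to
#' posterior odds (`prior_odds * LR`), and flags the pairs at or above the
#' ratio cutoff as predicted interactions. The default cutoff of 20 is the
#' operating point used to assemble the predicted network; it is a
#' configuration default, not a derived constant.
#'
#' @param profiles Evidence-profile data frame for the candidate pairs.
#' @param table A `likelihood_table`.
#' @param lr_cutoff Positive ratio threshold (default 20, `>=` semantics).
#' @param prior_odds Prior odds of interaction (default 1 so posterior odds
#'   equal the composite ratio numerically).
#' @param skip_absent Passed to [composite_lr()].
#' @return Data frame: the input pairs/bins plus `composite_lr`,
#'   `posterior_odds` and logical `passed`; attribute `summary` holds
#'   passed/failed counts.
#' @export
predict_network <- function(profiles, table, lr_cutoff = 20, prior_odds = 1,
                            skip_absent = FALSE) {
  stopifnot(lr_cutoff > 0, prior_odds > 0)
  lr <- composite_lr(profiles, table, skip_absent = skip_absent)
  out <- profiles
  out$composite_lr <- lr
  out$posterior_odds <- prior_odds * lr
  out$passed <- lr >= lr_cutoff
  attr(out, "summary") <- c(n = nrow(out), passed = sum(out$passed),
                            failed = sum(!out$passed))
  out
}
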
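#' Default evidence-channel binning configuration
#'
#' Each channel is discretized into ordered, exhaustive, non-overlapping bins
#' plus an explicit missing/absent bin, so every pair receives a complete
#' evidence profile. Intervals are left-closed/right-open with the final bin
#' closed. Defaults: smallest-shared-process size in \{<=10, 11-50, 51-200,
#' >200, absent\}; Pearson rho in \{[-1,0.2), [0.2,0.5), [0.5,0.8), [0.8,1],
#' absent\}; domain-domain support and each model-organism interolog channel
#' are boolean (`"true"`/`"false"`). Each species is its own evidence channel.
#'
#' @param species Character vector of model-organism channel suffixes.
#' @return A named list describing each channel's bins.
#' @export
default_binning <- function(species = default_species()) {
  list(
    ssbp = list(type = "interval",
                breaks = c(1, 11, 51, 201, Inf),
                labels = c("<=10", "11-50", "51-200", ">200"),
                absent = "absent"),
    ddi = list(type = "flag"),
    coexpr = list(type = "interval",
                  breaks = c(-1, 0.2, 0.5, 0.8, 1),
                  labels = c("[-1,0.2)", "[0.2,0.5)", "[0.5,0.8)", "[0.8,1]"),
                  absent = "absent"),
    interolog = list(type = "flag", species = species)
  )
}

#' Model organisms used for interolog channels
#' @return Character vector of species codes.
#' @export
default_species <- function() {
  c("celegans", "dmelanogaster", "scerevisiae",
    "rnorvegicus", "mmusculus", "ecoli")
}

# Names of the per-pair evidence columns implied by a binning config.
channel_names <- function(binning) {
  c("ssbp", "ddi", "coexpr", paste0("interolog.", binning$interolog$species))
}

# Full ordered bin label set per channel (including the absent bin).
channel_bins <- function(binning) {
  flag_bins <- c("true", "false")
  out <- list(
    ssbp = c(binning$ssbp$labels, binning$ssbp$absent),
    ddi = flag_bins,
    coexpr = c(binning$coexpr$labels, binning$coexpr$absent)
  )
  for (sp in binning$interolog$species) {
    out[[paste0("interolog.", sp)]] <- flag_bins
  }
  out
}

#' Discretize raw evidence values into declared bins
#'
#' Intervals are left-closed/right-open except the final bin, which is closed
#' at its upper boundary; `NA` maps to the absent bin. Values outside the
#' declared domain are an error.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param breaks Ascending break points, length one more than `labels`.
#' @param labels Bin labels.
#' @param absent Label assigned to `NA` values.
#' @return Character vector of bin labels.
#' @export
discretize_values <- function(x, breaks, labels, absent = "absent") {
  stopifnot(length(breaks) == length(labels) + 1, !is.unsorted(breaks))
  out <- rep(absent, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    v <- x[ok]
    if (any(v < breaks[1] | v > breaks[length(breaks)])) {
      stop("value outside the declared bin domain [",
           breaks[1], ", ", breaks[length(breaks)], "]")
    }
    idx <- findInterval(v, breaks, rightmost.closed = TRUE)
    out[ok] <- labels[idx]
  }
  out
}

#' Smallest shared biological process (SSBP) size
#'
#' For each pair, scans all annotated biological processes containing both
#' proteins and returns the member count of the smallest one. Small, specific
#' shared processes indicate functional similarity and hence a higher chance
#' of physical interaction; `NA` means the pair shares no process.
#'
#' @param pairs Data frame of pairs (columns `a`, `b`).
#' @param go Named list: process ID -> character vector of member proteins.
#' @return Integer vector (one per pair); `NA` when no process is shared.
#' @export
ssbp_count <- function(pairs, go) {
  stopifnot(is.list(go), length(go) > 0)
  sizes <- lengths(go)
  members <- unlist(go, use.names = FALSE)
  proc_of <- split(rep(seq_along(go), sizes), members)
  n <- nrow(pairs)
  out <- rep(NA_integer_, n)
  pa <- proc_of[pairs$a]
  pb <- proc_of[pairs$b]
  for (i in seq_len(n)) {
    shared <- intersect(pa[[i]], pb[[i]])
    if (length(shared)) out[i] <- min(sizes[shared])
  }
  out
}

#' Domain-domain interaction (DDI) support
#'
#' A pair is supported when any domain of one protein and any domain of the
#' other form a known interacting domain pair. Homotypic domain contacts
#' (`d1 == d2`) count. Proteins without domain annotation yield `FALSE`.
#'
#' @param pairs Data frame of pairs (columns `a`, `b`).
#' @param domain_map Named list: protein -> character vector of domains.
#' @param ddi Data frame of interacting domain pairs (two columns, unordered).
#' @return Logical vector, one per pair.
#' @export
ddi_support <- function(pairs, domain_map, ddi) {
  ddi_keys <- if (nrow(ddi)) unique(pair_key(ddi[[1]], ddi[[2]])) else character()
  n <- nrow(pairs)
  out <- logical(n)
  da <- domain_map[pairs$a]
  db <- domain_map[pairs$b]
  for (i in seq_len(n)) {
    xa <- da[[i]]
    xb <- db[[i]]
    if (is.null(xa) || is.null(xb) || !length(xa) || !length(xb)) next
    keys <- pair_key(rep(xa, times = length(xb)), rep(xb, each = length(xa)))
    out[i] <- any(keys %in% ddi_keys)
  }
  out
}

#' Pairwise co-expression (Pearson correlation)
#'
#' Pearson correlation of the two genes' expression profiles across shared
#' samples. Expression values are expected on the log2 scale (see
#' [log2_normalize()]). Degenerate cases (gene unmeasured, fewer than
#' `min_samples` complete observations, zero-variance profile) return `NA`
#' rather than an error: absence of co-expression measurement is itself a
#' bin downstream.
#'
#' @param pairs Data frame of pairs (columns `a`, `b`).
#' @param expr Numeric matrix, genes in rows (rownames = gene IDs).
#' @param min_samples Minimum complete observations required (default 3).
#' @return Numeric vector of correlations in `[-1, 1]`, `NA` where undefined.
#' @export
coexpression <- function(pairs, expr, min_samples = 3) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- nrow(pairs)
  out <- rep(NA_real_, n)
  ia <- match(pairs$a, rownames(expr))
  ib <- match(pairs$b, rownames(expr))
  for (i in seq_len(n)) {
    if (is.na(ia[i]) || is.na(ib[i])) next
    x <- expr[ia[i], ]
    y <- expr[ib[i], ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_samples) next
    x <- x[ok]
    y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out[i] <- stats::cor(x, y)
  }
  out
}

#' Cross-species interolog flags
#'
#' For each model organism, a human pair is an interolog when both proteins
#' have an ortholog in that species and the ortholog pair is a known
#' interaction there. A missing ortholog yields `FALSE`.
#'
#' @param pairs Data frame of pairs (columns `a`, `b`).
#' @param ortholog_maps Named list (per species) of named character vectors
#'   mapping human protein -> ortholog identifier.
#' @param species_ppi Named list (per species) of two-column data frames of
#'   interacting ortholog pairs.
#' @return Data frame of logicals, one column per species.
#' @export
interolog_flags <- function(pairs, ortholog_maps, species_ppi) {
  stopifnot(identical(sort(names(ortholog_maps)), sort(names(species_ppi))))
  out <- lapply(names(ortholog_maps), function(sp) {
    map <- ortholog_maps[[sp]]
    oa <- unname(map[pairs$a])
    ob <- unname(map[pairs$b])
    ppi <- species_ppi[[sp]]
    keys <- if (!is.null(ppi) && nrow(ppi)) unique(pair_key(ppi[[1]], ppi[[2]])) else character()
    flag <- !is.na(oa) & !is.na(ob)
    flag[flag] <- pair_key(oa[flag], ob[flag]) %in% keys
    flag
  })
  names(out) <- names(ortholog_maps)
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

#' Compute full discretized evidence profiles for candidate pairs
#'
#' Runs every evidence channel (SSBP, DDI, co-expression, per-species
#' interologs) against the supplied resources and discretizes the results
#' under `binning`. Each channel is symmetric in the pair, and every pair
#' receives a defined bin in every channel (missing evidence maps to the
#' absent bin, which downstream still carries a likelihood ratio: absence is
#' evidence too).
#'
#' @param pairs Data frame of canonical pairs (columns `a`, `b`).
#' @param resources List with elements `go` (process -> members),
#'   `domain_map`, `ddi_table`, `ortholog_maps`, `species_ppi`, and either
#'   `pair_rho` (data frame `a`, `b`, `rho`: a precomputed co-expression
#'   resource, taking precedence) or `expr` (log2 expression matrix).
#' @param binning Binning configuration, see [default_binning()].
#' @return Data frame: `a`, `b`, then one bin-label column per channel.
#' @export
evidence_profiles <- function(pairs, resources, binning = default_binning()) {
  pairs <- canonical_pairs(pairs$a, pairs$b, dedupe = FALSE)
  ssbp_raw <- ssbp_count(pairs, resources$go)
  ddi_raw <- ddi_support(pairs, resources$domain_map, resources$ddi_table)
  if (!is.null(resources$pair_rho)) {
    pr <- resources$pair_rho
    rho <- pr$rho[match(pair_key(pairs$a, pairs$b), pair_key(pr$a, pr$b))]
  } else if (!is.null(resources$expr)) {
    rho <- coexpression(pairs, resources$expr)
  } else {
    rho <- rep(NA_real_, nrow(pairs))
  }
  flags <- interolog_flags(pairs, resources$ortholog_maps, resources$species_ppi)
  out <- data.frame(
    a = pairs$a, b = pairs$b,
    ssbp = discretize_values(as.numeric(ssbp_raw), binning$ssbp$breaks,
                             binning$ssbp$labels, binning$ssbp$absent),
    ddi = ifelse(ddi_raw, "true", "false"),
    coexpr = discretize_values(rho, binning$coexpr$breaks,
                               binning$coexpr$labels, binning$coexpr$absent),
    stringsAsFactors = FALSE
  )
  for (sp in binning$interolog$species) {
    out[[paste0("interolog.", sp)]] <- ifelse(flags[[sp]], "true", "false")
  }
  out
}
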
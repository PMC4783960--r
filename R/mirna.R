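#' Normalize miRNA identifiers
#'
#' Repairs spacing artifacts (e.g. `"hsa -miR-506"`), strips surrounding and
#' internal whitespace, and canonicalizes case to the conventional
#' `hsa-miR-...` form so identical miRNAs from different tools compare equal.
#'
#' @param x Character vector of miRNA identifiers.
#' @return Normalized character vector.
#' @examples
#' normalize_mirna_ids(c("hsa -miR-506", " HSA-MIR-96 "))
#' @export
normalize_mirna_ids <- function(x) {
  x <- gsub("\\s+", "", as.character(x))
  x <- tolower(x)
  sub("^(hsa-)?mir-", "\\1miR-", x)
}

# Accepts either a long data frame (tool, gene, mirna) or a named list of
# per-tool gene -> miRNA-set lists, and standardizes to the long form with
# normalized identifiers.
standardize_predictions <- function(predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("tool", "gene", "mirna") %in% names(predictions)))
    df <- predictions[, c("tool", "gene", "mirna")]
  } else {
    stopifnot(is.list(predictions), !is.null(names(predictions)))
    parts <- lapply(names(predictions), function(tool) {
      per_gene <- predictions[[tool]]
      data.frame(tool = tool,
                 gene = rep(names(per_gene), lengths(per_gene)),
                 mirna = unlist(per_gene, use.names = FALSE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
  }
  df$tool <- as.character(df$tool)
  df$gene <- as.character(df$gene)
  df$mirna <- normalize_mirna_ids(df$mirna)
  unique(df)
}

#' Consensus miRNA assignments across prediction tools
#'
#' Intersects per-tool miRNA target predictions per gene: by default a miRNA
#' must be predicted by every supplied tool to enter the consensus
#' (`min_tools` allows majority-style voting). Genes absent from a tool
#' contribute the empty set, so under the all-tools default they have an
#' empty consensus.
#'
#' @param predictions Per-tool predictions: a long data frame with columns
#'   `tool`, `gene`, `mirna`, or a named list of per-tool `gene -> miRNA`
#'   lists. At least two tools are required.
#' @param genes Optional gene list restricting (and ordering) the output;
#'   default all genes seen in any tool.
#' @param min_tools Minimum number of tools that must predict a miRNA
#'   (default: all supplied tools, i.e. strict intersection).
#' @return Object of class `consensus_table`: data frame with `gene`,
#'   `consensus` (semicolon-joined miRNA IDs), `n_consensus` and one
#'   `n_<tool>` hit-count column per tool.
#' @export
mirna_consensus <- function(predictions, genes = NULL, min_tools = NULL) {
  df <- standardize_predictions(predictions)
  tools <- sort(unique(df$tool))
  if (length(tools) < 2) {
    stop("at least two prediction tools are required for a consensus")
  }
  if (is.null(min_tools)) min_tools <- length(tools)
  stopifnot(min_tools >= 1, min_tools <= length(tools))
  if (is.null(genes)) genes <- sort(unique(df$gene))
  genes <- as.character(genes)
  rows <- lapply(genes, function(g) {
    sub <- df[df$gene == g, , drop = FALSE]
    counts <- vapply(tools, function(t) sum(sub$tool == t), integer(1))
    support <- table(unique(sub[, c("tool", "mirna")])$mirna)
    cons <- sort(names(support)[support >= min_tools])
    out <- data.frame(gene = g,
                      consensus = paste(cons, collapse = ";"),
                      n_consensus = length(cons),
                      stringsAsFactors = FALSE)
    for (t in tools) out[[paste0("n_", t)]] <- counts[[t]]
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "tools") <- tools
  attr(res, "min_tools") <- min_tools
  class(res) <- c("consensus_table", "data.frame")
  res
}

#' Split a consensus string back into a miRNA ID vector
#' @param consensus Semicolon-joined consensus string (one element).
#' @return Character vector (empty for an empty consensus).
#' @export
consensus_mirnas <- function(consensus) {
  if (is.na(consensus) || !nzchar(consensus)) return(character())
  strsplit(consensus, ";", fixed = TRUE)[[1]]
}

#' Annotate consensus genes with regulatory roles
#'
#' Joins oncogene / tumor-suppressor annotations onto a consensus table.
#' Genes missing from the role table are labeled `"none"`; conflicting
#' duplicate role rows are an error naming the offending genes.
#'
#' @param consensus A `consensus_table` from [mirna_consensus()].
#' @param gene_roles Data frame with columns `gene` and `role` (values
#'   `"oncogene"`, `"tumor_suppressor"` or `"none"`).
#' @return The consensus table with an added `role` column.
#' @export
annotate_regulation <- function(consensus, gene_roles) {
  stopifnot(all(c("gene", "role") %in% names(gene_roles)))
  gr <- unique(gene_roles[, c("gene", "role")])
  dup <- unique(gr$gene[duplicated(gr$gene)])
  if (length(dup)) {
    stop("conflicting role annotations for gene(s): ",
         paste(dup, collapse = ", "))
  }
  i <- match(consensus$gene, gr$gene)
  consensus$role <- ifelse(is.na(i), "none", as.character(gr$role)[i])
  consensus
}

#' Worked caspase-9 consensus example
#'
#' Builds synthetic stand-ins for the three tool hit lists of the caspase-9
#' (CASP9) worked example: 51 Diana-MicroT predictions, 14 miRanda
#' predictions and 156 TargetScan predictions that share exactly five
#' miRNAs (hsa-miR-124, -182, -504, -506 and -96). Decoy identifiers are
#' synthetic tokens unique to each tool; one shared entry carries a spacing
#' artifact to exercise identifier normalization.
#'
#' @return Long prediction data frame (`tool`, `gene`, `mirna`) suitable for
#'   [mirna_consensus()].
#' @export
casp9_example <- function() {
  shared <- c("hsa-miR-124", "hsa-miR-182", "hsa-miR-504",
              "hsa-miR-506", "hsa-miR-96")
  sizes <- c(dianamicrot = 51L, miranda = 14L, targetscan = 156L)
  parts <- lapply(names(sizes), function(tool) {
    n_decoy <- sizes[[tool]] - length(shared)
    decoys <- sprintf("hsa-miR-%s%03d", substr(tool, 1, 1), seq_len(n_decoy))
    hits <- c(shared, decoys)
    data.frame(tool = tool, gene = "CASP9", mirna = hits,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  # reproduce a typographic spacing artifact seen in published tables
  df$mirna[df$tool == "miranda" & df$mirna == "hsa-miR-506"] <- "hsa -miR-506"
  df
}
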
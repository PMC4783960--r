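# Plain-text serialization of a synthetic world: TSV pair lists, GMT-style
# annotation sets, expression/probe tables, ortholog tables, miRNA hit
# lists, and a JSON truth manifest. All files are tab-delimited UTF-8.

write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  for (j in which(num)) d[[j]] <- sprintf("%.10g", d[[j]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, numeric_cols = character()) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         colClasses = "character", quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (j in intersect(numeric_cols, names(d))) d[[j]] <- as.numeric(d[[j]])
  d
}

write_matrix_tsv <- function(m, path, id_col = "gene") {
  d <- data.frame(rownames(m), stringsAsFactors = FALSE)
  names(d) <- id_col
  for (j in seq_len(ncol(m))) d[[colnames(m)[j]]] <- sprintf("%.10g", m[, j])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path, id_col = "gene") {
  d <- read_tsv(path)
  m <- as.matrix(d[, setdiff(names(d), id_col), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[id_col]]
  m
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, "synthetic process", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits TSV pair lists per source database, a sampled gold-negative pair
#' list, compartment membership lists, GMT-style process annotations, domain
#' and domain-interaction tables, ortholog and model-organism interaction
#' tables, the per-pair co-expression table, gene- and probe-level
#' expression matrices (header `sample:condition`), miRNA hit lists, gene
#' roles, the apoptotic seed list, the per-pair evidence-bin table and a
#' JSON truth manifest. The files round-trip through [read_world()].
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a manifest data frame (`file`, `md5`, `bytes`).
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  p <- function(f) file.path(dir, f)
  for (s in names(world$interaction_sources)) {
    src <- world$interaction_sources[[s]]
    src$source <- s
    write_tsv(src, p(sprintf("pairs_%s.tsv", s)))
  }
  write_tsv(world$negative_pairs, p("gsn_sample.tsv"))
  writeLines(world$membrane_set, p("membrane.txt"))
  writeLines(world$nuclear_set, p("nuclear.txt"))
  write_gmt(world$go, p("go_annotations.gmt"))
  dm <- data.frame(protein = rep(names(world$domain_map),
                                 lengths(world$domain_map)),
                   domain = unlist(world$domain_map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv(dm, p("domains.tsv"))
  write_tsv(world$ddi_table, p("ddi.tsv"))
  write_tsv(world$pair_rho, p("pair_rho.tsv"))
  orth <- do.call(rbind, lapply(names(world$ortholog_maps), function(sp) {
    m <- world$ortholog_maps[[sp]]
    data.frame(species = sp, human_id = names(m), ortholog_id = unname(m),
               stringsAsFactors = FALSE)
  }))
  write_tsv(orth, p("orthologs.tsv"))
  sppi <- do.call(rbind, lapply(names(world$species_ppi), function(sp) {
    d <- world$species_ppi[[sp]]
    data.frame(species = sp, a = d[[1]], b = d[[2]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(sppi, p("species_ppi.tsv"))
  em <- world$expression
  colnames(em) <- paste(colnames(em), world$condition, sep = ":")
  write_matrix_tsv(em, p("expression.tsv"))
  pm <- world$probe_matrix
  colnames(pm) <- colnames(em)
  pd <- data.frame(probe = rownames(pm), gene = world$probe_gene,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pm))) pd[[colnames(pm)[j]]] <- sprintf("%.10g", pm[, j])
  utils::write.table(pd, p("probes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv(world$mirna_predictions, p("mirna.tsv"))
  write_tsv(world$gene_roles, p("gene_roles.tsv"))
  writeLines(world$apoptotic, p("apoptotic.txt"))
  write_tsv(world$aliases, p("aliases.tsv"))
  write_tsv(world$evidence, p("evidence.tsv"))
  truth <- list(
    channels = world$truth$channels,
    spiked = world$truth$spiked,
    consensus = world$truth$consensus,
    seed = world$config$seed
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- sort(list.files(dir))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    bytes = file.size(file.path(dir, files)),
    stringsAsFactors = FALSE
  )
  invisible(manifest)
}

#' Read a synthetic world back from a directory
#'
#' Inverse of [write_world()]; reconstructs the resource structures, the
#' evidence-bin table and the truth manifest.
#'
#' @param dir Directory written by [write_world()].
#' @return A list with the same resource components as a `synthetic_world`
#'   (without the generator configuration).
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  src_files <- list.files(dir, pattern = "^pairs_.*\\.tsv$")
  interaction_sources <- lapply(src_files, function(f) {
    d <- read_tsv(p(f))
    d[, c("protein_a", "protein_b"), drop = FALSE]
  })
  names(interaction_sources) <- sub("^pairs_(.*)\\.tsv$", "\\1", src_files)
  dm <- read_tsv(p("domains.tsv"))
  domain_map <- split(dm$domain, dm$protein)
  orth <- read_tsv(p("orthologs.tsv"))
  ortholog_maps <- lapply(split(orth, orth$species), function(d) {
    stats::setNames(d$ortholog_id, d$human_id)
  })
  sppi <- read_tsv(p("species_ppi.tsv"))
  species_ppi <- lapply(split(sppi, sppi$species), function(d) {
    data.frame(a = d$a, b = d$b, stringsAsFactors = FALSE)
  })
  em <- read_matrix_tsv(p("expression.tsv"))
  condition <- sub("^.*:", "", colnames(em))
  colnames(em) <- sub(":.*$", "", colnames(em))
  pd <- read_tsv(p("probes.tsv"))
  val_cols <- setdiff(names(pd), c("probe", "gene"))
  pm <- as.matrix(pd[, val_cols, drop = FALSE])
  storage.mode(pm) <- "double"
  rownames(pm) <- pd$probe
  colnames(pm) <- sub(":.*$", "", val_cols)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$consensus <- lapply(truth$consensus, unlist)
  evidence <- read_tsv(p("evidence.tsv"))
  evidence$label <- evidence$label == "TRUE"
  list(
    interaction_sources = interaction_sources,
    aliases = read_tsv(p("aliases.tsv")),
    negative_pairs = read_tsv(p("gsn_sample.tsv")),
    membrane_set = readLines(p("membrane.txt")),
    nuclear_set = readLines(p("nuclear.txt")),
    go = read_gmt(p("go_annotations.gmt")),
    domain_map = domain_map,
    ddi_table = read_tsv(p("ddi.tsv")),
    pair_rho = read_tsv(p("pair_rho.tsv"), numeric_cols = "rho"),
    ortholog_maps = ortholog_maps,
    species_ppi = species_ppi,
    expression = em,
    condition = condition,
    probe_matrix = pm,
    probe_gene = pd$gene,
    apoptotic = readLines(p("apoptotic.txt")),
    gene_roles = read_tsv(p("gene_roles.tsv")),
    mirna_predictions = read_tsv(p("mirna.tsv")),
    evidence = evidence,
    truth = truth
  )
}
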
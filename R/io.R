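#' Static gene-symbol alias map
#'
#' Minimal alias table applied at load time to harmonize legacy symbols onto
#' current nomenclature (e.g. PRAS40 -> AKT1S1, FRAP1 -> MTOR). Live registry
#' lookups are deliberately out of scope; extend via the `extra` argument of
#' [harmonize_symbols()].
#' @format Named character vector: `names` are aliases, values the preferred
#'   symbols.
#' @export
gene_aliases <- c(
  PRAS40 = "AKT1S1", FRAP1 = "MTOR", RAFT1 = "MTOR", P70S6K = "RPS6KB1",
  S6K1 = "RPS6KB1", `4EBP1` = "EIF4EBP1", `4E-BP1` = "EIF4EBP1",
  GBL = "MLST8", KIAA1303 = "RPTOR", MIP1 = "RICTOR", MMAC1 = "PTEN",
  PI3K = "PIK3CA", AMPK = "PRKAA1"
)

#' Harmonize gene symbols against the static alias map
#'
#' @param x Character vector of symbols.
#' @param extra Optional named character vector of additional aliases.
#' @return Character vector with aliases replaced by preferred symbols.
#' @export
harmonize_symbols <- function(x, extra = NULL) {
  map <- c(gene_aliases, extra)
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a minimal MAF-like mutation table
#'
#' One row per mutated sample x gene cell with columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, `Cohort`.
#' @param alterations A [cohort_alterations()].
#' @param path Output file.
#' @export
write_maf <- function(alterations, path) {
  idx <- which(alterations$mutation, arr.ind = TRUE)
  df <- data.frame(
    Hugo_Symbol = alterations$genes[idx[, 2]],
    Tumor_Sample_Barcode = alterations$samples[idx[, 1]],
    Variant_Classification = "Missense_Mutation",
    Cohort = unname(alterations$cohort[idx[, 1]]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$Hugo_Symbol, df$Tumor_Sample_Barcode), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a minimal MAF-like mutation table
#' @param path MAF-like TSV with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode` and `Variant_Classification` columns.
#' @param harmonize Apply [harmonize_symbols()] to gene symbols.
#' @return Data frame of variant calls.
#' @export
read_maf <- function(path, harmonize = TRUE) {
  df <- read_tsv(path)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(need %in% names(df))) {
    stop("MAF input must contain columns: ", paste(need, collapse = ", "))
  }
  if (harmonize) df$Hugo_Symbol <- harmonize_symbols(df$Hugo_Symbol)
  df
}

#' Write a GISTIC-style thresholded copy-number matrix
#' @param alterations A [cohort_alterations()].
#' @param path Output TSV: first column `Gene`, one column per sample.
#' @export
write_gistic <- function(alterations, path) {
  m <- t(alterations$cna)
  df <- data.frame(Gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a GISTIC-style thresholded copy-number matrix
#' @param path TSV written by [write_gistic()] or equivalent.
#' @param harmonize Apply [harmonize_symbols()] to gene symbols.
#' @return Integer genes x samples matrix.
#' @export
read_gistic <- function(path, harmonize = TRUE) {
  df <- read_tsv(path)
  genes <- df[[1]]
  if (harmonize) genes <- harmonize_symbols(genes)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write / read a sample-to-cohort map
#' @param alterations A [cohort_alterations()].
#' @param path TSV with columns `Sample`, `Cohort`.
#' @export
write_cohort_map <- function(alterations, path) {
  write_tsv(data.frame(Sample = alterations$samples,
                       Cohort = unname(alterations$cohort),
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_cohort_map
#' @export
read_cohort_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("Sample", "Cohort") %in% names(df))) {
    stop("cohort map must contain columns Sample, Cohort")
  }
  stats::setNames(as.character(df$Cohort), df$Sample)
}

#' Assemble a cohort alteration table from MAF + GISTIC + cohort map files
#'
#' The evaluable sample universe is the cohort map; genes present in the MAF
#' but absent from the copy-number matrix get `NA` copy-number calls (logged
#' as a message).
#'
#' @param maf_path,gistic_path,cohort_map_path Paths to the three inputs.
#' @return A [cohort_alterations()].
#' @export
read_alterations <- function(maf_path, gistic_path, cohort_map_path) {
  maf <- read_maf(maf_path)
  cna <- read_gistic(gistic_path)
  cohort <- read_cohort_map(cohort_map_path)
  samples <- names(cohort)
  unknown <- setdiff(maf$Tumor_Sample_Barcode, samples)
  if (length(unknown)) {
    stop("MAF samples missing from the cohort map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  genes <- union(rownames(cna), unique(maf$Hugo_Symbol))
  mut <- matrix(FALSE, length(samples), length(genes),
                dimnames = list(samples, genes))
  mut[cbind(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol)] <- TRUE
  cna_full <- matrix(NA_integer_, length(samples), length(genes),
                     dimnames = list(samples, genes))
  shared <- intersect(genes, rownames(cna))
  shared_s <- intersect(samples, colnames(cna))
  cna_full[shared_s, shared] <- t(cna[shared, shared_s, drop = FALSE])
  missing_cna <- setdiff(genes, rownames(cna))
  if (length(missing_cna)) {
    message("genes without copy-number calls (NA): ",
            paste(missing_cna, collapse = ", "))
  }
  cohort_alterations(mut, cna_full, unname(cohort[samples]))
}

#' Write / read an expression matrix
#' @param expression Genes x samples numeric matrix.
#' @param path TSV: first column `Gene`, one column per sample.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(Gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read GMT module definitions
#' @param modules Named list of character vectors.
#' @param path GMT file (name, description, tab-separated members).
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(names(modules), function(nm) {
    paste(c(nm, "mtorwalk_module", modules[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param harmonize Apply [harmonize_symbols()] to member genes.
#' @export
read_gmt <- function(path, harmonize = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    if (harmonize) genes <- harmonize_symbols(genes)
    unique(genes)
  })
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

#' Write a STRING-style weighted edge list
#'
#' Scores are written on the conventional 0-1000 integer scale.
#' @param graph An `igraph` with per-channel edge attributes and
#'   `combined_score` in `[0, 1]`.
#' @param path Output TSV.
#' @export
write_string_edges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(
    protein1 = el[, 1], protein2 = el[, 2],
    textmining = round(1000 * igraph::E(graph)$textmining),
    experimental = round(1000 * igraph::E(graph)$experimental),
    database = round(1000 * igraph::E(graph)$database),
    coexpression = round(1000 * igraph::E(graph)$coexpression),
    combined_score = round(1000 * igraph::E(graph)$combined_score),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a STRING-style weighted edge list
#' @param path TSV with columns `protein1`, `protein2`, channel scores and
#'   `combined_score` (0-1000 integers or 0-1 floats; auto-detected).
#' @param harmonize Apply [harmonize_symbols()] to node symbols.
#' @return Data frame with scores rescaled to `[0, 1]`.
#' @export
read_string_edges <- function(path, harmonize = TRUE) {
  df <- read_tsv(path)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) {
    stop("STRING-style input must contain columns: ",
         paste(need, collapse = ", "),
         " (plus per-channel score columns)")
  }
  if (harmonize) {
    df$protein1 <- harmonize_symbols(df$protein1)
    df$protein2 <- harmonize_symbols(df$protein2)
  }
  score_cols <- setdiff(names(df), c("protein1", "protein2"))
  if (max(unlist(df[score_cols]), na.rm = TRUE) > 1) {
    df[score_cols] <- lapply(df[score_cols], function(x) x / 1000)
  }
  df
}

#' Write ground truth and metadata as JSON
#' @param x A list (ground truth, run metadata, ...).
#' @param path Output JSON file.
#' @export
write_json_meta <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write all synthetic fixtures for one configuration
#'
#' Emits the MAF, GISTIC, cohort-map, expression, GMT, STRING-edge and
#' ground-truth files into `dir`, regenerating everything from the
#' configuration's seed. Byte-identical across reruns for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_synthetic_fixtures <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_alteration_cohorts(config)
  ex <- simulate_expression(sim$alterations, config)
  paths <- c(
    maf = file.path(dir, "mutations.maf.tsv"),
    gistic = file.path(dir, "cna_thresholded.tsv"),
    cohorts = file.path(dir, "cohort_map.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gmt = file.path(dir, "modules.gmt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_maf(sim$alterations, paths["maf"])
  write_gistic(sim$alterations, paths["gistic"])
  write_cohort_map(sim$alterations, paths["cohorts"])
  write_expression(round(ex$expression, 6), paths["expression"])
  write_gmt(config$modules, paths["gmt"])
  truth <- sim$ground_truth
  if (!is.null(config$network)) {
    net <- simulate_interaction_network(config)
    paths["string"] <- file.path(dir, "string_edges.tsv")
    paths["nodes"] <- file.path(dir, "node_table.tsv")
    write_string_edges(net$graph, paths["string"])
    write_tsv(net$node_table, paths["nodes"])
    truth <- c(truth, net$ground_truth)
  }
  write_json_meta(truth, paths["truth"])
  invisible(paths)
}
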
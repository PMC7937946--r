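# Readers and writers for the external formats the pipeline touches:
# counts (TSV, genes in rows), sample metadata (TSV), gene sets (GMT),
# plain one-id-per-line gene lists, and the packaged clinical fixtures.

#' Construct a validated count matrix
#'
#' The root input of the pipeline: a genes-by-samples matrix of non-negative
#' integer read counts with unique gene rownames and sample colnames.
#'
#' @param counts A numeric matrix with gene ids as rownames and sample ids as
#'   colnames. All cells must be non-negative integers.
#' @return The validated integer matrix (invisibly classed `endo_counts`).
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`counts` must carry gene rownames and sample colnames.")
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("Duplicate gene identifiers: ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
          class = "endoseq_identifier_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample identifiers: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
          class = "endoseq_identifier_error")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("A count matrix needs at least 2 genes and 2 samples.",
          class = "endoseq_format_error")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-integer, negative or missing count at gene '%s', sample '%s'.",
      gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
      class = "endoseq_format_error")
  }
  storage.mode(counts) <- "double"  # doubles hold counts exactly; avoids int overflow on sums
  class(counts) <- c("endo_counts", class(counts))
  counts
}

#' Read a gene-by-sample count table
#'
#' Reads a tab-separated count table with gene ids in the first column and one
#' column per sample (genes-in-rows dialect only).
#'
#' @param path Path to a TSV file.
#' @return A validated count matrix (see [count_matrix()]).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) abort("Count TSV needs a gene id column plus >= 2 samples.",
                          class = "endoseq_format_error")
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    abort("Count TSV contains non-numeric cells.", class = "endoseq_format_error")
  }
  rownames(m) <- gene_ids
  count_matrix(m)
}

#' Write a count table
#'
#' Inverse of [read_counts()]; writing then reading reproduces the matrix.
#'
#' @param counts A count matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `name`, `description` and list-column `genes`,
#'   classed `endo_gsc`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1]),
          class = "endoseq_format_error")
  }
  sets <- purrr::map(parts, function(p) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("Gene set '%s' contains duplicated gene ids; deduplicated.", p[1]))
      genes <- unique(genes)
    }
    tibble(name = p[1], description = p[2], genes = list(genes))
  })
  out <- bind_rows(sets)
  if (anyDuplicated(out$name)) {
    abort("Duplicate gene-set names in GMT file.", class = "endoseq_identifier_error")
  }
  if (any(lengths(out$genes) == 0)) {
    abort("Empty gene set in GMT file.", class = "endoseq_format_error")
  }
  class(out) <- c("endo_gsc", class(out))
  out
}

#' Write a GMT gene-set collection
#'
#' @param gsc A gene-set collection tibble as returned by [read_gmt()] or
#'   [gene_set_collection()].
#' @param path Output GMT path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- purrr::pmap_chr(list(gsc$name, gsc$description, gsc$genes),
                           function(n, d, g) paste(c(n, d, g), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene-set collection from named lists
#'
#' @param sets A named list of character vectors of gene ids.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A gene-set collection tibble, classed `endo_gsc`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.", class = "endoseq_identifier_error")
  }
  if (any(lengths(sets) == 0)) abort("Gene sets must be non-empty.")
  out <- tibble(
    name = names(sets),
    description = descriptions %||% rep("", length(sets)),
    genes = purrr::map(unname(sets), unique)
  )
  class(out) <- c("endo_gsc", class(out))
  out
}

#' Read a sample metadata table
#'
#' TSV with at least a `sample_id` column; typically also `batch`, `cohort`,
#' `sex`, `timepoint` and optionally `group`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("Sample table must have a `sample_id` column.", class = "endoseq_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("Duplicate sample_id in sample table.", class = "endoseq_identifier_error")
  }
  df
}

#' Read a one-id-per-line gene list
#'
#' @param path Path to a plain text file, one gene id per line.
#' @return A character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

# Frozen digests of the packaged clinical fixtures; transcription cannot
# silently drift without a test noticing.
.fixture_digests <- c(
  pediatric_cohort1 = "7c84087d7d98941983a8fa126c10a03c",
  adult = "bd294577d0ee53e8930f704b21bb7310"
)

.fixture_files <- c(
  pediatric_cohort1 = "clinical_pediatric_cohort1.tsv",
  adult = "clinical_adult.tsv"
)

#' Load a packaged clinical table
#'
#' The package ships the clinical characteristics of the discovery pediatric
#' vasculitis cohort (30 patients) and of the adult cohort (11 patients):
#' endotype, clinical classification, ANCA status, timepoint, sex, organ-system
#' involvement and vasculitis activity score (PVAS for children, BVAS for
#' adults). File contents are checked against a frozen digest.
#'
#' @param cohort `"pediatric_cohort1"` or `"adult"`.
#' @return A tibble with one row per patient, classed `endo_clinical`.
#' @export
load_clinical_fixture <- function(cohort = c("pediatric_cohort1", "adult")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", .fixture_files[[cohort]], package = "endoseq")
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("Packaged clinical fixture '%s' is missing.", cohort),
          class = "endoseq_packaging_error")
  }
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  if (!identical(unname(hash(txt)), unname(.fixture_digests[[cohort]]))) {
    abort(sprintf("Clinical fixture '%s' does not match its frozen digest.", cohort),
          class = "endoseq_packaging_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          activity_score = readr::col_integer(),
                          .default = readr::col_character()))
  stopifnot(!anyDuplicated(df$patient_id), all(df$activity_score >= 0),
            all(df$endotype %in% c("A", "B", "other")))
  class(df) <- c("endo_clinical", class(df))
  df
}

#' Default globin gene symbols
#'
#' Hemoglobin gene symbols removed bioinformatically before normalization of
#' whole-blood RNA-seq; configurable because the removed set is
#' protocol-dependent.
#'
#' @return A character vector of gene symbols.
#' @export
default_globin_genes <- function() {
  read_gene_list(system.file("extdata", "globin_genes.txt", package = "endoseq"))
}

#' Default neutrophil-degranulation anchor genes
#'
#' Marker genes of neutrophil activation/degranulation (S100A8, S100A9, ...)
#' used to orient endotype labels: the major cluster with higher mean
#' variance-stabilized expression of these genes is called endotype A.
#'
#' @return A character vector of gene symbols.
#' @export
default_anchor_genes <- function() {
  read_gene_list(system.file("extdata", "neutrophil_anchor_genes.txt",
                             package = "endoseq"))
}
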
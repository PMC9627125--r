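#' Read a gene model table
#'
#' Loads a tab-separated gene model with one row per gene. Coordinates are
#' stored 0-based half-open (BED convention) internally; set `one_based =
#' TRUE` for 1-based inclusive input dialects (GTF-style), in which case
#' `start` is shifted down by one at the boundary. The strand-aware
#' transcription start site (TSS) and the genomic span length are derived.
#'
#' @param path path to a TSV with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` and optionally `biotype`.
#' @param one_based logical; input coordinates are 1-based inclusive.
#' @return a `data.frame` of class `gene_model` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `tss`, `length`.
#' @export
read_gene_model <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_gene_model(df, one_based = one_based)
}

#' Construct a validated gene model from a data frame
#'
#' @param df data frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   and optionally `biotype` and `tss`.
#' @inheritParams read_gene_model
#' @return a `gene_model` data frame (see [read_gene_model()]).
#' @export
as_gene_model <- function(df, one_based = FALSE) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_format("gene model is missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (one_based) df$start <- df$start - 1
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L) {
    stop_format("gene model row %d: start >= end (gene %s)", bad[1L],
                df$gene_id[bad[1L]])
  }
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1L]
    stop_format("duplicated gene_id in gene model: %s", dup)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop_format("strand must be '+' or '-'")
  }
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$length <- df$end - df$start
  rownames(df) <- df$gene_id
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read a gene-by-sample numeric matrix from TSV
#'
#' First column holds gene identifiers, remaining header fields are sample
#' identifiers. Cells are numeric; `NA` marks missing values and is kept as
#' missing, never coerced to zero. Any non-numeric cell is a format error
#' reporting its coordinates.
#'
#' @param path path to TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_format("matrix file '%s' has no data", path)
  }
  genes <- df[[1L]]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                dimnames = list(genes, names(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & !(cell %in% c("NA", "")))
    if (length(bad) > 0L) {
      stop_format("non-numeric cell at row %d, column '%s': '%s'",
                  bad[1L], names(df)[j + 1L], cell[bad[1L]])
    }
    mat[, j] <- num
  }
  mat
}

#' Write a gene-by-sample matrix as TSV
#'
#' Paired writer for [read_matrix()]; `read_matrix(write_matrix(x))` returns
#' an object equal to `x`.
#'
#' @param mat numeric matrix with rownames (genes) and colnames (samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cfDNA variant table
#'
#' @param path TSV with at least `chrom`, `pos`, `ref`, `alt`,
#'   `unique_read_support`, `vaf`; further filter columns
#'   (`mapq_mean`, `background_error`, `germline_vaf`, `leukocyte_depth`,
#'   `gene`, `copy_log_ratio`, `consequence`, `population_freq`) as needed by
#'   the downstream filters.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "unique_read_support", "vaf")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_format("variant table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (!is_fraction(df$vaf)) stop_format("vaf must be in [0, 1]")
  if (any(df$unique_read_support < 0)) stop_format("read counts must be nonnegative")
  df
}

#' Write a variant table as TSV
#' @param df variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_format("malformed GMT line: '%s'", l)
    unique(parts[-c(1L, 2L)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], "")
  sets
}

#' Read a tissue reference 5hmC panel
#'
#' @param path TSV, first column gene id, remaining columns one per tissue.
#' @return gene-by-tissue numeric matrix.
#' @export
read_tissue_panel <- function(path) {
  panel <- read_matrix(path)
  if (ncol(panel) < 2L) stop_format("tissue panel needs at least 2 tissues")
  if (any(panel < 0, na.rm = TRUE)) stop_format("tissue panel must be nonnegative")
  panel
}
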
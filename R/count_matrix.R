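#' Count matrix with attached sample metadata
#'
#' The basic container of the pipeline: an integer gene x sample count
#' matrix plus one metadata row per sample (population, garden,
#' acclimation days, tissue, batch).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design Data frame with a `sample` column matching the matrix
#'   columns; typically from [make_design()].
#' @return An object of class `count_matrix` (a list with elements
#'   `counts` and `design`).
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  design <- as.data.frame(design)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (!"sample" %in% names(design)) stop("design needs a 'sample' column")
  if (!identical(colnames(counts), as.character(design$sample)))
    stop("design rows must match count columns (same ids, same order)")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$design$population, x$design$garden)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x A [count_matrix()].
#' @param genes Gene ids or logical/integer index (default: all).
#' @param samples Sample ids or logical/integer index (default: all).
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  counts <- x$counts
  design <- x$design
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  }
  count_matrix(counts, design)
}

#' Read and write pipeline tables
#'
#' TSV round-trip helpers: counts are written gene x sample with a
#' `gene` id column first; metadata and result tables are plain TSVs
#' with a header row.
#'
#' @param path File path.
#' @param counts_path,design_path Paths of the count and metadata TSVs.
#' @return `read_counts()` returns a [count_matrix()]; `read_table()` a
#'   data frame; the writers return the path invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @param x Object to write.
#' @export
write_counts <- function(x, counts_path, design_path) {
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname pipeline_io
#' @export
read_counts <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  design <- utils::read.delim(design_path)
  count_matrix(counts, design)
}

#' @rdname pipeline_io
#' @export
read_table <- function(path) utils::read.delim(path)

#' @rdname pipeline_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-style annotation files
#'
#' Each line: term id, description, then member gene ids, tab
#' separated.
#'
#' @param path Path of the GMT file.
#' @return Named list term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  out
}
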
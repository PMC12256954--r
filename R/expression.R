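#' Expression matrix container
#'
#' A light S3 wrapper around a dense cells x genes matrix with a processing
#' stage tag. The canonical stored orientation is always cells in rows and
#' genes in columns; the gene-centred (nodes x cells) view used by the gene
#' encoder is exposed explicitly through [build_hypergraph()].
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids,gene_ids Unique identifiers; default taken from dimnames.
#' @param stage One of `"raw"`, `"filtered"`, `"normalized"`.
#' @return An object of class `hg_expr` with elements `values`, `cell_ids`,
#'   `gene_ids`, `stage`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values), stage = "raw") {
  stage <- match.arg(stage, c("raw", "filtered", "normalized"))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x genes)")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (any(!is.finite(values))) stop("expression values contain NA/NaN/Inf")
  if (stage != "normalized" && any(values < 0)) {
    stop("raw/filtered expression values must be non-negative")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 stage = stage),
            class = "hg_expr")
}

#' @export
print.hg_expr <- function(x, ...) {
  cat(sprintf("<hg_expr> %d cells x %d genes, stage = %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.hg_expr <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV layout: first row holds gene identifiers, first column holds
#' cell identifiers. Sparse layout (`format = "mtx"`): a Matrix Market
#' coordinate file with companion `cells.txt` (row ids) and `genes.txt`
#' (column ids) in the same directory, one identifier per line.
#'
#' @param path File path (for `mtx`, the `.mtx` file).
#' @param format `"csv"`, `"tsv"` or `"mtx"`. Default guessed from extension.
#' @return An `hg_expr` at stage `"raw"`.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dirn <- dirname(path)
    cf <- file.path(dirn, "cells.txt"); gf <- file.path(dirn, "genes.txt")
    if (!file.exists(cf) || !file.exists(gf)) {
      stop("mtx input requires companion cells.txt and genes.txt next to ", path)
    }
    cells <- readLines(cf); genes <- readLines(gf)
    if (length(cells) != nrow(m) || length(genes) != ncol(m)) {
      stop(sprintf(paste0("mtx dimensions (%d x %d) do not match cells.txt (%d) ",
                          "and genes.txt (%d); orientation must be cells x genes"),
                   nrow(m), ncol(m), length(cells), length(genes)))
    }
    return(expression_matrix(m, cells, genes, stage = "raw"))
  }
  sep <- if (format == "csv") "," else "\t"
  first <- readLines(path, n = 1L)
  lead <- strsplit(first, sep, fixed = TRUE)[[1L]][1L]
  if (nzchar(lead) && !is.na(suppressWarnings(as.numeric(lead)))) {
    stop("cannot determine orientation: the header corner of ", path,
         " is numeric; expected gene ids in the first row and cell ids in ",
         "the first column")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (anyNA(m)) stop("missing (NA) entries in ", path)
  expression_matrix(m, rownames(m), colnames(m), stage = "raw")
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; identifiers round-trip verbatim.
#'
#' @param x An `hg_expr`.
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "hg_expr"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(x$cell_ids, file.path(dirname(path), "cells.txt"))
    writeLines(x$gene_ids, file.path(dirname(path), "genes.txt"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(id = x$cell_ids, x$values, check.names = FALSE)
  names(df)[1L] <- ""
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor list (one symbol per line)
#' @param path File path.
#' @return Character vector of TF symbols.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
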
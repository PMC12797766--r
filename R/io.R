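# Shared readers/writers. All text readers are gzip-transparent (base R
# file connections auto-detect gzip on read); writers gzip when the path
# ends in .gz.

open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("FASTQ record count not a multiple of 4: ", path, call. = FALSE)
  }
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  data.frame(read_id = ids,
             seq  = lines[seq(2, length(lines), 4)],
             qual = lines[seq(4, length(lines), 4)],
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- open_write(path)
  on.exit(close(con))
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Read a barcode whitelist
#'
#' Plain text, one uppercase barcode per line (10X whitelist dialect);
#' gzip accepted. Barcodes containing N are rejected.
#'
#' @param path whitelist path.
#' @param barcode_len expected barcode length; `NULL` skips the check.
#' @return character vector of barcodes.
#' @export
read_whitelist <- function(path, barcode_len = 16) {
  bc <- toupper(trimws(readLines(path)))
  bc <- bc[nzchar(bc)]
  if (length(bc) == 0) stop("empty whitelist: ", path, call. = FALSE)
  assert_dna(bc, "whitelist barcode", allow_n = FALSE)
  if (!is.null(barcode_len) && any(nchar(bc) != barcode_len)) {
    stop(sprintf("whitelist entries must all be %d nt", barcode_len),
         call. = FALSE)
  }
  bc
}

#' Write/read simple TSV tables
#'
#' Thin wrappers fixing the dialect used throughout (tab-separated, header,
#' no quoting, no row names).
#'
#' @param x data.frame to write.
#' @param path file path (gzip-transparent on read; gzipped on write for
#'   `.gz` paths).
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(x, path) {
  con <- open_write(path)
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Count-matrix I/O (MatrixMarket and dense TSV)
#'
#' `write_count_matrix()` writes a Cell Ranger-style triplet directory
#' (`matrix.mtx`, `features.tsv`, `barcodes.tsv`, uncompressed);
#' `read_count_matrix()` reads either such a directory or a dense TSV
#' (genes in rows, cells in columns, first column = gene id).
#'
#' @param mat integer matrix, genes x cells, with dimnames.
#' @param dir output directory (created if absent).
#' @param is_mito optional logical vector flagging mitochondrial genes;
#'   defaults to `grepl("^MT", rownames(mat))` on read.
#' @param path directory or dense-TSV path.
#' @return `read_count_matrix()` returns a base matrix with a logical
#'   `is_mito` attribute.
#' @export
write_count_matrix <- function(mat, dir, is_mito = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  if (is.null(is_mito)) is_mito <- grepl("^MT", rownames(mat))
  feats <- data.frame(gene_id = rownames(mat), gene_name = rownames(mat),
                      feature_type = ifelse(is_mito, "Gene Expression (mito)",
                                            "Gene Expression"))
  con <- file(file.path(dir, "features.tsv"), "wb")
  write.table(feats, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    sm <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- read.delim(file.path(path, "features.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)
    bcs <- readLines(file.path(path, "barcodes.tsv"))
    mat <- as.matrix(sm)
    dimnames(mat) <- list(feats[[1]], bcs)
    is_mito <- if (ncol(feats) >= 3) grepl("mito", feats[[3]]) else
      grepl("^MT", feats[[1]])
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- tab[[1]]
    is_mito <- grepl("^MT", rownames(mat))
  }
  storage.mode(mat) <- "integer"
  attr(mat, "is_mito") <- is_mito
  mat
}
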
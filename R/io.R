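#' Read a count matrix
#'
#' Reads a genes x cells count matrix from disk. TSV files carry gene ids in
#' the first column and cell ids in the header row; MatrixMarket files must be
#' accompanied by `<path>.rownames` and `<path>.colnames` (one id per line).
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"` or `"mtx"`.
#' @return A numeric matrix with gene ids as rownames and cell ids as colnames.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2) stop("count matrix TSV needs a gene-id column plus >= 1 cell column")
    genes <- as.character(dt[[1L]])
    vals <- dt[, -1L, drop = FALSE]
    nonnum <- !vapply(vals, is.numeric, logical(1L))
    if (any(nonnum)) {
      j <- which(nonnum)[1L]
      i <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric count at row %s, column '%s'",
                   if (is.na(i)) "?" else as.character(i), colnames(vals)[j]))
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
  } else {
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn)) {
      stop("MTX matrix requires companion files ", rn, " and ", cn)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  }
  validate_count_matrix(m)
  m
}

#' Write a count matrix
#'
#' @param m Numeric matrix with gene rownames and cell colnames.
#' @param path Output path.
#' @param format `"tsv"` (canonical interchange) or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  validate_count_matrix(m)
  if (format == "tsv") {
    dt <- data.table::data.table(gene = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Validate a genes x cells matrix
#'
#' Enforces unique gene and cell ids, numeric non-negative values and complete
#' dimnames. Transformed (real-valued) matrices are allowed; negativity is not.
#'
#' @param m Matrix to check.
#' @param allow_real Permit non-integer values (post-transform matrices).
#' @return `m`, invisibly.
#' @export
validate_count_matrix <- function(m, allow_real = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("count matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene rownames and cell colnames")
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) stop("duplicate cell id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(m)) stop("count matrix contains missing values")
  if (any(m < 0)) stop("count matrix contains negative values")
  if (!allow_real && any(m != round(m))) stop("count matrix contains non-integer values")
  invisible(m)
}

#' Read per-cell metadata
#'
#' Expects a TSV with columns `cell_id`, `capture_time_h`, `mapped_reads` and
#' optionally `label`. Capture times are validated against `capture_set`.
#'
#' @param path Metadata TSV path.
#' @param capture_set Allowed capture times in hours (default `c(0, 24, 48)`).
#' @return A data.frame of cell records.
#' @export
read_cell_metadata <- function(path, capture_set = c(0, 24, 48)) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  validate_cell_metadata(df, capture_set = capture_set)
}

#' Write per-cell metadata
#' @param cells Cell-record data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_metadata <- function(cells, path) {
  data.table::fwrite(cells, path, sep = "\t")
  invisible(path)
}

#' Validate cell records
#'
#' @param cells data.frame with `cell_id`, `capture_time_h`, `mapped_reads`.
#' @param capture_set Allowed capture times (hours); `NULL` skips the check.
#' @return The validated data.frame (invisibly returns visibly for piping).
#' @export
validate_cell_metadata <- function(cells, capture_set = c(0, 24, 48)) {
  need <- c("cell_id", "capture_time_h", "mapped_reads")
  miss <- setdiff(need, colnames(cells))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  cells$cell_id <- as.character(cells$cell_id)
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup)) stop("duplicate cell id(s) in metadata: ", paste(unique(dup), collapse = ", "))
  if (any(cells$mapped_reads < 0)) stop("mapped_reads must be non-negative")
  if (!is.null(capture_set)) {
    bad <- setdiff(unique(cells$capture_time_h), capture_set)
    if (length(bad)) {
      stop("capture_time_h value(s) outside capture set {",
           paste(capture_set, collapse = ", "), "}: ", paste(bad, collapse = ", "))
    }
  }
  cells
}

#' Align a count matrix with its metadata
#'
#' Checks that every matrix cell has a metadata record and returns the records
#' reordered to the matrix column order.
#'
#' @param m Count matrix.
#' @param cells Cell-record data.frame.
#' @return `cells` reordered to `colnames(m)`.
#' @export
align_cells <- function(m, cells) {
  missing_cells <- setdiff(colnames(m), cells$cell_id)
  if (length(missing_cells)) {
    stop("cell(s) in matrix absent from metadata: ", paste(missing_cells, collapse = ", "))
  }
  cells[match(colnames(m), cells$cell_id), , drop = FALSE]
}

#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open. Columns beyond the first three (name, score,
#' strand) are kept when present.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (nrow(df) == 0L || ncol(df) < 3L) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  colnames(df) <- cols[seq_len(min(ncol(df), 6L))]
  if (any(df$start < 0)) stop("BED start coordinates must be >= 0")
  if (any(df$end <= df$start)) stop("BED intervals must satisfy start < end")
  df
}

#' Write intervals as BED
#' @param df data.frame with `chrom`, `start`, `end` and optional extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), colnames(df))
  data.table::fwrite(df[, cols, drop = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a TSS table (6-column BED)
#'
#' Each record is a 1-bp interval `[position, position + 1)` carrying the gene
#' id in the name column and the gene strand.
#'
#' @param path BED path.
#' @return data.frame with `gene`, `chrom`, `position`, `strand`.
#' @export
read_tss_table <- function(path) {
  df <- read_bed(path)
  need <- c("name", "strand")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("TSS table must be 6-column BED (missing ", paste(miss, collapse = ", "), ")")
  if (!all(df$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  data.frame(gene = df$name, chrom = df$chrom, position = df$start,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Write a TSS table as 6-column BED
#' @param tss data.frame with `gene`, `chrom`, `position`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  write_bed(data.frame(chrom = tss$chrom, start = tss$position,
                       end = tss$position + 1L, name = tss$gene,
                       score = 0L, strand = tss$strand), path)
}

# stage-tagged logging to stderr; output streams stay clean
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
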
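# Promoter-window transcription-factor occupancy calls. All coordinates are
# 0-based half-open [start, end), the BED convention.

#' Regulatory window around a TSS
#'
#' Default window spans 20 kb upstream to 4 kb downstream of the TSS,
#' oriented by gene strand (`stranded = FALSE` always takes
#' `[pos - up_bp, pos + down_bp)`). The start is clamped at 0.
#'
#' @param tss TSS table (data.frame with `gene`, `chrom`, `position`,
#'   `strand`) or a single TSS record.
#' @param up_bp,down_bp Upstream/downstream extents in bp.
#' @param stranded Orient the window by gene strand (default TRUE).
#' @return data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
regulatory_window <- function(tss, up_bp = 20000L, down_bp = 4000L,
                              stranded = TRUE) {
  if (is.null(up_bp) || is.null(down_bp)) stop("window parameters up_bp/down_bp required")
  plus <- if (stranded) tss$strand == "+" else rep(TRUE, nrow(tss))
  start <- ifelse(plus, tss$position - up_bp, tss$position - down_bp)
  end <- ifelse(plus, tss$position + down_bp, tss$position + up_bp)
  data.frame(gene = tss$gene, chrom = tss$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Does any interval overlap a region?
#'
#' True iff any interval overlaps the region by at least 1 bp on the same
#' chromosome, under half-open semantics (`a.start < b.end && b.start <
#' a.end`). Overlap is computed with the GenomicRanges machinery.
#'
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`).
#' @param region Single-row data.frame (`chrom`, `start`, `end`).
#' @return Logical scalar.
#' @export
binds_region <- function(intervals, region) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(FALSE)
  # suppressed warning: disjoint chromosome sets between query and subject
  any(suppressWarnings(
    IRanges::overlapsAny(.as_granges(intervals), .as_granges(region),
                         minoverlap = 1L)))
}

#' Call OSN occupancy for genes
#'
#' A gene is occupied when, in at least `min_datasets` of the three datasets,
#' all three factors have at least one interval overlapping the gene's
#' regulatory window (the "all factors within a publication, in >= 2 of 3
#' publications" rule). `rule = "per_factor"` implements the alternative
#' parse: every factor must bind in >= `min_datasets` datasets, counted per
#' factor.
#'
#' @param genes Gene ids to call; default every gene in the TSS table. A
#'   requested gene absent from the table is an error naming it.
#' @param tss TSS table (`gene`, `chrom`, `position`, `strand`).
#' @param binding Nested list `binding[[dataset]][[factor]]` of interval
#'   data.frames; exactly 3 datasets of exactly 3 factors.
#' @param up_bp,down_bp,stranded Window geometry, see [regulatory_window()].
#' @param rule `"all_factors_per_dataset"` (default) or `"per_factor"`.
#' @param min_datasets Qualifying-dataset threshold (default 2).
#' @return data.frame with one row per gene: per-dataset qualification
#'   booleans, `n_qualifying` and `occupied`.
#' @export
call_osn_occupancy <- function(genes = NULL, tss, binding,
                               up_bp = 20000L, down_bp = 4000L,
                               stranded = TRUE,
                               rule = c("all_factors_per_dataset", "per_factor"),
                               min_datasets = 2L) {
  rule <- match.arg(rule)
  if (length(binding) != 3L) stop("exactly 3 datasets are required")
  factor_counts <- vapply(binding, length, integer(1L))
  if (any(factor_counts != 3L)) stop("each dataset must carry exactly 3 factors")
  if (is.null(genes)) genes <- tss$gene
  absent <- setdiff(genes, tss$gene)
  if (length(absent)) {
    stop("gene(s) absent from TSS table: ", paste(absent, collapse = ", "))
  }
  tss_sub <- tss[match(genes, tss$gene), , drop = FALSE]
  windows <- regulatory_window(tss_sub, up_bp, down_bp, stranded)
  datasets <- names(binding)
  if (is.null(datasets)) datasets <- paste0("dataset", seq_along(binding))

  per_dataset_factor <- array(FALSE,
                              dim = c(length(genes), 3L, 3L),
                              dimnames = list(genes, datasets, names(binding[[1L]])))
  for (d in seq_along(binding)) {
    for (f in seq_along(binding[[d]])) {
      iv <- binding[[d]][[f]]
      if (is.null(iv) || nrow(iv) == 0L) next
      hits <- suppressWarnings(
        IRanges::overlapsAny(.as_granges(windows), .as_granges(iv),
                             minoverlap = 1L))
      per_dataset_factor[, d, f] <- hits
    }
  }
  qual <- apply(per_dataset_factor, c(1L, 2L), all)   # all factors per dataset
  if (length(genes) == 1L) qual <- matrix(qual, nrow = 1L, dimnames = list(genes, datasets))
  n_qual <- rowSums(qual)
  occupied <- if (rule == "all_factors_per_dataset") {
    n_qual >= min_datasets
  } else {
    factor_ds <- apply(per_dataset_factor, c(1L, 3L), sum)  # datasets per factor
    if (length(genes) == 1L) factor_ds <- matrix(factor_ds, nrow = 1L)
    apply(factor_ds >= min_datasets, 1L, all)
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (d in seq_along(datasets)) out[[datasets[d]]] <- unname(qual[, d])
  out$n_qualifying <- unname(n_qual)
  out$occupied <- unname(occupied)
  out
}

#' Read a factor-by-dataset binding landscape from BED files
#'
#' Expects nine files named `<dataset>_<factor>.bed` in `dir`.
#'
#' @param dir Directory holding the BED files.
#' @param factors Three factor names.
#' @param datasets Three dataset names.
#' @return Nested list `binding[[dataset]][[factor]]`.
#' @export
read_binding_landscape <- function(dir, factors = c("OCT4", "SOX2", "NANOG"),
                                   datasets = paste0("dataset", 1:3)) {
  stats::setNames(lapply(datasets, function(d) {
    stats::setNames(lapply(factors, function(f) {
      path <- file.path(dir, paste0(d, "_", f, ".bed"))
      if (!file.exists(path)) stop("binding BED not found: ", path)
      read_bed(path)
    }), factors)
  }), datasets)
}

#' Write a binding landscape as BED files
#' @param binding Nested list `binding[[dataset]][[factor]]`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_binding_landscape <- function(binding, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(binding)) {
    for (f in names(binding[[d]])) {
      write_bed(binding[[d]][[f]], file.path(dir, paste0(d, "_", f, ".bed")))
    }
  }
  invisible(dir)
}
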
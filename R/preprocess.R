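#' Retain cells by mapped-read depth
#'
#' A cell passes iff `mapped_reads >= min_reads` (inclusive boundary: the
#' published rule is "equal or greater than 6 million uniquely mapping
#' reads").
#'
#' @param cells Cell-record data.frame.
#' @param min_reads QC threshold.
#' @return Character vector of retained cell ids (possibly empty).
#' @export
filter_cells_by_mapped_reads <- function(cells, min_reads = 6e6) {
  if (nrow(cells) == 0L) return(character())
  if (anyNA(cells$mapped_reads)) stop("mapped_reads missing for some cells")
  cells$cell_id[cells$mapped_reads >= min_reads]
}

#' log10(x + 1) transform
#'
#' @param m Non-negative count matrix.
#' @return Matrix of `log10(x + 1)` values.
#' @export
log_transform_counts <- function(m) {
  if (any(m < 0)) stop("counts must be non-negative before log transform")
  log10(m + 1)
}

#' Drop transcripts with no variation
#'
#' A transcript is removed iff all its values are identical across the
#' retained cells. A zero-gene matrix may result; downstream stages reject it.
#'
#' @param m Count matrix.
#' @return The matrix restricted to varying transcripts.
#' @export
remove_invariant_transcripts <- function(m) {
  if (nrow(m) == 0L) return(m)
  keep <- apply(m, 1L, function(x) any(x != x[1L]))
  m[keep, , drop = FALSE]
}

#' Exclude high-marker cells of one capture group
#'
#' A cell is excluded iff it belongs to capture group `group_h` AND its
#' transformed marker expression is strictly above `threshold`; cells of other
#' groups are never excluded. This mirrors the exclusion of 48 h EpiLCs with
#' log10(Tfcp2l1 count + 1) > 1.5.
#'
#' @param m Transformed matrix (the scale `threshold` lives on).
#' @param cells Cell records aligned with `m` columns.
#' @param marker Marker gene id; must be present in `m`.
#' @param threshold Strict exclusion threshold.
#' @param group_h Capture group (hours) the rule applies to.
#' @return Character vector of retained cell ids.
#' @export
exclude_high_marker_cells <- function(m, cells, marker = "Tfcp2l1",
                                      threshold = 1.5, group_h = 48) {
  if (!marker %in% rownames(m)) stop("marker gene absent from matrix: ", marker)
  cells <- align_cells(m, cells)
  marker_val <- m[marker, cells$cell_id]
  drop <- cells$capture_time_h == group_h & marker_val > threshold
  cells$cell_id[!drop]
}

#' Median-of-ratios size factors
#'
#' The standard estimator: the reference for gene g is its geometric mean
#' across cells, computed only over genes with strictly positive counts in
#' every cell; the size factor of cell c is the median over those genes of
#' `count_gc / reference_g`.
#'
#' @param m Raw count matrix (retained cells).
#' @return Named positive numeric vector, one size factor per cell.
#' @export
median_of_ratios_size_factors <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix: cannot compute size factors")
  all_pos <- rowSums(m <= 0) == 0L
  if (!any(all_pos)) {
    stop("no transcript has strictly positive counts in all cells; ",
         "relax the reference-gene rule or pre-filter cells")
  }
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  sf <- apply(m[all_pos, , drop = FALSE] / ref, 2L, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-finite or non-positive size factor")
  sf
}

#' Normalize and transform counts
#'
#' Working value = `log10(count_gc / sf_c + 1)`.
#'
#' @param m Raw count matrix.
#' @param size_factors Positive per-cell factors, aligned with `m` columns.
#' @return Working matrix on the transformed scale.
#' @export
normalize_and_transform <- function(m, size_factors) {
  if (length(size_factors) != ncol(m)) {
    stop("size factor vector length (", length(size_factors),
         ") does not match cell count (", ncol(m), ")")
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")
  log10(sweep(m, 2L, size_factors, "/") + 1)
}

#' Between/within capture-time variance ratio
#'
#' For each transcript, `Var_between` is the sample variance of the per-group
#' means and `Var_within` the unweighted mean of per-group sample variances.
#' Score = between/within; zero within with positive between gives `Inf`
#' (sorts first); 0/0 gives 0.
#'
#' @param m Working matrix.
#' @param cells Cell records aligned with `m` columns.
#' @return Named numeric vector of per-gene scores.
#' @export
capture_variance_ratio <- function(m, cells) {
  cells <- align_cells(m, cells)
  groups <- split(seq_len(ncol(m)), cells$capture_time_h)
  if (length(groups) < 2L) stop("need >= 2 capture groups")
  small <- names(groups)[vapply(groups, length, integer(1L)) < 2L]
  if (length(small)) stop("capture group(s) with < 2 cells: ", paste(small, collapse = ", "))
  gmeans <- vapply(groups, function(j) rowMeans(m[, j, drop = FALSE]),
                   numeric(nrow(m)))
  gvars <- vapply(groups, function(j) apply(m[, j, drop = FALSE], 1L, stats::var),
                  numeric(nrow(m)))
  if (nrow(m) == 1L) { gmeans <- rbind(gmeans); gvars <- rbind(gvars) }
  between <- apply(gmeans, 1L, stats::var)
  within <- rowMeans(gvars)
  score <- ifelse(within > 0, between / within,
                  ifelse(between > 0, Inf, 0))
  stats::setNames(score, rownames(m))
}

#' Select the analysis transcript set
#'
#' Curated transcripts come first (missing ones are logged and skipped), then
#' the highest-scoring remaining transcripts fill up to `n_total`, descending
#' score with ties broken by ascending gene id.
#'
#' @param scores Named per-gene scores (from [capture_variance_ratio()]).
#' @param curated Gene ids always included.
#' @param n_total Total size of the analysis set.
#' @return Ordered character vector of `n_total` (or fewer, if the matrix is
#'   small) gene ids.
#' @export
select_analysis_genes <- function(scores, curated = character(), n_total) {
  curated <- unique(curated)
  present <- curated[curated %in% names(scores)]
  missing <- setdiff(curated, present)
  if (length(missing)) {
    log_stage("select", "curated gene(s) absent, skipped: ",
              paste(missing, collapse = ", "))
  }
  if (n_total < length(present)) {
    stop("n_total (", n_total, ") smaller than curated set (", length(present), ")")
  }
  rest <- scores[setdiff(names(scores), present)]
  ord <- order(-rest, names(rest))
  fill <- names(rest)[ord][seq_len(min(n_total - length(present), length(rest)))]
  c(present, fill)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: mapped-read filter, invariant-transcript removal,
#' log10(count + 1) transform, marker exclusion, median-of-ratios size factors
#' on the raw counts of surviving cells, normalize + transform, variance-ratio
#' transcript selection.
#'
#' @param counts Raw count matrix.
#' @param cells Cell records covering every matrix column.
#' @param config A [run_config()].
#' @return List with `working` (normalized transformed matrix), `cells`
#'   (surviving records), `size_factors`, `analysis_genes`, `scores` and
#'   `report` (a `PreprocessReport`-style list of stage counts).
#' @export
preprocess <- function(counts, cells, config) {
  validate_count_matrix(counts)
  cells <- align_cells(counts, cells)
  report <- list(cells_in = ncol(counts), genes_in = nrow(counts))

  keep <- filter_cells_by_mapped_reads(cells, config$min_mapped_reads)
  m <- counts[, keep, drop = FALSE]
  cells1 <- cells[match(keep, cells$cell_id), , drop = FALSE]
  report$cells_after_read_filter <- ncol(m)
  log_stage("preprocess", "read filter kept ", ncol(m), "/", report$cells_in, " cells")
  if (ncol(m) == 0L) stop("no cell passes the mapped-read filter")

  m <- remove_invariant_transcripts(m)
  report$genes_after_invariant_filter <- nrow(m)
  if (nrow(m) == 0L) stop("all transcripts invariant: nothing to analyse")

  transformed <- log_transform_counts(m)
  marker_matrix <- transformed
  if (config$marker_on_normalized) {
    sf0 <- median_of_ratios_size_factors(m)
    marker_matrix <- normalize_and_transform(m, sf0)
  }
  keep <- exclude_high_marker_cells(marker_matrix, cells1, config$marker_gene,
                                    config$marker_threshold, config$marker_group_h)
  m <- m[, keep, drop = FALSE]
  cells2 <- cells1[match(keep, cells1$cell_id), , drop = FALSE]
  report$cells_after_marker_filter <- ncol(m)
  log_stage("preprocess", "marker exclusion kept ", ncol(m), "/",
            report$cells_after_read_filter, " cells")

  sf <- median_of_ratios_size_factors(m)
  working <- normalize_and_transform(m, sf)
  scores <- capture_variance_ratio(working, cells2)
  analysis_genes <- select_analysis_genes(scores, config$curated_genes,
                                          min(config$n_analysis_genes, nrow(working)))
  report$size_factors <- sf
  report$analysis_genes <- analysis_genes
  list(working = working, cells = cells2, size_factors = sf,
       analysis_genes = analysis_genes, scores = scores, report = report)
}
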
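#' Simulation configuration
#'
#' Describes the synthetic world the generator emulates: three capture groups
#' (0/24/48 h) of ~20-25 cells, a few hundred transcripts split into downward,
#' upward and flat pseudotime trajectory classes on the log10 scale,
#' overdispersed counts and lognormal per-cell size factors.
#'
#' @param n_cells_per_group Cells per capture group (default 22).
#' @param capture_set Capture times in hours.
#' @param sigma_tau_true True sd (hours) of pseudotime around capture time.
#' @param n_down,n_up,n_flat Transcripts per trajectory class.
#' @param amplitude Sigmoid swing of dynamic genes, log10 units (default 1.5,
#'   roughly a 30-fold expression change).
#' @param baseline_range Flat baseline range on the log10 scale.
#' @param dispersion sd of the Gaussian noise on the log10 scale (default
#'   0.25, so the default amplitude is 6x the noise sd: strong signal).
#' @param sf_log_sd sd of log size factors (lognormal, default 0.3).
#' @param mapped_reads_mean Mean mapped reads per cell (all above the 6e6 QC
#'   threshold unless `n_failing_cells` > 0).
#' @param n_failing_cells Cells given sub-threshold mapped reads.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells_per_group = 22L,
                       capture_set = c(0, 24, 48),
                       sigma_tau_true = 8,
                       n_down = 40L, n_up = 40L, n_flat = 80L,
                       amplitude = 1.5,
                       baseline_range = c(0.5, 1.5),
                       dispersion = 0.25,
                       sf_log_sd = 0.3,
                       mapped_reads_mean = 8e6,
                       n_failing_cells = 0L,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  if (n_cells_per_group < 1L) stop("n_cells_per_group must be >= 1")
  if (n_down + n_up + n_flat < 1L) stop("at least one transcript must be requested")
  if (dispersion < 0 || sf_log_sd < 0) stop("dispersion and sf_log_sd must be >= 0")
  structure(list(n_cells_per_group = as.integer(n_cells_per_group),
                 capture_set = sort(capture_set),
                 sigma_tau_true = sigma_tau_true,
                 n_down = as.integer(n_down), n_up = as.integer(n_up),
                 n_flat = as.integer(n_flat), amplitude = amplitude,
                 baseline_range = baseline_range, dispersion = dispersion,
                 sf_log_sd = sf_log_sd, mapped_reads_mean = mapped_reads_mean,
                 n_failing_cells = as.integer(n_failing_cells),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sigmoid in pseudotime; center/width in hours
.sigmoid <- function(tau, center, width) 1 / (1 + exp(-(tau - center) / width))

# per-gene mean curve on the log10 scale
.gene_mean <- function(class, tau, base, amp, center, width) {
  switch(class,
         down = base + amp * (1 - .sigmoid(tau, center, width)),
         up   = base + amp * .sigmoid(tau, center, width),
         flat = rep(base, length(tau)))
}

#' Simulate a pseudotime-structured single-cell count matrix
#'
#' Cells get true pseudotimes `tau* ~ Normal(capture_time, sigma_tau_true^2)`
#' (untruncated; negative pseudotimes permitted, as in the capture prior).
#' Down/up transcripts follow smooth monotone sigmoid mean curves of `tau*`
#' on the log10 scale, flat transcripts are constant. Observed counts are
#' `max(0, round(sf_c * 10^(mean + noise) - 1))` with Gaussian noise on the
#' log10 scale, which yields overdispersed counts after exponentiation.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x cells integer matrix), `cells`
#'   (metadata data.frame) and `truth` (list with `cell_truth`, `gene_truth`,
#'   `dispersion`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_expression_impl(config))
}

.simulate_expression_impl <- function(config) {
  groups <- rep(config$capture_set, each = config$n_cells_per_group)
  n_cells <- length(groups)
  cell_id <- sprintf("cell%03d_t%02d", seq_len(n_cells), as.integer(groups))
  tau_true <- stats::rnorm(n_cells, mean = groups, sd = config$sigma_tau_true)
  sf_true <- exp(stats::rnorm(n_cells, 0, config$sf_log_sd))

  classes <- rep(c("down", "up", "flat"),
                 times = c(config$n_down, config$n_up, config$n_flat))
  n_genes <- length(classes)
  gene_id <- sprintf("gene%04d_%s", seq_len(n_genes), classes)
  # real marker names by class, so the marker-exclusion and curated-gene rules
  # exercise realistically: naive markers fall, epiblast markers rise
  naive_dn <- c("Esrrb", "Tfcp2l1", "Klf2", "Klf4", "Nanog", "Prdm14", "Zfp42")
  epi_up <- c("Fgf5", "Lin28b", "Dnmt3b", "Pou3f1", "Otx2", "Pdk1", "Pdk3",
              "Slc2a1", "Stk11")
  flat_ctrl <- c("Idh2", "Cox7a1", "Cpt1a", "Actb", "Gapdh")
  for (cls in c("down", "up", "flat")) {
    pool <- switch(cls, down = naive_dn, up = epi_up, flat = flat_ctrl)
    ix <- which(classes == cls)
    n_named <- min(length(ix), length(pool))
    if (n_named > 0L && (config$n_down + config$n_up) > 0L) {
      gene_id[ix[seq_len(n_named)]] <- pool[seq_len(n_named)]
    }
  }
  base <- stats::runif(n_genes, config$baseline_range[1L], config$baseline_range[2L])
  t_mid <- mean(range(config$capture_set))
  span <- diff(range(config$capture_set))
  center <- stats::runif(n_genes, t_mid - span / 4, t_mid + span / 4)
  width <- stats::runif(n_genes, span / 8, span / 4)

  mu <- matrix(0, n_genes, n_cells, dimnames = list(gene_id, cell_id))
  for (g in seq_len(n_genes)) {
    mu[g, ] <- .gene_mean(classes[g], tau_true, base[g], config$amplitude,
                          center[g], width[g])
  }
  noise <- matrix(stats::rnorm(n_genes * n_cells, 0, config$dispersion),
                  n_genes, n_cells)
  counts <- pmax(round(rep(sf_true, each = n_genes) * 10^(mu + noise) - 1), 0)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_id, cell_id)

  mapped <- round(stats::rnorm(n_cells, config$mapped_reads_mean, 5e5))
  mapped <- pmax(mapped, 6e6)  # all pass QC by default
  if (config$n_failing_cells > 0L) {
    fail <- sample.int(n_cells, min(config$n_failing_cells, n_cells))
    mapped[fail] <- round(stats::runif(length(fail), 1e6, 5.9e6))
  }
  cells <- data.frame(cell_id = cell_id, capture_time_h = groups,
                      mapped_reads = mapped,
                      label = paste0("dye_t", as.integer(groups)),
                      stringsAsFactors = FALSE)
  truth <- list(
    cell_truth = data.frame(cell_id = cell_id, tau_true = tau_true,
                            size_factor_true = sf_true, stringsAsFactors = FALSE),
    gene_truth = data.frame(gene = gene_id, class = classes, baseline = base,
                            amplitude = ifelse(classes == "flat", 0, config$amplitude),
                            center = center, width = width, stringsAsFactors = FALSE),
    dispersion = config$dispersion)
  list(counts = counts, cells = cells, truth = truth)
}

#' Simulate a null (structureless) count matrix
#'
#' All transcripts are flat-class with independent noise: no pseudotime
#' structure exists by construction, so any cell ordering is exchangeable with
#' a random one.
#'
#' @param config A [sim_config()]; its class counts are overridden so that all
#'   requested transcripts are flat.
#' @return List with `counts` and `cells` as in [simulate_expression()].
#' @export
simulate_null_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_down + config$n_up + config$n_flat
  cfg <- config
  cfg$n_down <- 0L; cfg$n_up <- 0L; cfg$n_flat <- n_total
  sim <- withr::with_seed(cfg$seed, .simulate_expression_impl(cfg))
  sim[c("counts", "cells")]
}

#' Simulate a toy OCT4/SOX2/NANOG binding landscape
#'
#' Plants genes with known occupancy truth: occupied genes have all three
#' factors overlapping their regulatory window in at least two of three
#' datasets; unoccupied genes violate the rule in a controlled way (all three
#' factors in exactly one dataset, one factor missing everywhere, or no
#' binding at all).
#'
#' @param n_genes Number of genes (>= 1).
#' @param prop_occupied Proportion planted as occupied.
#' @param up_bp,down_bp Regulatory window extents in bp (defaults 20 kb / 4 kb).
#' @param factors Exactly three factor names.
#' @param datasets Exactly three dataset names.
#' @param seed Mandatory RNG seed.
#' @return List with `tss` (TSS table), `binding` (nested list
#'   `binding[[dataset]][[factor]]` of interval data.frames) and `truth`
#'   (data.frame with per-gene `occupied_true` and violation `mode`).
#' @export
simulate_binding_landscape <- function(n_genes = 20L, prop_occupied = 0.5,
                                       up_bp = 20000L, down_bp = 4000L,
                                       factors = c("OCT4", "SOX2", "NANOG"),
                                       datasets = paste0("dataset", 1:3),
                                       seed = NULL) {
  if (is.null(seed)) stop("simulate_binding_landscape requires a seed")
  if (n_genes < 1L) stop("need >= 1 gene")
  if (length(factors) != 3L || length(datasets) != 3L) {
    stop("exactly 3 factors and 3 datasets are required")
  }
  if (is.null(up_bp) || is.null(down_bp)) stop("window parameters up_bp/down_bp required")
  withr::with_seed(seed, {
    gene <- sprintf("gene%03d", seq_len(n_genes))
    # genes spaced 200 kb apart so windows never collide
    position <- 100000L + (seq_len(n_genes) - 1L) * 200000L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- data.frame(gene = gene, chrom = "chr1", position = position,
                      strand = strand, stringsAsFactors = FALSE)
    windows <- regulatory_window(tss, up_bp = up_bp, down_bp = down_bp)

    occupied <- stats::runif(n_genes) < prop_occupied
    mode <- ifelse(occupied, "occupied",
                   sample(c("one_dataset", "missing_factor", "empty"),
                          n_genes, replace = TRUE))

    binding <- stats::setNames(lapply(datasets, function(d) {
      stats::setNames(lapply(factors, function(f) {
        data.frame(chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
      }), factors)
    }), datasets)

    add_peak <- function(binding, d, f, win) {
      w <- max(200L, min(1000L, win$end - win$start))
      s <- win$start + sample.int(max(1L, win$end - win$start - w), 1L) - 1L
      peak <- data.frame(chrom = win$chrom, start = s, end = s + w,
                         stringsAsFactors = FALSE)
      binding[[d]][[f]] <- rbind(binding[[d]][[f]], peak)
      binding
    }

    for (i in seq_len(n_genes)) {
      win <- windows[i, ]
      if (mode[i] == "occupied") {
        ds <- sample(datasets, sample(2:3, 1L))
        for (d in ds) for (f in factors) binding <- add_peak(binding, d, f, win)
      } else if (mode[i] == "one_dataset") {
        d <- sample(datasets, 1L)
        for (f in factors) binding <- add_peak(binding, d, f, win)
      } else if (mode[i] == "missing_factor") {
        # two qualifying-looking datasets, but one factor absent in each
        drop_f <- sample(factors, 1L)
        for (d in sample(datasets, 2L)) {
          for (f in setdiff(factors, drop_f)) binding <- add_peak(binding, d, f, win)
        }
      }  # "empty": no intervals anywhere
    }
    truth <- data.frame(gene = gene, occupied_true = occupied, mode = mode,
                        stringsAsFactors = FALSE)
    list(tss = tss, binding = binding, truth = truth)
  })
}
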
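test_that("regulatory window is strand-aware, clamped and flag-switchable", {
  tss <- data.frame(gene = c("gp", "gm", "gc"), chrom = "chr1",
                    position = c(100000L, 100000L, 5000L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- regulatory_window(tss)
  expect_equal(w$start, c(80000L, 96000L, 0L))
  expect_equal(w$end, c(104000L, 120000L, 9000L))
  wu <- regulatory_window(tss, stranded = FALSE)
  expect_equal(wu$start[2], 80000L)   # strand ignored
  expect_error(regulatory_window(tss, up_bp = NULL), "window")
})

test_that("binds_region follows half-open overlap semantics", {
  region <- data.frame(chrom = "chr1", start = 80000L, end = 104000L)
  expect_true(binds_region(data.frame(chrom = "chr1", start = 103999L, end = 104500L), region))
  expect_false(binds_region(data.frame(chrom = "chr1", start = 104000L, end = 104500L), region))
  expect_false(binds_region(data.frame(chrom = "chr2", start = 90000L, end = 90001L), region))
  expect_false(binds_region(data.frame(chrom = character(), start = integer(), end = integer()), region))
})

test_that("occupancy rule: all three factors, at least two of three datasets", {
  tss <- data.frame(gene = "g", chrom = "chr1", position = 100000L, strand = "+",
                    stringsAsFactors = FALSE)
  win_peak <- data.frame(chrom = "chr1", start = 90000L, end = 90500L)
  none <- data.frame(chrom = character(), start = integer(), end = integer())
  mk <- function(d1, d2, d3) {
    fill <- function(spec) setNames(lapply(spec, function(x) if (x) win_peak else none),
                                    c("OCT4", "SOX2", "NANOG"))
    list(dataset1 = fill(d1), dataset2 = fill(d2), dataset3 = fill(d3))
  }
  # datasets 1 and 3 complete, dataset 2 missing SOX2 -> occupied
  b <- mk(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  res <- call_osn_occupancy(tss = tss, binding = b)
  expect_true(res$occupied); expect_equal(res$n_qualifying, 2L)
  # complete in exactly one dataset -> not occupied
  b1 <- mk(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE))
  expect_false(call_osn_occupancy(tss = tss, binding = b1)$occupied)
  # no intervals at all -> false
  b0 <- mk(c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE))
  expect_false(call_osn_occupancy(tss = tss, binding = b0)$occupied)
  # alternative parse: every factor in >= 2 datasets
  b2 <- mk(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_false(call_osn_occupancy(tss = tss, binding = b2)$occupied)
  expect_true(call_osn_occupancy(tss = tss, binding = b2, rule = "per_factor")$occupied)
  # unknown gene is an error naming it
  expect_error(call_osn_occupancy("ghost", tss, b), "ghost")
  expect_error(call_osn_occupancy(tss = tss, binding = b[1:2]), "3 datasets")
})

test_that("engine agrees with the brute-force oracle on random landscapes", {
  withr::with_seed(77, for (i in 1:60) {
    region <- data.frame(chrom = sample(c("chr1", "chr2"), 1),
                         start = s <- sample.int(1e5, 1), end = s + sample.int(5e4, 1))
    n <- sample.int(50, 1)
    st <- sample.int(2e5, n)
    iv <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = st, end = st + sample.int(2e3, n, replace = TRUE))
    expect_identical(binds_region(iv, region), overlaps_oracle(iv, region))
  })
})

test_that("occupancy is monotone in added intervals and strand-mirror symmetric", {
  sim <- simulate_binding_landscape(n_genes = 15, seed = 5)
  base_calls <- call_osn_occupancy(tss = sim$tss, binding = sim$binding)
  # add every window as a peak for every factor/dataset: occupancy never drops
  wins <- regulatory_window(sim$tss)
  extra <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end)
  richer <- lapply(sim$binding, function(d) lapply(d, function(f) rbind(f, extra)))
  rich_calls <- call_osn_occupancy(tss = sim$tss, binding = richer)
  expect_true(all(rich_calls$occupied >= base_calls$occupied))
  # mirror all coordinates around a large constant and flip strands
  M <- 10000000L
  mtss <- sim$tss
  mtss$position <- M - sim$tss$position
  mtss$strand <- ifelse(sim$tss$strand == "+", "-", "+")
  mirror_iv <- function(df) data.frame(chrom = df$chrom, start = M - df$end,
                                       end = M - df$start)
  mbind <- lapply(sim$binding, function(d) lapply(d, mirror_iv))
  mcalls <- call_osn_occupancy(tss = mtss, binding = mbind)
  expect_identical(mcalls$occupied, base_calls$occupied)
})
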
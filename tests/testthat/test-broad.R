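test_that("peaks closer than the gap threshold merge transitively", {
  m <- merge_close_peaks(genomic_intervals(c("chr1", "chr1"), c(0, 500),
                                           c(100, 600)))
  expect_equal(as.data.frame(m)[, c("start", "end")],
               data.frame(start = 0L, end = 600L))
  # gap of exactly 1000 is not < 1000
  m2 <- merge_close_peaks(genomic_intervals(c("chr1", "chr1"), c(0, 1100),
                                            c(100, 1200)))
  expect_equal(nrow(m2), 2L)
  m3 <- merge_close_peaks(genomic_intervals(c("chr1", "chr1"), c(0, 1099),
                                            c(100, 1200)))
  expect_equal(nrow(m3), 1L)
  # chain with 500-bp gaps collapses to a single domain
  chain <- genomic_intervals(rep("chr1", 3), c(0, 600, 1200),
                             c(100, 700, 1300))
  expect_equal(as.data.frame(merge_close_peaks(chain))[, c("start", "end")],
               data.frame(start = 0L, end = 1300L))
})

test_that("merging is idempotent", {
  set.seed(41)
  iv <- random_intervals(60, max_coord = 30000L)
  once <- merge_close_peaks(iv)
  twice <- merge_close_peaks(once)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("elbow point maximizes chord distance with stated tie rules", {
  widths <- c(100, 55, 54, 53, 52, 51, 50, 49, 48, 47)
  # independent geometry oracle: explicit point-to-line distance formula
  oracle_elbow <- function(w) {
    n <- length(w)
    d <- vapply(seq_len(n), function(i) {
      abs((w[n] - w[1]) * i - (n - 1) * w[i] + n * w[1] - w[n]) /
        sqrt((n - 1)^2 + (w[n] - w[1])^2)
    }, 0)
    which.max(d)
  }
  expect_equal(elbow_point(widths), 2L)
  expect_equal(elbow_point(widths), oracle_elbow(widths))
  # perfectly linear: all distances zero, tie-break to rank 1
  expect_equal(elbow_point(seq(100, 10, by = -10)), 1L)
  # two linear segments meeting at rank k: elbow at the junction
  for (k in c(5L, 12L, 20L)) {
    w <- c(2000 - 50 * (0:(k - 1)), 2000 - 50 * (k - 1) - 1 * (1:(30 - k)))
    expect_equal(elbow_point(w), k)
    expect_equal(elbow_point(w), oracle_elbow(w))
  }
  expect_error(elbow_point(c(3, 2)), ">= 3")
  expect_error(elbow_point(c(1, 2, 3)), "descending")
})

test_that("elbow index is invariant to uniform rescaling of widths", {
  set.seed(42)
  w <- sort(rlnorm(200, log(1000), 0.6), decreasing = TRUE)
  expect_equal(elbow_point(w), elbow_point(w * 1e4))
  expect_equal(elbow_point(w), elbow_point(w * 1e-4))
})

test_that("broad/typical split partitions the peaks", {
  proms <- promoter_table(data.frame(gene_id = "g1", chrom = "chr1",
                                     tss = 500L, strand = "+"))
  widths <- c(100, 55, 54, 53, 52, 51, 50, 49, 48, 47)
  peaks <- genomic_intervals(rep("chr1", 10),
                             seq(0, by = 5000, length.out = 10),
                             seq(0, by = 5000, length.out = 10) + widths)
  cb <- classify_broad(peaks, proms)
  expect_equal(nrow(cb$broad), 1L)
  expect_equal(nrow(cb$typical), 9L)
  expect_equal(cb$broad$width, 100L)
  expect_equal(cb$genes$gene_id, "g1")  # widest peak covers the promoter
  # identical widths: degenerate geometry, documented 1-broad convention
  same <- genomic_intervals(rep("chr1", 5),
                            seq(0, by = 5000, length.out = 5),
                            seq(0, by = 5000, length.out = 5) + 100)
  cb2 <- classify_broad(same, proms)
  expect_equal(nrow(cb2$broad), 1L)
  expect_equal(nrow(cb2$broad) + nrow(cb2$typical), 5L)
  expect_error(classify_broad(peaks[1:2, ], proms), ">= 3")
})

test_that("planted broad domains are recovered from simulated peaks", {
  cfg <- sim_config(seed = 43, n_genes = 800,
                    n_cell_types = 5, markers_per_type = 10,
                    state_priors = c(K4_ONLY = 1, BIVALENT = 0,
                                     K27_ONLY = 0, NONE = 0),
                    broad_n = 25, jitter_sd = 0, dropout_prob = 0,
                    k4_width_dist = "uniform")
  b <- simulate_bivalency_data(cfg)
  cons <- consensus_peaks(lapply(b$peaks$H3K4me3$P7, peak_set,
                                 mark = "H3K4me3", timepoint = "P7"))
  cb <- classify_broad(merge_close_peaks(cons), b$tss)
  called <- unique(cb$genes$gene_id)
  hits <- intersect(called, b$truth$broad_genes)
  expect_gte(length(hits) / length(called), 0.95)
  expect_gte(length(hits) / length(b$truth$broad_genes), 0.95)
})
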
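window <- data.frame(chrom = "chr1", start = 500L, end = 1501L)

test_that("promoter classification follows the overlap rules", {
  k4 <- genomic_intervals("chr1", 400, 900)
  k27 <- genomic_intervals("chr1", 800, 1600)
  expect_equal(classify_promoter(k4, k27, window), "BIVALENT")
  expect_equal(classify_promoter(k4, genomic_intervals(), window), "K4_ONLY")
  expect_equal(classify_promoter(genomic_intervals(), k27, window), "K27_ONLY")
  expect_equal(classify_promoter(genomic_intervals(), genomic_intervals(),
                                 window), "NONE")
})

test_that("non-overlapping dual marks follow the dual policy", {
  k4 <- genomic_intervals("chr1", 400, 700)
  k27 <- genomic_intervals("chr1", 1200, 1600)
  expect_equal(classify_promoter(k4, k27, window), "DUAL_NONOVERLAP")
  expect_equal(classify_promoter(k4, k27, window, dual_policy = "bivalent"),
               "BIVALENT")
})

toy_promoters <- promoter_table(data.frame(
  gene_id = c("g1", "g2"), chrom = "chr1", tss = c(1000L, 50000L),
  strand = c("+", "-"), stringsAsFactors = FALSE))

toy_peaks <- list(
  H3K4me3 = list(P7 = genomic_intervals("chr1", 400, 900)),
  H3K27me3 = list(P7 = genomic_intervals("chr1", 800, 1600)))

test_that("classify_all builds a complete state table", {
  st <- classify_all(toy_promoters, toy_peaks)
  expect_s3_class(st, "state_table")
  expect_equal(st$state[st$gene_id == "g1"], "BIVALENT")
  expect_equal(st$state[st$gene_id == "g2"], "NONE")
  expect_error(classify_all(toy_promoters, toy_peaks["H3K4me3"]),
               "missing mark")
  expect_error(
    classify_all(toy_promoters,
                 list(H3K4me3 = toy_peaks$H3K4me3,
                      H3K27me3 = list(P12 = genomic_intervals()))),
    "missing consensus")
})

test_that("states partition the gene set at every timepoint", {
  b <- simulate_bivalency_data(sim_config(seed = 21, n_genes = 300,
                                          n_cell_types = 5, markers_per_type = 10))
  st <- classify_all(b$tss, bundle_consensus(b))
  counts <- state_counts(st)
  expect_true(all(colSums(counts) == 300))
  expect_equal(anyDuplicated(paste(st$gene_id, st$timepoint)), 0L)
})

test_that("planted states are recovered exactly without noise", {
  b <- simulate_bivalency_data(sim_config(seed = 22, n_genes = 400, n_cell_types = 5,
                                          markers_per_type = 10,
                                          jitter_sd = 0, dropout_prob = 0))
  st <- classify_all(b$tss, bundle_consensus(b))
  expect_equal(state_recovery(st, b$truth$states), 1)
})

test_that("enlarging the flank never turns a bivalent promoter into NONE", {
  b <- simulate_bivalency_data(sim_config(seed = 23, n_genes = 200,
                                          n_cell_types = 5, markers_per_type = 10))
  cons <- bundle_consensus(b)
  st1 <- classify_all(b$tss, cons, flank = 500)
  st2 <- classify_all(b$tss, cons, flank = 2000)
  was_biv <- st1$state == "BIVALENT"
  expect_false(any(st2$state[was_biv] == "NONE"))
})

test_that("the bivalent dual policy only grows the BIVALENT class", {
  b <- simulate_bivalency_data(sim_config(seed = 24, n_genes = 200,
                                          n_cell_types = 5, markers_per_type = 10))
  cons <- bundle_consensus(b)
  sep <- state_counts(classify_all(b$tss, cons, dual_policy = "separate"))
  biv <- state_counts(classify_all(b$tss, cons, dual_policy = "bivalent"))
  expect_true(all(biv["BIVALENT", ] >= sep["BIVALENT", ]))
  expect_true(all(biv["DUAL_NONOVERLAP", ] == 0))
  expect_equal(biv["K4_ONLY", ], sep["K4_ONLY", ])
  expect_equal(biv["K27_ONLY", ], sep["K27_ONLY", ])
  expect_equal(biv["NONE", ], sep["NONE", ])
})

test_that("bivalent regions are the pairwise mark intersections", {
  r <- bivalent_regions(genomic_intervals("chr1", 0, 100),
                        genomic_intervals("chr1", 50, 150))
  expect_equal(r[, c("start", "end")], data.frame(start = 50L, end = 100L))
  expect_equal(r$k4_width, 100L)
  expect_equal(r$k27_width, 100L)

  expect_equal(nrow(bivalent_regions(genomic_intervals("chr1", 0, 100),
                                     genomic_intervals("chr1", 200, 300))), 0L)

  r2 <- bivalent_regions(genomic_intervals("chr1", 0, 300),
                         genomic_intervals(c("chr1", "chr1"), c(50, 200),
                                           c(100, 250)))
  expect_equal(r2$start, c(50L, 200L))
  expect_equal(r2$end, c(100L, 250L))
})

test_that("region annotation uses midpoints with promoter precedence", {
  proms <- promoter_table(data.frame(gene_id = "g1", chrom = "chr1",
                                     tss = 1000L, strand = "+"))
  bodies <- genomic_intervals("chr1", 1000, 5000)
  regions <- data.frame(chrom = c("chr1", "chr1", "chr9"),
                        start = c(900L, 3000L, 10L),
                        end = c(1100L, 3200L, 100L))
  ann <- annotate_regions(regions, proms, bodies)
  expect_equal(ann$regions$category, c("promoter", "gene_body", "intergenic"))
  expect_equal(sum(ann$fractions), 1)
})
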
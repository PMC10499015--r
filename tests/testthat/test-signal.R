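proms1 <- promoter_table(data.frame(gene_id = "g1", chrom = "chr1",
                                    tss = 1000L, strand = "+"))

test_that("TSS signal sums per-base coverage over the window", {
  cov <- data.frame(chrom = "chr1", start = 0L, end = 2000L, value = 2.0)
  expect_equal(unname(quantify_tss_signal(cov, proms1)), 2.0 * 1001)
  # no coverage on the chromosome
  cov2 <- data.frame(chrom = "chr5", start = 0L, end = 2000L, value = 2.0)
  expect_equal(unname(quantify_tss_signal(cov2, proms1)), 0)
  # partial overlap
  cov3 <- data.frame(chrom = "chr1", start = 900L, end = 1100L, value = 1.0)
  expect_equal(unname(quantify_tss_signal(cov3, proms1)), 200)
  # overlapping track is rejected
  cov4 <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L),
                     value = 1)
  expect_error(quantify_tss_signal(cov4, proms1), "overlap")
})

test_that("size factors implement median-of-ratios", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  sf <- unname(size_factors(m2))
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(unname(size_factors(matrix(5:7, ncol = 1))), 1)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "size factors")
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(51)
  m <- matrix(rpois(400, lambda = rep(c(20, 40, 80, 10), each = 100)),
              ncol = 4)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("size factors recover planted scalar multiples up to a constant", {
  set.seed(52)
  base <- rpois(200, 50) + 1
  scal <- c(0.5, 1, 2, 4)
  m <- outer(base, scal)
  sf <- unname(size_factors(m))
  expect_equal(sf / sf[2], scal / scal[2], tolerance = 1e-10)
})

test_that("bivalency ratio matches direct arithmetic and is antisymmetric", {
  k4 <- matrix(40, 1, 1, dimnames = list("g1", "s1"))
  k27 <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  # pre-normalized inputs: log2((40 + 1) / (10 + 1))
  expect_equal(unname(bivalency_ratio(k4, k27, normalize = FALSE)),
               log2(41 / 11))
  # single gene with joint normalization: normalized means are equal by
  # construction, so the ratio collapses to 0
  expect_equal(unname(bivalency_ratio(k4, k27)), 0)
  # multi-gene case against hand-computed normalization
  k4m <- matrix(c(40, 100), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  k27m <- matrix(c(10, 100), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  r <- bivalency_ratio(k4m, k27m)
  sf <- size_factors(cbind(k4m, k27m))
  want <- log2((k4m[, 1] / sf[1] + 1) / (k27m[, 1] / sf[2] + 1))
  expect_equal(r, want)
  # swapping the marks flips the sign
  expect_equal(bivalency_ratio(k4m, k27m), -bivalency_ratio(k27m, k4m))
  # identical matrices give ratio zero everywhere
  expect_equal(unname(bivalency_ratio(k4m, k4m)), c(0, 0))
  expect_error(bivalency_ratio(k4m, k27m[2:1, , drop = FALSE]), "same genes")
})

test_that("expression quintiles split by rank with stable ties", {
  q <- expression_quintiles(setNames(1:10, paste0("g", 1:10)))
  expect_equal(unname(q), rep(1:5, each = 2))
  # all-equal values fall back to input order
  q2 <- expression_quintiles(rep(7, 10))
  expect_equal(unname(q2), rep(1:5, each = 2))
  # 7 genes: sizes 2,2,1,1,1
  q3 <- expression_quintiles(c(3, 1, 2, 7, 6, 5, 4))
  expect_equal(as.integer(table(q3)), c(2L, 2L, 1L, 1L, 1L))
  expect_equal(unname(q3[order(c(3, 1, 2, 7, 6, 5, 4))]),
               c(1L, 1L, 2L, 2L, 3L, 4L, 5L))
  expect_error(expression_quintiles(1:4), ">= 5")
})

test_that("metaprofiles bin coverage and orient minus-strand genes 5' first", {
  proms <- promoter_table(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1", tss = c(10000L, 50000L),
    strand = c("+", "-"), stringsAsFactors = FALSE))
  groups <- c(gp = "plus", gm = "minus")
  # constant coverage: every bin equals the constant
  cov <- data.frame(chrom = "chr1", start = 0L, end = 60000L, value = 3)
  mp <- metaprofile(cov, proms, groups, flank = 2500, bins = 100)
  expect_true(all(abs(mp - 3) < 1e-12))
  # spike at the TSS base only: a single center bin is nonzero
  cov2 <- data.frame(chrom = "chr1", start = 10000L, end = 10001L, value = 9)
  mp2 <- metaprofile(cov2, proms["gp" == proms$gene_id, ], groups["gp"],
                     flank = 2500, bins = 100)
  expect_equal(sum(mp2 > 0), 1L)
  expect_equal(which(mp2 > 0), 50L)  # tss base falls in the center bin
  # increasing ramp reads decreasing for a minus-strand gene
  ramp <- data.frame(chrom = "chr1",
                     start = seq(47500L, 52400L, by = 100L),
                     end = seq(47600L, 52500L, by = 100L),
                     value = 1:50)
  mpm <- metaprofile(ramp, proms[proms$gene_id == "gm", ], groups["gm"],
                     flank = 2500, bins = 50)
  expect_true(all(diff(as.numeric(mpm)) < 0))
})
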
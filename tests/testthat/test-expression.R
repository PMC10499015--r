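test_that("Fisher's exact test matches enumeration on worked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p.value,
               0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))$p.value,
               2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 2, 2), 2)), "non-negative")
})

test_that("Fisher p and odds ratio agree with stats::fisher.test", {
  set.seed(61)
  for (i in 1:150) {
    x <- matrix(rpois(4, 8), 2)
    mine <- fisher_exact_2x2(x)
    ref <- stats::fisher.test(x)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
    if (is.finite(mine$odds_ratio) && mine$odds_ratio > 0) {
      expect_equal(mine$odds_ratio, unname(ref$estimate), tolerance = 1e-3)
    }
  }
  # boundary tables give 0 / Inf sentinels, as fisher.test does
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 5, 2), 2))$odds_ratio, 0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 2, 7), 2))$odds_ratio, Inf)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(0.03, 10)), rep(0.03, 10))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is monotone in rank and invariant to input order", {
  set.seed(62)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})

test_that("DE filtering uses the stated boundary semantics", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.0, 0.99, -2.0, 1.5),
                   padj = c(0.009, 1e-4, 0.005, 0.01))
  out <- de_filter(de)
  expect_equal(out$gene_id, c("a", "c"))       # lfc >= 1 inclusive,
  expect_equal(out$direction, c("up", "down")) # padj < 0.01 strict
})

test_that("highest stage is the argmax with earliest-stage ties flagged", {
  tpm <- matrix(c(1, 2, 5, 3,  4, 4, 4, 4), 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"),
                                c("P7-GCP", "P7-GC", "P12", "P21")))
  hs <- highest_stage(tpm)
  expect_equal(hs$stage, c("P12", "P7-GCP"))
  expect_equal(hs$tie, c(FALSE, TRUE))
  expect_equal(nrow(highest_stage(tpm, character(0))), 0L)
})

test_that("per-state expression recovers the planted ordering", {
  b <- simulate_bivalency_data(sim_config(seed = 63, n_genes = 1200))
  st <- make_state_table(b$truth$states)
  res <- suppressWarnings(expression_by_state(b$tpm, st, "P7"))
  med <- setNames(res$summary$median, res$summary$state)
  expect_gt(med["K4_ONLY"], med["BIVALENT"])
  expect_gt(med["BIVALENT"], med["K27_ONLY"])
  expect_lt(res$kruskal_p, 1e-10)
  pw <- res$pairwise
  key_pairs <- pw$state1 %in% c("K4_ONLY", "BIVALENT", "K27_ONLY") &
    pw$state2 %in% c("K4_ONLY", "BIVALENT", "K27_ONLY")
  expect_true(all(pw$p_adj[key_pairs] < 0.01))
})

test_that("single-state tables produce summaries without tests", {
  st <- make_state_table(matrix("K4_ONLY", 10, 1,
                                dimnames = list(paste0("g", 1:10), "P7")))
  tpm <- setNames(rlnorm(10), paste0("g", 1:10))
  res <- suppressWarnings(expression_by_state(tpm, st, "P7"))
  expect_equal(nrow(res$summary), 1L)
  expect_null(res$pairwise)
})

test_that("Dunn's z reduces to the classic form without ties", {
  set.seed(64)
  x <- rnorm(60)
  g <- factor(rep(c("a", "b", "c"), each = 20))
  d <- dunn_test(x, g)
  r <- rank(x)
  rb <- tapply(r, g, mean)
  se <- sqrt((60 * 61 / 12) * (1 / 20 + 1 / 20))
  expect_equal(d$z[d$state1 == "a" & d$state2 == "b"],
               unname((rb["a"] - rb["b"]) / se))
})

test_that("DE-by-state proportions and Fisher tests match hand values", {
  genes <- paste0("g", 1:250)
  wide <- matrix(c(rep("BIVALENT", 50), rep("K4_ONLY", 200)), 250, 1,
                 dimnames = list(genes, "P7"))
  st <- make_state_table(wide)
  de <- data.frame(gene_id = genes, log2fc = 0, padj = 1)
  up_biv <- 1:8; down_biv <- 9:10; up_k4 <- 51:55; down_k4 <- 56:60
  de$log2fc[c(up_biv, up_k4)] <- 2
  de$log2fc[c(down_biv, down_k4)] <- -2
  de$padj[c(up_biv, down_biv, up_k4, down_k4)] <- 0.001
  res <- de_by_state(de, st, "P7")
  pb <- res$proportions[res$proportions$state == "BIVALENT", ]
  pk <- res$proportions[res$proportions$state == "K4_ONLY", ]
  expect_equal(c(pb$frac_up, pb$frac_down), c(0.16, 0.04))
  expect_equal(c(pk$frac_up, pk$frac_down), c(0.025, 0.025))
  expect_equal(res$pairwise$p, oracle_fisher_p(8, 2, 5, 5))
  # identical compositions give p = 1
  de2 <- de
  de2$log2fc[up_biv] <- c(2, 2, -2, -2, 0, 0, 0, 0)
  de2$log2fc[down_biv] <- 0
  de2$padj[9:10] <- 1
  res2 <- de_by_state(de2, st, "P7")
  expect_equal(res2$pairwise$p, 1)
})

test_that("planted bivalent up-regulation bias is detected", {
  b <- simulate_bivalency_data(sim_config(seed = 65, n_genes = 5000))
  st <- make_state_table(b$truth$states)
  res <- de_by_state(b$de_treatment, st, "P7")
  pw <- res$pairwise
  biv_vs_mono <- (pw$state1 == "BIVALENT" &
                    pw$state2 %in% c("K4_ONLY", "K27_ONLY")) |
    (pw$state2 == "BIVALENT" & pw$state1 %in% c("K4_ONLY", "K27_ONLY"))
  expect_true(all(pw$p_adj[biv_vs_mono] < 0.05, na.rm = TRUE))
})

test_that("direction concordance counts sign agreement", {
  deA <- data.frame(gene_id = paste0("g", 1:4),
                    log2fc = c(2, 1.5, -2, -1.2), padj = 0.001)
  deB <- data.frame(gene_id = paste0("g", 1:4),
                    log2fc = c(1, -0.5, -0.2, 0.4), padj = 0.5)
  expect_equal(direction_concordance(deA, deB)$fraction, 0.5)
  expect_equal(direction_concordance(deA, deA)$fraction, 1)
  expect_error(direction_concordance(
    deA, data.frame(gene_id = "zz", log2fc = 1, padj = 1)), "overlap")
})

test_that("planted concordance is estimated within a few points", {
  b <- simulate_bivalency_data(sim_config(seed = 66, n_genes = 8000,
                                          de_rate_up = 0.08,
                                          de_rate_down = 0.08))
  cc <- direction_concordance(b$de_treatment, b$de_perturbation)
  expect_gt(cc$n_compared, 500)
  expect_lt(abs(cc$fraction - 0.70), 0.03)
})

test_that("TRAP depletion uses strict thresholds over timepoints", {
  mk <- function(r) {
    input <- matrix(10, 1, 4, dimnames = list("g1", paste0("t", 1:4)))
    list(trap = input * matrix(r, 1), input = input)
  }
  run <- function(r) trap_depletion_filter(mk(r)$trap, mk(r)$input)
  expect_equal(run(c(0.5, 0.5, 0.5, 0.9)), "g1")
  expect_equal(run(c(0.5, 0.7, 0.7, 0.7)), character(0))
  # 0.6 is not < 0.6: still three timepoints below
  expect_equal(run(c(0.59, 0.6, 0.59, 0.59)), "g1")
  # degenerate ratios: 0/0 counts as 1, x/0 as +Inf
  trap <- matrix(c(0, 5, 0, 0), 1, 4, dimnames = list("g1", paste0("t", 1:4)))
  input <- matrix(0, 1, 4, dimnames = list("g1", paste0("t", 1:4)))
  expect_equal(trap_depletion_filter(trap, input), character(0))
  expect_error(trap_depletion_filter(trap, input[, 1:3]), "match")
})

test_that("bivalent TF catalog applies the strict mean-TPM cutoff", {
  wide <- matrix(c("BIVALENT", "K4_ONLY", "BIVALENT",
                   "K4_ONLY", "K4_ONLY", "BIVALENT"), 3, 2,
                 dimnames = list(c("tf1", "tf2", "tf3"), c("P7", "P21")))
  st <- make_state_table(wide)
  tpm <- matrix(c(6, 6, 100, 100, 5, 5), 3, 2, byrow = TRUE,
                dimnames = list(c("tf1", "tf2", "tf3"), c("P7", "P21")))
  expect_equal(bivalent_tf_catalog(st, c("tf1", "tf2", "tf3"), tpm), "tf1")
  # tf2 never bivalent despite high TPM; tf3 bivalent but mean TPM == 5
})
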
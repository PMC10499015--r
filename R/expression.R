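#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the standard probability rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table (within a small
#' relative tolerance for floating-point ties). The reported odds ratio is
#' the conditional maximum-likelihood estimate under Fisher's noncentral
#' hypergeometric distribution, with 0 / `Inf` sentinels at the boundary of
#' the table's support.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @param compute_or also compute the conditional-MLE odds ratio
#'   (default `TRUE`; disable in bulk sweeps where only p is needed).
#' @return list with `p.value` and `odds_ratio` (`NA` when
#'   `compute_or = FALSE`).
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p.value  # ~0.4857
#' @export
fisher_exact_2x2 <- function(x, compute_or = TRUE) {
  x <- as.matrix(x)
  if (!all(dim(x) == 2)) stop("x must be a 2x2 table", call. = FALSE)
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative", call. = FALSE)
  if (any(x != round(x))) stop("counts must be integers", call. = FALSE)
  a <- x[1, 1]; b <- x[1, 2]; c_ <- x[2, 1]; d <- x[2, 2]
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- dens[support == a]
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- NA_real_
  if (compute_or) or <- conditional_or(a, m, n, k)
  list(p.value = p, odds_ratio = or)
}

# Conditional MLE of the odds ratio: psi such that the mean of Fisher's
# noncentral hypergeometric distribution equals the observed count.
#' @noRd
conditional_or <- function(a, m, n, k) {
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (lo == hi) return(NA_real_)  # degenerate support
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  support <- lo:hi
  logdc <- stats::dhyper(support, m, n, k, log = TRUE)
  ncmean <- function(log_psi) {
    w <- logdc + support * log_psi
    w <- exp(w - max(w))
    sum(support * w) / sum(w)
  }
  f <- function(log_psi) ncmean(log_psi) - a
  root <- stats::uniroot(f, lower = -50, upper = 50, tol = 1e-9)
  exp(root$root)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: monotone non-decreasing in rank, capped at 1,
#' returned in the original input order. `NA` values are propagated.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter a differential-expression table to significant genes
#'
#' Boundary semantics follow the stated thresholds exactly: a gene is
#' differentially expressed when `|log2FC| >= lfc_min` (inclusive) and
#' adjusted p `< padj_max` (strict).
#'
#' @param de data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_min minimal absolute log2 fold change (default 1).
#' @param padj_max adjusted-p cutoff, exclusive (default 0.01).
#' @return data.frame `gene_id`, `log2fc`, `padj`, `direction`
#'   (`"up"`/`"down"`).
#' @export
de_filter <- function(de, lfc_min = 1, padj_max = 0.01) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  if (any(de$padj < 0 | de$padj > 1, na.rm = TRUE)) {
    stop("padj must lie in [0, 1]", call. = FALSE)
  }
  keep <- !is.na(de$padj) & !is.na(de$log2fc) &
    abs(de$log2fc) >= lfc_min & de$padj < padj_max
  out <- de[keep, c("gene_id", "log2fc", "padj"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Stage of maximal expression
#'
#' For each gene, the stage with the highest (mean) TPM; ties go to the
#' earliest stage (column order) and are flagged.
#'
#' @param tpm numeric matrix, genes x ordered stages.
#' @param genes optional gene subset (default all rows).
#' @return data.frame `gene_id`, `stage`, `tie`.
#' @export
highest_stage <- function(tpm, genes = rownames(tpm)) {
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(), stage = character(),
                      tie = logical()))
  }
  missing <- setdiff(genes, rownames(tpm))
  if (length(missing)) {
    stop("genes absent from tpm: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
  }
  sub <- tpm[genes, , drop = FALSE]
  idx <- apply(sub, 1, which.max)  # first maximum = earliest stage
  tie <- apply(sub, 1, function(r) sum(r == max(r)) > 1)
  data.frame(gene_id = genes, stage = colnames(tpm)[idx], tie = unname(tie),
             row.names = NULL)
}

#' Expression by promoter state
#'
#' Summarizes expression within each promoter state at one timepoint
#' (n, median, quartiles), tests for an overall state effect with the
#' Kruskal-Wallis rank test, and compares all state pairs with Dunn's post
#' hoc z-test, Benjamini-Hochberg adjusted.
#'
#' @param tpm named numeric vector of expression values, or a genes x stage
#'   matrix containing a column named `timepoint`.
#' @param states a `state_table`.
#' @param timepoint timepoint at which to take states.
#' @return list with `summary` (per-state stats), `kruskal_p`, and
#'   `pairwise` (state pair, z, p, p_adj); `pairwise` is `NULL` when fewer
#'   than 2 states are present (a warning lists skipped states).
#' @export
expression_by_state <- function(tpm, states, timepoint) {
  if (is.matrix(tpm) || is.data.frame(tpm)) {
    if (!timepoint %in% colnames(tpm)) {
      stop("timepoint ", timepoint, " not in tpm columns", call. = FALSE)
    }
    tpm <- setNames(as.matrix(tpm)[, timepoint], rownames(tpm))
  }
  st <- states[states$timepoint == timepoint, ]
  if (nrow(st) == 0) stop("timepoint ", timepoint, " not in states", call. = FALSE)
  st <- st[st$gene_id %in% names(tpm), ]
  x <- tpm[st$gene_id]
  g <- factor(st$state, levels = PROMOTER_STATES)
  present <- levels(g)[table(g) > 0]
  absent <- setdiff(levels(g), present)
  if (length(absent)) {
    warning("states with no genes skipped: ", paste(absent, collapse = ", "))
  }
  g <- factor(as.character(g), levels = present)
  summ <- do.call(rbind, lapply(present, function(s) {
    v <- x[g == s]
    data.frame(state = s, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  rownames(summ) <- NULL
  if (length(present) < 2) {
    return(list(summary = summ, kruskal_p = NA_real_, pairwise = NULL))
  }
  kp <- stats::kruskal.test(x, g)$p.value
  pw <- dunn_test(x, g)
  pw$p_adj <- bh_fdr(pw$p)
  list(summary = summ, kruskal_p = kp, pairwise = pw)
}

#' Dunn's post hoc test
#'
#' Pairwise mean-rank comparisons following a Kruskal-Wallis test: pooled
#' ranks with the tie correction, z statistic
#' `(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups, two-sided normal p.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return data.frame `state1`, `state2`, `z`, `p` (unadjusted).
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(x)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / nn[[i]] + 1 / nn[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(state1 = pairs[1, ], state2 = pairs[2, ],
             z = res["z", ], p = res["p", ], row.names = NULL)
}

#' Differential expression by promoter state
#'
#' For each promoter state at one timepoint: the fraction of its genes
#' up- and down-regulated (denominator = all genes in the state that appear
#' in the DE table), plus pairwise Fisher's exact tests comparing the
#' up-vs-down composition between every pair of states, BH-adjusted. Pairs
#' involving a state with no DE gene are reported as `NA`.
#'
#' @param de DE table (`gene_id`, `log2fc`, `padj`).
#' @param states a `state_table`.
#' @param timepoint timepoint at which to take states.
#' @param lfc_min,padj_max significance thresholds (see [de_filter()]).
#' @return list with `proportions` (state, n, up, down, frac_up, frac_down)
#'   and `pairwise` (state1, state2, odds_ratio, p, p_adj).
#' @export
de_by_state <- function(de, states, timepoint, lfc_min = 1,
                        padj_max = 0.01) {
  st <- states[states$timepoint == timepoint, ]
  if (nrow(st) == 0) stop("timepoint ", timepoint, " not in states", call. = FALSE)
  st <- st[st$gene_id %in% de$gene_id, ]
  if (nrow(st) == 0) stop("no genes shared between DE table and states", call. = FALSE)
  sig <- de_filter(de, lfc_min, padj_max)
  dir <- setNames(sig$direction, sig$gene_id)
  present <- intersect(PROMOTER_STATES, unique(st$state))
  props <- do.call(rbind, lapply(present, function(s) {
    genes <- st$gene_id[st$state == s]
    up <- sum(dir[genes] == "up", na.rm = TRUE)
    down <- sum(dir[genes] == "down", na.rm = TRUE)
    data.frame(state = s, n = length(genes), up = up, down = down,
               frac_up = up / length(genes), frac_down = down / length(genes))
  }))
  rownames(props) <- NULL
  pairwise <- NULL
  if (length(present) >= 2) {
    prs <- utils::combn(present, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      s1 <- prs[1, i]; s2 <- prs[2, i]
      r1 <- props[props$state == s1, ]
      r2 <- props[props$state == s2, ]
      if (r1$up + r1$down < 1 || r2$up + r2$down < 1) {
        return(data.frame(state1 = s1, state2 = s2, odds_ratio = NA_real_,
                          p = NA_real_))
      }
      ft <- fisher_exact_2x2(matrix(c(r1$up, r2$up, r1$down, r2$down), 2))
      data.frame(state1 = s1, state2 = s2, odds_ratio = ft$odds_ratio,
                 p = ft$p.value)
    }))
    pairwise$p_adj <- bh_fdr(pairwise$p)
  }
  list(proportions = props, pairwise = pairwise)
}

#' Directional concordance between two DE tables
#'
#' Among the significant genes of `deA` (after [de_filter()]) that are also
#' present in `deB`, the fraction whose log2 fold change has the same sign
#' in both tables.
#'
#' @param deA,deB DE tables (`gene_id`, `log2fc`, `padj`).
#' @param lfc_min,padj_max thresholds applied to `deA` (and to `deB` when
#'   `require_b_significant`).
#' @param require_b_significant also require significance in `deB`
#'   (default `FALSE`: direction only).
#' @return list with `fraction`, `n_compared`, `n_concordant`.
#' @export
direction_concordance <- function(deA, deB, lfc_min = 1, padj_max = 0.01,
                                  require_b_significant = FALSE) {
  sigA <- de_filter(deA, lfc_min, padj_max)
  b <- if (require_b_significant) de_filter(deB, lfc_min, padj_max) else deB
  m <- merge(sigA[, c("gene_id", "log2fc")],
             b[, c("gene_id", "log2fc")], by = "gene_id",
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no overlapping genes between DE tables", call. = FALSE)
  conc <- sign(m$log2fc_a) == sign(m$log2fc_b) & m$log2fc_b != 0
  list(fraction = mean(conc), n_compared = nrow(m),
       n_concordant = sum(conc))
}

#' TRAP depletion filter
#'
#' Flags genes highly depleted in the cell-type-specific (TRAP) fraction:
#' a gene is excluded when the TRAP/input expression ratio is strictly below
#' `threshold` in at least `min_timepoints` of the timepoints. Degenerate
#' ratios: input 0 with TRAP 0 counts as 1 (not depleted); input 0 with
#' TRAP > 0 counts as +Inf.
#'
#' @param trap,input numeric matrices, genes x timepoints, matching dimnames.
#' @param threshold ratio cutoff, strict (default 0.6).
#' @param min_timepoints minimal number of depleted timepoints (default 3).
#' @return character vector of excluded gene ids.
#' @export
trap_depletion_filter <- function(trap, input, threshold = 0.6,
                                  min_timepoints = 3L) {
  trap <- as.matrix(trap)
  input <- as.matrix(input)
  if (!identical(dim(trap), dim(input)) ||
      !identical(colnames(trap), colnames(input)) ||
      !identical(rownames(trap), rownames(input))) {
    stop("trap and input tables must match in genes and timepoints",
         call. = FALSE)
  }
  ratio <- trap / input
  ratio[input == 0 & trap == 0] <- 1
  ratio[input == 0 & trap > 0] <- Inf
  n_below <- rowSums(ratio < threshold)
  rownames(trap)[n_below >= min_timepoints]
}

#' Bivalent transcription-factor catalog
#'
#' TFs (an externally supplied annotation) whose promoter is bivalent at at
#' least one timepoint and whose mean TPM across stages is strictly greater
#' than `mean_tpm_min`.
#'
#' @param states a `state_table`.
#' @param tf_list character vector of TF gene ids.
#' @param tpm numeric matrix, genes x stages.
#' @param mean_tpm_min mean-TPM cutoff, strict (default 5).
#' @return character vector of gene ids, sorted.
#' @export
bivalent_tf_catalog <- function(states, tf_list, tpm, mean_tpm_min = 5) {
  biv <- unique(states$gene_id[states$state == "BIVALENT"])
  cand <- intersect(tf_list, biv)
  cand <- cand[cand %in% rownames(tpm)]
  mean_tpm <- rowMeans(as.matrix(tpm)[cand, , drop = FALSE])
  sort(cand[mean_tpm > mean_tpm_min])
}
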
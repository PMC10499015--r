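#' Summed coverage in promoter windows
#'
#' For every gene, the sum over bases of per-base coverage within the TSS
#' +/- `flank` window (bases not covered by any bedGraph interval count 0).
#'
#' @param coverage bedGraph data frame (`chrom`, `start`, `end`, `value`;
#'   disjoint intervals) or a path readable by [read_bedgraph()].
#' @param promoters promoter table.
#' @param flank window half-width (default 500).
#' @return named numeric vector, one value per gene.
#' @export
quantify_tss_signal <- function(coverage, promoters, flank = 500L) {
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  coverage <- validate_bedgraph(as.data.frame(coverage))
  wins <- promoter_windows(promoters, flank)
  out <- setNames(numeric(nrow(wins)), wins$gene_id)
  if (nrow(coverage)) {
    ov <- suppress_seqinfo(GenomicRanges::findOverlaps(as_granges(wins), as_granges(coverage)))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      bp <- pmin(wins$end[qi], coverage$end[si]) -
        pmax(wins$start[qi], coverage$start[si])
      contrib <- bp * coverage$value[si]
      agg <- rowsum(contrib, group = qi)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out[promoters$gene_id]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample, the median over
#' genes (restricted to genes with a positive geometric mean across samples)
#' of the ratio count / geometric mean.
#'
#' @param counts numeric matrix, genes x samples, non-negative.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  loggeo <- rowMeans(log(counts))
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    stop("no gene with all-positive counts; size factors undefined",
         call. = FALSE)
  }
  apply(counts, 2, function(col) {
    exp(stats::median((log(col) - loggeo)[usable & col > 0]))
  })
}

#' Bivalency ratio at promoters
#'
#' The log2 ratio of normalized H3K4me3 to H3K27me3 signal at each TSS
#' window: samples of both marks are normalized jointly by median-of-ratios
#' size factors, averaged within mark, and compared with a pseudocount.
#' Positive values indicate H3K4me3 dominance, negative values H3K27me3
#' dominance; the ratio is antisymmetric under swapping the marks.
#'
#' @param k4,k27 numeric matrices (genes x samples) of TSS-window counts for
#'   each mark, with identical rownames (genes).
#' @param pseudocount added to both normalized means (default 1).
#' @param normalize apply joint median-of-ratios normalization (default
#'   `TRUE`); set `FALSE` when the inputs are already normalized.
#' @return named numeric vector of per-gene log2 ratios.
#' @examples
#' bivalency_ratio(matrix(40), matrix(10), normalize = FALSE)  # log2(41/11)
#' @export
bivalency_ratio <- function(k4, k27, pseudocount = 1, normalize = TRUE) {
  k4 <- as.matrix(k4)
  k27 <- as.matrix(k27)
  if (nrow(k4) != nrow(k27) ||
      (!is.null(rownames(k4)) && !identical(rownames(k4), rownames(k27)))) {
    stop("k4 and k27 must cover the same genes in the same order",
         call. = FALSE)
  }
  combined <- cbind(k4, k27)
  norm <- if (normalize) {
    sweep(combined, 2, size_factors(combined), "/")
  } else {
    combined
  }
  m4 <- rowMeans(norm[, seq_len(ncol(k4)), drop = FALSE])
  m27 <- rowMeans(norm[, ncol(k4) + seq_len(ncol(k27)), drop = FALSE])
  setNames(log2((m4 + pseudocount) / (m27 + pseudocount)), rownames(k4))
}

#' Expression quintiles
#'
#' Splits genes into 5 groups by TPM rank (quintile 1 = lowest expression),
#' with group sizes differing by at most one (extra genes go to the lowest
#' quintiles) and ties broken by stable input order.
#'
#' @param tpm numeric vector of expression values (optionally named).
#' @return integer vector of quintile labels 1..5, same order as input.
#' @export
expression_quintiles <- function(tpm) {
  n <- length(tpm)
  if (n < 5) stop("need >= 5 genes for quintiles", call. = FALSE)
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- rep.int(1:5, sizes)
  out <- integer(n)
  out[order(tpm, seq_len(n))] <- q  # stable: ties keep input order
  names(out) <- names(tpm)
  out
}

#' TSS metaprofile
#'
#' Mean coverage around TSSs, binned: for each gene the window
#' `[tss - flank, tss + flank + 1)` is split into `bins` equal-width bins of
#' mean per-base coverage; minus-strand genes are reversed so bin 1 is
#' always the 5' side; genes are then averaged within each group.
#'
#' @param coverage bedGraph data frame or path.
#' @param promoters promoter table.
#' @param groups named character vector, gene_id -> group label (genes not
#'   listed are skipped).
#' @param flank window half-width (default 2500).
#' @param bins number of bins (default 100).
#' @return matrix of class `metaprofile`, groups x bins.
#' @export
metaprofile <- function(coverage, promoters, groups, flank = 2500L,
                        bins = 100L) {
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  coverage <- validate_bedgraph(as.data.frame(coverage))
  promoters <- promoters[promoters$gene_id %in% names(groups), , drop = FALSE]
  if (nrow(promoters) == 0) stop("no promoter matches groups", call. = FALSE)
  L <- 2L * as.integer(flank) + 1L
  bin_of <- 1L + as.integer(floor((seq_len(L) - 1L) * bins / L))
  labels <- sort(unique(groups))
  acc <- matrix(0, length(labels), bins, dimnames = list(labels, NULL))
  cnt <- setNames(integer(length(labels)), labels)

  cov_by_chr <- split(coverage, coverage$chrom)
  for (i in seq_len(nrow(promoters))) {
    tss <- promoters$tss[i]
    w0 <- tss - flank  # may be negative; out-of-range bases count 0
    base <- numeric(L)
    cc <- cov_by_chr[[promoters$chrom[i]]]
    if (!is.null(cc)) {
      sel <- cc$end > w0 & cc$start < w0 + L
      for (j in which(sel)) {
        a <- max(cc$start[j], w0) - w0 + 1L
        b <- min(cc$end[j], w0 + L) - w0
        if (b >= a) base[a:b] <- cc$value[j]
      }
    }
    if (promoters$strand[i] == "-") base <- rev(base)
    prof <- rowsum(base, bin_of) / tabulate(bin_of, bins)
    g <- groups[[promoters$gene_id[i]]]
    acc[g, ] <- acc[g, ] + as.numeric(prof)
    cnt[g] <- cnt[g] + 1L
  }
  keep <- cnt > 0
  out <- acc[keep, , drop = FALSE] / cnt[keep]
  structure(out, flank = flank, bins = bins, n_genes = cnt[keep],
            class = c("metaprofile", "matrix"))
}

#' @export
plot.metaprofile <- function(x, ...) {
  flank <- attr(x, "flank")
  pos <- seq(-flank, flank, length.out = ncol(x))
  graphics::matplot(pos, t(unclass(x)), type = "l", lty = 1,
                    xlab = "distance from TSS (bp)", ylab = "mean coverage",
                    ...)
  graphics::legend("topright", legend = rownames(x), lty = 1,
                   col = seq_len(nrow(x)), bty = "n")
  invisible(x)
}
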
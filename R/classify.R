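#' Promoter chromatin states
#'
#' The five mutually exclusive promoter states used throughout the package:
#' `K4_ONLY` (H3K4me3 only), `BIVALENT` (overlapping H3K4me3 and H3K27me3
#' peaks at the promoter), `K27_ONLY`, `DUAL_NONOVERLAP` (both marks at the
#' promoter but no pair of peaks overlaps) and `NONE`.
#'
#' @export
PROMOTER_STATES <- c("K4_ONLY", "BIVALENT", "K27_ONLY", "DUAL_NONOVERLAP",
                     "NONE")

#' Classify one promoter window
#'
#' A promoter is `BIVALENT` when some H3K4me3 peak and some H3K27me3 peak
#' each overlap the TSS window (by >= 1 bp) and also overlap each other
#' (>= 1 bp). When both marks hit the window but no pair of peaks overlaps,
#' the call depends on `dual_policy`: `"separate"` (default, strict reading)
#' labels it `DUAL_NONOVERLAP`; `"bivalent"` folds it into `BIVALENT`.
#'
#' @param k4,k27 consensus peak sets (peak_set or interval data frame) for
#'   one timepoint.
#' @param window 1-row data frame with `chrom`, `start`, `end` (the TSS
#'   window from [promoter_window()]).
#' @param dual_policy `"separate"` or `"bivalent"`.
#' @return A state string (one of [PROMOTER_STATES]).
#' @export
classify_promoter <- function(k4, k27, window,
                              dual_policy = c("separate", "bivalent")) {
  dual_policy <- match.arg(dual_policy)
  k4 <- peak_intervals(k4)
  k27 <- peak_intervals(k27)
  w4 <- overlapping_rows(k4, window)
  w27 <- overlapping_rows(k27, window)
  if (nrow(w4) == 0 && nrow(w27) == 0) return("NONE")
  if (nrow(w27) == 0) return("K4_ONLY")
  if (nrow(w4) == 0) return("K27_ONLY")
  pair <- any(outer(seq_len(nrow(w4)), seq_len(nrow(w27)),
                    function(i, j) w4$chrom[i] == w27$chrom[j] &
                      w4$start[i] < w27$end[j] & w27$start[j] < w4$end[i]))
  if (pair) return("BIVALENT")
  if (dual_policy == "bivalent") "BIVALENT" else "DUAL_NONOVERLAP"
}

#' @noRd
overlapping_rows <- function(df, window) {
  if (nrow(df) == 0) return(df)
  hit <- df$chrom == window$chrom[1] & df$start < window$end[1] &
    window$start[1] < df$end
  df[hit, , drop = FALSE]
}

#' Classify every promoter at every timepoint
#'
#' Builds the gene x timepoint state table from consensus peak sets. Every
#' gene in the promoter table receives exactly one state per timepoint
#' (the states partition the gene set).
#'
#' @param promoters promoter table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param peaks nested list `peaks[[mark]][[timepoint]]` of consensus peak
#'   sets; both `"H3K4me3"` and `"H3K27me3"` must be present for every
#'   timepoint.
#' @param flank TSS window half-width in bases (default 500).
#' @param dual_policy see [classify_promoter()].
#' @param timepoints ordered timepoint labels; default the timepoints found
#'   under the H3K4me3 entry.
#' @return A `state_table`: data frame (`gene_id`, `timepoint`, `state`)
#'   with the ordered timepoints, flank and dual policy stored as
#'   attributes.
#' @export
classify_all <- function(promoters, peaks, flank = 500L,
                         dual_policy = c("separate", "bivalent"),
                         timepoints = NULL) {
  dual_policy <- match.arg(dual_policy)
  for (m in c("H3K4me3", "H3K27me3")) {
    if (is.null(peaks[[m]])) stop("missing mark: ", m, call. = FALSE)
  }
  if (is.null(timepoints)) timepoints <- names(peaks[["H3K4me3"]])
  for (m in c("H3K4me3", "H3K27me3")) {
    miss <- setdiff(timepoints, names(peaks[[m]]))
    if (length(miss)) {
      stop("missing consensus peaks for ", m, " at ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  wins <- promoter_windows(promoters, flank)
  res <- lapply(timepoints, function(tp) {
    st <- classify_timepoint(wins, peak_intervals(peaks[["H3K4me3"]][[tp]]),
                             peak_intervals(peaks[["H3K27me3"]][[tp]]),
                             dual_policy)
    data.frame(gene_id = promoters$gene_id, timepoint = tp,
               state = st[promoters$gene_id], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, timepoints = timepoints, flank = as.integer(flank),
            dual_policy = dual_policy,
            class = c("state_table", "data.frame"))
}

# Vectorized classification of all windows against one timepoint's peaks.
#' @noRd
classify_timepoint <- function(wins, k4, k27, dual_policy) {
  gw <- as_granges(wins)
  state <- rep("NONE", nrow(wins))
  names(state) <- wins$gene_id
  hit4 <- hit27 <- NULL
  if (nrow(k4)) {
    g4 <- as_granges(k4)
    hit4 <- suppress_seqinfo(GenomicRanges::findOverlaps(gw, g4))
  }
  if (nrow(k27)) {
    g27 <- as_granges(k27)
    hit27 <- suppress_seqinfo(GenomicRanges::findOverlaps(gw, g27))
  }
  has4 <- if (is.null(hit4)) logical(nrow(wins)) else
    seq_len(nrow(wins)) %in% S4Vectors::queryHits(hit4)
  has27 <- if (is.null(hit27)) logical(nrow(wins)) else
    seq_len(nrow(wins)) %in% S4Vectors::queryHits(hit27)
  state[has4 & !has27] <- "K4_ONLY"
  state[!has4 & has27] <- "K27_ONLY"
  both <- which(has4 & has27)
  if (length(both)) {
    # gene is BIVALENT iff some window-hitting K4 peak overlaps some
    # window-hitting K27 peak
    pair <- suppress_seqinfo(GenomicRanges::findOverlaps(g4, g27))
    d4 <- data.frame(win = S4Vectors::queryHits(hit4),
                     p4 = S4Vectors::subjectHits(hit4))
    d27 <- data.frame(win = S4Vectors::queryHits(hit27),
                      p27 = S4Vectors::subjectHits(hit27))
    dp <- data.frame(p4 = S4Vectors::queryHits(pair),
                     p27 = S4Vectors::subjectHits(pair))
    j <- merge(merge(d4, dp, by = "p4"), d27, by = c("win", "p27"))
    biv <- intersect(both, unique(j$win))
    dual <- setdiff(both, biv)
    state[biv] <- "BIVALENT"
    state[dual] <- if (dual_policy == "bivalent") "BIVALENT" else
      "DUAL_NONOVERLAP"
  }
  state
}

#' Per-timepoint state counts
#' @param states a `state_table`.
#' @return matrix of counts, states x timepoints.
#' @export
state_counts <- function(states) {
  tps <- attr(states, "timepoints")
  table(factor(states$state, levels = PROMOTER_STATES),
        factor(states$timepoint, levels = tps))
}

#' @export
print.state_table <- function(x, ...) {
  tps <- attr(x, "timepoints")
  cat("<state_table> ", length(unique(x$gene_id)), " genes x ",
      length(tps), " timepoints (flank ", attr(x, "flank"), " bp, dual policy '",
      attr(x, "dual_policy"), "')\n", sep = "")
  print(state_counts(x))
  invisible(x)
}

#' Genome-wide bivalent regions
#'
#' Pairwise intersections of H3K4me3 and H3K27me3 consensus peaks: the
#' regions where the two marks overlap, each annotated with the widths of
#' its parent peaks.
#'
#' @param k4,k27 consensus peak sets (peak_set or interval data frame).
#' @return interval data frame with `k4_width` and `k27_width` columns.
#' @export
bivalent_regions <- function(k4, k27) {
  k4 <- merge_intervals(peak_intervals(k4))
  k27 <- merge_intervals(peak_intervals(k27))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), k4_width = integer(),
                      k27_width = integer())
  if (nrow(k4) == 0 || nrow(k27) == 0) return(empty)
  g4 <- as_granges(k4)
  g27 <- as_granges(k27)
  ov <- suppress_seqinfo(GenomicRanges::findOverlaps(g4, g27))
  if (length(ov) == 0) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  pieces <- IRanges::pintersect(g4[qi], g27[si])
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = GenomicRanges::start(pieces) - 1L,
    end = GenomicRanges::end(pieces),
    k4_width = k4$end[qi] - k4$start[qi],
    k27_width = k27$end[si] - k27$start[si],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate regions by genomic category
#'
#' Assigns each region one category by the position of its midpoint, with
#' precedence promoter > gene body > intergenic. A simplified annotator:
#' the promoter category is the TSS +/- `flank` window.
#'
#' @param regions interval data frame.
#' @param promoters promoter table.
#' @param gene_bodies optional interval data frame of gene bodies.
#' @param flank promoter window half-width (default 500).
#' @return list with `regions` (input plus `category` column) and
#'   `fractions` (named proportions over categories).
#' @export
annotate_regions <- function(regions, promoters, gene_bodies = NULL,
                             flank = 500L) {
  cats <- c("promoter", "gene_body", "intergenic")
  if (nrow(regions) == 0) {
    regions$category <- character(0)
    return(list(regions = regions,
                fractions = setNames(rep(NA_real_, 3), cats)))
  }
  mid <- (regions$start + regions$end) %/% 2L
  mids <- data.frame(chrom = regions$chrom, start = mid, end = mid + 1L)
  inside <- function(targets) {
    if (is.null(targets) || nrow(targets) == 0) return(logical(nrow(mids)))
    ov <- suppress_seqinfo(GenomicRanges::findOverlaps(as_granges(mids), as_granges(targets)))
    seq_len(nrow(mids)) %in% S4Vectors::queryHits(ov)
  }
  category <- rep("intergenic", nrow(regions))
  category[inside(gene_bodies)] <- "gene_body"
  category[inside(promoter_windows(promoters, flank))] <- "promoter"
  regions$category <- category
  frac <- prop.table(table(factor(category, levels = cats)))
  list(regions = regions, fractions = c(frac))
}
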
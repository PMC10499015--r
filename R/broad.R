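#' Merge nearby peaks
#'
#' Peaks separated by a gap (next start minus previous end, in the 0-based
#' half-open convention) strictly less than `max_gap` are merged
#' transitively; widths are recomputed. The default reproduces the
#' "peaks closer than 1 kb are merged" preprocessing used before broad-domain
#' detection.
#'
#' @param peaks peak_set or interval data frame.
#' @param max_gap merge when gap < this many bases (default 1000).
#' @return merged interval data frame (peak_set in, peak_set out).
#' @export
merge_close_peaks <- function(peaks, max_gap = 1000L) {
  iv <- merge_intervals(peak_intervals(peaks), max_gap = as.integer(max_gap))
  if (inherits(peaks, "peak_set")) {
    out <- peaks
    out$intervals <- as.data.frame(iv)
    out
  } else {
    iv
  }
}

#' Elbow point of a descending curve
#'
#' The classic geometric knee detector: for points `(rank, width)` with
#' widths sorted descending, returns the rank maximizing the perpendicular
#' distance to the chord joining the first and last point. Ties are broken
#' by the smallest rank. All ranks strictly before the returned index lie on
#' the "broad" side of the cutoff.
#'
#' The argmax is invariant to uniform rescaling of the widths (the chord
#' denominator does not depend on the rank).
#'
#' @param widths numeric vector, >= 3 values, sorted descending.
#' @return integer rank index of the elbow.
#' @export
elbow_point <- function(widths) {
  n <- length(widths)
  if (n < 3) stop("need >= 3 values for an elbow point", call. = FALSE)
  if (any(diff(widths) > 0)) {
    stop("widths must be sorted in descending order", call. = FALSE)
  }
  x <- seq_len(n)
  # distance from (x_i, y_i) to the line through (1, y_1) and (n, y_n),
  # up to the constant chord length
  num <- abs((widths[n] - widths[1]) * (x - 1) -
               (n - 1) * (widths - widths[1]))
  which.max(num)  # ties -> smallest rank
}

#' Broad vs typical H3K4me3 peaks
#'
#' Ranks merged peaks by width (descending) and splits them at the elbow
#' point of the rank-width curve: ranks strictly before the elbow are
#' "broad", the rest "typical". In the degenerate case where the curve is a
#' straight line (all perpendicular distances zero, e.g. identical widths),
#' the elbow lands at rank 1 and the single widest peak is called broad;
#' this documented convention keeps the output a partition. Each broad peak
#' is annotated with the genes whose promoter window it overlaps.
#'
#' @param peaks merged peak set (see [merge_close_peaks()]).
#' @param promoters promoter table.
#' @param flank promoter window half-width for gene annotation (default 500).
#' @return list with `broad` and `typical` interval data frames (a partition
#'   of the input), `elbow` (rank index), `widths` (sorted descending) and
#'   `genes` (data frame gene_id x broad peak coordinates).
#' @export
classify_broad <- function(peaks, promoters, flank = 500L) {
  iv <- peak_intervals(peaks)
  if (nrow(iv) < 3) stop("need >= 3 peaks", call. = FALSE)
  iv$width <- iv$end - iv$start
  ord <- order(-iv$width, iv$chrom, iv$start)  # deterministic tie order
  iv <- iv[ord, , drop = FALSE]
  rownames(iv) <- NULL
  k <- elbow_point(iv$width)
  n_broad <- if (k == 1L) 1L else k - 1L
  broad <- iv[seq_len(n_broad), , drop = FALSE]
  typical <- iv[setdiff(seq_len(nrow(iv)), seq_len(n_broad)), , drop = FALSE]
  rownames(typical) <- NULL

  wins <- promoter_windows(promoters, flank)
  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), width = integer())
  if (nrow(broad) && nrow(wins)) {
    ov <- suppress_seqinfo(GenomicRanges::findOverlaps(as_granges(broad), as_granges(wins)))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      genes <- data.frame(gene_id = wins$gene_id[S4Vectors::subjectHits(ov)],
                          chrom = broad$chrom[qi], start = broad$start[qi],
                          end = broad$end[qi], width = broad$width[qi],
                          stringsAsFactors = FALSE)
      genes <- genes[order(genes$gene_id), , drop = FALSE]
      rownames(genes) <- NULL
    }
  }
  list(broad = broad, typical = typical, elbow = k,
       widths = iv$width, genes = genes)
}
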
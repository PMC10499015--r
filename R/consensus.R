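#' Consensus peaks across replicates
#'
#' Collapses replicate peak calls for one mark at one timepoint into a single
#' consensus set by base-resolution majority voting: each replicate
#' contributes 0/1 support per base (after merging its own overlapping
#' peaks), and maximal runs of bases supported by at least `min_support`
#' replicates become consensus intervals. The default `min_support` is the
#' strict majority `floor(n/2) + 1`, so peaks found in the majority of
#' replicates are retained (for n = 2 both replicates are required).
#'
#' @param peaksets list of [peak_set()] objects (or bare interval data
#'   frames) for one mark x timepoint.
#' @param min_support minimal number of supporting replicates per base;
#'   default strict majority.
#' @param min_width drop consensus runs shorter than this many bases
#'   (default 1, i.e. keep everything).
#' @return A [peak_set()] with the consensus intervals (mark/timepoint
#'   inherited when the inputs are peak_set objects).
#' @examples
#' reps <- list(
#'   genomic_intervals("chr1", 0, 100),
#'   genomic_intervals("chr1", 50, 150),
#'   genomic_intervals("chr1", 60, 90)
#' )
#' consensus_peaks(reps)$intervals  # [50, 100)
#' @export
consensus_peaks <- function(peaksets, min_support = NULL, min_width = 1L) {
  if (length(peaksets) == 0) stop("need at least one replicate", call. = FALSE)
  is_ps <- vapply(peaksets, inherits, logical(1), "peak_set")
  mark <- timepoint <- NULL
  if (any(is_ps)) {
    marks <- unique(vapply(peaksets[is_ps], `[[`, "", "mark"))
    tps <- unique(vapply(peaksets[is_ps], `[[`, "", "timepoint"))
    if (length(marks) > 1 || length(tps) > 1) {
      stop("replicates mix marks or timepoints: ",
           paste(marks, collapse = "/"), " @ ", paste(tps, collapse = "/"),
           call. = FALSE)
    }
    mark <- marks
    timepoint <- tps
  }
  n <- length(peaksets)
  if (is.null(min_support)) min_support <- n %/% 2L + 1L
  min_support <- as.integer(min_support)
  if (min_support < 1 || min_support > n) {
    stop("min_support must be in 1..", n, call. = FALSE)
  }

  merged <- lapply(peaksets, function(p) merge_intervals(peak_intervals(p)))
  nonempty <- merged[vapply(merged, nrow, 0L) > 0]
  if (length(nonempty) < min_support) {
    out <- genomic_intervals()
  } else {
    # replicates may cover disjoint chromosome sets; combining is intended
    grl <- suppressWarnings(do.call(c, lapply(nonempty, as_granges)))
    cov <- GenomicRanges::coverage(grl)
    runs <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    out <- do.call(rbind, lapply(names(runs), function(ch) {
      r <- runs[[ch]]
      if (length(r) == 0) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    }))
    if (is.null(out)) out <- genomic_intervals()
    out <- sort_intervals(out)
    if (min_width > 1 && nrow(out)) {
      out <- out[(out$end - out$start) >= min_width, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  if (is.null(mark)) {
    structure(list(intervals = as.data.frame(out), mark = NA_character_,
                   timepoint = NA_character_, replicate = NULL,
                   min_support = min_support, n_replicates = n),
              class = "peak_set")
  } else {
    ps <- peak_set(as.data.frame(out), mark, timepoint)
    ps$min_support <- min_support
    ps$n_replicates <- n
    ps
  }
}
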
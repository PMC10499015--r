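#' Genomic intervals in BED convention
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `name` and `score`. Coordinates are 0-based, half-open
#' `[start, end)` -- the BED convention -- everywhere inside the package;
#' conversion to the 1-based closed convention happens only at the
#' GenomicRanges boundary, internally.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions (>= 0).
#' @param end integer vector, 0-based exclusive end positions (> start).
#' @param name optional character vector of labels.
#' @param score optional non-negative numeric vector.
#' @param sort sort by (chrom, start, end)? Default `TRUE`.
#'
#' @return A `data.frame` with class `genomic_intervals` prepended, sorted by
#'   (chrom, start, end) unless `sort = FALSE`.
#' @examples
#' genomic_intervals(c("chr1", "chr1"), c(0L, 50L), c(100L, 150L))
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = NULL, score = NULL,
                              sort = TRUE) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length", call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  if (sort && n > 1) df <- sort_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' @noRd
validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$chrom)) {
    stop(what, " table contains missing coordinates", call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(what, " start positions must be >= 0", call. = FALSE)
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(what, " with start >= end at row ", bad[1],
         " (", df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")",
         call. = FALSE)
  }
  invisible(df)
}

#' @noRd
sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# 0-based half-open -> GRanges (1-based closed) and back. Internal only.
#' @noRd
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' @noRd
granges_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  sort_intervals(df)
}

#' Merge overlapping or bookended intervals
#'
#' Collapses a set of intervals into its union: overlapping intervals (and,
#' optionally, intervals closer than `max_gap`) are fused.
#'
#' @param df interval data frame (`chrom`, `start`, `end`).
#' @param max_gap merge intervals whose gap (`next start - previous end`) is
#'   strictly less than this many bases. `0` (default) merges only
#'   overlapping/bookended runs of bases, i.e. the plain union.
#' @return Sorted, disjoint interval data frame.
#' @export
merge_intervals <- function(df, max_gap = 0L) {
  validate_intervals(df)
  if (nrow(df) == 0) {
    return(genomic_intervals())
  }
  # merged iff gap < max(max_gap, 1): plain union (max_gap = 0) also fuses
  # bookended runs, matching per-base semantics; for max_gap > 0 the
  # "distance < max_gap" rule is strict, so a gap of exactly max_gap stays
  gr <- GenomicRanges::reduce(as_granges(df),
                              min.gapwidth = max(as.integer(max_gap), 1L))
  out <- granges_to_df(gr)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Total width of an interval set
#' @param df interval data frame.
#' @return Integer, sum of `end - start`.
#' @export
interval_width <- function(df) {
  if (nrow(df) == 0) return(0L)
  sum(df$end - df$start)
}

#' Promoter window around a TSS
#'
#' The +/-`flank` bp window around a transcription start site, as the
#' half-open interval `[max(0, tss - flank), tss + flank + 1)`. The window is
#' symmetric about the TSS base (width `2 * flank + 1` away from the
#' chromosome start) and therefore strand-independent.
#'
#' @param tss integer vector of 0-based TSS positions.
#' @param flank bases on each side of the TSS (default 500, giving the
#'   TSS +/- 500 bp window used for promoter-state calls).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   one row per TSS.
#' @examples
#' promoter_window(1000)      # [500, 1501)
#' promoter_window(200, 500)  # clamped at 0: [0, 701)
#' @export
promoter_window <- function(tss, flank = 500L) {
  tss <- as.integer(tss)
  if (anyNA(tss) || any(tss < 0)) stop("tss must be >= 0", call. = FALSE)
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  data.frame(start = pmax(0L, tss - as.integer(flank)),
             end = tss + as.integer(flank) + 1L)
}

#' Promoter windows for a promoter table
#' @param promoters promoter table (see [read_tss_table()]).
#' @param flank bases on each side of the TSS.
#' @return interval data frame with a `gene_id` column.
#' @export
promoter_windows <- function(promoters, flank = 500L) {
  w <- promoter_window(promoters$tss, flank)
  df <- data.frame(chrom = promoters$chrom, start = w$start, end = w$end,
                   gene_id = promoters$gene_id, stringsAsFactors = FALSE)
  sort_intervals(df)
}

#' Replicate peak set
#'
#' A set of peak intervals for one histone mark at one developmental
#' timepoint, optionally for one replicate.
#'
#' @param intervals interval data frame.
#' @param mark histone mark, `"H3K4me3"` or `"H3K27me3"`.
#' @param timepoint stage label (e.g. `"P7"`).
#' @param replicate optional replicate identifier.
#' @return A `peak_set` object.
#' @export
peak_set <- function(intervals, mark, timepoint, replicate = NULL) {
  mark <- match.arg(mark, c("H3K4me3", "H3K27me3"))
  validate_intervals(intervals, "peak")
  structure(
    list(intervals = sort_intervals(as.data.frame(intervals)),
         mark = mark, timepoint = as.character(timepoint),
         replicate = replicate),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", x$mark, " @ ", x$timepoint,
      if (!is.null(x$replicate)) paste0(" (rep ", x$replicate, ")"),
      ": ", nrow(x$intervals), " peaks, ",
      interval_width(x$intervals), " bp total\n", sep = "")
  invisible(x)
}

# Accept either a peak_set or a bare interval data frame.
#' @noRd
peak_intervals <- function(x) {
  if (inherits(x, "peak_set")) x$intervals else as.data.frame(x)
}

# findOverlaps warns when query and subject share no chromosome; disjoint
# chromosome sets are a legitimate situation here (coverage restricted to a
# subset of chromosomes), so the warning is muffled.
#' @noRd
suppress_seqinfo <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
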
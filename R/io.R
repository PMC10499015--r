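#' Read a BED file
#'
#' Reads BED3+ into a sorted interval data frame. `track`, `browser` and `#`
#' comment lines are skipped. Coordinates are kept in the file's native
#' 0-based half-open convention.
#'
#' @param path file path.
#' @return `genomic_intervals` data frame (columns `chrom`, `start`, `end`,
#'   plus `name`/`score` when present in the file).
#' @export
read_bed <- function(path) {
  lines <- read_data_lines(path)
  if (nrow(lines) == 0) return(genomic_intervals())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lines$lineno[which(nf < 3)[1]]
    stop("BED parse error at line ", bad, ": fewer than 3 fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), lines$lineno, "start")
  end <- parse_coord(vapply(fields, `[[`, "", 3L), lines$lineno, "end")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", lines$lineno[bad[1]],
         ": start >= end", call. = FALSE)
  }
  name <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else NULL
  genomic_intervals(chrom, start, end, name = name, score = score)
}

#' @noRd
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  lineno <- seq_along(txt)
  keep <- !grepl("^(#|track\\b|browser\\b)", txt) & nzchar(trimws(txt))
  data.frame(lineno = lineno[keep], text = txt[keep], stringsAsFactors = FALSE)
}

#' @noRd
parse_coord <- function(x, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | as.character(v) != sub("^\\+", "", x))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": non-integer ", what,
         " '", x[bad[1]], "'", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("BED parse error at line ", lineno[which(v < 0)[1]],
         ": negative ", what, call. = FALSE)
  }
  v
}

#' Read an ENCODE narrowPeak file
#'
#' 10-column narrowPeak. The `signalValue` column (7) is stored as `score`;
#' the summit offset (column 10) is kept as `summit` when >= 0 and recorded
#' as `NA` when the file stores -1 (summit absent).
#'
#' @param path file path.
#' @return `genomic_intervals` data frame with `name`, `score` (signalValue)
#'   and `summit` columns.
#' @export
read_narrowpeak <- function(path) {
  lines <- read_data_lines(path)
  if (nrow(lines) == 0) return(genomic_intervals())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10)) {
    bad <- lines$lineno[which(nf != 10)[1]]
    stop("narrowPeak parse error at line ", bad,
         ": expected 10 columns, found ", nf[which(nf != 10)[1]],
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), lines$lineno, "start")
  end <- parse_coord(vapply(fields, `[[`, "", 3L), lines$lineno, "end")
  if (any(start >= end)) {
    stop("narrowPeak parse error at line ",
         lines$lineno[which(start >= end)[1]], ": start >= end", call. = FALSE)
  }
  df <- genomic_intervals(
    chrom, start, end,
    name = vapply(fields, `[[`, "", 4L),
    score = as.numeric(vapply(fields, `[[`, "", 7L)),
    sort = FALSE
  )
  summit <- as.integer(vapply(fields, `[[`, "", 10L))
  summit[summit < 0] <- NA_integer_
  df$summit <- summit
  df <- sort_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a promoter (TSS) table
#'
#' Accepts either a TSV with header columns `gene_id`, `chrom`, `tss`,
#' `strand` (tss is the 0-based position of the first transcribed base) or a
#' headerless BED6 file, in which case the TSS is `start` for `+` genes and
#' `end - 1` for `-` genes.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"tsv"` or `"bed6"`.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`;
#'   one row per gene, `gene_id` unique.
#' @export
read_tss_table <- function(path, format = c("auto", "tsv", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("gene_id", first)) "tsv" else "bed6"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(tab))) {
      stop("TSS table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(gene_id = as.character(tab$gene_id),
                      chrom = as.character(tab$chrom),
                      tss = as.integer(tab$tss),
                      strand = as.character(tab$strand),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("BED6 TSS file needs 6 columns", call. = FALSE)
    out <- data.frame(gene_id = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      tss = ifelse(tab[[6]] == "+", as.integer(tab[[2]]),
                                   as.integer(tab[[3]]) - 1L),
                      strand = as.character(tab[[6]]),
                      stringsAsFactors = FALSE)
  }
  promoter_table(out)
}

#' Construct/validate a promoter table
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @return validated promoter table (rownames dropped).
#' @export
promoter_table <- function(df) {
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id in promoter table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$tss) || any(df$tss < 0)) {
    stop("tss must be a non-negative integer", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Emits deterministic ordering (chromosome lexicographic, then start) with a
#' leading `#` header comment naming the columns, so that
#' `read_bed(write_bed(x))` round-trips sorted interval sets.
#'
#' @param df interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  df <- sort_intervals(as.data.frame(df))
  cols <- c("chrom", "start", "end")
  if (!is.null(df$score) && is.null(df$name)) df$name <- "."
  if (!is.null(df$name)) cols <- c(cols, "name")
  if (!is.null(df$score)) cols <- c(cols, "score")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' 4 columns: chrom, start, end, value (0-based half-open). Intervals must be
#' disjoint within each chromosome; overlapping intervals are an error since
#' per-base coverage would be ambiguous.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`, `value`, sorted.
#' @export
read_bedgraph <- function(path) {
  lines <- read_data_lines(path)
  if (nrow(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop("bedGraph parse error at line ",
         lines$lineno[which(lengths(fields) < 4)[1]],
         ": fewer than 4 fields", call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = parse_coord(vapply(fields, `[[`, "", 2L), lines$lineno, "start"),
    end = parse_coord(vapply(fields, `[[`, "", 3L), lines$lineno, "end"),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  validate_bedgraph(df)
}

#' @noRd
validate_bedgraph <- function(df) {
  validate_intervals(df, "bedGraph")
  df <- sort_intervals(df)
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)])) {
    stop("bedGraph intervals overlap; per-base coverage is ambiguous",
         call. = FALSE)
  }
  df
}

#' Write a bedGraph coverage track
#' @param df data.frame `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  df <- validate_bedgraph(df)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tvalue", con)
  if (nrow(df)) {
    write.table(format_num_df(df[, c("chrom", "start", "end", "value")]),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Deterministic numeric formatting for byte-stable writers.
#' @noRd
format_num_df <- function(df, digits = 6) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  df
}

#' Write a table as TSV with a deterministic format
#' @param df data.frame.
#' @param path output path.
#' @param digits significant digits for doubles.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, digits = 6) {
  write.table(format_num_df(as.data.frame(df), digits), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
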
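#' Row z-scores of a metacell matrix
#'
#' Scales each gene's normalized counts across cell types to z-scores
#' (sample standard deviation, denominator n - 1). Zero-variance rows are
#' set to all-zero and flagged.
#'
#' @param metacells numeric matrix, genes x cell types (>= 2 columns).
#' @return z-score matrix with attribute `zero_variance` (logical per gene).
#' @export
zscore_matrix <- function(metacells) {
  m <- as.matrix(metacells)
  if (ncol(m) < 2) stop("need >= 2 cell types", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- sdv == 0 | is.na(sdv)
  sdv[zero] <- 1
  z <- (m - mu) / sdv
  z[zero, ] <- 0
  attr(z, "zero_variance") <- zero
  z
}

#' Call cell-type marker genes
#'
#' For each cell type, candidate markers are the genes whose maximal
#' z-score is attained at that type (so marker lists are disjoint by
#' construction) with a positive z, and whose top z is at least `ratio_min`
#' times the gene's second-highest z. The ratio rule only applies when the
#' second-highest z is positive (a ratio of negative z-scores is
#' meaningless), so a gene whose signal is confined to one cell type passes
#' automatically. Surviving candidates are sorted by z descending and cut
#' at the elbow point of the sorted curve (see [elbow_point()]); ranks up
#' to and including the elbow are retained -- on marker-like curves the
#' maximal-distance point is the corner vertex at the end of the
#' high-z limb, i.e. the last marker, so the cutoff is inclusive. The two
#' rules are therefore conjunctive (a gene must pass both). Cell types
#' with fewer than 3 candidates skip the elbow cut (ratio rule alone, with
#' a warning).
#'
#' @param z z-score matrix from [zscore_matrix()].
#' @param ratio_min top-to-second z ratio (default 1.5).
#' @return A `marker_catalog`: data frame `cell_type`, `gene_id`, `z`,
#'   `rank`, with per-type elbow indices stored in the `elbow` attribute.
#' @export
call_markers <- function(z, ratio_min = 1.5) {
  z <- as.matrix(z)
  if (is.null(rownames(z))) stop("z must have gene rownames", call. = FALSE)
  top_idx <- max.col(z, ties.method = "first")
  ord2 <- apply(z, 1, function(r) sort(r, decreasing = TRUE)[2])
  top <- z[cbind(seq_len(nrow(z)), top_idx)]
  types <- colnames(z)
  if (is.null(types)) types <- paste0("type", seq_len(ncol(z)))
  out <- list()
  elbows <- setNames(rep(NA_integer_, length(types)), types)
  pass_ratio <- ord2 <= 0 | top >= ratio_min * ord2
  for (ci in seq_along(types)) {
    cand <- which(top_idx == ci & top > 0 & pass_ratio)
    if (length(cand) == 0) next
    o <- cand[order(-top[cand], rownames(z)[cand])]
    zc <- top[o]
    if (length(o) >= 3) {
      k <- elbow_point(zc)
      elbows[ci] <- k
      o <- o[seq_len(k)]
    } else {
      warning("cell type ", types[ci], " has < 3 candidates; ",
              "elbow cut skipped, ratio rule alone applies")
    }
    if (length(o)) {
      out[[types[ci]]] <- data.frame(
        cell_type = types[ci], gene_id = rownames(z)[o], z = top[o],
        rank = seq_along(o), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_type = character(), gene_id = character(),
               z = numeric(), rank = integer())
  rownames(res) <- NULL
  structure(res, elbow = elbows, ratio_min = ratio_min,
            class = c("marker_catalog", "data.frame"))
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("<marker_catalog> ", nrow(x), " markers across ",
      length(unique(x$cell_type)), " cell types\n", sep = "")
  print(table(x$cell_type))
  invisible(x)
}

#' Bivalency enrichment of cell-type markers
#'
#' For each cell type, tests whether its marker genes are bivalent (at the
#' given timepoint) more often than the rest of the genome: a 2x2 Fisher's
#' exact test of (bivalent vs not) x (marker vs rest), BH-adjusted across
#' cell types. Marker genes missing from the state table are dropped with a
#' warning; empty marker lists give an `NA` row.
#'
#' @param markers a `marker_catalog` (or data frame with `cell_type`,
#'   `gene_id`).
#' @param states a `state_table`.
#' @param timepoint timepoint at which bivalency is assessed (e.g. the
#'   progenitor stage).
#' @param target_state state tested for enrichment (default `"BIVALENT"`).
#' @return data.frame `cell_type`, `n_markers`, `n_target`, `prop_markers`,
#'   `prop_genome`, `odds_ratio`, `p`, `p_adj`.
#' @export
marker_bivalency_enrichment <- function(markers, states, timepoint,
                                        target_state = "BIVALENT") {
  st <- states[states$timepoint == timepoint, ]
  if (nrow(st) == 0) stop("timepoint ", timepoint, " not in states", call. = FALSE)
  genome <- setNames(st$state == target_state, st$gene_id)
  types <- unique(markers$cell_type)
  missing <- setdiff(markers$gene_id, names(genome))
  if (length(missing)) {
    warning(length(missing), " marker genes absent from the state table ",
            "were dropped")
  }
  rows <- lapply(types, function(ct) {
    genes <- intersect(markers$gene_id[markers$cell_type == ct],
                       names(genome))
    if (length(genes) == 0) {
      return(data.frame(cell_type = ct, n_markers = 0L, n_target = 0L,
                        prop_markers = NA_real_, prop_genome = NA_real_,
                        odds_ratio = NA_real_, p = NA_real_))
    }
    in_mark <- names(genome) %in% genes
    a <- sum(genome[in_mark])            # marker & target state
    b <- sum(!genome[in_mark])           # marker & other
    c_ <- sum(genome[!in_mark])          # rest & target state
    d <- sum(!genome[!in_mark])
    ft <- fisher_exact_2x2(matrix(c(a, c_, b, d), 2))
    data.frame(cell_type = ct, n_markers = length(genes), n_target = a,
               prop_markers = a / length(genes),
               prop_genome = c_ / (c_ + d),
               odds_ratio = ft$odds_ratio, p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
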
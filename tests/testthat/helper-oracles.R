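# Independent brute-force oracles and small fixture builders.

# Per-base counting consensus oracle: tally replicate support for every base
# on a dense vector, then read off maximal runs >= min_support.
oracle_consensus <- function(replicates, min_support, max_coord = 10000L) {
  chroms <- unique(unlist(lapply(replicates, function(df) df$chrom)))
  out <- NULL
  for (ch in chroms) {
    support <- integer(max_coord)
    for (df in replicates) {
      covered <- logical(max_coord)
      sub <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        covered[(sub$start[i] + 1L):sub$end[i]] <- TRUE  # 1-indexed base b-1
      }
      support <- support + covered
    }
    ok <- support >= min_support
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep] - 1L,
                                 end = ends[keep], stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Full hypergeometric enumeration for the two-sided Fisher p-value, written
# from the choose() formula (independent of dhyper).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  av <- lo:hi
  logp <- lchoose(m, av) + lchoose(n, k - av) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[av == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

random_intervals <- function(n, max_coord = 10000L, chroms = c("chr1", "chr2")) {
  start <- sample.int(max_coord - 200L, n, replace = TRUE) - 1L
  width <- sample.int(150L, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    pmin(start + width, max_coord))
}

# Hand-built state table (long form) from a wide gene x timepoint matrix.
make_state_table <- function(wide, timepoints = colnames(wide)) {
  rn <- rownames(wide)
  if (is.null(rn)) rn <- character(0)
  df <- data.frame(
    gene_id = rep(rn, times = ncol(wide)),
    timepoint = rep(timepoints, each = nrow(wide)),
    state = as.vector(wide), stringsAsFactors = FALSE)
  structure(df, timepoints = timepoints, flank = 500L,
            dual_policy = "separate",
            class = c("state_table", "data.frame"))
}

# Consensus peak sets for every mark x timepoint of a simulated bundle.
bundle_consensus <- function(bundle) {
  lapply(setNames(nm = names(bundle$peaks)), function(m) {
    lapply(setNames(nm = names(bundle$peaks[[m]])), function(tp) {
      consensus_peaks(lapply(bundle$peaks[[m]][[tp]], peak_set,
                             mark = m, timepoint = tp))
    })
  })
}

# Fraction of (gene, timepoint) classifications matching the planted truth.
state_recovery <- function(states, truth_states) {
  mean(states$state == truth_states[cbind(states$gene_id, states$timepoint)])
}

per_type_precision_recall <- function(called, truth) {
  types <- unique(truth$cell_type)
  t(vapply(types, function(ct) {
    cg <- called$gene_id[called$cell_type == ct]
    tg <- truth$gene_id[truth$cell_type == ct]
    c(precision = length(intersect(cg, tg)) / max(1, length(cg)),
      recall = length(intersect(cg, tg)) / length(tg))
  }, c(precision = 0, recall = 0)))
}
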
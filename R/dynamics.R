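#' State transition counts between two timepoints
#'
#' @param states a `state_table` from [classify_all()] (or any data frame
#'   with `gene_id`, `timepoint`, `state`).
#' @param t_from,t_to timepoint labels present in the table.
#' @return integer matrix, origin states (rows) x destination states
#'   (columns); row sums equal the per-state counts at `t_from`.
#' @export
transition_matrix <- function(states, t_from, t_to) {
  tps <- attr(states, "timepoints")
  if (is.null(tps)) tps <- unique(states$timepoint)
  for (tp in c(t_from, t_to)) {
    if (!tp %in% tps) stop("unknown timepoint: ", tp, call. = FALSE)
  }
  a <- states[states$timepoint == t_from, c("gene_id", "state")]
  b <- states[states$timepoint == t_to, c("gene_id", "state")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_from", "_to"))
  table(factor(m$state_from, levels = PROMOTER_STATES),
        factor(m$state_to, levels = PROMOTER_STATES))
}

#' How genes in one state resolve between timepoints
#'
#' For genes in `from_state` at `t_from`, the fraction reaching each
#' destination state at `t_to` (e.g. the fraction of bivalent promoters that
#' have lost H3K27me3 by the last stage).
#'
#' @inheritParams transition_matrix
#' @param from_state origin state.
#' @return data.frame `state`, `count`, `fraction` (fractions sum to 1);
#'   zero rows with a warning when `from_state` is absent at `t_from`.
#' @export
resolution_summary <- function(states, t_from, t_to, from_state) {
  from_state <- match.arg(from_state, PROMOTER_STATES)
  tm <- transition_matrix(states, t_from, t_to)
  counts <- tm[from_state, ]
  n <- sum(counts)
  if (n == 0) {
    warning("no genes in state ", from_state, " at ", t_from)
    return(data.frame(state = character(), count = integer(),
                      fraction = numeric()))
  }
  data.frame(state = colnames(tm), count = as.integer(counts),
             fraction = as.numeric(counts) / n, row.names = NULL)
}

#' State trajectories across all timepoints
#'
#' One record per distinct state trajectory (ordered tuple of states across
#' timepoints) with its gene count and fraction, as plotted in alluvial
#' diagrams. By default only genes that are `BIVALENT` or `K27_ONLY` at some
#' timepoint are included; trajectories covering less than `min_fraction` of
#' included genes are flagged `omitted` (a plotting simplification) but kept
#' in the table, so the flag never changes any statistic.
#'
#' @param states a `state_table`.
#' @param min_fraction flag trajectories below this fraction (default 0.005).
#' @param restrict keep only genes bivalent or H3K27me3-only at >= 1
#'   timepoint (default `TRUE`).
#' @return data.frame `trajectory`, `count`, `fraction`, `omitted`, sorted by
#'   decreasing count.
#' @export
flow_table <- function(states, min_fraction = 0.005, restrict = TRUE) {
  tps <- attr(states, "timepoints")
  if (is.null(tps)) tps <- unique(states$timepoint)
  if (length(tps) < 2) stop("need >= 2 timepoints", call. = FALSE)
  wide <- state_matrix(states, tps)
  if (restrict) {
    keep <- apply(wide, 1, function(s) any(s %in% c("BIVALENT", "K27_ONLY")))
    wide <- wide[keep, , drop = FALSE]
  }
  if (nrow(wide) == 0) {
    return(data.frame(trajectory = character(), count = integer(),
                      fraction = numeric(), omitted = logical()))
  }
  traj <- apply(wide, 1, paste, collapse = ">")
  tab <- sort(table(traj), decreasing = TRUE)
  out <- data.frame(trajectory = names(tab), count = as.integer(tab),
                    fraction = as.integer(tab) / sum(tab), row.names = NULL)
  out$omitted <- out$fraction < min_fraction
  out
}

#' Gene x timepoint state matrix
#' @param states a `state_table`.
#' @param timepoints ordered timepoints (default from the table attribute).
#' @return character matrix, genes x timepoints.
#' @export
state_matrix <- function(states, timepoints = NULL) {
  if (is.null(timepoints)) {
    timepoints <- attr(states, "timepoints")
    if (is.null(timepoints)) timepoints <- unique(states$timepoint)
  }
  genes <- unique(states$gene_id)
  m <- matrix(NA_character_, length(genes), length(timepoints),
              dimnames = list(genes, timepoints))
  for (tp in timepoints) {
    sub <- states[states$timepoint == tp, ]
    m[sub$gene_id, tp] <- sub$state
  }
  m
}
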
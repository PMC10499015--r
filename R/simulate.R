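#' Simulation configuration
#'
#' Defaults describe a developing neuronal-progenitor population profiled at
#' three postnatal stages: a mixture of active (`K4_ONLY`), bivalent,
#' repressed (`K27_ONLY`) and unmarked promoters at the first stage, with
#' stage-to-stage transition matrices under which roughly half of the
#' initially bivalent promoters resolve to H3K4me3-only by the last stage
#' while repressed promoters are comparatively stable (two-step maintenance
#' ~0.63). Peaks are placed over promoter windows according to the planted
#' state (bivalent promoters receive mutually overlapping H3K4me3/H3K27me3
#' peaks), with per-replicate boundary jitter and dropout; expression is
#' coupled to state (active high, bivalent intermediate, repressed/unmarked
#' low) and, within bivalent genes, to the planted H3K4me3/H3K27me3 ratio.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param timepoints ordered stage labels.
#' @param chrom_count,gene_spacing chromosome layout: genes are placed every
#'   `gene_spacing` bases across `chrom_count` chromosomes.
#' @param state_priors named probability vector over
#'   `K4_ONLY`, `BIVALENT`, `K27_ONLY`, `NONE` at the first timepoint.
#' @param transitions list of row-stochastic 4x4 matrices, one per
#'   consecutive timepoint pair (recycled if length 1).
#' @param sampler `"quota"` (default): state counts follow the planted
#'   probabilities exactly by largest-remainder allocation, so the planted
#'   matrix is the exact empirical transition table; `"multinomial"`: each
#'   gene samples its destination independently.
#' @param n_replicates replicate peak calls per mark x timepoint.
#' @param jitter_sd per-replicate Gaussian jitter of peak boundaries (bases).
#' @param dropout_prob per-replicate probability that a peak call is missed.
#' @param k4_width_dist,k4_width_range H3K4me3 peak-width model:
#'   `"lognormal"` (default) or `"uniform"` over `k4_width_range`.
#' @param k4_width_meanlog,k4_width_sdlog,k27_width_meanlog,k27_width_sdlog
#'   lognormal peak-width parameters per mark.
#' @param broad_n number of planted broad-H3K4me3 genes (widths drawn
#'   uniformly from `broad_width` instead of the lognormal).
#' @param broad_width length-2 range of broad peak widths (bases).
#' @param signal_base,signal_bg mean TSS-window ChIP signal for a present /
#'   absent mark.
#' @param n_signal_reps samples per mark in the signal matrices.
#' @param ratio_sd SD of the planted per-gene log2 H3K4me3/H3K27me3 balance
#'   of bivalent promoters.
#' @param ratio_slope log2-TPM change per unit of planted ratio (the
#'   monotone bivalency-ratio -> expression link).
#' @param tpm_medians named median TPM per state.
#' @param expr_sdlog lognormal expression noise (sdlog).
#' @param de_rate_up,de_rate_down baseline probabilities that a gene is
#'   planted up-/down-regulated in the treatment DE table.
#' @param biv_up_mult multiplier on `de_rate_up` for bivalent genes (the
#'   planted enrichment).
#' @param concordance planted probability that the paired perturbation DE
#'   table agrees in sign with the treatment table.
#' @param n_cell_types,markers_per_type,marker_fold metacell matrix shape
#'   and planted marker fold change.
#' @param marker_biv_frac fraction of planted markers drawn from
#'   bivalent-at-t0 genes (the planted marker-bivalency enrichment).
#' @param trap_timepoints stage labels of the TRAP/input tables.
#' @param trap_depleted_frac fraction of genes planted as TRAP-depleted.
#' @param tf_frac fraction of genes labelled as transcription factors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       timepoints = c("P7", "P12", "P21"),
                       chrom_count = 4L,
                       gene_spacing = 20000L,
                       state_priors = c(K4_ONLY = 0.40, BIVALENT = 0.25,
                                        K27_ONLY = 0.15, NONE = 0.20),
                       transitions = NULL,
                       sampler = c("quota", "multinomial"),
                       n_replicates = 3L,
                       jitter_sd = 50,
                       dropout_prob = 0.05,
                       k4_width_dist = c("lognormal", "uniform"),
                       k4_width_range = c(500, 2000),
                       k4_width_meanlog = log(1200), k4_width_sdlog = 0.25,
                       k27_width_meanlog = log(2200), k27_width_sdlog = 0.30,
                       broad_n = 0L,
                       broad_width = c(5000, 10000),
                       signal_base = 400, signal_bg = 5,
                       n_signal_reps = 2L,
                       ratio_sd = 2.0,
                       ratio_slope = 0.8,
                       tpm_medians = c(K4_ONLY = 50, BIVALENT = 10,
                                       K27_ONLY = 1, NONE = 1),
                       expr_sdlog = 0.4,
                       de_rate_up = 0.04, de_rate_down = 0.04,
                       biv_up_mult = 4,
                       concordance = 0.70,
                       n_cell_types = 10L,
                       markers_per_type = 30L,
                       marker_fold = 8,
                       marker_biv_frac = 0.45,
                       trap_timepoints = c("P7_GCP", "P7_GC", "P12", "P21"),
                       trap_depleted_frac = 0.10,
                       tf_frac = 0.08) {
  sampler <- match.arg(sampler)
  k4_width_dist <- match.arg(k4_width_dist)
  states <- c("K4_ONLY", "BIVALENT", "K27_ONLY", "NONE")
  if (is.null(transitions)) {
    t1 <- rbind(
      K4_ONLY  = c(0.970, 0.010, 0.005, 0.015),
      BIVALENT = c(0.290, 0.640, 0.060, 0.010),
      K27_ONLY = c(0.060, 0.030, 0.794, 0.116),
      NONE     = c(0.030, 0.010, 0.020, 0.940))
    t2 <- rbind(
      K4_ONLY  = c(0.970, 0.010, 0.005, 0.015),
      BIVALENT = c(0.340, 0.570, 0.070, 0.020),
      K27_ONLY = c(0.060, 0.030, 0.794, 0.116),
      NONE     = c(0.030, 0.010, 0.020, 0.940))
    colnames(t1) <- colnames(t2) <- states
    transitions <- list(t1, t2)
  }
  if (!is.list(transitions)) transitions <- list(transitions)
  n_steps <- length(timepoints) - 1L
  if (n_steps > 0 && length(transitions) == 1) {
    transitions <- rep(transitions, n_steps)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              timepoints = timepoints, chrom_count = as.integer(chrom_count),
              gene_spacing = as.integer(gene_spacing),
              state_priors = state_priors, transitions = transitions,
              sampler = sampler, n_replicates = as.integer(n_replicates),
              jitter_sd = jitter_sd, dropout_prob = dropout_prob,
              k4_width_dist = k4_width_dist,
              k4_width_range = k4_width_range,
              k4_width_meanlog = k4_width_meanlog,
              k4_width_sdlog = k4_width_sdlog,
              k27_width_meanlog = k27_width_meanlog,
              k27_width_sdlog = k27_width_sdlog,
              broad_n = as.integer(broad_n), broad_width = broad_width,
              signal_base = signal_base, signal_bg = signal_bg,
              n_signal_reps = as.integer(n_signal_reps),
              ratio_sd = ratio_sd, ratio_slope = ratio_slope,
              tpm_medians = tpm_medians, expr_sdlog = expr_sdlog,
              de_rate_up = de_rate_up, de_rate_down = de_rate_down,
              biv_up_mult = biv_up_mult, concordance = concordance,
              n_cell_types = as.integer(n_cell_types),
              markers_per_type = as.integer(markers_per_type),
              marker_fold = marker_fold, marker_biv_frac = marker_biv_frac,
              trap_timepoints = trap_timepoints,
              trap_depleted_frac = trap_depleted_frac, tf_frac = tf_frac)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$state_priors) - 1) > 1e-8) {
    stop("state_priors must sum to 1", call. = FALSE)
  }
  for (tm in cfg$transitions) {
    if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8)) {
      stop("transition matrices must be row-stochastic", call. = FALSE)
    }
  }
  max_w <- max(exp(cfg$k4_width_meanlog + 4 * cfg$k4_width_sdlog),
               exp(cfg$k27_width_meanlog + 4 * cfg$k27_width_sdlog),
               if (cfg$broad_n > 0) cfg$broad_width[2] else 0)
  if (max_w >= cfg$gene_spacing - 2000) {
    stop("peaks can be wider than the gene spacing; increase gene_spacing",
         call. = FALSE)
  }
  bad <- c(cfg$dropout_prob, cfg$trap_depleted_frac, cfg$marker_biv_frac,
           cfg$concordance, cfg$tf_frac)
  if (any(bad < 0 | bad > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Largest-remainder integer allocation of n slots to probabilities p.
#' @noRd
quota_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Produces, deterministically for a given seed, every input the pipeline
#' consumes -- TSS table, per-replicate peak calls per mark x timepoint,
#' coverage tracks, TPM tables, DE tables, a metacell matrix, TRAP/input
#' tables, a TF list -- together with a truth manifest recording the planted
#' states, broad genes, markers, DE signs and depleted genes.
#'
#' @param config a [sim_config()].
#' @return list (class `sim_bundle`) with elements `tss`, `peaks`
#'   (`[[mark]][[timepoint]]` = list of replicate interval data frames),
#'   `coverage` (`[[mark]][[timepoint]]` = bedGraph data frame), `signal`
#'   (`[[mark]]` = genes x replicates count matrix at the first timepoint),
#'   `tpm` (genes x timepoints), `de` (per consecutive stage pair),
#'   `de_treatment`, `de_perturbation`, `metacell`, `trap`, `trap_input`,
#'   `tf_list`, `config` and `truth`.
#' @export
simulate_bivalency_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_impl(config, null_model = FALSE))
}

#' Generate a null dataset (no planted couplings)
#'
#' Same shapes as [simulate_bivalency_data()] but with every planted effect
#' removed: expression is independent of promoter state, DE status is
#' independent of state, and marker gene sets are drawn uniformly from the
#' genome (no fold change, no bivalency preference). Used for
#' type-I-error calibration.
#'
#' @param config a [sim_config()].
#' @return A `sim_bundle` list.
#' @export
simulate_null_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_impl(config, null_model = TRUE))
}

#' @noRd
simulate_impl <- function(cfg, null_model) {
  states <- c("K4_ONLY", "BIVALENT", "K27_ONLY", "NONE")
  n <- cfg$n_genes
  tps <- cfg$timepoints
  genes <- sprintf("g%05d", seq_len(n))

  # -- gene layout ---------------------------------------------------------
  chrom_of <- paste0("chr", 1L + (seq_len(n) - 1L) %% cfg$chrom_count)
  idx_on_chr <- ave(seq_len(n), chrom_of, FUN = seq_along)
  tss <- as.integer(10000L + (idx_on_chr - 1L) * cfg$gene_spacing)
  strand <- rep(c("+", "-"), length.out = n)
  tss_tab <- promoter_table(data.frame(gene_id = genes, chrom = chrom_of,
                                       tss = tss, strand = strand,
                                       stringsAsFactors = FALSE))

  # -- planted states ------------------------------------------------------
  state_mat <- matrix(NA_character_, n, length(tps),
                      dimnames = list(genes, tps))
  p0 <- cfg$state_priors[states]
  if (cfg$sampler == "quota") {
    cnt <- quota_counts(n, p0)
    s0 <- sample(rep(states, cnt))
  } else {
    s0 <- sample(states, n, replace = TRUE, prob = p0)
  }
  state_mat[, 1] <- s0
  if (length(tps) > 1) {
    for (step in seq_len(length(tps) - 1L)) {
      tm <- cfg$transitions[[step]]
      prev <- state_mat[, step]
      nxt <- character(n)
      for (s in states) {
        idx <- which(prev == s)
        if (!length(idx)) next
        if (cfg$sampler == "quota") {
          cnt <- quota_counts(length(idx), tm[s, states])
          nxt[idx] <- sample(rep(states, cnt))
        } else {
          nxt[idx] <- sample(states, length(idx), replace = TRUE,
                             prob = tm[s, states])
        }
      }
      state_mat[, step + 1L] <- nxt
    }
  }

  # -- per-gene peak geometry ---------------------------------------------
  k4_width <- if (cfg$k4_width_dist == "uniform") {
    round(stats::runif(n, cfg$k4_width_range[1], cfg$k4_width_range[2]))
  } else {
    pmax(600, round(stats::rlnorm(n, cfg$k4_width_meanlog,
                                  cfg$k4_width_sdlog)))
  }
  k27_width <- pmax(600, round(stats::rlnorm(n, cfg$k27_width_meanlog,
                                             cfg$k27_width_sdlog)))
  broad_genes <- character(0)
  if (cfg$broad_n > 0) {
    has_k4_t0 <- state_mat[, 1] %in% c("K4_ONLY", "BIVALENT")
    pool <- which(has_k4_t0)
    if (length(pool) < cfg$broad_n) {
      stop("not enough H3K4me3-bearing genes to plant broad domains",
           call. = FALSE)
    }
    bi <- sort(sample(pool, cfg$broad_n))
    k4_width[bi] <- round(stats::runif(cfg$broad_n, cfg$broad_width[1],
                                       cfg$broad_width[2]))
    broad_genes <- genes[bi]
  }
  center_off <- round(stats::runif(n, -100, 100))

  # -- planted bivalency balance and signal --------------------------------
  ratio <- stats::rnorm(n, 0, cfg$ratio_sd)  # meaningful for bivalent genes
  s4 <- s27 <- rep(cfg$signal_bg, n)
  for (i in seq_len(n)) {
    st <- state_mat[i, 1]
    if (st == "K4_ONLY") s4[i] <- cfg$signal_base
    if (st == "K27_ONLY") s27[i] <- cfg$signal_base
    if (st == "BIVALENT") {
      s4[i] <- cfg$signal_base * 2^(ratio[i] / 2)
      s27[i] <- cfg$signal_base * 2^(-ratio[i] / 2)
    }
  }

  # -- replicate peak calls + coverage -------------------------------------
  peaks <- list(H3K4me3 = list(), H3K27me3 = list())
  coverage <- list(H3K4me3 = list(), H3K27me3 = list())
  for (tp_i in seq_along(tps)) {
    tp <- tps[tp_i]
    st_tp <- state_mat[, tp_i]
    for (mark in c("H3K4me3", "H3K27me3")) {
      present <- if (mark == "H3K4me3") {
        st_tp %in% c("K4_ONLY", "BIVALENT")
      } else {
        st_tp %in% c("K27_ONLY", "BIVALENT")
      }
      w <- if (mark == "H3K4me3") k4_width else k27_width
      sig <- if (mark == "H3K4me3") s4 else s27
      ctr <- tss + center_off
      p_start <- pmax(0L, as.integer(ctr - w %/% 2L))
      p_end <- as.integer(ctr + w %/% 2L + 1L)
      reps <- lapply(seq_len(cfg$n_replicates), function(r) {
        keep <- present & (stats::runif(n) >= cfg$dropout_prob)
        if (!any(keep)) {
          return(genomic_intervals())
        }
        js <- round(stats::rnorm(sum(keep), 0, cfg$jitter_sd))
        je <- round(stats::rnorm(sum(keep), 0, cfg$jitter_sd))
        st_ <- pmax(0L, as.integer(p_start[keep] + js))
        en_ <- as.integer(p_end[keep] + je)
        en_ <- pmax(en_, st_ + 100L)  # jitter never inverts a peak
        genomic_intervals(chrom_of[keep], st_, en_, name = genes[keep])
      })
      peaks[[mark]][[tp]] <- reps
      covkeep <- which(present)
      coverage[[mark]][[tp]] <- sort_intervals(data.frame(
        chrom = chrom_of[covkeep], start = p_start[covkeep],
        end = p_end[covkeep],
        value = round(sig[covkeep] / 100, 3),
        stringsAsFactors = FALSE))
    }
  }

  # -- signal matrices at the first timepoint ------------------------------
  depth <- seq(0.8, 1.2, length.out = cfg$n_signal_reps)
  mk_signal <- function(sig) {
    m <- vapply(depth, function(d) stats::rpois(n, d * sig), numeric(n))
    dimnames(m) <- list(genes, paste0("rep", seq_len(cfg$n_signal_reps)))
    m
  }
  signal <- list(H3K4me3 = mk_signal(s4), H3K27me3 = mk_signal(s27))

  # -- expression ----------------------------------------------------------
  tpm <- matrix(0, n, length(tps), dimnames = list(genes, tps))
  for (tp_i in seq_along(tps)) {
    st_tp <- if (null_model) {
      sample(state_mat[, tp_i])  # decouple state from expression
    } else {
      state_mat[, tp_i]
    }
    med <- cfg$tpm_medians[st_tp]
    link <- ifelse(!null_model & st_tp == "BIVALENT",
                   2^(cfg$ratio_slope * ratio), 1)
    tpm[, tp_i] <- med * link * stats::rlnorm(n, 0, cfg$expr_sdlog)
  }

  # -- DE tables -----------------------------------------------------------
  mk_de <- function(de_sign) {
    is_de <- de_sign != 0
    lfc <- stats::rnorm(n, 0, 0.3)
    lfc[is_de] <- de_sign[is_de] * (1 + stats::rexp(sum(is_de), 1.2))
    padj <- stats::runif(n, 0.02, 1)
    padj[is_de] <- stats::runif(sum(is_de), 0, 0.009)
    data.frame(gene_id = genes, log2fc = lfc, padj = padj,
               stringsAsFactors = FALSE)
  }
  # stage-pair DE: sign tied to expression change
  de <- list()
  if (length(tps) > 1) {
    for (step in seq_len(length(tps) - 1L)) {
      lfc_true <- log2((tpm[, step + 1L] + 0.5) / (tpm[, step] + 0.5))
      sgn <- ifelse(abs(lfc_true) >= 1, sign(lfc_true), 0)
      de[[paste0(tps[step + 1L], "_vs_", tps[step])]] <- mk_de(sgn)
    }
  }
  # treatment DE with planted state enrichment among up-regulated genes
  p_up <- rep(cfg$de_rate_up, n)
  if (!null_model) {
    p_up[state_mat[, 1] == "BIVALENT"] <- cfg$de_rate_up * cfg$biv_up_mult
  }
  u <- stats::runif(n)
  de_sign <- ifelse(u < p_up, 1L,
                    ifelse(u < p_up + cfg$de_rate_down, -1L, 0L))
  de_treatment <- mk_de(de_sign)
  # paired perturbation table with planted direction concordance
  flip <- stats::runif(n) >= cfg$concordance
  pert_sign <- ifelse(de_sign == 0, 0L, ifelse(flip, -de_sign, de_sign))
  de_perturbation <- mk_de(pert_sign)
  de_perturbation$log2fc <- de_perturbation$log2fc * 0.5
  # genes null in A but nonzero-sign in B do not matter for concordance;
  # keep B's non-DE genes with small symmetric noise (sign ~ random)

  # -- metacell matrix + markers -------------------------------------------
  types <- paste0("celltype", seq_len(cfg$n_cell_types))
  base_expr <- stats::rlnorm(n, log(10), 0.5)
  # bounded multiplicative noise: metacells average many cells, so no
  # background gene should look like an accidental single-type marker
  metacell <- matrix(base_expr, n, cfg$n_cell_types,
                     dimnames = list(genes, types)) *
    matrix(stats::runif(n * cfg$n_cell_types, 0.6, 1.4), n)
  n_mark <- cfg$markers_per_type * cfg$n_cell_types
  if (n_mark > n) stop("more planted markers than genes", call. = FALSE)
  if (null_model) {
    marker_idx <- sample(n, n_mark)
  } else {
    biv0 <- which(state_mat[, 1] == "BIVALENT")
    other <- setdiff(seq_len(n), biv0)
    n_biv <- min(length(biv0), round(n_mark * cfg$marker_biv_frac))
    marker_idx <- c(sample(biv0, n_biv), sample(other, n_mark - n_biv))
    marker_idx <- sample(marker_idx)  # shuffle before type assignment
  }
  marker_type <- rep(types, each = cfg$markers_per_type)
  if (!null_model) {
    metacell[cbind(marker_idx,
                   match(marker_type, types))] <-
      metacell[cbind(marker_idx, match(marker_type, types))] * cfg$marker_fold
  }
  truth_markers <- data.frame(cell_type = marker_type,
                              gene_id = genes[marker_idx],
                              stringsAsFactors = FALSE)
  truth_markers <- truth_markers[order(truth_markers$cell_type,
                                       truth_markers$gene_id), ]
  rownames(truth_markers) <- NULL

  # -- TRAP / input --------------------------------------------------------
  n_trap_tp <- length(cfg$trap_timepoints)
  depleted <- sort(sample(n, round(n * cfg$trap_depleted_frac)))
  input_tab <- matrix(stats::rlnorm(n * n_trap_tp, log(20), 0.4), n,
                      dimnames = list(genes, cfg$trap_timepoints))
  ratio_tab <- matrix(stats::runif(n * n_trap_tp, 0.7, 1.6), n)
  ratio_tab[depleted, ] <- stats::runif(length(depleted) * n_trap_tp,
                                        0.10, 0.55)
  trap_tab <- input_tab * ratio_tab

  # -- TF list -------------------------------------------------------------
  tf_list <- sort(sample(genes, round(n * cfg$tf_frac)))

  truth <- list(
    states = state_mat,
    ratio = setNames(ratio, genes),
    broad_genes = broad_genes,
    markers = truth_markers,
    de_signs = setNames(de_sign, genes),
    concordant = setNames(!flip & de_sign != 0, genes),
    depleted_genes = genes[depleted],
    transitions = cfg$transitions,
    state_priors = cfg$state_priors
  )
  structure(list(tss = tss_tab, peaks = peaks, coverage = coverage,
                 signal = signal, tpm = tpm, de = de,
                 de_treatment = de_treatment,
                 de_perturbation = de_perturbation,
                 metacell = metacell, trap = trap_tab,
                 trap_input = input_tab, tf_list = tf_list,
                 config = cfg, truth = truth),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle> ", x$config$n_genes, " genes x ",
      length(x$config$timepoints), " timepoints (seed ", x$config$seed,
      ")\n", sep = "")
  print(table(factor(x$truth$states[, 1],
                     levels = c("K4_ONLY", "BIVALENT", "K27_ONLY", "NONE"))))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits the bundle as the plain-text formats the pipeline reads (BED peak
#' files, bedGraph coverage, TSV tables, truth manifest TSVs). Output is
#' byte-identical for identical bundles.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_tsv(bundle$tss, p("tss.tsv"))
  for (mark in names(bundle$peaks)) {
    for (tp in names(bundle$peaks[[mark]])) {
      reps <- bundle$peaks[[mark]][[tp]]
      for (r in seq_along(reps)) {
        write_bed(reps[[r]], p(sprintf("%s_%s_rep%d.bed", mark, tp, r)))
      }
      write_bedgraph(bundle$coverage[[mark]][[tp]],
                     p(sprintf("%s_%s_coverage.bedgraph", mark, tp)))
    }
  }
  for (mark in names(bundle$signal)) {
    write_tsv(cbind(gene_id = rownames(bundle$signal[[mark]]),
                    as.data.frame(bundle$signal[[mark]])),
              p(sprintf("signal_%s.tsv", mark)))
  }
  write_tsv(cbind(gene_id = rownames(bundle$tpm),
                  as.data.frame(bundle$tpm)), p("tpm.tsv"))
  for (nm in names(bundle$de)) {
    write_tsv(bundle$de[[nm]], p(sprintf("de_%s.tsv", nm)))
  }
  write_tsv(bundle$de_treatment, p("de_treatment.tsv"))
  write_tsv(bundle$de_perturbation, p("de_perturbation.tsv"))
  write_tsv(cbind(gene_id = rownames(bundle$metacell),
                  as.data.frame(bundle$metacell)), p("metacell.tsv"))
  write_tsv(cbind(gene_id = rownames(bundle$trap),
                  as.data.frame(bundle$trap)), p("trap.tsv"))
  write_tsv(cbind(gene_id = rownames(bundle$trap_input),
                  as.data.frame(bundle$trap_input)), p("trap_input.tsv"))
  writeLines(bundle$tf_list, p("tf_list.txt"))
  # truth manifest
  st <- bundle$truth$states
  write_tsv(cbind(gene_id = rownames(st), as.data.frame(st)),
            p("truth_states.tsv"))
  writeLines(bundle$truth$broad_genes, p("truth_broad_genes.txt"))
  write_tsv(bundle$truth$markers, p("truth_markers.tsv"))
  writeLines(bundle$truth$depleted_genes, p("truth_depleted.txt"))
  invisible(dir)
}
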
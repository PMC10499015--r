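#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end from a YAML (or list) configuration:
#' either simulates a dataset or reads user-supplied files, computes
#' replicate consensus peaks, promoter-state classification, state
#' dynamics, broad-domain detection, the bivalency ratio, expression and DE
#' integration, marker calling and marker-bivalency enrichment, writing one
#' TSV per stage plus a machine-readable run manifest (parameters, package
#' version, seed, per-file MD5 checksums). Reruns with identical inputs are
#' byte-identical; no stage mutates its inputs.
#'
#' Config keys: `seed`; `output_dir`; either `simulate:` (arguments to
#' [sim_config()]) or `inputs:` (paths: `tss`, `peaks` as
#' `mark -> timepoint -> [replicate BED files]`, and optional `tpm`,
#' `de`, `metacell`, `trap`, `trap_input`, `tf_list`); `stages:` (subset of
#' `consensus`, `classify`, `dynamics`, `broad`, `ratio`, `expression`,
#' `de_by_state`, `trap_filter`, `markers`, `marker_enrichment`);
#' `params:` (`flank`, `dual_policy`, `max_gap`, `lfc_min`, `padj_max`,
#' `trap_threshold`, `trap_min_timepoints`, `ratio_min`, `mean_tpm_min`,
#' `pseudocount`).
#'
#' @param config path to a YAML file or a config list.
#' @param output_dir overrides the config's `output_dir`.
#' @return the run manifest (list), invisibly; outputs under
#'   `output_dir/results`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_pipeline("config", "config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_pipeline("config", "config must be a list or path")
  outdir <- output_dir %||% config$output_dir
  if (is.null(outdir)) stop_pipeline("config", "output_dir is required")

  defaults <- list(flank = 500L, dual_policy = "separate", max_gap = 1000L,
                   lfc_min = 1, padj_max = 0.01, trap_threshold = 0.6,
                   trap_min_timepoints = 3L, ratio_min = 1.5,
                   mean_tpm_min = 5, pseudocount = 1)
  params <- utils::modifyList(defaults, config$params %||% list())

  all_stages <- c("consensus", "classify", "dynamics", "broad", "ratio",
                  "expression", "de_by_state", "trap_filter", "markers",
                  "marker_enrichment")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop_pipeline("config", "unknown stage(s): ", paste(bad, collapse = ", "))
  }
  deps <- list(classify = "consensus", dynamics = "classify",
               expression = "classify", de_by_state = "classify",
               marker_enrichment = c("classify", "markers"))
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss)) {
      stop_pipeline("config", "stage '", s, "' requires stage(s) ",
                    paste(miss, collapse = ", "), " to run first")
    }
  }

  # ---- resolve inputs (before any stage runs) ----------------------------
  seed <- as.integer(config$seed %||% 1L)
  data_dir <- file.path(outdir, "data")
  res_dir <- file.path(outdir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                 config$simulate))
    bundle <- simulate_bivalency_data(cfg)
    write_sim_bundle(bundle, data_dir)
    inputs <- bundle_inputs(data_dir, cfg)
  } else if (!is.null(config$inputs)) {
    inputs <- config$inputs
    check_input_files(inputs)
  } else {
    stop_pipeline("config", "config needs either 'simulate' or 'inputs'")
  }

  tss <- read_tss_table(inputs$tss)
  manifest <- list(package = "bivalomics",
                   version = as.character(utils::packageVersion("bivalomics")),
                   seed = seed, params = params, stages = stages,
                   status = "running", outputs = list())
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(res_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(NULL)
    tryCatch(fun(), error = function(e) {
      manifest$status <<- paste0("failed:", name)
      write_manifest(manifest, outputs, res_dir)
      stop_pipeline("stage", "stage '", name, "' failed: ",
                    conditionMessage(e))
    })
  }

  consensus <- states <- markers <- NULL
  run_stage("consensus", function() {
    consensus <<- list()
    for (mark in names(inputs$peaks)) {
      consensus[[mark]] <<- list()
      for (tp in names(inputs$peaks[[mark]])) {
        reps <- lapply(inputs$peaks[[mark]][[tp]], read_bed)
        cons <- consensus_peaks(lapply(reps, peak_set, mark = mark,
                                       timepoint = tp))
        consensus[[mark]][[tp]] <<- cons
        path <- file.path(res_dir,
                          sprintf("consensus_%s_%s.bed", mark, tp))
        write_bed(cons$intervals, path)
        outputs <<- c(outputs, path)
      }
    }
  })
  run_stage("classify", function() {
    states <<- classify_all(tss, consensus, flank = params$flank,
                            dual_policy = params$dual_policy)
    emit(as.data.frame(states), "states.tsv")
  })
  run_stage("dynamics", function() {
    tps <- attr(states, "timepoints")
    for (i in seq_len(length(tps) - 1L)) {
      tm <- transition_matrix(states, tps[i], tps[i + 1L])
      df <- as.data.frame.matrix(tm)
      emit(cbind(from_state = rownames(df), df),
           sprintf("transitions_%s_%s.tsv", tps[i], tps[i + 1L]))
    }
    emit(flow_table(states), "flows.tsv")
  })
  run_stage("broad", function() {
    for (tp in names(consensus$H3K4me3)) {
      merged <- merge_close_peaks(consensus$H3K4me3[[tp]],
                                  max_gap = params$max_gap)
      cb <- classify_broad(merged, tss, flank = params$flank)
      path <- file.path(res_dir, sprintf("broad_%s.bed", tp))
      write_bed(cb$broad[, c("chrom", "start", "end")], path)
      outputs <<- c(outputs, path)
      emit(data.frame(rank = seq_along(cb$widths), width = cb$widths,
                      broad = seq_along(cb$widths) <=
                        max(1L, cb$elbow - 1L) & cb$elbow >= 1L),
           sprintf("broad_widths_%s.tsv", tp))
    }
  })
  run_stage("ratio", function() {
    if (is.null(inputs$signal)) return(NULL)
    k4 <- read_signal_matrix(inputs$signal$H3K4me3)
    k27 <- read_signal_matrix(inputs$signal$H3K27me3)
    r <- bivalency_ratio(k4, k27, pseudocount = params$pseudocount)
    emit(data.frame(gene_id = names(r), bivalency_ratio = r), "ratio.tsv")
  })
  tpm <- NULL
  if (!is.null(inputs$tpm)) {
    tpm <- read_signal_matrix(inputs$tpm)
  }
  run_stage("expression", function() {
    if (is.null(tpm)) return(NULL)
    tp0 <- attr(states, "timepoints")[1]
    ebs <- suppressWarnings(expression_by_state(tpm, states, tp0))
    emit(ebs$summary, "expression_by_state_summary.tsv")
    if (!is.null(ebs$pairwise)) {
      emit(ebs$pairwise, "expression_by_state_pairwise.tsv")
    }
  })
  run_stage("de_by_state", function() {
    if (is.null(inputs$de)) return(NULL)
    de <- utils::read.delim(inputs$de, stringsAsFactors = FALSE)
    tp0 <- attr(states, "timepoints")[1]
    dbs <- de_by_state(de, states, tp0, lfc_min = params$lfc_min,
                       padj_max = params$padj_max)
    emit(dbs$proportions, "de_by_state_proportions.tsv")
    if (!is.null(dbs$pairwise)) emit(dbs$pairwise, "de_by_state_pairwise.tsv")
  })
  run_stage("trap_filter", function() {
    if (is.null(inputs$trap) || is.null(inputs$trap_input)) return(NULL)
    excl <- trap_depletion_filter(read_signal_matrix(inputs$trap),
                                  read_signal_matrix(inputs$trap_input),
                                  threshold = params$trap_threshold,
                                  min_timepoints = params$trap_min_timepoints)
    path <- file.path(res_dir, "trap_excluded.txt")
    writeLines(excl, path)
    outputs <<- c(outputs, path)
  })
  run_stage("markers", function() {
    if (is.null(inputs$metacell)) return(NULL)
    z <- zscore_matrix(read_signal_matrix(inputs$metacell))
    markers <<- call_markers(z, ratio_min = params$ratio_min)
    emit(as.data.frame(markers), "markers.tsv")
  })
  run_stage("marker_enrichment", function() {
    if (is.null(markers)) return(NULL)
    tp0 <- attr(states, "timepoints")[1]
    emit(marker_bivalency_enrichment(markers, states, tp0),
         "marker_enrichment.tsv")
  })

  manifest$status <- "complete"
  manifest <- write_manifest(manifest, outputs, res_dir)
  invisible(manifest)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_pipeline <- function(kind, ...) {
  stop(structure(class = c(paste0("bivalomics_", kind, "_error"),
                           "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' @noRd
check_input_files <- function(inputs) {
  flat <- c(inputs$tss, unlist(inputs$peaks), inputs$tpm, inputs$de,
            inputs$metacell, inputs$trap, inputs$trap_input,
            unlist(inputs$signal))
  missing <- flat[!file.exists(flat)]
  if (length(missing)) {
    stop_pipeline("input", "missing input file(s): ",
                  paste(utils::head(missing, 5), collapse = ", "))
  }
}

#' @noRd
bundle_inputs <- function(data_dir, cfg) {
  p <- function(...) file.path(data_dir, ...)
  peaks <- list()
  for (mark in c("H3K4me3", "H3K27me3")) {
    peaks[[mark]] <- list()
    for (tp in cfg$timepoints) {
      peaks[[mark]][[tp]] <- p(sprintf("%s_%s_rep%d.bed", mark, tp,
                                       seq_len(cfg$n_replicates)))
    }
  }
  list(tss = p("tss.tsv"), peaks = peaks, tpm = p("tpm.tsv"),
       de = p("de_treatment.tsv"), metacell = p("metacell.tsv"),
       trap = p("trap.tsv"), trap_input = p("trap_input.tsv"),
       signal = list(H3K4me3 = p("signal_H3K4me3.tsv"),
                     H3K27me3 = p("signal_H3K27me3.tsv")))
}

#' @noRd
read_signal_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @noRd
write_manifest <- function(manifest, outputs, res_dir) {
  sums <- tools::md5sum(sort(unique(outputs)))
  manifest$outputs <- lapply(seq_along(sums), function(i) {
    list(file = basename(names(sums)[i]), md5 = unname(sums[i]))
  })
  jsonlite::write_json(manifest, file.path(res_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
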
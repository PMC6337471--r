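# One-call orchestration of the full reference-gene workflow: quantities,
# the four per-gene stability algorithms, consensus rank aggregation, the
# geNorm V-curve, GrayNorm combination scoring and (optionally) target-gene
# normalization, with every result also written as a CSV.

#' Pipeline configuration
#'
#' @param ct Path to a wide Ct CSV, or a [ct_matrix()].
#' @param samples Path to a sample-sheet CSV, or a [sample_sheet()].
#' @param eff Path to an efficiency CSV, an [efficiency_table()], or `NULL`
#'   for E = 2 everywhere.
#' @param out_dir Output directory for result CSVs, or `NULL` to skip
#'   writing.
#' @param targets Character vector of target genes present in the Ct table;
#'   they are excluded from the candidate panel and normalized at the end.
#' @param algorithms Character subset of
#'   `c("delta_ct", "bestkeeper", "genorm", "normfinder")` to run.
#' @param v_threshold geNorm pairwise-variation cut-off (default 0.15).
#' @param m_cutoff geNorm instability flag threshold (default 1.5).
#' @param combo_size GrayNorm combination size (default 3).
#' @param bestkeeper_key Ranking key fed into the aggregation for
#'   BestKeeper: `"r"` (default) or `"SD"` (ascending mean absolute
#'   deviation).
#' @param ce Named list of [aggregate_ce()] hyperparameter overrides.
#' @param seed Integer seed for the stochastic aggregation step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ct, samples, eff = NULL, out_dir = NULL,
                            targets = character(0),
                            algorithms = c("delta_ct", "bestkeeper",
                                           "genorm", "normfinder"),
                            v_threshold = 0.15, m_cutoff = 1.5,
                            combo_size = 3,
                            bestkeeper_key = c("r", "SD"),
                            ce = list(), seed = 1L) {
  stopifnot(v_threshold > 0, m_cutoff > 0, combo_size >= 1)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (length(algorithms) < 2)
    stop("need at least two algorithms to aggregate")
  bestkeeper_key <- match.arg(bestkeeper_key)
  structure(list(ct = ct, samples = samples, eff = eff, out_dir = out_dir,
                 targets = targets, algorithms = algorithms,
                 v_threshold = v_threshold, m_cutoff = m_cutoff,
                 combo_size = combo_size, bestkeeper_key = bestkeeper_key,
                 ce = ce, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full reference-gene evaluation pipeline
#'
#' Executes, in order: input reading and cross-validation, efficiency-
#' corrected relative quantification, the enabled per-gene stability
#' algorithms, cross-entropy consensus aggregation of their rankings, the
#' geNorm V-curve, GrayNorm scoring of all size-`combo_size` combinations
#' (when the sample sheet has a control group), and normalization of any
#' target genes against the best GrayNorm combination. When `out_dir` is
#' set, one CSV per stage is written plus a JSON run log; partial outputs
#' are removed if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle` with elements `rankings` (named
#'   list of [stability_ranking()]), `consensus`, `v_curve`, `graynorm`,
#'   `expression` (list per target), `q`, `ct`, `sheet`, `eff`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ct <- if (inherits(config$ct, "ct_matrix")) config$ct
        else read_ct_table(config$ct)
  sheet <- if (inherits(config$samples, "sample_sheet")) config$samples
           else read_sample_sheet(config$samples)
  sheet <- validate_dataset(ct, sheet)
  eff <- if (is.null(config$eff)) {
    efficiency_table(NULL, ct$gene_ids)
  } else if (inherits(config$eff, "efficiency_table")) {
    config$eff
  } else {
    read_efficiencies(config$eff, ct$gene_ids)
  }

  targets <- intersect(config$targets, ct$gene_ids)
  panel <- setdiff(ct$gene_ids, targets)
  ct_panel <- ct_matrix(ct$ct[panel, , drop = FALSE])
  q <- relative_quantities(ct_panel, eff)
  has_ctrl <- !is.na(attr(sheet, "control_group"))
  grp_sizes <- table(sheet$group)
  grouped_ok <- length(grp_sizes) >= 2 && all(grp_sizes >= 3)

  written <- character(0)
  emit <- function(fn, name) {
    if (is.null(config$out_dir)) return(invisible(NULL))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, name)
    fn(path)
    written <<- c(written, path)
    invisible(path)
  }

  run <- function() {
    rankings <- list()
    if ("delta_ct" %in% config$algorithms)
      rankings$delta_ct <- delta_ct_msd(ct_panel)
    if ("bestkeeper" %in% config$algorithms) {
      bk <- bestkeeper(ct_panel)
      if (config$bestkeeper_key == "SD") {
        sd_scores <- stats::setNames(bk$extras$stats$SD, bk$extras$stats$gene)
        bk <- stability_ranking("bestkeeper", sd_scores, "lower_is_stabler",
                                extras = bk$extras)
      }
      rankings$bestkeeper <- bk
    }
    if ("genorm" %in% config$algorithms)
      rankings$genorm <- genorm(q, m_cutoff = config$m_cutoff)
    if ("normfinder" %in% config$algorithms)
      rankings$normfinder <- normfinder(q, if (grouped_ok) sheet else NULL)

    for (nm in names(rankings))
      emit(function(p) write_ranking_table(rankings[[nm]], p),
           paste0(nm, ".csv"))

    ce_args <- c(list(lists = unname(rankings), seed = config$seed),
                 config$ce)
    consensus <- do.call(aggregate_ce, ce_args)
    emit(function(p) utils::write.csv(
      data.frame(rank = seq_along(consensus$ranking),
                 gene = consensus$ranking,
                 objective = consensus$objective,
                 n_lists = length(rankings)),
      p, row.names = FALSE), "consensus.csv")

    v_curve <- NULL
    if ("genorm" %in% config$algorithms && length(panel) >= 3) {
      v_curve <- genorm_v_curve(q, rankings$genorm,
                                threshold = config$v_threshold)
      emit(function(p) utils::write.csv(
        data.frame(comparison = names(v_curve$v), v = unname(v_curve$v),
                   threshold = v_curve$threshold,
                   recommended_n = v_curve$recommended_n),
        p, row.names = FALSE), "genorm_v.csv")
      emit(function(p) utils::write.csv(rankings$genorm$extras$trace, p,
                                        row.names = FALSE),
           "genorm_trace.csv")
    }

    gn <- NULL
    if (has_ctrl && config$combo_size <= length(panel)) {
      gn <- graynorm(q, sheet, size = config$combo_size)
      emit(function(p) utils::write.csv(gn$table, p, row.names = FALSE),
           "graynorm.csv")
    }

    expression <- list()
    if (length(targets) > 0 && has_ctrl) {
      refs <- if (!is.null(gn)) gn$combinations[[1]]$genes
              else consensus$ranking[seq_len(min(3, length(panel)))]
      nf <- normalization_factor(q, refs, sheet)
      for (tg in targets) {
        rex <- relative_expression(ct, tg, eff, nf, sheet)
        expression[[tg]] <- rex
        emit(function(p) utils::write.csv(rex$samples, p, row.names = FALSE),
             paste0("expression_", tg, ".csv"))
        emit(function(p) utils::write.csv(rex$groups, p, row.names = FALSE),
             paste0("expression_summary_", tg, ".csv"))
      }
    }

    bundle <- structure(
      list(rankings = rankings, consensus = consensus, v_curve = v_curve,
           graynorm = gn, expression = expression,
           q = q, ct = ct, sheet = sheet, eff = eff, files = written),
      class = "pipeline_bundle")
    emit(function(p) jsonlite::write_json(
      list(seed = config$seed,
           algorithms = config$algorithms,
           n_genes = length(panel), n_samples = length(ct$sample_ids),
           targets = targets,
           consensus_objective = consensus$objective,
           package_version = as.character(utils::packageVersion("refstab")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      p, auto_unbox = TRUE, digits = NA), "run_log.json")
    bundle$files <- written
    bundle
  }

  tryCatch(run(), error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Summarize a pipeline bundle as one recommendation row per method
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param k Genes per recommendation (default 3).
#' @return Data frame with columns `method` and `combination` (genes joined
#'   by `+`): each enabled per-gene algorithm's top-k, the rank-aggregation
#'   consensus top-k, and GrayNorm's best combination.
#' @export
consensus_report <- function(bundle, k = 3) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  rows <- lapply(names(bundle$rankings), function(nm) {
    r <- bundle$rankings[[nm]]
    data.frame(method = nm,
               combination = paste(r$ranking[seq_len(min(k, length(r$ranking)))],
                                   collapse = "+"))
  })
  rows <- c(rows, list(data.frame(
    method = "rankaggreg",
    combination = paste(bundle$consensus$ranking[seq_len(
      min(k, length(bundle$consensus$ranking)))], collapse = "+"))))
  if (!is.null(bundle$graynorm))
    rows <- c(rows, list(data.frame(
      method = "graynorm",
      combination = paste(bundle$graynorm$combinations[[1]]$genes,
                          collapse = "+"))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
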
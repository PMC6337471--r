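# Multi-reference normalization of target genes: per-sample normalization
# factors from a chosen reference set, and efficiency-corrected relative
# expression (fold vs the calibrator group).

#' Per-sample normalization factor from a reference-gene set
#'
#' NF_s is the geometric mean of the reference genes' relative quantities
#' in sample s, rescaled so the calibrator (control) group's mean NF is
#' exactly 1.
#'
#' @param q A `quantity_matrix`.
#' @param refs Non-empty character vector of reference genes.
#' @param sheet A [sample_sheet()] with one control group.
#' @return Named numeric vector of NF values per sample.
#' @export
normalization_factor <- function(q, refs, sheet) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(refs) == 0) stop("empty reference set")
  missing_g <- setdiff(refs, q$gene_ids)
  if (length(missing_g) > 0)
    stop("reference gene(s) not in panel: ", paste(missing_g, collapse = ", "))
  ctrl <- attr(sheet, "control_group")
  if (is.na(ctrl)) stop("normalization needs a calibrator (control) group")
  sheet <- validate_dataset(
    structure(list(ct = q$q, gene_ids = q$gene_ids,
                   sample_ids = q$sample_ids), class = "ct_matrix"),
    sheet)
  nf <- 2^colMeans(q$log2q[refs, , drop = FALSE])
  nf <- nf / mean(nf[sheet$group == ctrl])
  names(nf) <- q$sample_ids
  nf
}

#' Efficiency-corrected relative expression of a target gene
#'
#' Computes the target's raw relative quantity against the calibrator-group
#' mean Ct, \eqn{RQ_s = E^{\overline{Ct}_{cal} - Ct_s}}, divides by the
#' per-sample normalization factor, and rescales folds so the calibrator
#' group's mean fold is exactly 1. Group summaries report the mean fold and
#' its standard error over the biological replicates in each group.
#'
#' @param ct A [ct_matrix()] containing the target gene.
#' @param target Target gene id.
#' @param eff An [efficiency_table()] (or `NULL` for E = 2).
#' @param nf Per-sample normalization factor, as from
#'   [normalization_factor()] (or `NULL` for no normalization; the raw RQ
#'   is then reported as the fold).
#' @param sheet A [sample_sheet()] with one control (calibrator) group.
#' @return List of class `relative_expression`: `target`, `samples` (data
#'   frame sample_id, group, raw_rq, nf, fold), `groups` (group, mean_fold,
#'   se, n), `calibrator`.
#' @export
relative_expression <- function(ct, target, eff = NULL, nf = NULL, sheet) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!target %in% ct$gene_ids) stop("target gene '", target, "' not in Ct matrix")
  ctrl <- attr(sheet, "control_group")
  if (is.na(ctrl)) stop("relative expression needs a calibrator (control) group")
  sheet <- validate_dataset(ct, sheet)
  if (is.null(eff)) eff <- efficiency_table(NULL, ct$gene_ids)
  e_t <- unclass(eff)[target]
  cal_idx <- sheet$group == ctrl
  if (!any(cal_idx)) stop("calibrator group is empty")
  raw_rq <- e_t ^ (mean(ct$ct[target, cal_idx]) - ct$ct[target, ])
  if (is.null(nf)) {
    nf_v <- rep(1, length(raw_rq))
  } else {
    if (!all(ct$sample_ids %in% names(nf)))
      stop("normalization factor missing sample(s)")
    nf_v <- nf[ct$sample_ids]
  }
  fold <- raw_rq / nf_v
  fold <- fold / mean(fold[cal_idx])  # calibrator group mean fold -> 1
  samples <- data.frame(sample_id = ct$sample_ids,
                        group = sheet$group,
                        raw_rq = unname(raw_rq),
                        nf = unname(nf_v),
                        fold = unname(fold))
  groups <- do.call(rbind, lapply(unique(sheet$group), function(gr) {
    x <- fold[sheet$group == gr]
    data.frame(group = gr, mean_fold = mean(x),
               se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x))
  }))
  structure(list(target = target, samples = samples, groups = groups,
                 calibrator = ctrl),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("relative_expression of %s (calibrator group '%s')\n",
              x$target, x$calibrator))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
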
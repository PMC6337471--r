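# GrayNorm-style combinatorial scoring: every candidate reference-gene
# combination is judged by how close each treatment group's mean reciprocal
# normalization factor (1/NF) stays to 1.0 after anchoring the control
# group at 1.

#' Enumerate reference-gene combinations
#'
#' @param genes Character vector of candidate genes.
#' @param size A single subset size, or `"all"` for every non-empty subset
#'   (2^n - 1 of them).
#' @param max_all Guard on `size = "all"`: refuse for panels larger than
#'   this (default 20; 2^20 - 1 subsets is already over a million).
#' @return List of character vectors, ordered by size then lexicographically
#'   in the input gene order.
#' @export
enumerate_combinations <- function(genes, size = "all", max_all = 20) {
  n <- length(genes)
  if (n < 1) stop("need at least one gene")
  if (identical(size, "all")) {
    if (n > max_all)
      stop("refusing to enumerate 2^", n, " - 1 subsets; pass a fixed size")
    sizes <- seq_len(n)
  } else {
    size <- as.integer(size)
    if (size < 1 || size > n) stop("size must be between 1 and ", n)
    sizes <- size
  }
  out <- list()
  for (k in sizes) {
    cmb <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) genes[cmb[, j]]))
  }
  out
}

#' Score one reference-gene combination (GrayNorm principle)
#'
#' The per-sample normalization factor NF is the geometric mean of the
#' combination's relative quantities. NF is rescaled so the control group's
#' mean NF is exactly 1; per group, the mean and CV of 1/NF are computed.
#' The score is the mean over non-control groups of |mean(1/NF) - 1|: the
#' closer each treatment group's mean 1/NF stays to 1, the less the
#' combination itself responds to treatment and the better it normalizes.
#'
#' @param q A `quantity_matrix`.
#' @param sheet A [sample_sheet()] with exactly one control group.
#' @param combo Character vector: a non-empty subset of the panel.
#' @return A `combination_score`: list with `genes`, `per_group` (data frame
#'   of group, mean_inv_nf, cv_inv_nf, n), `score`, `mean_cv`.
#' @export
graynorm_score <- function(q, sheet, combo) {
  stopifnot(inherits(q, "quantity_matrix"))
  if (length(combo) == 0) stop("empty combination")
  missing_g <- setdiff(combo, q$gene_ids)
  if (length(missing_g) > 0)
    stop("combination gene(s) not in panel: ", paste(missing_g, collapse = ", "))
  ctrl <- attr(sheet, "control_group")
  if (is.na(ctrl)) stop("GrayNorm needs a control group in the sample sheet")
  sheet <- validate_dataset(
    structure(list(ct = q$q, gene_ids = q$gene_ids,
                   sample_ids = q$sample_ids), class = "ct_matrix"),
    sheet)
  lnf <- colMeans(q$log2q[combo, , drop = FALSE])  # log2 NF per sample
  nf <- 2^lnf
  nf <- nf / mean(nf[sheet$group == ctrl])         # control mean NF -> 1
  inv <- 1 / nf
  groups <- unique(sheet$group)
  per_group <- do.call(rbind, lapply(groups, function(gr) {
    x <- inv[sheet$group == gr]
    data.frame(group = gr,
               mean_inv_nf = mean(x),
               cv_inv_nf = if (length(x) > 1) stats::sd(x) / mean(x) else 0,
               n = length(x))
  }))
  treat <- per_group[per_group$group != ctrl, , drop = FALSE]
  if (nrow(treat) == 0) stop("no non-control group to score against")
  structure(list(genes = combo,
                 per_group = per_group,
                 score = mean(abs(treat$mean_inv_nf - 1)),
                 mean_cv = mean(per_group$cv_inv_nf),
                 control_group = ctrl),
            class = "combination_score")
}

#' @export
print.combination_score <- function(x, ...) {
  cat(sprintf("combination %s: score = %.4g (mean CV %.4g)\n",
              paste(x$genes, collapse = "+"), x$score, x$mean_cv))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Order combination scores from best to worst
#'
#' Ascending by score; ties broken by ascending mean CV of 1/NF, then
#' lexicographically by the joined gene names.
#'
#' @param scores List of `combination_score` objects.
#' @param top_k Keep only the best `top_k` (default: all).
#' @return The reordered (possibly truncated) list.
#' @export
rank_combinations <- function(scores, top_k = Inf) {
  if (length(scores) == 0) stop("no combination scores to rank")
  key_score <- vapply(scores, function(s) s$score, numeric(1))
  key_cv <- vapply(scores, function(s) s$mean_cv, numeric(1))
  key_lex <- vapply(scores, function(s) paste(s$genes, collapse = "+"),
                    character(1))
  o <- order(key_score, key_cv, key_lex)
  scores[o][seq_len(min(top_k, length(scores)))]
}

#' Evaluate and rank all reference-gene combinations of a given size
#'
#' @param q A `quantity_matrix`.
#' @param sheet A [sample_sheet()] with one control group.
#' @param size Combination size (default 3, the usual multi-reference
#'   recommendation) or `"all"`.
#' @param top_k Keep the best `top_k` combinations (default: all).
#' @return List of class `graynorm_result`: ranked `combinations` plus a
#'   tidy `table` data frame (genes joined by `+`, per-group means, score).
#' @export
graynorm <- function(q, sheet, size = 3, top_k = Inf) {
  combos <- enumerate_combinations(q$gene_ids, size)
  scored <- lapply(combos, function(cb) graynorm_score(q, sheet, cb))
  ranked <- rank_combinations(scored, top_k)
  tab <- do.call(rbind, lapply(ranked, function(s) {
    row <- data.frame(combination = paste(s$genes, collapse = "+"),
                      size = length(s$genes),
                      score = s$score, mean_cv = s$mean_cv)
    for (i in seq_len(nrow(s$per_group)))
      row[[paste0("mean_inv_nf.", s$per_group$group[i])]] <-
        s$per_group$mean_inv_nf[i]
    row
  }))
  structure(list(combinations = ranked, table = tab),
            class = "graynorm_result")
}

#' @export
print.graynorm_result <- function(x, n = 10, ...) {
  cat(sprintf("graynorm_result: %d combination(s), best first\n",
              length(x$combinations)))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}
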
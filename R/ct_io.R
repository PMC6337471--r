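# Input/output for the three pipeline tables: Ct matrix, sample sheet,
# efficiencies. All readers validate hard; downstream code assumes a
# complete, in-range matrix.

CT_MIN <- 0
CT_MAX <- 45  # instrument runs 45 amplification cycles

#' Construct a Ct matrix object
#'
#' A `ct_matrix` holds quantification-cycle (Ct) values for a panel of genes
#' across samples, optionally retaining the technical-replicate layer the
#' per-sample values were collapsed from.
#'
#' @param ct Numeric matrix, genes in rows, samples in columns, with unique
#'   dimnames. Values must be finite and in (0, 45] cycles.
#' @param replicate_ct Optional 3-d array `gene x sample x replicate` whose
#'   mean over the replicate axis equals `ct` (NA-padded for uneven
#'   replicate counts).
#' @return An object of class `ct_matrix` with fields `ct`, `gene_ids`,
#'   `sample_ids` and `replicate_ct`.
#' @export
ct_matrix <- function(ct, replicate_ct = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must carry gene row names and sample column names")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  bad <- which(!is.finite(ct) | ct <= CT_MIN | ct > CT_MAX, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("Ct value out of (%g, %g] at gene '%s', sample '%s' (value %s)",
                 CT_MIN, CT_MAX,
                 rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]],
                 format(ct[bad[1, , drop = FALSE]])))
  }
  if (!is.null(replicate_ct)) {
    stopifnot(length(dim(replicate_ct)) == 3,
              dim(replicate_ct)[1] == nrow(ct),
              dim(replicate_ct)[2] == ncol(ct))
    m <- apply(replicate_ct, c(1, 2), mean, na.rm = TRUE)
    if (max(abs(m - ct)) > 1e-8)
      stop("`ct` must equal the replicate mean when `replicate_ct` is given")
  }
  structure(list(ct = ct,
                 gene_ids = rownames(ct),
                 sample_ids = colnames(ct),
                 replicate_ct = replicate_ct),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d samples%s\n",
              length(x$gene_ids), length(x$sample_ids),
              if (is.null(x$replicate_ct)) "" else
                sprintf(" (%d technical replicates retained)",
                        dim(x$replicate_ct)[3])))
  cat("Ct range:", sprintf("%.2f-%.2f", min(x$ct), max(x$ct)), "cycles\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Read a wide-format Ct table
#'
#' Expects a CSV whose first column holds gene ids and whose remaining
#' columns hold one sample each. Technical replicates may be supplied as
#' columns suffixed `__r<k>` (for example `L1__r1`, `L1__r2`, `L1__r3`);
#' they are collapsed to one Ct per gene and sample.
#'
#' @param path Path to the CSV file.
#' @param replicate_policy How replicate columns are collapsed: `"mean"`
#'   (default, the usual convention for triplicate assays), `"median"`, or
#'   `"error"` to refuse replicated input.
#' @param drop_incomplete_samples If `TRUE`, samples with one or more
#'   missing Ct values are removed (with a warning); the default is a hard
#'   error, because every downstream statistic assumes a complete matrix.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path,
                          replicate_policy = c("mean", "median", "error"),
                          drop_incomplete_samples = FALSE) {
  replicate_policy <- match.arg(replicate_policy)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("Ct table needs a gene column plus >= 1 sample column")
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(suppress))
      if (length(bad) > 0)
        stop(sprintf("non-numeric Ct at gene '%s', sample column '%s': '%s'",
                     genes[bad[1]], names(vals)[j], v[bad[1]]))
      vals[[j]] <- suppress
    }
  }
  cols <- names(vals)
  rep_match <- regmatches(cols, regexec("^(.*)__r([0-9]+)$", cols))
  base_of <- vapply(seq_along(cols), function(j) {
    if (length(rep_match[[j]]) == 3) rep_match[[j]][2] else cols[j]
  }, character(1))
  has_reps <- any(vapply(rep_match, length, integer(1)) == 3)
  sample_ids <- unique(base_of)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  if (has_reps && replicate_policy == "error")
    stop("replicate columns present but replicate_policy = 'error'")

  n_rep <- max(table(base_of))
  rep_arr <- NULL
  if (has_reps || n_rep > 1) {
    rep_arr <- array(NA_real_, dim = c(length(genes), length(sample_ids), n_rep),
                     dimnames = list(genes, sample_ids, NULL))
    for (s in sample_ids) {
      jj <- which(base_of == s)
      for (k in seq_along(jj)) rep_arr[, s, k] <- vals[[jj[k]]]
    }
    collapse <- if (replicate_policy == "median") {
      function(x) stats::median(x, na.rm = TRUE)
    } else {
      function(x) mean(x, na.rm = TRUE)
    }
    m <- apply(rep_arr, c(1, 2), function(x) {
      if (all(is.na(x))) NA_real_ else collapse(x)
    })
    if (replicate_policy == "median") rep_arr_keep <- NULL else rep_arr_keep <- rep_arr
  } else {
    m <- as.matrix(vals)
    dimnames(m) <- list(genes, sample_ids)
    rep_arr_keep <- NULL
  }
  rownames(m) <- genes

  if (anyNA(m)) {
    if (drop_incomplete_samples) {
      bad_s <- colnames(m)[apply(m, 2, anyNA)]
      warning("dropping incomplete sample(s): ", paste(bad_s, collapse = ", "))
      m <- m[, !colnames(m) %in% bad_s, drop = FALSE]
      if (!is.null(rep_arr_keep))
        rep_arr_keep <- rep_arr_keep[, !dimnames(rep_arr_keep)[[2]] %in% bad_s,
                                     , drop = FALSE]
      if (ncol(m) == 0) stop("all samples incomplete")
    } else {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("missing Ct at gene '%s', sample '%s' ",
                          "(use drop_incomplete_samples = TRUE to discard ",
                          "such samples)"),
                   rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
  }
  ct_matrix(m, replicate_ct = rep_arr_keep)
}

#' Construct or read a sample sheet
#'
#' The sample sheet assigns every sample to a condition group (tissue, time
#' point, treatment) and flags the group that serves as control/calibrator.
#'
#' @param x A data frame with columns `sample_id`, `group`, `is_control`.
#' @param require_control If `TRUE`, exactly one group must be flagged as
#'   control (needed by GrayNorm and target-gene normalization).
#' @return A `sample_sheet` data frame; groups keep their order of first
#'   appearance.
#' @export
sample_sheet <- function(x, require_control = FALSE) {
  need <- c("sample_id", "group", "is_control")
  if (!all(need %in% names(x)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$sample_id <- as.character(x$sample_id)
  x$group <- as.character(x$group)
  x$is_control <- as.logical(x$is_control)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  if (anyNA(x$is_control)) stop("is_control must be TRUE/FALSE")
  ctrl_groups <- unique(x$group[x$is_control])
  non_ctrl_flag <- x$group %in% ctrl_groups & !x$is_control
  if (any(non_ctrl_flag) || length(ctrl_groups) > 1) {
    # control status is a property of the group, not of individual samples
    if (length(ctrl_groups) > 1)
      stop("more than one group flagged is_control: ",
           paste(ctrl_groups, collapse = ", "))
    stop("group '", ctrl_groups, "' has samples with inconsistent is_control")
  }
  if (require_control && length(ctrl_groups) == 0)
    stop("no control group flagged, but one is required")
  attr(x, "groups") <- unique(x$group)
  attr(x, "control_group") <-
    if (length(ctrl_groups) == 1) ctrl_groups else NA_character_
  class(x) <- c("sample_sheet", "data.frame")
  x
}

#' @rdname sample_sheet
#' @param path Path to a CSV with columns `sample_id,group,is_control`.
#' @export
read_sample_sheet <- function(path, require_control = FALSE) {
  sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE),
               require_control = require_control)
}

#' Amplification-efficiency table
#'
#' Per-gene amplification efficiencies E, expressed as fold-increase per
#' cycle (perfect doubling is E = 2). Genes without a supplied value
#' default to E = 2.
#'
#' @param e Named numeric vector of efficiencies, or `NULL` for all-default.
#' @param genes Character vector: the full gene universe to cover.
#' @param max_e Upper plausibility bound (default 2.2; values above it are
#'   usually pipetting or inhibition artifacts).
#' @return Named numeric vector of class `efficiency_table` covering `genes`.
#' @export
efficiency_table <- function(e = NULL, genes, max_e = 2.2) {
  out <- rep(2.0, length(genes))
  names(out) <- genes
  if (!is.null(e) && length(e) > 0) {
    if (is.null(names(e))) stop("efficiencies must be named by gene")
    bad <- e <= 1.0 | e > max_e | !is.finite(e)
    if (any(bad))
      stop(sprintf("efficiency out of (1, %g] for gene '%s': %s",
                   max_e, names(e)[bad][1], format(e[bad][1])))
    known <- intersect(names(e), genes)
    out[known] <- e[known]
  }
  structure(out, class = "efficiency_table")
}

#' @rdname efficiency_table
#' @param path Path to a CSV with columns `gene,E`, or `NULL`/missing file
#'   for all-default efficiencies.
#' @export
read_efficiencies <- function(path = NULL, genes, max_e = 2.2) {
  if (is.null(path)) return(efficiency_table(NULL, genes, max_e))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("efficiency table needs columns gene,E")
  e <- as.numeric(raw[[2]])
  names(e) <- as.character(raw[[1]])
  if (anyDuplicated(names(e))) stop("duplicate gene in efficiency table")
  efficiency_table(e, genes, max_e)
}

#' Cross-validate a Ct matrix against a sample sheet
#'
#' @param ct A [ct_matrix()].
#' @param sheet A [sample_sheet()].
#' @return Invisibly, the sheet reordered to the Ct matrix's sample order.
#' @export
validate_dataset <- function(ct, sheet) {
  missing_s <- setdiff(ct$sample_ids, sheet$sample_id)
  if (length(missing_s) > 0)
    stop("sample(s) in Ct matrix absent from sample sheet: ",
         paste(missing_s, collapse = ", "))
  extra <- setdiff(sheet$sample_id, ct$sample_ids)
  if (length(extra) > 0)
    stop("sample(s) in sheet absent from Ct matrix: ",
         paste(extra, collapse = ", "))
  out <- sheet[match(ct$sample_ids, sheet$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- attr(sheet, "groups")
  attr(out, "control_group") <- attr(sheet, "control_group")
  class(out) <- class(sheet)
  invisible(out)
}

#' Write one or more stability rankings as a CSV table
#'
#' Mirrors the usual published layout: one `rank` column, then a
#' `(gene, score)` column pair per algorithm.
#'
#' @param rankings A single `stability_ranking` or a list of them, all over
#'   the same gene universe.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_ranking_table <- function(rankings, path) {
  if (inherits(rankings, "stability_ranking")) rankings <- list(rankings)
  if (length(rankings) == 0) stop("no rankings to write")
  universes <- lapply(rankings, function(r) sort(r$ranking))
  if (length(rankings) > 1 &&
      !all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("rankings cover different gene universes")
  n <- length(rankings[[1]]$ranking)
  if (n == 0) stop("empty ranking")
  out <- data.frame(rank = seq_len(n))
  for (r in rankings) {
    out[[paste0("gene_", r$algorithm)]] <- r$ranking
    out[[paste0("score_", r$algorithm)]] <- unname(r$scores[r$ranking])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a Ct matrix back to the wide CSV dialect read_ct_table() reads
#'
#' @param ct A [ct_matrix()].
#' @param path Output CSV path.
#' @export
write_ct_table <- function(ct, path) {
  df <- data.frame(gene = ct$gene_ids, ct$ct, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
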
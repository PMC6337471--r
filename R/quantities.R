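# Ct -> efficiency-corrected relative quantities, and standard-curve
# efficiency estimation.

#' Efficiency-corrected relative quantities
#'
#' Converts Ct values to relative template quantities
#' \eqn{Q_{gs} = E_g^{\min_{s'} Ct_{gs'} - Ct_{gs}}}. Each gene is anchored
#' at its minimum-Ct sample (the sample with the most template), so the
#' per-gene maximum quantity is exactly 1. With E = 2 this is the familiar
#' \eqn{2^{-\Delta Ct}} transformation.
#'
#' @param ct A [ct_matrix()].
#' @param eff An [efficiency_table()] covering the matrix's genes; omitted
#'   means E = 2 for every gene.
#' @return A `quantity_matrix`: list with `q`, `log2q` (both gene x sample),
#'   `gene_ids`, `sample_ids`, `efficiencies`.
#' @export
relative_quantities <- function(ct, eff = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (is.null(eff)) eff <- efficiency_table(NULL, ct$gene_ids)
  missing_e <- setdiff(ct$gene_ids, names(eff))
  if (length(missing_e) > 0)
    stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "))
  e <- unclass(eff)[ct$gene_ids]
  dct <- apply(ct$ct, 1, min) - ct$ct          # min Ct minus Ct, per gene
  q <- e ^ dct                                  # rows recycle e per gene
  dimnames(q) <- dimnames(ct$ct)
  structure(list(q = q,
                 log2q = log2(q),
                 gene_ids = ct$gene_ids,
                 sample_ids = ct$sample_ids,
                 efficiencies = e),
            class = "quantity_matrix")
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("quantity_matrix: %d genes x %d samples (per-gene max = 1)\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Fill (or re-fill) the log2 layer of a quantity matrix
#'
#' Idempotent; errors on non-positive quantities.
#'
#' @param q A `quantity_matrix` (or a bare positive matrix, which is wrapped).
#' @return The `quantity_matrix` with `log2q` consistent with `q`.
#' @export
log_transform <- function(q) {
  if (!inherits(q, "quantity_matrix")) {
    stopifnot(is.matrix(q), is.numeric(q))
    q <- structure(list(q = q, log2q = NULL,
                        gene_ids = rownames(q), sample_ids = colnames(q),
                        efficiencies = NULL),
                   class = "quantity_matrix")
  }
  if (any(!is.finite(q$q) | q$q <= 0))
    stop("quantities must be positive and finite to take logs")
  q$log2q <- log2(q$q)
  q
}

#' Construct a dilution series
#'
#' @param gene_id Gene label.
#' @param log10_input Numeric vector of log10 relative template inputs,
#'   strictly monotone.
#' @param ct Mean Ct observed at each input.
#' @return A `dilution_series` object.
#' @export
dilution_series <- function(gene_id, log10_input, ct) {
  stopifnot(length(log10_input) == length(ct))
  if (length(ct) < 3) stop("a dilution series needs >= 3 points")
  d <- diff(log10_input)
  if (!(all(d > 0) || all(d < 0)))
    stop("log10 inputs must be strictly increasing or decreasing")
  structure(list(gene_id = gene_id,
                 log10_input = as.numeric(log10_input),
                 ct = as.numeric(ct)),
            class = "dilution_series")
}

#' Amplification efficiency from a standard curve
#'
#' Fits Ct against log10 template input by ordinary least squares and
#' converts the slope to an amplification efficiency via
#' \eqn{E = 10^{-1/slope}}. A perfect doubling assay has slope
#' \eqn{-1/\log_{10} 2 \approx -3.3219} and E = 2.
#'
#' @param series A [dilution_series()].
#' @return List with `slope` (cycles per log10 input), `E`, `r_squared`,
#'   `intercept`.
#' @export
efficiency_from_dilution <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  fit <- stats::lm(ct ~ log10_input,
                   data = data.frame(log10_input = series$log10_input,
                                     ct = series$ct))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop(sprintf("non-negative slope (%.4g) for gene '%s': not an amplifying assay",
                 slope, series$gene_id))
  ss_tot <- sum((series$ct - mean(series$ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(gene_id = series$gene_id,
       slope = slope,
       E = 10^(-1 / slope),
       r_squared = r2,
       intercept = unname(stats::coef(fit)[1]))
}
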
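# Per-gene stability algorithms: comparative delta-Ct mSD, BestKeeper,
# geNorm (M-values, exclusion, V-curve), NormFinder-style stability value.
# All four return a common `stability_ranking` so their orderings can be
# aggregated and tabulated side by side.

#' Construct a stability ranking
#'
#' @param algorithm Short algorithm label (e.g. `"delta_ct"`).
#' @param scores Named numeric vector of per-gene scores (NA allowed for
#'   undefined scores; NA ranks last).
#' @param orientation `"lower_is_stabler"` or `"higher_is_stabler"`.
#' @param ranking Optional explicit ordering (most stable first); computed
#'   from the scores when omitted.
#' @param ties Optional list of character vectors naming tied gene sets.
#' @param extras Optional named list of algorithm-specific side results.
#' @return An object of class `stability_ranking`.
#' @export
stability_ranking <- function(algorithm, scores,
                              orientation = c("lower_is_stabler",
                                              "higher_is_stabler"),
                              ranking = NULL, ties = NULL, extras = list()) {
  orientation <- match.arg(orientation)
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (is.null(ranking)) {
    key <- if (orientation == "lower_is_stabler") scores else -scores
    ranking <- names(scores)[order(key, seq_along(scores), na.last = TRUE)]
  }
  if (!setequal(ranking, names(scores)) ||
      length(ranking) != length(scores))
    stop("ranking must be a permutation of the scored genes")
  if (is.null(ties)) {
    ok <- !is.na(scores)
    grp <- split(names(scores)[ok], scores[ok])
    ties <- unname(grp[vapply(grp, length, integer(1)) > 1])
  }
  structure(list(algorithm = algorithm, scores = scores,
                 orientation = orientation, ranking = ranking,
                 ties = ties, extras = extras),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, n = Inf, ...) {
  cat(sprintf("stability_ranking [%s], %s\n", x$algorithm, x$orientation))
  k <- min(n, length(x$ranking))
  df <- data.frame(rank = seq_len(k), gene = x$ranking[seq_len(k)],
                   score = unname(x$scores[x$ranking[seq_len(k)]]))
  print(df, row.names = FALSE)
  if (length(x$ties) > 0)
    cat("ties:", paste(vapply(x$ties, paste, "", collapse = "="),
                       collapse = "; "), "\n")
  invisible(x)
}

#' Comparative delta-Ct stability (mean pairwise SD)
#'
#' For every ordered gene pair, takes the standard deviation across samples
#' of the pairwise Ct difference; a gene's mSD is the mean of its SDs
#' against all other candidates. Stable genes keep a constant offset to
#' every partner, so low mSD means stable.
#'
#' @param ct A [ct_matrix()] with at least 2 genes and 2 samples.
#' @return A [stability_ranking()] (`lower_is_stabler`) whose `extras$pair_sd`
#'   holds the full pairwise SD matrix.
#' @export
delta_ct_msd <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  m <- ct$ct
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("delta-Ct needs >= 2 genes and >= 2 samples")
  g <- nrow(m)
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(g - 1)) {
    d <- m[rep(i, g - i), , drop = FALSE] - m[(i + 1):g, , drop = FALSE]
    s <- apply(d, 1, stats::sd)
    pair_sd[i, (i + 1):g] <- s
    pair_sd[(i + 1):g, i] <- s
  }
  msd <- rowSums(pair_sd) / (g - 1)
  stability_ranking("delta_ct", msd, "lower_is_stabler",
                    extras = list(pair_sd = pair_sd))
}

#' BestKeeper descriptive statistics and index correlation
#'
#' Computes per-gene descriptive statistics of the raw Ct values (mean,
#' SD, CV%) and the BestKeeper index — the per-sample geometric mean Ct
#' over all candidates — then ranks genes by the Pearson correlation `r`
#' of their Ct with the index (higher r = more representative = stabler).
#' The "SD" follows the original BestKeeper convention of the mean absolute
#' deviation from the mean; `sd_mode = "classic"` switches to the ordinary
#' n-1 standard deviation.
#'
#' @param ct A [ct_matrix()], >= 2 genes and >= 3 samples.
#' @param sd_mode `"mad"` (mean absolute deviation, default) or `"classic"`.
#' @return A [stability_ranking()] (`higher_is_stabler`, scores = r) whose
#'   `extras$stats` data frame carries AM, SD, CV and r, and `extras$index`
#'   the per-sample index.
#' @export
bestkeeper <- function(ct, sd_mode = c("mad", "classic")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(ct, "ct_matrix"))
  m <- ct$ct
  if (nrow(m) < 2 || ncol(m) < 3)
    stop("BestKeeper needs >= 2 genes and >= 3 samples")
  am <- rowMeans(m)
  sd_v <- if (sd_mode == "mad") {
    rowMeans(abs(m - am))
  } else {
    apply(m, 1, stats::sd)
  }
  cv <- 100 * sd_v / am
  index <- exp(colMeans(log(m)))  # geometric mean Ct per sample
  r <- rep(NA_real_, nrow(m))
  names(r) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    if (stats::sd(m[i, ]) > 0 && stats::sd(index) > 0)
      r[i] <- stats::cor(m[i, ], index)
  }
  if (anyNA(r))
    warning("zero-variance gene(s) have undefined r and rank last: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  stats_df <- data.frame(gene = rownames(m), AM = am, SD = sd_v, CV = cv,
                         r = unname(r), row.names = NULL)
  stability_ranking("bestkeeper", r, "higher_is_stabler",
                    extras = list(stats = stats_df, index = index,
                                  sd_mode = sd_mode))
}

# SD over samples of log2(Q_j / Q_k) for all gene pairs of a log2-quantity
# matrix; the workhorse of geNorm.
.pairwise_v <- function(lq) {
  g <- nrow(lq)
  v <- matrix(0, g, g, dimnames = list(rownames(lq), rownames(lq)))
  for (i in seq_len(g - 1)) {
    d <- lq[rep(i, g - i), , drop = FALSE] - lq[(i + 1):g, , drop = FALSE]
    s <- apply(d, 1, stats::sd)
    v[i, (i + 1):g] <- s
    v[(i + 1):g, i] <- s
  }
  v
}

#' geNorm expression-stability M-values with iterative exclusion
#'
#' A gene's M-value is its mean pairwise variation — the standard deviation
#' across samples of the log2 expression ratio — against all other
#' remaining candidates. The least stable gene (highest M) is removed and
#' M recomputed, until two genes remain; those two cannot be separated and
#' tie at ranks 1-2. The reported score per gene is its M at the step of
#' its removal (for the final pair, their mutual pairwise variation).
#' Genes with M at or above `m_cutoff` are flagged as unstable.
#'
#' @param q A `quantity_matrix` from [relative_quantities()], >= 3 genes.
#' @param m_cutoff Stability flag threshold on M (default 1.5).
#' @return A [stability_ranking()] (`lower_is_stabler`). `extras$trace` is a
#'   data frame of the exclusion steps, `extras$initial_m` the full-panel
#'   M-values, `extras$unstable` the flagged genes.
#' @export
genorm <- function(q, m_cutoff = 1.5) {
  stopifnot(inherits(q, "quantity_matrix"))
  lq <- q$log2q
  if (nrow(lq) < 3) stop("geNorm needs >= 3 candidate genes")
  genes <- rownames(lq)
  order_idx <- stats::setNames(seq_along(genes), genes)

  remaining <- genes
  removal <- character(0)
  score <- stats::setNames(rep(NA_real_, length(genes)), genes)
  trace <- list()
  initial_m <- NULL
  step <- 0
  while (length(remaining) > 2) {
    step <- step + 1
    v <- .pairwise_v(lq[remaining, , drop = FALSE])
    m <- rowSums(v) / (length(remaining) - 1)
    if (is.null(initial_m)) initial_m <- m
    worst_m <- max(m)
    cand <- names(m)[m == worst_m]
    # tie on M: remove the later gene in input order
    out_gene <- cand[which.max(order_idx[cand])]
    score[out_gene] <- worst_m
    trace[[step]] <- data.frame(step = step,
                                n_remaining = length(remaining),
                                removed = out_gene, m = worst_m,
                                tie = length(cand) > 1)
    removal <- c(removal, out_gene)
    remaining <- setdiff(remaining, out_gene)
  }
  # final pair: mutual V is both genes' M
  v_final <- stats::sd(lq[remaining[1], ] - lq[remaining[2], ])
  score[remaining] <- v_final
  final_pair <- remaining[order(order_idx[remaining])]
  ranking <- c(final_pair, rev(removal))
  if (is.null(initial_m)) {  # exactly 3 genes: initial_m computed in loop
    v <- .pairwise_v(lq)
    initial_m <- rowSums(v) / (nrow(lq) - 1)
  }
  trace_df <- do.call(rbind, trace)
  unstable <- names(score)[score >= m_cutoff]
  stability_ranking("genorm", score, "lower_is_stabler",
                    ranking = ranking,
                    ties = list(final_pair),
                    extras = list(trace = trace_df,
                                  initial_m = initial_m,
                                  unstable = unstable,
                                  m_cutoff = m_cutoff))
}

#' geNorm pairwise-variation curve (how many reference genes are needed)
#'
#' Builds normalization factors NF_n from the n most stable genes (geometric
#' mean of their quantities) for n = 2..N-1 and computes
#' V_{n/n+1} = SD across samples of log2(NF_n / NF_{n+1}). The recommended
#' gene number is the smallest n whose V drops below the threshold
#' (conventionally 0.15); if none does, N-1 is returned and flagged.
#'
#' @param q A `quantity_matrix`.
#' @param ranking The geNorm [stability_ranking()] (or any ranking whose
#'   order defines "most stable first").
#' @param threshold V cut-off, default 0.15.
#' @return List of class `pv_curve`: `v` (named vector `V2/3`, `V3/4`, ...),
#'   `recommended_n`, `threshold`, `below_threshold`.
#' @export
genorm_v_curve <- function(q, ranking, threshold = 0.15) {
  stopifnot(inherits(q, "quantity_matrix"))
  genes <- if (inherits(ranking, "stability_ranking")) ranking$ranking
           else as.character(ranking)
  n_tot <- length(genes)
  if (n_tot < 3) stop("V-curve needs >= 3 genes")
  lq <- q$log2q[genes, , drop = FALSE]
  # log2 NF_n = mean of the top-n genes' log2 quantities
  cs <- apply(lq, 2, cumsum)
  v <- numeric(n_tot - 2)
  names(v) <- paste0("V", 2:(n_tot - 1), "/", 3:n_tot)
  for (n in 2:(n_tot - 1)) {
    lnf_n <- cs[n, ] / n
    lnf_n1 <- cs[n + 1, ] / (n + 1)
    v[n - 1] <- stats::sd(lnf_n - lnf_n1)
  }
  ok <- which(v < threshold)
  structure(list(v = v,
                 recommended_n = if (length(ok) > 0) (2:(n_tot - 1))[ok[1]]
                                 else n_tot - 1,
                 below_threshold = length(ok) > 0,
                 threshold = threshold),
            class = "pv_curve")
}

#' @export
print.pv_curve <- function(x, ...) {
  print(round(x$v, 4))
  cat(sprintf("recommended n = %d (threshold %.2f%s)\n", x$recommended_n,
              x$threshold,
              if (x$below_threshold) "" else "; no V below threshold"))
  invisible(x)
}

#' NormFinder-style stability value
#'
#' Works on log2 quantities with per-sample loading removed: each sample's
#' across-gene mean is subtracted, leaving residual expression y. Without
#' groups the stability value is the residual SD with a
#' \eqn{\sqrt{G/(G-1)}} small-panel correction. With condition groups the
#' value combines, per group, the absolute inter-group deviation of the
#' gene's group mean from its grand mean and the intra-group sampling error
#' \eqn{\sqrt{s^2_g/n_g}}, averaged over groups — genes that both track the
#' panel within groups and do not shift between groups score low.
#'
#' @param q A `quantity_matrix`, >= 3 genes.
#' @param sheet Optional [sample_sheet()]; with it the grouped estimator is
#'   used and every group must have at least 3 samples.
#' @return A [stability_ranking()] (`lower_is_stabler`); grouped runs carry
#'   `extras$group_means` and `extras$intra_var`.
#' @export
normfinder <- function(q, sheet = NULL) {
  stopifnot(inherits(q, "quantity_matrix"))
  lq <- q$log2q
  if (nrow(lq) < 3) stop("NormFinder needs >= 3 candidate genes")
  g <- nrow(lq)
  y <- sweep(lq, 2, colMeans(lq))  # remove per-sample loading
  if (is.null(sheet)) {
    sv <- apply(y, 1, stats::sd) * sqrt(g / (g - 1))
    return(stability_ranking("normfinder", sv, "lower_is_stabler"))
  }
  sheet <- validate_dataset(
    structure(list(ct = lq, gene_ids = rownames(lq),
                   sample_ids = colnames(lq)), class = "ct_matrix"),
    sheet)
  grp <- split(seq_along(sheet$sample_id), factor(sheet$group,
                                                  levels = unique(sheet$group)))
  n_g <- vapply(grp, length, integer(1))
  if (any(n_g < 3))
    stop("NormFinder grouped mode needs more than two samples per group; ",
         "group(s) too small: ",
         paste(names(n_g)[n_g < 3], collapse = ", "))
  gm <- vapply(grp, function(j) rowMeans(y[, j, drop = FALSE]),
               numeric(g))                     # gene x group means
  iv <- vapply(grp, function(j) apply(y[, j, drop = FALSE], 1, stats::var),
               numeric(g))                     # gene x group intra variance
  z <- gm - rowMeans(gm)                       # inter-group deviation
  sv <- rowMeans(abs(z) + sqrt(sweep(iv, 2, n_g, "/")))
  names(sv) <- rownames(lq)
  stability_ranking("normfinder", sv, "lower_is_stabler",
                    extras = list(group_means = gm, intra_var = iv,
                                  group_sizes = n_g))
}
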
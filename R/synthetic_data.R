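# Synthetic Ct datasets with known ground truth. The generator emulates a
# multi-condition qPCR reference-gene screen: a panel mixing stable and
# treatment-responsive candidates, lognormal biological noise, per-sample
# loading offsets, gene-specific amplification efficiencies, and optional
# target genes with known fold changes.

#' Specification of a synthetic qPCR dataset
#'
#' The default specification is the package's benchmark scenario: 3 stable
#' reference candidates (sigma 0.1 log2 units), 3 mildly responsive ones
#' (a one-group shift of one log2 unit, mixed up/down), 2 strongly
#' responsive ones (three log2 units, one induced and one repressed), a
#' per-sample loading SD of 0.5 log2 units, three condition groups of three
#' biological replicates with the first group as control, and one target
#' gene at fold 4 in the second treatment group. Baseline Ct values are
#' drawn uniformly in 18-30 cycles and amplification efficiencies uniformly
#' in 1.85-2.05, the span typical of validated assays.
#'
#' @param n_stable Number of stable reference candidates.
#' @param n_unstable Number of responsive candidates; the first
#'   `round(2/3 * n_unstable)` are "mild" (shift `mild_shift`), the rest
#'   "strong" (shift `strong_shift`), with alternating sign unless
#'   `group_effects` overrides the whole matrix.
#' @param groups Data frame with columns `group`, `n`, `is_control`.
#' @param sigma_stable,sigma_unstable Biological noise SD (log2 units) for
#'   stable and responsive genes.
#' @param mild_shift,strong_shift Magnitudes (log2 units) of the one-group
#'   expression shifts of mild and strong responders.
#' @param group_effects Optional explicit gene-by-group matrix of log2
#'   shifts (overrides the mild/strong construction).
#' @param sigma_loading SD (log2 units) of the shared per-sample loading
#'   offset (RNA input / RT yield artifact).
#' @param baseline_ct_range Range baseline Ct values are drawn from.
#' @param efficiency_range Range amplification efficiencies are drawn from.
#' @param targets Data frame with columns `gene`, `group`, `log2_fold`
#'   giving target genes and their true per-group log2 fold changes
#'   (unlisted groups = fold 1), or `NULL` for no targets.
#' @param sigma_target Biological noise SD for target genes.
#' @param report_e `"true"` to emit the real efficiencies, `"assume2"` to
#'   emit E = 2 for every gene (efficiency mis-specification mode).
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_stable = 3,
                           n_unstable = 5,
                           groups = data.frame(
                             group = c("control", "treatA", "treatB"),
                             n = 3,
                             is_control = c(TRUE, FALSE, FALSE)),
                           sigma_stable = 0.1,
                           sigma_unstable = 0.3,
                           mild_shift = 1,
                           strong_shift = 3,
                           group_effects = NULL,
                           sigma_loading = 0.5,
                           baseline_ct_range = c(18, 30),
                           efficiency_range = c(1.85, 2.05),
                           targets = data.frame(gene = "TGT1",
                                                group = "treatB",
                                                log2_fold = 2),
                           sigma_target = 0.1,
                           report_e = c("true", "assume2"),
                           seed = 1L) {
  report_e <- match.arg(report_e)
  stopifnot(n_stable >= 0, n_unstable >= 0, n_stable + n_unstable >= 2,
            sigma_stable >= 0, sigma_unstable >= 0, sigma_loading >= 0,
            sigma_target >= 0,
            all(groups$n >= 1), sum(groups$is_control) <= 1,
            efficiency_range[1] > 1, efficiency_range[2] <= 2.2,
            diff(baseline_ct_range) >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Default gene x group shift matrix: mild responders shift by +/- mild_shift
# in the first non-control group, strong ones by +/- strong_shift in the
# last group; signs alternate (treatments induce some genes, repress others).
.default_group_effects <- function(spec, ref_genes) {
  grs <- spec$groups$group
  eff <- matrix(0, length(ref_genes), length(grs),
                dimnames = list(ref_genes, grs))
  non_ctrl <- grs[!spec$groups$is_control]
  if (spec$n_unstable == 0 || length(non_ctrl) == 0) return(eff)
  n_mild <- round(2 / 3 * spec$n_unstable)
  unstable <- ref_genes[spec$n_stable + seq_len(spec$n_unstable)]
  mild_group <- non_ctrl[1]
  strong_group <- non_ctrl[length(non_ctrl)]
  for (i in seq_len(spec$n_unstable)) {
    sign <- if (i %% 2 == 1) 1 else -1
    if (i <= n_mild) {
      eff[unstable[i], mild_group] <- sign * spec$mild_shift
    } else {
      eff[unstable[i], strong_group] <- sign * spec$strong_shift
    }
  }
  eff
}

#' Generate a synthetic Ct dataset with known ground truth
#'
#' Latent log2 expression is
#' \eqn{L_{gs} = \beta_{g,group(s)} + \lambda_s + \epsilon_{gs}} with
#' \eqn{\epsilon \sim N(0, \sigma_g^2)} and loading
#' \eqn{\lambda \sim N(0, \sigma_{loading}^2)}; Ct values follow as
#' \eqn{Ct_{gs} = C0_g - L_{gs} \ln 2 / \ln E_g}, i.e. one log2 unit of
#' expression moves Ct by one cycle when E = 2. Deterministic for a fixed
#' spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ct` ([ct_matrix()] over references and targets),
#'   `sheet` ([sample_sheet()]), `eff` ([efficiency_table()]) and `truth`
#'   (stable/unstable/target gene sets, loading offsets, true efficiencies,
#'   group-effect matrix, true target folds per group).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  stable_genes <- if (spec$n_stable > 0) paste0("S", seq_len(spec$n_stable))
                  else character(0)
  unstable_genes <- if (spec$n_unstable > 0) paste0("U", seq_len(spec$n_unstable))
                    else character(0)
  ref_genes <- c(stable_genes, unstable_genes)
  target_genes <- if (is.null(spec$targets)) character(0)
                  else unique(as.character(spec$targets$gene))
  genes <- c(ref_genes, target_genes)

  grs <- spec$groups$group
  sample_ids <- unlist(lapply(seq_along(grs), function(i)
    paste0(grs[i], "_", seq_len(spec$groups$n[i]))))
  sample_group <- rep(grs, spec$groups$n)
  ns <- length(sample_ids)

  beta <- matrix(0, length(genes), length(grs),
                 dimnames = list(genes, grs))
  ge <- if (is.null(spec$group_effects)) .default_group_effects(spec, ref_genes)
        else spec$group_effects
  beta[rownames(ge), colnames(ge)] <- ge
  if (!is.null(spec$targets)) {
    for (i in seq_len(nrow(spec$targets)))
      beta[as.character(spec$targets$gene[i]),
           as.character(spec$targets$group[i])] <- spec$targets$log2_fold[i]
  }

  sigma <- c(rep(spec$sigma_stable, spec$n_stable),
             rep(spec$sigma_unstable, spec$n_unstable),
             rep(spec$sigma_target, length(target_genes)))
  lambda <- stats::rnorm(ns, 0, spec$sigma_loading)
  names(lambda) <- sample_ids
  eps <- matrix(stats::rnorm(length(genes) * ns), length(genes), ns) * sigma
  latent <- beta[, sample_group, drop = FALSE] + rep(lambda, each = length(genes)) + eps

  c0 <- stats::runif(length(genes), spec$baseline_ct_range[1],
                     spec$baseline_ct_range[2])
  e_true <- stats::runif(length(genes), spec$efficiency_range[1],
                         spec$efficiency_range[2])
  names(c0) <- names(e_true) <- genes
  ct_vals <- c0 - latent * log(2) / log(e_true)
  dimnames(ct_vals) <- list(genes, sample_ids)

  sheet <- sample_sheet(data.frame(sample_id = sample_ids,
                                   group = sample_group,
                                   is_control = rep(spec$groups$is_control,
                                                    spec$groups$n)))
  e_report <- if (spec$report_e == "assume2") NULL else e_true
  eff <- efficiency_table(e_report, genes)

  target_folds <- NULL
  if (!is.null(spec$targets)) {
    target_folds <- lapply(target_genes, function(tg) {
      f <- 2^beta[tg, ]
      names(f) <- grs
      f
    })
    names(target_folds) <- target_genes
  }

  list(ct = ct_matrix(ct_vals),
       sheet = sheet,
       eff = eff,
       truth = list(stable_genes = stable_genes,
                    unstable_genes = unstable_genes,
                    target_genes = target_genes,
                    loading_offsets = lambda,
                    baseline_ct = c0,
                    true_efficiencies = e_true,
                    group_effects = beta,
                    target_folds = target_folds))
}

#' Generate a dilution-series standard curve
#'
#' Ct at log10 input x is \eqn{c_0 - x / \log_{10} E} plus optional normal
#' noise. Inputs start at the undiluted template (x = 0) and step down by
#' the dilution factor.
#'
#' @param gene_id Gene label.
#' @param true_E True amplification efficiency, in (1, 2.2].
#' @param c0 Ct of the undiluted template.
#' @param dilution_factor Fold dilution per step (default 5).
#' @param n_points Number of points (>= 3, default 5).
#' @param noise_sd SD of Ct noise (cycles; default 0).
#' @return A [dilution_series()].
#' @export
generate_dilution_series <- function(gene_id, true_E, c0 = 30,
                                     dilution_factor = 5, n_points = 5,
                                     noise_sd = 0) {
  if (true_E <= 1 || true_E > 2.2) stop("true_E must be in (1, 2.2]")
  if (n_points < 3) stop("need >= 3 dilution points")
  x <- -(seq_len(n_points) - 1) * log10(dilution_factor)
  ct <- c0 - x / log10(true_E) +
    if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
  dilution_series(gene_id, x, ct)
}

#' Write a synthetic dataset as the CSV/JSON files the readers consume
#'
#' Emits `ct.csv`, `samples.csv`, `eff.csv` and `truth.json` into `dir`.
#'
#' @param ds Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(ds$ct, file.path(dir, "ct.csv"))
  utils::write.csv(as.data.frame(ds$sheet), file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(gene = names(ds$eff), E = as.numeric(ds$eff)),
                   file.path(dir, "eff.csv"), row.names = FALSE)
  truth <- ds$truth
  truth$group_effects <- as.data.frame(truth$group_effects)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
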
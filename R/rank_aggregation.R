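# Consensus ranking across stability algorithms: weighted Spearman-footrule
# objective, minimized either exhaustively (small panels) or by a
# cross-entropy Monte-Carlo search over permutations.

#' Spearman footrule distance between two rankings
#'
#' Sum over items of the absolute difference of their (1-based) positions.
#'
#' @param a,b Character vectors: permutations of the same item set.
#' @return Non-negative integer distance.
#' @export
footrule_distance <- function(a, b) {
  if (!setequal(a, b) || length(a) != length(b) || anyDuplicated(a))
    stop("rankings must be permutations of the same item set")
  sum(abs(seq_along(a) - match(a, b)))
}

# Coerce a list of rankings (character vectors or stability_ranking objects)
# to a common universe; returns list(genes=..., pos = matrix lists x genes of
# positions).
.ranking_positions <- function(lists) {
  lists <- lapply(lists, function(l) {
    if (inherits(l, "stability_ranking")) l$ranking else as.character(l)
  })
  if (length(lists) < 2) stop("need at least two rankings to aggregate")
  genes <- lists[[1]]
  for (l in lists[-1]) {
    if (!setequal(l, genes) || length(l) != length(genes))
      stop("rankings cover different gene universes")
  }
  pos <- matrix(unlist(lapply(lists, function(l) match(genes, l))),
                nrow = length(lists), byrow = TRUE)  # lists x genes
  list(genes = genes, pos = pos)
}

# Objective of candidate position vectors. cand_pos: matrix candidates x
# genes, entry = position of gene in candidate. pos: lists x genes.
.footrule_objective <- function(cand_pos, pos, weights) {
  obj <- numeric(nrow(cand_pos))
  for (l in seq_len(nrow(pos))) {
    obj <- obj + weights[l] *
      rowSums(abs(sweep(cand_pos, 2, pos[l, ])))
  }
  obj
}

new_consensus <- function(genes, order_idx, objective, n_iterations,
                          converged, seed, method) {
  structure(list(ranking = genes[order_idx],
                 objective = objective,
                 n_iterations = n_iterations,
                 converged = converged,
                 seed = seed,
                 method = method),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("consensus_ranking (%s): objective = %g after %d iteration(s)%s\n",
              x$method, x$objective, x$n_iterations,
              if (isTRUE(x$converged)) "" else " [search stopped at iteration cap]"))
  cat(paste(seq_along(x$ranking), x$ranking, collapse = "  "), "\n")
  invisible(x)
}

#' Exhaustive footrule-optimal consensus ranking
#'
#' Enumerates every permutation of the gene universe and returns the one
#' minimizing the summed (weighted) footrule distance to the input lists.
#' Ties are broken lexicographically in the gene order of the first input
#' list. Limited to 8 genes (8! = 40320 permutations); use [aggregate_ce()]
#' beyond that.
#'
#' @param lists List of >= 2 rankings (character vectors or
#'   `stability_ranking` objects) over the same gene universe.
#' @param weights Per-list weights, default all 1.
#' @return A `consensus_ranking`.
#' @export
aggregate_exhaustive <- function(lists, weights = NULL) {
  rp <- .ranking_positions(lists)
  n <- length(rp$genes)
  if (n > 8) stop("exhaustive search limited to 8 genes; use aggregate_ce()")
  if (is.null(weights)) weights <- rep(1, nrow(rp$pos))
  perms <- .permutations(n)              # each row: gene index at position k
  cand_pos <- matrix(0L, nrow(perms), n)
  idx <- cbind(rep(seq_len(nrow(perms)), n), as.vector(perms))
  cand_pos[idx] <- rep(seq_len(n), each = nrow(perms))
  obj <- .footrule_objective(cand_pos, rp$pos, weights)
  # lexicographic tie-break: .permutations() emits rows in lexicographic
  # order of gene indices, so the first minimum is the lexicographic winner
  best <- which.min(obj)
  new_consensus(rp$genes, perms[best, ], obj[best],
                n_iterations = 1L, converged = TRUE, seed = NA_integer_,
                method = "exhaustive")
}

# All permutations of 1..n, rows in lexicographic order.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), k)
    out[rows, 1] <- k
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
  }
  out
}

#' Cross-entropy Monte-Carlo consensus ranking
#'
#' Minimizes the summed weighted footrule distance to the input lists over
#' permutations. The sampler maintains a gene-by-position probability
#' matrix, initialized uniform. Each iteration draws candidate permutations
#' position by position without replacement (sequential renormalization of
#' the matrix columns), scores them, and re-fits the matrix to the elite
#' `rho` fraction with a convex smoothing step
#' `P <- (1 - smoothing) * P_elite + smoothing * P_old`. The input lists
#' themselves are scored in the first iteration, so the returned consensus
#' can never be worse than any input list. The search stops after
#' `stagnation_limit` iterations without improvement of the best-ever
#' objective, or at `max_iter`.
#'
#' @param lists List of >= 2 rankings over the same gene universe.
#' @param weights Per-list weights, default 1.
#' @param seed Integer RNG seed; fixed seed gives a bit-reproducible result.
#' @param samples_per_iter Candidates per iteration; default
#'   `max(2000, 40 * n)`.
#' @param rho Elite fraction (default 0.1).
#' @param smoothing Weight kept on the previous probability matrix
#'   (default 0.25).
#' @param stagnation_limit Iterations without improvement before stopping
#'   (default 15).
#' @param max_iter Hard iteration cap (default 200).
#' @return A `consensus_ranking` with the best-ever candidate, its exact
#'   objective, iteration count and convergence flag.
#' @export
aggregate_ce <- function(lists, weights = NULL, seed = 1L,
                         samples_per_iter = NULL, rho = 0.1,
                         smoothing = 0.25, stagnation_limit = 15L,
                         max_iter = 200L) {
  rp <- .ranking_positions(lists)
  n <- length(rp$genes)
  if (is.null(weights)) weights <- rep(1, nrow(rp$pos))
  if (is.null(samples_per_iter)) samples_per_iter <- max(2000L, 40L * n)
  ns <- as.integer(samples_per_iter)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  prob <- matrix(1 / n, n, n)  # genes x positions
  best_obj <- Inf
  best_perm <- NULL
  stagnant <- 0L
  iter <- 0L

  # positions of the input lists as candidates (elitism at iteration 0)
  input_pos <- rp$pos
  storage.mode(input_pos) <- "integer"

  while (iter < max_iter) {
    iter <- iter + 1L
    # --- sample ns permutations via Gumbel-max per position ---
    cand <- matrix(0L, ns, n)          # gene index at each position
    taken <- matrix(FALSE, ns, n)      # genes already placed, per candidate
    for (k in seq_len(n)) {
      w <- matrix(prob[, k], ns, n, byrow = TRUE)
      w[taken] <- 0
      gumbel <- -log(-log(matrix(stats::runif(ns * n), ns, n)))
      pick <- max.col(log(w) + gumbel, ties.method = "first")
      cand[, k] <- pick
      taken[cbind(seq_len(ns), pick)] <- TRUE
    }
    cand_pos <- matrix(0L, ns, n)
    cand_pos[cbind(rep(seq_len(ns), n), as.vector(cand))] <-
      rep(seq_len(n), each = ns)
    if (iter == 1L) cand_pos <- rbind(cand_pos, input_pos)
    obj <- .footrule_objective(cand_pos, rp$pos, weights)

    o <- order(obj)
    if (obj[o[1]] < best_obj) {
      best_obj <- obj[o[1]]
      best_perm <- cand_pos[o[1], ]    # positions per gene
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    if (stagnant >= stagnation_limit) break

    # --- refit probability matrix from the elite fraction ---
    elite <- cand_pos[o[seq_len(max(1L, ceiling(rho * nrow(cand_pos))))], ,
                      drop = FALSE]
    p_hat <- matrix(0, n, n)
    for (g in seq_len(n)) {
      tab <- tabulate(elite[, g], nbins = n)
      p_hat[g, ] <- tab / nrow(elite)
    }
    prob <- (1 - smoothing) * p_hat + smoothing * prob
    prob <- pmax(prob, 1e-12)
  }
  ord <- order(best_perm)  # genes sorted by assigned position
  new_consensus(rp$genes, ord, best_obj,
                n_iterations = iter,
                converged = stagnant >= stagnation_limit,
                seed = as.integer(seed), method = "cross_entropy")
}

#' Read rank lists from a CSV shaped like published ranking tables
#'
#' Columns = algorithms, rows = rank positions, cells = gene ids.
#'
#' @param path CSV path.
#' @return Named list of character rankings.
#' @export
read_rankings <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lists <- lapply(raw, as.character)
  lists[vapply(lists, function(x) !all(x == "" | is.na(x)), logical(1))]
}
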
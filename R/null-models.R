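# Randomization schemes behind the F-values. Two complementary nulls are
# used: extinction risks are shuffled across the phylogeny while cell
# composition stays fixed (expected PD-loss is a property of a site), and
# species identities are shuffled within cells at fixed richness (HEDGE and
# BED are properties of species, wherever they occur).

new_null_ensemble <- function(statistic, observed, sim, seed, n_rep) {
  stopifnot(nrow(sim) == length(observed), ncol(sim) == n_rep)
  structure(list(statistic = statistic, observed = observed, sim = sim,
                 seed = seed, n_rep = n_rep),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble for '", x$statistic, "': ", length(x$observed),
      " cells x ", x$n_rep, " replicates (seed ",
      if (is.null(x$seed)) "none" else x$seed, ")\n", sep = "")
  invisible(x)
}

# Shared per-cell expected PD-loss engine for the risk-shuffle null. Works in
# clamped log space (log p floored at -1e6, exp of which underflows to 0) so
# that the observed value and every replicate run through the same arithmetic:
# permuting an identical probability vector reproduces the observed values
# bit-exactly, which the strict-inequality F definition relies on.
cellwise_epl_engine <- function(bt, comm, rooting) {
  m_t <- t(comm[, bt$tips, drop = FALSE])        # species x cells
  counts <- bt$desc %*% m_t
  keep <- counts > 0
  if (rooting == "subset_mrca") {
    ksize <- colSums(m_t)
    keep <- keep & sweep(counts, 2L, ksize, "<")
  }
  len <- bt$length
  function(p) {
    lp <- ifelse(p > 0, log(p), -1e6)
    s <- bt$desc %*% (m_t * lp)
    colSums(len * (exp(s) * keep))
  }
}

#' Risk-shuffle null model for expected PD-loss
#'
#' Permutes the extinction-probability vector across the species of the
#' filtered pool `n_rep` times (cell composition fixed) and recomputes the
#' per-cell expected PD-loss for each permutation. With `exhaustive = TRUE`
#' all permutations are enumerated instead (small pools only), which lets
#' tests compare replicate means against the exact permutation mean.
#'
#' @param tree A `phylo` object.
#' @param probs Named extinction probabilities; their names define the pool.
#' @param comm Cells x species binary occurrence matrix.
#' @param n_rep Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param rooting Branch-retention rule for per-cell expected PD-loss.
#' @param exhaustive Enumerate all permutations (pool size <= 8).
#' @return A `null_ensemble` object.
#' @export
shuffle_risks <- function(tree, probs, comm, n_rep = 1000, seed = NULL,
                          rooting = c("regional_root", "subset_mrca"),
                          exhaustive = FALSE) {
  rooting <- match.arg(rooting)
  sp <- names(probs)
  if (is.null(sp)) stop("probs must be named by species")
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  miss <- setdiff(sp, colnames(comm))
  if (length(miss)) stop("species not in matrix: ", paste(miss, collapse = ", "))
  stopifnot(n_rep >= 1)
  tr <- prune_to(tree, sp)
  bt <- branch_table(tr)
  engine <- cellwise_epl_engine(bt, comm, rooting)
  p <- probs[bt$tips]
  observed <- stats::setNames(engine(p), rownames(comm))
  perms <- if (exhaustive) {
    if (length(p) > 8L) stop("exhaustive enumeration limited to 8 species")
    all_permutations(length(p))
  } else {
    with_seed(seed, replicate(n_rep, sample.int(length(p)), simplify = FALSE))
  }
  sim <- vapply(perms, function(ix) engine(p[ix]), numeric(nrow(comm)))
  new_null_ensemble("exp_pd_loss", observed,
                    matrix(sim, nrow = nrow(comm),
                           dimnames = list(rownames(comm), NULL)),
                    seed, length(perms))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_permutations(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

#' Identity-shuffle null model at fixed richness
#'
#' For every replicate and every cell of richness k, draws k distinct species
#' uniformly from the regional scored pool and sums their scores; draws are
#' independent across cells and replicates. The observed statistic is the sum
#' of scores of the species actually present.
#'
#' @param scores Named per-species scores; their names define the pool.
#' @param comm Cells x species binary occurrence matrix.
#' @param n_rep Number of replicates (default 1000).
#' @param seed Optional integer seed.
#' @param statistic Label stored in the ensemble.
#' @return A `null_ensemble` object.
#' @export
shuffle_identities <- function(scores, comm, n_rep = 1000, seed = NULL,
                               statistic = "score_sum") {
  pool <- names(scores)
  if (is.null(pool)) stop("scores must be named by species")
  miss <- setdiff(pool, colnames(comm))
  if (length(miss)) stop("species not in matrix: ", paste(miss, collapse = ", "))
  stopifnot(n_rep >= 1)
  m <- comm[, pool, drop = FALSE]
  k <- rowSums(m)
  np <- length(pool)
  if (any(k > np)) {
    stop("cell richness exceeds the species pool (",
         paste(rownames(comm)[k > np], collapse = ", "), ")")
  }
  sc <- unname(scores[pool])
  observed <- stats::setNames(as.vector(m %*% scores[pool]), rownames(comm))
  sim <- matrix(0, nrow(comm), n_rep, dimnames = list(rownames(comm), NULL))
  with_seed(seed, {
    for (ci in seq_len(nrow(comm))) {
      kk <- k[ci]
      if (kk == 0) next
      draws <- matrix(0L, kk, n_rep)
      for (j in seq_len(n_rep)) draws[, j] <- sample.int(np, kk)
      sim[ci, ] <- colSums(matrix(sc[draws], nrow = kk))
    }
  })
  new_null_ensemble(statistic, observed, sim, seed, n_rep)
}

#' F-values from a null ensemble
#'
#' The frequency with which the observed per-cell value strictly exceeds the
#' simulated values. Ties count against the observed cell, so fully
#' degenerate inputs (all values equal) give F = 0.
#'
#' @param ensemble A `null_ensemble`.
#' @return Named numeric vector of F-values in \[0, 1\], one per cell.
#' @export
f_values <- function(ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  stats::setNames(rowSums(ensemble$sim < ensemble$observed) / ensemble$n_rep,
                  names(ensemble$observed))
}

#' Random equally-sized cell sets
#'
#' Uniform draws of k distinct cells, used as the randomized-hotspot null for
#' complementarity capture and protected-area coverage.
#'
#' @param cells Character vector of cell ids.
#' @param k Set size.
#' @param n_rep Number of draws.
#' @param seed Optional integer seed.
#' @return List of character vectors of length k.
#' @export
random_cell_sets <- function(cells, k, n_rep = 1000, seed = NULL) {
  stopifnot(k >= 1, k <= length(cells), n_rep >= 1)
  with_seed(seed, replicate(n_rep, sample(cells, k), simplify = FALSE))
}
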
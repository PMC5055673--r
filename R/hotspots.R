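# Hotspot selection, complementarity capture, richness surrogates and the
# polytomy-placement sensitivity harness.

index_columns <- function(index) {
  switch(index,
         exp_pd_loss = c(f = "f_exp_pd_loss", raw = "exp_pd_loss"),
         hedge = c(f = "f_hedge", raw = "sum_hedge"),
         bed = c(f = "f_bed", raw = "sum_bed"),
         stop("unknown index '", index, "'"))
}

#' Rank grid cells for an index
#'
#' Cells are ordered best-first by F-value, with ties broken by the raw score
#' and finally by cell id (ascending) for determinism. F is a right-tail
#' frequency, so high-F cells rank first; this is equivalent to sorting cells
#' in increasing order and reading the ranking from the tail.
#'
#' @param table Cell-score data frame carrying the F and raw columns for the
#'   index (e.g. `f_exp_pd_loss` and `exp_pd_loss`).
#' @param index One of `"exp_pd_loss"`, `"hedge"`, `"bed"`.
#' @return Character vector of cell ids, best first.
#' @export
rank_cells <- function(table, index = c("exp_pd_loss", "hedge", "bed")) {
  index <- match.arg(index)
  cols <- index_columns(index)
  need <- c(cols[["f"]], cols[["raw"]], "cell")
  absent <- setdiff(need, names(table))
  if (length(absent)) {
    stop("cell-score table lacks columns: ", paste(absent, collapse = ", "))
  }
  ord <- order(-table[[cols[["f"]]]], -table[[cols[["raw"]]]], table$cell)
  table$cell[ord]
}

new_hotspot_set <- function(index, rule, cells, fraction = NA_real_,
                            seed = NULL, n_rep = NA_integer_) {
  structure(list(index = index, rule = rule, cells = cells,
                 fraction = fraction, seed = seed, n_rep = n_rep),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("Hotspot set (", x$rule, ", index ", x$index, "): ", length(x$cells),
      " cells\n", sep = "")
  invisible(x)
}

hotspot_cells <- function(hotspots) {
  if (inherits(hotspots, "hotspot_set")) hotspots$cells else as.character(hotspots)
}

#' Select hotspots under the Aichi area target
#'
#' Takes the top round(fraction * N) ranked cells (round-half-up), matching
#' the Convention on Biological Diversity target of protecting 17% of land
#' area.
#'
#' @param ranked Character vector of cell ids, best first (from
#'   [rank_cells()]).
#' @param fraction Selection fraction in (0, 1); default 0.17.
#' @param index Optional index label stored in the result.
#' @return A `hotspot_set`; its cells are a prefix of `ranked`.
#' @export
select_aichi <- function(ranked, fraction = 0.17, index = NA_character_) {
  assert_fraction(fraction, "fraction")
  k <- floor(fraction * length(ranked) + 0.5)
  if (k < 1L) stop("selection of 0 cells (fraction too small for ",
                   length(ranked), " cells)")
  new_hotspot_set(index, "aichi_17", ranked[seq_len(k)], fraction)
}

#' Threshold-based alternative hotspot definition
#'
#' Independent of the 17% area target: expected PD-loss hotspots are cells
#' whose raw value strictly exceeds the mean over all cells and whose F-value
#' is at least 0.5; HEDGE and BED hotspots are cells containing at least one
#' top-scoring species with F at least 0.5. The selection may be smaller or
#' larger than 17% of cells.
#'
#' @param table Cell-score data frame with F-values and top-species counts.
#' @param index One of `"exp_pd_loss"`, `"hedge"`, `"bed"`.
#' @return A `hotspot_set` (possibly empty), cells in rank order.
#' @export
select_alternative <- function(table, index = c("exp_pd_loss", "hedge", "bed")) {
  index <- match.arg(index)
  cols <- index_columns(index)
  f <- table[[cols[["f"]]]]
  sel <- if (index == "exp_pd_loss") {
    table$exp_pd_loss > mean(table$exp_pd_loss) & f >= 0.5
  } else {
    ntop <- table[[paste0("n_top_", index)]]
    ntop >= 1L & f >= 0.5
  }
  ranked <- rank_cells(table, index)
  new_hotspot_set(index, "alternative", ranked[ranked %in% table$cell[sel]])
}

#' Complementarity capture of a hotspot set
#'
#' Pools the species occurring in at least one hotspot cell and measures the
#' unique evolutionary history the pool represents — expected PD-loss of the
#' pooled assemblage, or the summed HEDGE/BED scores — as a percentage of the
#' regional value. The p-value is the frequency with which equally sized
#' random cell sets capture at least as much (ties count towards p, per the
#' randomized-hotspot definition).
#'
#' @param hotspots A `hotspot_set` or character vector of cell ids.
#' @param comm Cells x species binary occurrence matrix.
#' @param index One of `"exp_pd_loss"`, `"hedge"`, `"bed"`.
#' @param tree,probs Required for `"exp_pd_loss"`; pooled expected PD-loss is
#'   computed with the same regional rooting as the per-cell values.
#' @param scores Required for `"hedge"`/`"bed"`: named per-species scores.
#' @param n_rep Number of random cell sets (default 1000).
#' @param seed Optional integer seed.
#' @param rooting Branch-retention rule for pooled expected PD-loss.
#' @return List with `observed_pct`, `p_value`, `n_rep`, `index`.
#' @export
capture_complementarity <- function(hotspots, comm,
                                    index = c("exp_pd_loss", "hedge", "bed"),
                                    tree = NULL, probs = NULL, scores = NULL,
                                    n_rep = 1000, seed = NULL,
                                    rooting = "regional_root") {
  index <- match.arg(index)
  cells_hot <- hotspot_cells(hotspots)
  if (!length(cells_hot)) stop("hotspot set is empty")
  unknown <- setdiff(cells_hot, rownames(comm))
  if (length(unknown)) stop("unknown cells: ", paste(unknown, collapse = ", "))
  if (index == "exp_pd_loss") {
    if (is.null(tree) || is.null(probs)) {
      stop("tree and probs are required for index 'exp_pd_loss'")
    }
    scope <- intersect(names(probs), colnames(comm))
    bt <- branch_table(prune_to(tree, scope))
    metric <- function(sp) {
      if (!length(sp)) 0 else expected_pd_loss_bt(bt, probs, sp, rooting)
    }
  } else {
    if (is.null(scores)) stop("scores are required for index '", index, "'")
    scope <- intersect(names(scores), colnames(comm))
    metric <- function(sp) sum(scores[sp])
  }
  pool_of <- function(cl) {
    scope[colSums(comm[cl, scope, drop = FALSE]) > 0]
  }
  total <- metric(pool_of(rownames(comm)))
  if (total <= 0) stop("regional metric is zero; capture undefined")
  obs <- metric(pool_of(cells_hot))
  sets <- random_cell_sets(rownames(comm), length(cells_hot), n_rep, seed)
  rnd <- vapply(sets, function(s) metric(pool_of(s)), numeric(1))
  list(observed_pct = 100 * obs / total,
       p_value = mean(rnd >= obs),
       n_rep = n_rep, index = index)
}

#' Spearman correlations with species-richness surrogates
#'
#' Quantifies how well a plain richness approach would reproduce the
#' phylogenetic surfaces: richness vs PD, threatened-species richness vs
#' expected PD-loss and vs summed HEDGE, and range-restricted-species
#' richness vs summed BED. Mid-ranks are used for ties; two-sided p-values
#' come from the asymptotic t approximation.
#'
#' @param table Cell-score data frame from [cell_scores()].
#' @param pd_per_cell Named numeric vector of per-cell PD (see [cells_pd()]).
#' @return Data frame with columns `comparison`, `rho`, `p_value`,
#'   `degenerate` (TRUE when a zero-variance vector leaves rho undefined).
#' @export
richness_correlations <- function(table, pd_per_cell) {
  if (nrow(table) < 3L) stop("need at least 3 cells")
  pd <- pd_per_cell[match(table$cell, names(pd_per_cell))]
  pairs <- list(
    richness_pd = list(table$richness, unname(pd)),
    threatened_exp_pd_loss = list(table$threatened_richness, table$exp_pd_loss),
    threatened_hedge = list(table$threatened_richness, table$sum_hedge),
    restricted_bed = list(table$restricted_richness, table$sum_bed))
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]][[1L]]
    y <- pairs[[nm]][[2L]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(comparison = nm, rho = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(comparison = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Sensitivity of cell rankings to polytomy placement
#'
#' Species grafted into the phylogeny as within-genus polytomies carry
#' placement uncertainty. This harness re-grafts every missing species at a
#' random position within its genus subtree per replicate, recomputes the
#' per-cell raw scores, and reports the Spearman correlation between each
#' replicate's cell ranking and the baseline ranking obtained with the
#' genus-MRCA polytomy placement. With no missing species every replicate
#' reproduces the baseline and rho is exactly 1.
#'
#' @param tree The phylogeny without the missing species.
#' @param missing Data frame with columns `species` and `genus`.
#' @param comm Occurrence matrix covering missing species too.
#' @param species_table Species attributes covering missing species too.
#' @param n_rep Number of random re-graft replicates.
#' @param seed Optional integer seed.
#' @param top_fraction,mapping Passed to [cell_scores()].
#' @return Data frame with columns `replicate`, `index`, `rho`.
#' @export
polytomy_sensitivity <- function(tree, missing, comm, species_table,
                                 n_rep = 50, seed = NULL, top_fraction = 0.1,
                                 mapping = iucn50_probabilities()) {
  stopifnot(is.data.frame(missing),
            all(c("species", "genus") %in% names(missing)))
  graft_all <- function(mode, base_seed) {
    tr <- tree
    for (j in seq_len(nrow(missing))) {
      g <- missing$genus[j]
      members <- species_table$species[
        species_table$genus == g &
          species_table$species %in% tr$tip.label &
          species_table$species != missing$species[j]]
      if (!length(members)) stop("genus '", g, "' absent from tree")
      tr <- graft_polytomy(tr, missing$species[j], members, mode,
                           seed = if (is.null(base_seed)) NULL else base_seed + j)
    }
    tr
  }
  score_cols <- c("exp_pd_loss", "sum_hedge", "sum_bed")
  index_of <- c(exp_pd_loss = "exp_pd_loss", sum_hedge = "hedge",
                sum_bed = "bed")
  raw_scores <- function(tr) {
    cs <- cell_scores(tr, comm, species_table, top_fraction, mapping)
    cs[order(cs$cell), score_cols, drop = FALSE]
  }
  base <- raw_scores(graft_all("mrca_polytomy", NULL))
  rows <- lapply(seq_len(n_rep), function(r) {
    rs <- if (is.null(seed)) NULL else substream_seed(seed, paste0("regraft-", r))
    rep_scores <- raw_scores(graft_all("random_within_genus", rs))
    data.frame(replicate = r,
               index = unname(index_of[score_cols]),
               rho = vapply(score_cols, function(cl) {
                 spearman_rho(base[[cl]], rep_scores[[cl]])
               }, numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
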
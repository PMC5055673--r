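#' Load a cells x species occurrence matrix from CSV
#'
#' Expects a header row, a first column of cell ids and one 0/1 column per
#' species. Non-binary entries are rejected with their coordinates. Species
#' columns that are all zero are dropped with a warning; when a phylogeny is
#' supplied, species absent from it are dropped with a message reporting the
#' count.
#'
#' @param path CSV file path.
#' @param tree Optional `phylo` object used to screen species columns.
#' @return Integer matrix (cells x species) with cell ids as row names.
#' @export
load_matrix <- function(path, tree = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix CSV needs a cell-id column plus species columns")
  cells <- as.character(df[[1L]])
  if (anyDuplicated(cells)) {
    stop("duplicate cell ids: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1L])) {
    stop("duplicate species columns: ",
         paste(unique(names(df)[-1L][duplicated(names(df)[-1L])]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-binary entry '", df[bad[1L, 1L], bad[1L, 2L] + 1L],
         "' at cell '", cells[bad[1L, 1L]],
         "', species '", colnames(m)[bad[1L, 2L]], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- cells
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " species with no occurrences: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  if (!is.null(tree)) {
    extra <- setdiff(colnames(m), tree$tip.label)
    if (length(extra)) {
      message("dropping ", length(extra), " species absent from the phylogeny")
      m <- m[, setdiff(colnames(m), extra), drop = FALSE]
    }
  }
  m
}

#' Top-scoring species
#'
#' The ceiling(fraction * n) species with the highest scores; ties at the
#' cutoff are broken by species id (lexicographic) for determinism.
#'
#' @param scores Named numeric vector of per-species scores.
#' @param fraction Proportion of species to keep, in (0, 1].
#' @return Character vector of selected species ids.
#' @export
top_species <- function(scores, fraction = 0.1) {
  if (!length(scores)) stop("empty score vector")
  assert_fraction(fraction, "fraction", closed_upper = TRUE)
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}

# Smallest-range species set (ties at the cutoff broken by species id).
smallest_range_species <- function(comm, fraction = 0.1) {
  r <- colSums(comm)
  k <- ceiling(fraction * length(r))
  ord <- order(r, names(r))
  names(r)[ord][seq_len(k)]
}

#' Per-cell scores for all indices
#'
#' Aggregates every per-cell quantity the hotspot analysis needs: expected
#' PD-loss of the cell assemblage, sums of species HEDGE and BED scores,
#' species richness, richness in threatened (CR/EN/VU) species, richness in
#' range-restricted species (top `top_fraction` smallest ranges), and counts
#' of top HEDGE / top BED species present. Index-specific filtering is applied
#' internally: DD species are excluded from the probability-based indices but
#' retained for BED, and EX/RE/NA species are excluded throughout.
#'
#' @param tree A `phylo` object covering the species pool.
#' @param comm Cells x species binary occurrence matrix.
#' @param species_table Data frame with columns `species`, `iucn_category`
#'   and optionally `extinction_prob` (filled from `mapping` otherwise).
#' @param top_fraction Fraction defining "top" species sets (default 0.10).
#' @param mapping Category-to-probability mapping (default IUCN50 preset).
#' @param rooting Branch-retention rule for per-cell expected PD-loss.
#' @param bed_weighting BED variant, see [bed_scores()].
#' @return Data frame with one row per cell; per-species scores and the
#'   probability vector are attached as the `"species_scores"` attribute.
#' @export
cell_scores <- function(tree, comm, species_table, top_fraction = 0.1,
                        mapping = iucn50_probabilities(),
                        rooting = c("regional_root", "subset_mrca"),
                        bed_weighting = c("union_range", "occurrence_sum")) {
  rooting <- match.arg(rooting)
  bed_weighting <- match.arg(bed_weighting)
  sp_all <- colnames(comm)
  risk_sp <- intersect(intersect(species_filter(species_table, "hedge"), sp_all),
                       tree$tip.label)
  bed_sp <- intersect(intersect(species_filter(species_table, "bed"), sp_all),
                      tree$tip.label)
  probs <- extinction_probs(species_table, risk_sp, mapping)

  tree_risk <- prune_to(tree, risk_sp)
  bt_risk <- branch_table(tree_risk)
  hh <- hed_hedge(tree_risk, probs)
  hedge <- stats::setNames(hh$hedge, hh$species)
  tree_bed <- prune_to(tree, bed_sp)
  bed <- bed_scores(tree_bed, comm[, bed_sp, drop = FALSE], bed_weighting)

  m_risk <- comm[, risk_sp, drop = FALSE]
  epl <- vapply(seq_len(nrow(comm)), function(ci) {
    expected_pd_loss_bt(bt_risk, probs, risk_sp[m_risk[ci, ] == 1L], rooting)
  }, numeric(1))

  cats <- stats::setNames(as.character(species_table$iucn_category),
                          species_table$species)
  threatened <- sp_all[cats[sp_all] %in% c("VU", "EN", "CR")]
  restricted <- smallest_range_species(comm, top_fraction)
  top_hedge <- top_species(hedge, top_fraction)
  top_bed <- top_species(bed, top_fraction)

  count_present <- function(set) {
    if (!length(set)) return(rep(0L, nrow(comm)))
    as.integer(rowSums(comm[, set, drop = FALSE]))
  }
  out <- data.frame(
    cell = rownames(comm),
    richness = as.integer(rowSums(comm)),
    threatened_richness = count_present(threatened),
    restricted_richness = count_present(restricted),
    exp_pd_loss = epl,
    sum_hedge = as.vector(comm[, names(hedge), drop = FALSE] %*% hedge),
    sum_bed = as.vector(comm[, names(bed), drop = FALSE] %*% bed),
    n_top_hedge = count_present(top_hedge),
    n_top_bed = count_present(top_bed),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "species_scores") <- list(hedge = hedge, bed = bed, probs = probs,
                                      top_hedge = top_hedge, top_bed = top_bed)
  out
}
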
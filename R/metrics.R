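#' Phylogenetic diversity of a species subset
#'
#' Sum of branch lengths of the minimum path joining a species set on the
#' tree. With `rooting = "regional_root"` every branch from the subset up to
#' the regional tree root is counted (a branch contributes whenever at least
#' one of its descendants is in the set); `"subset_mrca"` drops branches above
#' the subset's most recent common ancestor.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of tip labels.
#' @param rooting `"regional_root"` (default) or `"subset_mrca"`.
#' @return Total branch length (numeric scalar); 0 for an empty set.
#' @export
pd_subset <- function(tree, species,
                      rooting = c("regional_root", "subset_mrca")) {
  rooting <- match.arg(rooting)
  bt <- branch_table(tree)
  pd_subset_bt(bt, species, rooting)
}

pd_subset_bt <- function(bt, species, rooting = "regional_root") {
  unknown <- setdiff(species, bt$tips)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  if (!length(species)) return(0)
  k <- rowSums(bt$desc[, species, drop = FALSE])
  keep <- k > 0
  if (rooting == "subset_mrca") keep <- keep & k < length(species)
  sum(bt$length[keep])
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Divides each branch equally among its descendant tips:
#' `ED_i = sum over root-path branches of L_b / |D(b)|`. The scores partition
#' the tree, so they sum to the total branch length.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector of ED scores, one per tip.
#' @export
fair_proportion_ed <- function(tree) {
  bt <- branch_table(tree)
  w <- bt$length / rowSums(bt$desc)
  stats::setNames(as.vector(crossprod(bt$desc, w)), bt$tips)
}

#' Expected loss of phylogenetic diversity
#'
#' Expected total branch length lost when every species of an assemblage goes
#' extinct independently with its own probability. A branch is lost only if
#' all its descendants within the assemblage are lost (phylogenetic
#' complementarity), so the value is
#' `sum over branches b of L_b * prod_{i in D(b) & assemblage} p_i`,
#' restricted to branches retained under the chosen rooting.
#'
#' @param tree A `phylo` object.
#' @param probs Named numeric vector of extinction probabilities in \[0, 1\].
#' @param assemblage Character vector of tip labels (defaults to all species
#'   with a probability).
#' @param rooting `"regional_root"` (default; per-cell loss of regional
#'   evolutionary history) or `"subset_mrca"`.
#' @return Expected PD loss, in the tree's branch-length units.
#' @export
expected_pd_loss <- function(tree, probs, assemblage = names(probs),
                             rooting = c("regional_root", "subset_mrca")) {
  rooting <- match.arg(rooting)
  bt <- branch_table(tree)
  expected_pd_loss_bt(bt, probs, assemblage, rooting)
}

expected_pd_loss_bt <- function(bt, probs, assemblage, rooting = "regional_root") {
  unknown <- setdiff(assemblage, bt$tips)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(assemblage, names(probs))
  if (length(miss)) {
    stop("missing extinction probability for: ", paste(miss, collapse = ", "))
  }
  if (!length(assemblage)) return(0)
  p <- probs[assemblage]
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("extinction probabilities must lie in [0, 1]")
  }
  inset <- bt$desc[, assemblage, drop = FALSE]
  k <- rowSums(inset)
  keep <- k > 0
  if (rooting == "subset_mrca") keep <- keep & k < length(assemblage)
  total <- 0
  for (e in which(keep)) {
    total <- total + bt$length[e] * prod_prob(p[inset[e, ]])
  }
  total
}

#' Heightened evolutionary distinctiveness and global endangerment
#'
#' `HED_i` is the expected phylogenetic diversity secured by guaranteeing
#' species i's survival: each branch on i's root path contributes its length
#' times the probability that all other descendants of the branch go extinct.
#' `HEDGE_i = p_i * HED_i` weights that by the species' own extinction risk.
#' HED is bounded between the species' terminal branch length (no relative at
#' risk) and its root-to-tip distance (all relatives certain to go extinct).
#'
#' @param tree A `phylo` object; probabilities are required for all tips.
#' @param probs Named numeric vector of extinction probabilities.
#' @return Data frame with columns `species`, `hed`, `hedge`.
#' @export
hed_hedge <- function(tree, probs) {
  bt <- branch_table(tree)
  miss <- setdiff(bt$tips, names(probs))
  if (length(miss)) {
    stop("missing extinction probability for: ", paste(miss, collapse = ", "))
  }
  p <- probs[bt$tips]
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("extinction probabilities must lie in [0, 1]")
  }
  nb <- nrow(bt$desc)
  # per branch: number of zero-probability descendants, and the product of the
  # positive ones -- lets the leave-one-out product be formed exactly even
  # when some p_i are 0
  zeros <- integer(nb)
  pos_prod <- numeric(nb)
  for (e in seq_len(nb)) {
    pe <- p[bt$desc[e, ]]
    zeros[e] <- sum(pe == 0)
    pos_prod[e] <- prod_prob(pe[pe > 0])
  }
  hed <- numeric(bt$n_tip)
  for (i in seq_len(bt$n_tip)) {
    path <- which(bt$desc[, i])
    if (p[i] > 0) {
      term <- ifelse(zeros[path] == 0L, pos_prod[path] / p[i], 0)
    } else {
      term <- ifelse(zeros[path] == 1L, pos_prod[path], 0)
    }
    hed[i] <- sum(bt$length[path] * term)
  }
  data.frame(species = bt$tips, hed = hed, hedge = unname(p) * hed,
             stringsAsFactors = FALSE)
}

#' Biogeographically weighted evolutionary distinctiveness
#'
#' Down-weights each branch of a species' root path by the spatial extent of
#' the clade the branch supports. Under the default `"union_range"` weighting
#' the denominator is the number of grid cells occupied by at least one
#' descendant of the branch (the union of the clade's ranges), so a deep
#' branch is range-restricted only if all its descendants are confined to the
#' same small area. The `"occurrence_sum"` variant partitions each branch
#' among descendants in proportion to their own range sizes
#' (`L_b * r_i / sum_j r_j`), matching the original formulation of the metric.
#'
#' @param tree A `phylo` object; every tip must occur in the matrix.
#' @param comm Cells x species binary occurrence matrix with dimnames.
#' @param weighting `"union_range"` (default) or `"occurrence_sum"`.
#' @return Named numeric vector of BED scores, one per tip.
#' @export
bed_scores <- function(tree, comm,
                       weighting = c("union_range", "occurrence_sum")) {
  weighting <- match.arg(weighting)
  bt <- branch_table(tree)
  absent <- setdiff(bt$tips, colnames(comm))
  if (length(absent)) {
    stop("species absent from the occurrence matrix: ",
         paste(absent, collapse = ", "))
  }
  m <- comm[, bt$tips, drop = FALSE]
  r <- colSums(m)
  if (any(r == 0)) {
    stop("species with empty range: ",
         paste(bt$tips[r == 0], collapse = ", "))
  }
  if (weighting == "union_range") {
    occ <- bt$desc %*% t(m)        # branches x cells occurrence counts
    union_range <- rowSums(occ > 0)
    w <- bt$length / union_range
    scores <- as.vector(crossprod(bt$desc, w))
  } else {
    denom <- as.vector(bt$desc %*% r)
    scores <- r * as.vector(crossprod(bt$desc, bt$length / denom))
  }
  stats::setNames(scores, bt$tips)
}

#' Phylogenetic diversity per grid cell
#'
#' @param tree A `phylo` object.
#' @param comm Cells x species binary occurrence matrix.
#' @param rooting Branch-retention rule, as in [pd_subset()].
#' @return Named numeric vector of PD values, one per cell.
#' @export
cells_pd <- function(tree, comm, rooting = c("regional_root", "subset_mrca")) {
  rooting <- match.arg(rooting)
  sp <- intersect(colnames(comm), tree$tip.label)
  tr <- prune_to(tree, sp)
  bt <- branch_table(tr)
  counts <- bt$desc %*% t(comm[, bt$tips, drop = FALSE])
  keep <- counts > 0
  if (rooting == "subset_mrca") {
    ksize <- colSums(comm[, bt$tips, drop = FALSE])
    keep <- keep & sweep(counts, 2L, ksize, "<")
  }
  stats::setNames(as.vector(crossprod(keep, bt$length)), rownames(comm))
}

# Prune a tree to a species set (no-op when the set covers all tips).
prune_to <- function(tree, species) {
  if (length(species) < 2L) {
    stop("need at least two species to form a tree; got ", length(species))
  }
  if (length(species) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}
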
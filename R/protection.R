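# Protected-area overlay: per-cell coverage fractions under two category
# sets, protection flags under two scenarios, the F_PA randomization test and
# the efficiency classification.

#' Validate a protection layer
#'
#' A protection layer records, per grid cell, the fraction covered by any
#' protected area and the fraction covered by areas of IUCN management
#' categories I, II and IV (the categories whose objectives directly target
#' species protection). The category-restricted fraction can never exceed the
#' overall fraction.
#'
#' @param layer Data frame with columns `cell`, `covered_fraction_all`,
#'   `covered_fraction_i_ii_iv`.
#' @return The validated layer, invisibly usable downstream.
#' @export
validate_protection_layer <- function(layer) {
  need <- c("cell", "covered_fraction_all", "covered_fraction_i_ii_iv")
  absent <- setdiff(need, names(layer))
  if (length(absent)) {
    stop("protection layer lacks columns: ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(layer$cell)) stop("duplicate cell ids in protection layer")
  fa <- layer$covered_fraction_all
  fc <- layer$covered_fraction_i_ii_iv
  if (anyNA(fa) || anyNA(fc) || any(fa < 0 | fa > 1) || any(fc < 0 | fc > 1)) {
    stop("covered fractions must lie in [0, 1]")
  }
  if (any(fc > fa + 1e-12)) {
    stop("covered_fraction_i_ii_iv exceeds covered_fraction_all for cell(s): ",
         paste(layer$cell[fc > fa + 1e-12], collapse = ", "))
  }
  layer
}

#' Load a protection layer from CSV
#'
#' @param path CSV with columns `cell`, `covered_fraction_all`,
#'   `covered_fraction_i_ii_iv`.
#' @return Validated protection-layer data frame.
#' @export
load_protection <- function(path) {
  validate_protection_layer(
    utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-cell protection flags
#'
#' Under the minimum scenario a cell counts as protected if it intersects at
#' least one protected area (covered fraction > 0); under the strong scenario
#' more than half of its area must be covered (strictly greater than 0.5, so
#' exactly 50% does not qualify). Either all protected areas or only
#' categories I/II/IV contribute.
#'
#' @param layer Protection-layer data frame.
#' @param scenario `"minimum"` or `"strong"`.
#' @param categories `"all"` or `"i_ii_iv"`.
#' @return Named integer vector of 0/1 flags, one per cell.
#' @export
protected_flags <- function(layer, scenario = c("minimum", "strong"),
                            categories = c("all", "i_ii_iv")) {
  scenario <- match.arg(scenario)
  categories <- match.arg(categories)
  layer <- validate_protection_layer(layer)
  frac <- layer[[paste0("covered_fraction_", categories)]]
  flag <- if (scenario == "minimum") frac > 0 else frac > 0.5
  stats::setNames(as.integer(flag), layer$cell)
}

#' Classify an F_PA value into an efficiency class
#'
#' Half-open intervals: UNDER when F_PA <= 0.25, AS_EXPECTED when
#' 0.25 < F_PA <= 0.75, OVER when F_PA > 0.75.
#'
#' @param f_pa Numeric F_PA value(s) in \[0, 1\].
#' @return Character vector of classes.
#' @export
classify_f_pa <- function(f_pa) {
  stopifnot(all(f_pa >= 0 & f_pa <= 1))
  ifelse(f_pa <= 0.25, "UNDER", ifelse(f_pa <= 0.75, "AS_EXPECTED", "OVER"))
}

#' Randomization test of hotspot protection (F_PA)
#'
#' Compares the observed proportion of hotspot cells that are protected with
#' the proportions obtained when equally many cells are designated hotspots
#' at random. F_PA is the frequency with which the observed proportion
#' strictly exceeds the simulated one; ties count against the observed value,
#' so fully degenerate layers (e.g. every cell protected) give F_PA = 0 and
#' are flagged so the UNDER class is not misread.
#'
#' @param hotspots A `hotspot_set` or character vector of cell ids.
#' @param flags Named 0/1 protection flags from [protected_flags()].
#' @param n_rep Number of random cell sets (default 1000).
#' @param seed Optional integer seed.
#' @return List with `observed` (proportion protected), `f_pa`, `class`,
#'   `ties` (TRUE when every simulation tied the observed value), `n_rep`.
#' @export
f_pa <- function(hotspots, flags, n_rep = 1000, seed = NULL) {
  cells_hot <- hotspot_cells(hotspots)
  if (!length(cells_hot)) stop("hotspot set is empty")
  unknown <- setdiff(cells_hot, names(flags))
  if (length(unknown)) stop("unknown cells: ", paste(unknown, collapse = ", "))
  observed <- mean(flags[cells_hot])
  sets <- random_cell_sets(names(flags), length(cells_hot), n_rep, seed)
  sims <- vapply(sets, function(s) mean(flags[s]), numeric(1))
  value <- mean(observed > sims)
  ties <- all(sims == observed)
  if (ties) {
    warning("all simulated proportions tie the observed value; ",
            "F_PA = 0 is a degenerate tie, not evidence of under-protection")
  }
  list(observed = observed, f_pa = value, class = classify_f_pa(value),
       ties = ties, n_rep = n_rep)
}

#' Top species with no protected occurrence
#'
#' Identifies top-scoring species whose entire range lies in unprotected
#' cells — the species-level protection gap.
#'
#' @param comm Cells x species binary occurrence matrix.
#' @param flags Named 0/1 protection flags covering the matrix cells.
#' @param top_set Character vector of top species ids.
#' @return Character vector of gap species (subset of `top_set`).
#' @export
species_gap <- function(comm, flags, top_set) {
  if (!length(top_set)) return(character(0))
  absent <- setdiff(top_set, colnames(comm))
  if (length(absent)) {
    stop("top species absent from matrix: ", paste(absent, collapse = ", "))
  }
  fl <- flags[rownames(comm)]
  if (anyNA(fl)) stop("flags must cover every cell of the matrix")
  prot_occ <- colSums(comm[fl == 1L, top_set, drop = FALSE])
  any_occ <- colSums(comm[, top_set, drop = FALSE])
  top_set[prot_occ == 0 & any_occ > 0]
}
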
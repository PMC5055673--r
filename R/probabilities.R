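#' IUCN50 extinction-probability preset
#'
#' The shipped transformation of IUCN Red List categories into probabilities
#' of extinction within 50 years (the "IUCN50" transformation of Mooers et
#' al. 2008, PLoS ONE 3:e3700): LC 0.00005, NT 0.004, VU 0.05, EN 0.42,
#' CR 0.97. The preset is data, not code — it is read from
#' `inst/extdata/iucn50_probabilities.json` and any alternative mapping with
#' the same monotonicity can be supplied wherever a `mapping` argument is
#' accepted.
#'
#' @return Named numeric vector with elements LC, NT, VU, EN, CR.
#' @export
iucn50_probabilities <- function() {
  path <- system.file("extdata", "iucn50_probabilities.json",
                      package = "phylospot", mustWork = TRUE)
  unlist(jsonlite::read_json(path))
}

validate_probability_mapping <- function(mapping) {
  need <- c("LC", "NT", "VU", "EN", "CR")
  absent <- setdiff(need, names(mapping))
  if (length(absent)) {
    stop("probability mapping lacks categories: ", paste(absent, collapse = ", "))
  }
  p <- as.numeric(mapping[need])
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("mapped probabilities must lie in [0, 1]")
  }
  if (any(diff(p) <= 0)) {
    stop("probability mapping must be strictly increasing LC < NT < VU < EN < CR")
  }
  invisible(TRUE)
}

#' Convert IUCN categories to extinction probabilities
#'
#' @param category Character vector of IUCN categories (subset of the mapping
#'   names; DD/EX/RE/NA must be removed beforehand via [species_filter()]).
#' @param mapping Named numeric vector, validated to increase strictly along
#'   LC < NT < VU < EN < CR. Defaults to the shipped IUCN50 preset.
#' @return Numeric vector of probabilities, same length as `category`.
#' @export
category_to_probability <- function(category, mapping = iucn50_probabilities()) {
  validate_probability_mapping(mapping)
  category <- as.character(category)
  bad <- unique(category[!category %in% names(mapping)])
  if (length(bad) || anyNA(category)) {
    stop("no extinction probability mapped for category: ",
         paste(unique(c(bad, if (anyNA(category)) "NA")), collapse = ", "))
  }
  unname(mapping[category])
}

#' Index-specific species filtering rules
#'
#' Extinct (EX), regionally extinct (RE) and not-applicable (NA) species are
#' always excluded. Data-deficient (DD) species are excluded for the
#' probability-based indices (expected PD-loss, HEDGE) but retained for BED,
#' which relies on range sizes only.
#'
#' @param species_table Data frame with columns `species` and `iucn_category`.
#' @param index One of `"exp_pd_loss"`, `"hedge"`, `"bed"`.
#' @return Character vector of retained species ids.
#' @export
species_filter <- function(species_table, index = c("exp_pd_loss", "hedge", "bed")) {
  index <- match.arg(tolower(index[1L]), c("exp_pd_loss", "hedge", "bed"))
  stopifnot(is.data.frame(species_table),
            all(c("species", "iucn_category") %in% names(species_table)))
  cat <- as.character(species_table$iucn_category)
  cat[is.na(cat)] <- "NA"
  keep <- !cat %in% c("EX", "RE", "NA")
  if (index %in% c("exp_pd_loss", "hedge")) keep <- keep & cat != "DD"
  species_table$species[keep]
}

# Per-species extinction probabilities for a scope: taken from an
# `extinction_prob` column when present and complete, otherwise mapped from
# the IUCN category.
extinction_probs <- function(species_table, species, mapping = iucn50_probabilities()) {
  idx <- match(species, species_table$species)
  if (anyNA(idx)) {
    stop("species absent from the species table: ",
         paste(species[is.na(idx)], collapse = ", "))
  }
  p <- if ("extinction_prob" %in% names(species_table)) {
    species_table$extinction_prob[idx]
  } else {
    rep(NA_real_, length(idx))
  }
  miss <- is.na(p)
  if (any(miss)) {
    p[miss] <- category_to_probability(species_table$iucn_category[idx[miss]], mapping)
  }
  if (any(p < 0 | p > 1)) stop("extinction probabilities must lie in [0, 1]")
  stats::setNames(as.numeric(p), species)
}
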
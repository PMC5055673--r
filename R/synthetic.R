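# Synthetic-data generators: Yule trees, spreading-dye ranges, threat
# categories with phylogenetic clustering and a threat-range association,
# protection layers, and the planted-hotspot scenario used as an end-to-end
# recovery harness. Every generator is reproducible from an explicit seed;
# composite scenarios derive one named substream per stage from a root seed.

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth process grown from the root split: while k lineages are extant
#' the waiting time to the next split is exponential with rate
#' `birth_rate * k` and a uniformly chosen lineage splits; after the n-th
#' lineage appears the present is placed one further (uncensored) waiting
#' time later. The expected root-to-tip depth is therefore
#' `sum_{k=2..n} 1 / (birth_rate * k)`.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (per lineage per time unit).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` object with tips `s001`, `s002`, ...
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = NULL) {
  stopifnot(n >= 2, birth_rate > 0)
  with_seed(seed, {
    waits <- stats::rexp(n - 1L, rate = birth_rate * (2:n))
    picks <- if (n > 2L) {
      vapply(2:(n - 1L), function(k) sample.int(k, 1L), integer(1))
    } else integer(0)
    build_yule_tree(n, waits, picks)
  })
}

build_yule_tree <- function(n, waits, picks) {
  root <- n + 1L
  lin_parent <- c(root, root)
  lin_start <- c(0, 0)
  n_edge <- 2L * n - 2L
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  ne <- 0L
  next_node <- n + 2L
  t <- 0
  for (j in seq_len(n - 2L)) {
    t <- t + waits[j]
    i <- picks[j]
    ne <- ne + 1L
    edge[ne, ] <- c(lin_parent[i], next_node)
    elen[ne] <- t - lin_start[i]
    lin_parent[i] <- next_node
    lin_start[i] <- t
    lin_parent <- c(lin_parent, next_node)
    lin_start <- c(lin_start, t)
    next_node <- next_node + 1L
  }
  t <- t + waits[n - 1L]
  for (i in seq_along(lin_parent)) {
    ne <- ne + 1L
    edge[ne, ] <- c(lin_parent[i], i)
    elen[ne] <- t - lin_start[i]
  }
  tree <- structure(
    list(edge = edge, edge.length = elen,
         tip.label = sprintf("s%03d", seq_len(n)), Nnode = n - 1L),
    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# Rescale branch lengths so the maximum root-to-tip depth equals `target`.
rescale_depth <- function(tree, target) {
  d <- max(node_depths(tree)[seq_along(tree$tip.label)])
  tree$edge.length <- tree$edge.length * target / d
  tree
}

grid_cell_ids <- function(n_cells) {
  sprintf("c%0*d", max(3L, nchar(n_cells)), seq_len(n_cells))
}

# 4- or 8-neighbour adjacency for a nrow x ncol grid, row-major cell indices.
grid_neighbours <- function(nrow, ncol, neighbourhood = 4) {
  nrow <- as.integer(nrow)
  ncol <- as.integer(ncol)
  idx <- function(r, c) (r - 1L) * ncol + c
  lapply(seq_len(nrow * ncol), function(i) {
    r <- (i - 1L) %/% ncol + 1L
    c <- (i - 1L) %% ncol + 1L
    off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    if (neighbourhood == 8) {
      off <- c(off, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
    }
    nb <- vapply(off, function(o) {
      rr <- r + o[1L]; cc <- c + o[2L]
      if (rr < 1L || rr > nrow || cc < 1L || cc > ncol) NA_integer_ else idx(rr, cc)
    }, integer(1))
    nb[!is.na(nb)]
  })
}

spreading_dye <- function(neighbours, n_cells, size) {
  in_patch <- logical(n_cells)
  start <- sample.int(n_cells, 1L)
  in_patch[start] <- TRUE
  frontier <- neighbours[[start]]
  while (sum(in_patch) < size) {
    if (!length(frontier)) stop("grid is disconnected: spreading dye stalled")
    f <- frontier[sample.int(length(frontier), 1L)]
    in_patch[f] <- TRUE
    frontier <- frontier[frontier != f]
    new <- neighbours[[f]]
    frontier <- c(frontier, new[!in_patch[new] & !(new %in% frontier)])
  }
  which(in_patch)
}

#' Simulate spatially contiguous species ranges
#'
#' Spreading-dye model: each range starts from a uniformly chosen seed cell
#' and grows by repeatedly adding a uniformly chosen frontier cell (4- or
#' 8-neighbourhood) until the exact target size is reached, so every range is
#' connected and exactly sized.
#'
#' @param dims Grid dimensions `c(nrow, ncol)`.
#' @param sizes Integer vector of target range sizes (one per species),
#'   optionally named by species id; each must lie in \[1, nrow * ncol\].
#' @param seed Optional integer seed.
#' @param neighbourhood 4 (default) or 8.
#' @return Cells x species binary integer matrix with dimnames.
#' @export
simulate_ranges <- function(dims, sizes, seed = NULL, neighbourhood = 4) {
  stopifnot(length(dims) == 2L, all(dims >= 1), neighbourhood %in% c(4, 8))
  n_cells <- as.integer(dims[1L] * dims[2L])
  species <- names(sizes) %||% sprintf("s%03d", seq_along(sizes))
  sizes <- as.integer(round(sizes))
  if (any(sizes < 1L) || any(sizes > n_cells)) {
    stop("range sizes must lie in [1, ", n_cells, "]")
  }
  nb <- grid_neighbours(dims[1L], dims[2L], neighbourhood)
  with_seed(seed, {
    m <- matrix(0L, n_cells, length(sizes),
                dimnames = list(grid_cell_ids(n_cells), species))
    for (j in seq_along(sizes)) {
      m[spreading_dye(nb, n_cells, sizes[j]), j] <- 1L
    }
    m
  })
}

#' Assign IUCN categories with phylogenetic and spatial structure
#'
#' Draws a latent severity for every species by mixing (a) the normal scores
#' of negative range size (severity-range association controlled by
#' `threat_range_corr`), (b) a Brownian-motion trait simulated on the tree
#' (phylogenetic clustering of extinction risk, strength `clustering`) and
#' (c) independent noise, then thresholds the latent severity into LC...CR at
#' the configured proportions (most severe categories to the highest latent
#' values). At `threat_range_corr = 1` the smallest-range species receive the
#' most severe categories exactly (up to ties). An optional fraction of
#' species is relabelled data-deficient (DD) uniformly at random.
#'
#' @param tree A `phylo` object.
#' @param comm Occurrence matrix whose column sums give range sizes.
#' @param clustering Phylogenetic clustering strength in \[0, 1\].
#' @param threat_range_corr Target rank correlation between severity and
#'   negative range size, in \[-1, 1\]. The realized Spearman correlation of
#'   category severity with negative range size is attenuated slightly by the
#'   categorical thresholding.
#' @param seed Optional integer seed.
#' @param proportions Named category proportions (LC, NT, VU, EN, CR).
#' @param dd_fraction Fraction of species relabelled DD (default 0.05).
#' @param mapping Category-to-probability mapping for `extinction_prob`.
#' @param endemic_max_frac A species is flagged endemic when its range covers
#'   at most this fraction of the grid (default 0.1).
#' @return Data frame with columns `species`, `genus`, `iucn_category`,
#'   `extinction_prob` (NA for DD), `endemic`, `range_size`.
#' @export
assign_categories <- function(tree, comm, clustering = 0.3,
                              threat_range_corr = 0.5, seed = NULL,
                              proportions = c(LC = 0.55, NT = 0.15, VU = 0.12,
                                              EN = 0.10, CR = 0.08),
                              dd_fraction = 0.05,
                              mapping = iucn50_probabilities(),
                              endemic_max_frac = 0.1) {
  stopifnot(clustering >= 0, clustering <= 1,
            threat_range_corr >= -1, threat_range_corr <= 1,
            dd_fraction >= 0, dd_fraction < 1,
            all(tree$tip.label %in% colnames(comm)))
  proportions <- proportions / sum(proportions)
  n <- length(tree$tip.label)
  r <- colSums(comm)[tree$tip.label]
  normal_scores <- function(x) {
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  }
  with_seed(seed, {
    u <- normal_scores(-r)
    b <- normal_scores(ape::rTraitCont(tree, model = "BM"))
    e <- stats::rnorm(n)
    resid <- if (clustering >= 1) b else {
      clustering * b + sqrt(1 - clustering^2) * e
    }
    rho <- threat_range_corr
    latent <- if (abs(rho) >= 1) sign(rho) * u else {
      rho * u + sqrt(1 - rho^2) * resid
    }
    q <- (rank(latent, ties.method = "first") - 0.5) / n
    category <- as.character(cut(q, breaks = c(0, cumsum(proportions)),
                                 labels = names(proportions)))
    if (dd_fraction > 0) {
      ndd <- round(dd_fraction * n)
      if (ndd > 0) category[sample.int(n, ndd)] <- "DD"
    }
    prob <- rep(NA_real_, n)
    ok <- category != "DD"
    prob[ok] <- category_to_probability(category[ok], mapping)
    data.frame(species = tree$tip.label,
               genus = unname(genus_from_tree(tree)),
               iucn_category = category,
               extinction_prob = prob,
               endemic = unname(r) <= endemic_max_frac * nrow(comm),
               range_size = unname(r),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a protected-area coverage layer
#'
#' Generates spatially clustered per-cell covered fractions: an independent
#' Gaussian field is smoothed (`clustering` neighbour-averaging passes), its
#' rank transform decides which cells intersect at least one protected area
#' (an `intersect_fraction` share of cells, the rest having exactly zero
#' coverage, emulating sparse real-world networks), and intersecting cells
#' receive Beta-distributed fractions calibrated so the grid-wide mean
#' coverage is `target_coverage`. A zero-inflated Beta share with mean
#' `category_split` assigns part of each cell's coverage to protected areas
#' of categories I/II/IV, so category-restricted coverage is sparser than
#' overall coverage.
#'
#' @param dims Grid dimensions `c(nrow, ncol)`.
#' @param target_coverage Mean covered fraction in \[0, 1\].
#' @param category_split Mean share of coverage in categories I/II/IV.
#' @param clustering Number of smoothing passes (>= 0).
#' @param intersect_fraction Share of cells intersecting any protected area
#'   (raised automatically when `target_coverage` requires it).
#' @param seed Optional integer seed.
#' @return Protection-layer data frame (see [validate_protection_layer()]).
#' @export
simulate_protection <- function(dims, target_coverage = 0.05,
                                category_split = 0.2, clustering = 2,
                                intersect_fraction = 0.5, seed = NULL) {
  stopifnot(length(dims) == 2L,
            target_coverage >= 0, target_coverage <= 1,
            category_split >= 0, category_split <= 1, clustering >= 0,
            intersect_fraction > 0, intersect_fraction <= 1)
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  n_cells <- nr * nc
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_cells), nr, nc)
    for (i in seq_len(round(clustering))) {
      up <- z[c(1L, seq_len(nr - 1L)), , drop = FALSE]
      down <- z[c(seq_len(nr)[-1L], nr), , drop = FALSE]
      left <- z[, c(1L, seq_len(nc - 1L)), drop = FALSE]
      right <- z[, c(seq_len(nc)[-1L], nc), drop = FALSE]
      z <- (z + up + down + left + right) / 5
    }
    v <- as.vector(t(z))   # row-major, matching grid cell ids
    u <- (rank(v, ties.method = "first") - 0.5) / n_cells
    covered_all <- if (target_coverage <= 0) {
      rep(0, n_cells)
    } else if (target_coverage >= 1) {
      rep(1, n_cells)
    } else {
      pf <- max(intersect_fraction, min(1, 2 * target_coverage))
      mu <- target_coverage / pf
      hit <- u > 1 - pf
      frac <- rep(0, n_cells)
      frac[hit] <- stats::qbeta((u[hit] - (1 - pf)) / pf,
                                2 * mu, 2 * (1 - mu))
      frac
    }
    share <- if (category_split <= 0) {
      rep(0, n_cells)
    } else if (category_split >= 1) {
      rep(1, n_cells)
    } else {
      q <- min(1, 2 * category_split)
      mu_s <- category_split / q
      present <- stats::rbinom(n_cells, 1L, q)
      b <- if (mu_s >= 1) rep(1, n_cells) else {
        stats::rbeta(n_cells, 2 * mu_s, 2 * (1 - mu_s))
      }
      present * b
    }
    validate_protection_layer(data.frame(
      cell = grid_cell_ids(n_cells),
      covered_fraction_all = covered_all,
      covered_fraction_i_ii_iv = covered_all * share,
      stringsAsFactors = FALSE))
  })
}

#' Planted-hotspot scenario
#'
#' Deterministic (seeded) input bundle with known ground truth: 17% of grid
#' cells are designated hotspots and exclusively contain all members of one
#' evolutionarily distinct, critically endangered clade, while least-concern
#' background species occur everywhere. The background tree and a smaller
#' planted clade are simulated as Yule trees, rescaled and joined at a new
#' root with a long stem below the planted clade (high evolutionary
#' distinctiveness). Used to check that the expected PD-loss pipeline
#' recovers the planted cells.
#'
#' @param seed Root seed; every stage draws a named substream from it.
#' @param dims Grid dimensions (default 10 x 10).
#' @param n_background Number of background (LC) species.
#' @param n_planted Number of planted (CR) clade species.
#' @param hotspot_fraction Fraction of cells planted (default 0.17).
#' @param mapping Category-to-probability mapping.
#' @return List with elements `tree`, `comm`, `species_table`, `protection`,
#'   `planted_cells`, `hotspot_fraction`, `seed`; class `planted_scenario`.
#' @export
planted_hotspot_scenario <- function(seed = 1, dims = c(10, 10),
                                     n_background = 50, n_planted = 12,
                                     hotspot_fraction = 0.17,
                                     mapping = iucn50_probabilities()) {
  ss <- function(name) substream_seed(seed, name)
  n_cells <- as.integer(dims[1L] * dims[2L])
  cells <- grid_cell_ids(n_cells)

  bg <- rescale_depth(simulate_tree(n_background, 1, ss("background-tree")), 1)
  bg$tip.label <- sprintf("b%03d", seq_len(n_background))
  pl <- rescale_depth(simulate_tree(n_planted, 1, ss("planted-tree")), 0.4)
  pl$tip.label <- sprintf("p%03d", seq_len(n_planted))
  strip <- function(tr) sub(";$", "", ape::write.tree(tr))
  tree <- parse_newick(sprintf("(%s:0.1,%s:0.7);", strip(bg), strip(pl)))

  k_hot <- floor(hotspot_fraction * n_cells + 0.5)
  planted_cells <- with_seed(ss("planted-cells"), sample(cells, k_hot))

  bg_sizes <- with_seed(ss("background-sizes"), {
    stats::setNames(pmax(1L, pmin(n_cells, as.integer(round(
      stats::rlnorm(n_background, log(15), 0.6))))), bg$tip.label)
  })
  comm_bg <- simulate_ranges(dims, bg_sizes, ss("background-ranges"))

  comm_pl <- with_seed(ss("planted-ranges"), {
    m <- matrix(0L, n_cells, n_planted, dimnames = list(cells, pl$tip.label))
    for (j in seq_len(n_planted)) {
      m[sample(planted_cells, sample.int(min(4L, k_hot), 1L)), j] <- 1L
    }
    uncovered <- planted_cells[rowSums(m[planted_cells, , drop = FALSE]) == 0]
    for (cl in uncovered) m[cl, sample.int(n_planted, 1L)] <- 1L
    m
  })
  comm <- cbind(comm_bg, comm_pl)

  ranges <- colSums(comm)[tree$tip.label]
  category <- ifelse(startsWith(tree$tip.label, "p"), "CR", "LC")
  species_table <- data.frame(
    species = tree$tip.label,
    genus = unname(genus_from_tree(tree)),
    iucn_category = category,
    extinction_prob = category_to_probability(category, mapping),
    endemic = unname(ranges) <= 0.1 * n_cells,
    range_size = unname(ranges),
    stringsAsFactors = FALSE)

  protection <- simulate_protection(dims, 0.05, 0.2, 2, seed = ss("protection"))

  structure(list(tree = tree, comm = comm, species_table = species_table,
                 protection = protection, planted_cells = planted_cells,
                 hotspot_fraction = hotspot_fraction, seed = seed,
                 dims = dims),
            class = "planted_scenario")
}
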
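score_table <- function(cell, f, raw) {
  data.frame(cell = cell, f_exp_pd_loss = f, exp_pd_loss = raw,
             stringsAsFactors = FALSE)
}

test_that("cells rank by F, then raw score, then cell id", {
  tb <- score_table(c("c1", "c2"), c(0.1, 0.9), c(1, 1))
  expect_identical(rank_cells(tb, "exp_pd_loss"), c("c2", "c1"))
  tb <- score_table(c("c1", "c2"), c(0.5, 0.5), c(5, 7))
  expect_identical(rank_cells(tb, "exp_pd_loss"), c("c2", "c1"))
  tb <- score_table(c("c2", "c1"), c(0.5, 0.5), c(7, 7))
  expect_identical(rank_cells(tb, "exp_pd_loss"), c("c1", "c2"))
})

test_that("Aichi selection rounds half-up and returns a ranked prefix", {
  ranked100 <- sprintf("c%03d", 1:100)
  expect_length(select_aichi(ranked100, 0.17)$cells, 17L)
  ranked477 <- sprintf("c%03d", 1:477)
  hs <- select_aichi(ranked477, 0.17)
  expect_length(hs$cells, 81L)
  expect_identical(hs$cells, ranked477[1:81])
  expect_length(select_aichi(sprintf("c%04d", 1:1489), 0.17)$cells, 253L)
  expect_error(select_aichi(c("a", "b"), 0.17), "0 cells")
})

test_that("alternative hotspots follow threshold rules without a size cap", {
  tb <- data.frame(cell = c("c1", "c2", "c3"),
                   exp_pd_loss = c(2, 2, 2), f_exp_pd_loss = c(1, 1, 1))
  expect_length(select_alternative(tb, "exp_pd_loss")$cells, 0L)

  tb2 <- data.frame(cell = c("c1", "c2", "c3"),
                    sum_hedge = c(9, 1, 1), f_hedge = c(1, 0.2, 0.2),
                    n_top_hedge = c(1L, 0L, 0L))
  expect_identical(select_alternative(tb2, "hedge")$cells, "c1")

  # the rule may select more than 17% of cells
  tb3 <- data.frame(cell = sprintf("c%02d", 1:10),
                    sum_hedge = 10:1, f_hedge = rep(0.9, 10),
                    n_top_hedge = rep(1L, 10))
  expect_length(select_alternative(tb3, "hedge")$cells, 10L)
})

test_that("complementarity capture is total for the full grid and monotone", {
  sc <- planted_hotspot_scenario(seed = 3, n_background = 20, n_planted = 6)
  cs <- cell_scores(sc$tree, sc$comm, sc$species_table)
  hedge <- attr(cs, "species_scores")$hedge
  all_cells <- rownames(sc$comm)
  cap_all <- capture_complementarity(all_cells, sc$comm, "hedge",
                                     scores = hedge, n_rep = 50, seed = 5)
  expect_equal(cap_all$observed_pct, 100)
  expect_equal(cap_all$p_value, 1)   # every random set captures the total too

  base_cells <- sc$planted_cells[1:5]
  cap_small <- capture_complementarity(base_cells, sc$comm, "hedge",
                                       scores = hedge, n_rep = 50, seed = 5)
  cap_grown <- capture_complementarity(c(base_cells, setdiff(all_cells, base_cells)[1:10]),
                                       sc$comm, "hedge",
                                       scores = hedge, n_rep = 50, seed = 5)
  expect_gte(cap_grown$observed_pct, cap_small$observed_pct)
})

test_that("planted hotspots capture all threatened history significantly", {
  sc <- planted_hotspot_scenario(seed = 11)
  cs <- cell_scores(sc$tree, sc$comm, sc$species_table)
  sp_scores <- attr(cs, "species_scores")
  cap <- capture_complementarity(sc$planted_cells, sc$comm, "exp_pd_loss",
                                 tree = sc$tree, probs = sp_scores$probs,
                                 n_rep = 400, seed = 21)
  # all CR species are confined to the planted cells, so essentially the whole
  # regional expected loss is captured (the residual comes from the few
  # least-concern background species absent from those cells)
  expect_gte(cap$observed_pct, 99.5)
  expect_lte(cap$p_value, 0.05)
  hcap <- capture_complementarity(sc$planted_cells, sc$comm, "hedge",
                                  scores = sp_scores$hedge,
                                  n_rep = 400, seed = 22)
  expect_gte(hcap$observed_pct, 99.5)
  expect_lte(hcap$p_value, 0.05)
})

test_that("richness correlations match the rank formula and flag degeneracy", {
  tb <- data.frame(cell = sprintf("c%d", 1:5),
                   richness = c(1, 2, 3, 4, 5),
                   threatened_richness = c(0, 1, 1, 2, 3),
                   restricted_richness = c(4, 3, 2, 1, 0),
                   exp_pd_loss = c(0.5, 1, 2, 4, 8),
                   sum_hedge = c(0.1, 0.4, 0.3, 0.9, 1.2),
                   sum_bed = c(0.5, 1, 1.5, 2, 4))
  pd <- stats::setNames(c(3, 4, 6, 8, 10), tb$cell)
  out <- richness_correlations(tb, pd)
  expect_equal(out$rho[out$comparison == "richness_pd"], 1)       # monotone pair
  expect_equal(out$rho[out$comparison == "restricted_bed"], -1)   # reversed pair
  # brute-force mid-rank formula for the tied pair
  brute <- stats::cor(rank(tb$threatened_richness), rank(tb$exp_pd_loss))
  expect_equal(out$rho[out$comparison == "threatened_exp_pd_loss"], brute,
               tolerance = 1e-12)
  tb$threatened_richness <- rep(1, 5)
  out2 <- richness_correlations(tb, pd)
  expect_true(out2$degenerate[out2$comparison == "threatened_hedge"])
  expect_true(is.na(out2$rho[out2$comparison == "threatened_hedge"]))
})

polytomy_fixture <- function(seed = 2) {
  full <- simulate_tree(22, 1, seed = seed)
  dims <- c(6, 6)
  sizes <- stats::setNames(rep(6L, 22), full$tip.label)
  comm <- simulate_ranges(dims, sizes, seed = seed + 1)
  st <- assign_categories(full, comm, clustering = 0.3,
                          threat_range_corr = 0.4, seed = seed + 2,
                          dd_fraction = 0)
  genera <- table(st$genus)
  cand <- st$species[st$genus %in% names(genera[genera >= 3])]
  missing <- st[st$species %in% cand[1:2], c("species", "genus")]
  tree <- ape::drop.tip(full, missing$species)
  list(tree = tree, comm = comm, st = st, missing = missing)
}

test_that("polytomy sensitivity returns rho exactly 1 with nothing to graft", {
  fx <- polytomy_fixture()
  none <- fx$missing[0, ]
  out <- polytomy_sensitivity(fx$tree, none, fx$comm, fx$st, n_rep = 2,
                              seed = 1)
  expect_true(all(out$rho == 1))
  expect_setequal(unique(out$index), c("exp_pd_loss", "hedge", "bed"))
})

test_that("cell rankings are robust to within-genus graft placement", {
  fx <- polytomy_fixture()
  out <- polytomy_sensitivity(fx$tree, fx$missing, fx$comm, fx$st,
                              n_rep = 5, seed = 31)
  expect_equal(nrow(out), 15L)
  expect_gte(stats::median(out$rho), 0.8)
  # deterministic given the seed
  out2 <- polytomy_sensitivity(fx$tree, fx$missing, fx$comm, fx$st,
                               n_rep = 5, seed = 31)
  expect_identical(out, out2)
  bad <- data.frame(species = "zz", genus = "no_such_genus")
  expect_error(polytomy_sensitivity(fx$tree, bad, fx$comm, fx$st, n_rep = 1),
               "absent from tree")
})
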
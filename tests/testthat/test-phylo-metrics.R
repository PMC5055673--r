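test_that("parse_newick reads valid trees and rejects malformed input", {
  tr <- t1()
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[match("A", tr$tip.label)], 2)

  expect_error(parse_newick("((A:1,A:1):1);"), "duplicate tip labels: A")
  expect_error(parse_newick("((A:1,B:1):1,C:2):0;)"), "position")
  expect_error(parse_newick("(((A:1,B:1):1,C:2:0;"), "position")
  expect_error(parse_newick("((A:1,B:-1):1,C:2);"), "finite and >= 0")
})

test_that("parse -> serialize -> parse round-trips branch lengths", {
  set.seed(11)
  for (i in 1:5) {
    tr <- rand_tree(8)
    rt <- parse_newick(ape::write.tree(tr))
    expect_equal(sort(rt$tip.label), sort(tr$tip.label))
    d1 <- ape::node.depth.edgelength(tr)[seq_len(8)]
    d2 <- ape::node.depth.edgelength(rt)[seq_len(8)]
    expect_equal(d2[match(tr$tip.label, rt$tip.label)], d1)
  }
})

test_that("category mapping looks up probabilities and enforces monotonicity", {
  mp <- c(LC = 0.01, NT = 0.02, VU = 0.1, EN = 0.4, CR = 0.97)
  expect_equal(category_to_probability("CR", mp), 0.97)
  expect_equal(category_to_probability(c("LC", "EN"), mp), c(0.01, 0.4))
  expect_error(category_to_probability("XX", mp), "XX")
  bad <- mp; bad["EN"] <- 0.05
  expect_error(category_to_probability("LC", bad), "strictly increasing")
})

test_that("shipped IUCN50 preset matches its transcription exactly", {
  preset <- iucn50_probabilities()
  expect_identical(preset[c("LC", "NT", "VU", "EN", "CR")],
                   c(LC = 0.00005, NT = 0.004, VU = 0.05, EN = 0.42, CR = 0.97))
  raw <- unlist(jsonlite::read_json(system.file(
    "extdata", "iucn50_probabilities.json", package = "phylospot")))
  expect_identical(preset, raw)
})

test_that("species_filter applies index-specific rules", {
  st <- data.frame(species = c("A", "B", "C", "D", "E"),
                   iucn_category = c("LC", "DD", "EX", "RE", "NA"))
  expect_setequal(species_filter(st, "hedge"), "A")
  expect_setequal(species_filter(st, "exp_pd_loss"), "A")
  expect_setequal(species_filter(st, "bed"), c("A", "B"))
  empty <- st[0, ]
  expect_length(species_filter(empty, "hedge"), 0)
})

test_that("pd_subset handles both rootings", {
  tr <- t1()
  expect_equal(pd_subset(tr, c("A", "B", "C")), 5)
  expect_equal(pd_subset(tr, "A"), 2)
  expect_equal(pd_subset(tr, c("A", "B"), "subset_mrca"), 2)
  expect_equal(pd_subset(tr, c("A", "B")), 3)
  expect_equal(pd_subset(tr, c("A", "B", "C"), "subset_mrca"), 5)
  expect_equal(pd_subset(tr, character(0)), 0)
  expect_error(pd_subset(tr, "Z"), "unknown species: Z")
})

test_that("fair proportion divides branches equally and partitions the tree", {
  ed <- fair_proportion_ed(t1())
  expect_equal(ed, c(A = 1.5, B = 1.5, C = 2))
  star <- parse_newick("(A:3,B:3,C:3,D:3);")
  expect_equal(unname(fair_proportion_ed(star)), rep(3, 4))
  set.seed(21)
  for (i in 1:10) {
    tr <- rand_tree(sample(4:30, 1))
    expect_equal(sum(fair_proportion_ed(tr)), sum(tr$edge.length),
                 tolerance = 1e-12)
  }
})

test_that("fair proportion agrees with an independent implementation", {
  skip_if_not_installed("picante")
  set.seed(31)
  tr <- rand_tree(25)
  ref <- picante::evol.distinct(tr, type = "fair.proportion")
  expect_equal(unname(fair_proportion_ed(tr)[ref$Species]), ref$w,
               tolerance = 1e-10)
})

test_that("expected PD loss matches hand calculations and boundaries", {
  tr <- t1()
  p <- c(A = 0.5, B = 0.5, C = 0.1)
  expect_equal(expected_pd_loss(tr, p), 1.45)
  ones <- c(A = 1, B = 1, C = 1)
  expect_equal(expected_pd_loss(tr, ones), pd_subset(tr, names(ones)))
  expect_equal(expected_pd_loss(tr, ones * 0), 0)
  expect_error(expected_pd_loss(tr, p[-1], c("A", "B")),
               "missing extinction probability for: A")
})

test_that("expected PD loss is monotone in each extinction probability", {
  set.seed(41)
  for (i in 1:10) {
    tr <- rand_tree(8)
    p <- rand_probs(tr$tip.label)
    base <- expected_pd_loss(tr, p)
    j <- sample(8, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + stats::runif(1, 0, 1 - p[j]))
    expect_gte(expected_pd_loss(tr, p2) + 1e-12, base)
  }
})

test_that("shared extinction probability bounds from complementarity hold", {
  set.seed(51)
  for (i in 1:5) {
    tr <- rand_tree(9)
    pd <- sum(tr$edge.length)
    p <- stats::runif(1, 0.05, 0.95)
    loss <- expected_pd_loss(tr, stats::setNames(rep(p, 9), tr$tip.label))
    expect_gte(loss, p^9 * pd - 1e-12)
    expect_lte(loss, p * pd + 1e-12)
  }
})

test_that("HED and HEDGE match hand calculations and limits", {
  tr <- t1()
  hh <- hed_hedge(tr, c(A = 0.5, B = 1, C = 0.1))
  expect_equal(hh$hed[hh$species == "A"], 2)   # doomed sibling secures shared branch
  hh <- hed_hedge(tr, c(A = 0.5, B = 0.5, C = 0.1))
  expect_equal(hh$hed[hh$species == "A"], 1.5)
  expect_equal(hh$hedge[hh$species == "A"], 0.75)
  expect_equal(hh$hedge, ifelse(hh$species == "C", 0.1, 0.5) * hh$hed)
  hh0 <- hed_hedge(tr, c(A = 0, B = 0, C = 0))
  expect_equal(stats::setNames(hh0$hed, hh0$species), c(A = 1, B = 1, C = 2))
})

test_that("HED stays within its terminal-branch and root-path bounds", {
  set.seed(61)
  for (i in 1:10) {
    tr <- rand_tree(10)
    p <- rand_probs(tr$tip.label)
    hh <- hed_hedge(tr, p)
    term <- tr$edge.length[match(seq_len(10), tr$edge[, 2])]
    depth <- ape::node.depth.edgelength(tr)[seq_len(10)]
    expect_true(all(hh$hed >= term - 1e-12))
    expect_true(all(hh$hed <= depth + 1e-12))
    expect_equal(hh$hedge, unname(p[hh$species]) * hh$hed)
  }
})

test_that("BED with union-range weighting matches hand calculations", {
  tr <- t1()
  comm <- comm_from_ranges(list(A = "c1", B = "c1", C = "c2"), c("c1", "c2"))
  b <- bed_scores(tr, comm)
  expect_equal(b[["A"]], 2)   # 1/1 terminal + 1/1 shared branch
  expect_equal(b[["C"]], 2)   # 2/1 terminal

  one_cell <- comm_from_ranges(list(A = "c1", B = "c1", C = "c1"), "c1")
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(bed_scores(tr, one_cell)[tr$tip.label]), depths)

  empty <- comm; empty[, "B"] <- 0L
  expect_error(bed_scores(tr, empty), "species with empty range: B")
})

test_that("duplicating every occupied cell halves union-range BED", {
  set.seed(71)
  tr <- rand_tree(6)
  cells <- sprintf("x%02d", 1:8)
  comm <- matrix(rbinom(48, 1, 0.4), 8, 6,
                 dimnames = list(cells, tr$tip.label))
  comm[1, colSums(comm) == 0] <- 1L
  doubled <- rbind(comm, comm)
  rownames(doubled) <- c(cells, sprintf("y%02d", 1:8))
  expect_equal(bed_scores(tr, doubled), bed_scores(tr, comm) / 2)
})

test_that("occurrence-sum BED partitions total branch length", {
  set.seed(81)
  tr <- rand_tree(7)
  comm <- matrix(rbinom(70, 1, 0.5), 10, 7,
                 dimnames = list(sprintf("x%02d", 1:10), tr$tip.label))
  comm[1, colSums(comm) == 0] <- 1L
  b <- bed_scores(tr, comm, weighting = "occurrence_sum")
  expect_equal(sum(b), sum(tr$edge.length), tolerance = 1e-10)
})

test_that("polytomy grafting preserves ultrametricity and inverts by pruning", {
  tr <- simulate_tree(10, 1, seed = 5)
  members <- tr$tip.label[1:4]
  g <- graft_polytomy(tr, "new_sp", members, "mrca_polytomy")
  expect_equal(length(g$tip.label), 11L)
  expect_true(ape::is.ultrametric(g, tol = 1e-8))
  pruned <- ape::drop.tip(g, "new_sp")
  expect_equal(sum(pruned$edge.length), sum(tr$edge.length), tolerance = 1e-10)

  # single-member genus: forced attachment as a mid-branch cherry
  g1 <- graft_polytomy(tr, "new_sp", tr$tip.label[1], "random_within_genus",
                       seed = 3)
  expect_true(ape::is.ultrametric(g1, tol = 1e-8))
  expect_equal(sum(ape::drop.tip(g1, "new_sp")$edge.length),
               sum(tr$edge.length), tolerance = 1e-10)

  expect_error(graft_polytomy(tr, "q", character(0)), "non-empty")
  expect_error(graft_polytomy(tr, tr$tip.label[2], members), "already a tip")
})

test_that("random grafts are reproducible by seed", {
  tr <- simulate_tree(12, 1, seed = 9)
  members <- tr$tip.label[3:8]
  g1 <- graft_polytomy(tr, "nv", members, "random_within_genus", seed = 17)
  g2 <- graft_polytomy(tr, "nv", members, "random_within_genus", seed = 17)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
})
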
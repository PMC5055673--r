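# Fixtures and independent oracles. The enumeration oracles below rebuild
# branch incidence from ape::nodepath and average over all 2^n extinction
# outcomes, independently of the package's product-form implementations.

t1 <- function() parse_newick("((A:1,B:1):1,C:2):0;")

rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

rand_probs <- function(tips) {
  p <- stats::runif(length(tips))
  j <- stats::runif(length(tips)) < 0.1
  if (any(j)) p[j] <- sample(c(0, 1), sum(j), replace = TRUE)
  stats::setNames(p, tips)
}

# Per-species root-path edge indices, via ape::nodepath.
edge_path_matrix <- function(tree, species) {
  root <- length(tree$tip.label) + 1L
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  out <- matrix(FALSE, length(species), nrow(tree$edge))
  for (i in seq_along(species)) {
    np <- ape::nodepath(tree, root, match(species[i], tree$tip.label))
    out[i, match(paste(np[-length(np)], np[-1]), key)] <- TRUE
  }
  out
}

# Expected PD loss by exhaustive enumeration of all 2^n extinction outcomes:
# for each outcome, surviving PD is the total length of edges on some
# survivor's root path; loss is weighted by the outcome probability.
oracle_epl <- function(tree, probs, assemblage = names(probs)) {
  n <- length(assemblage)
  P <- edge_path_matrix(tree, assemblage)
  L <- tree$edge.length
  pd_a <- sum(L[colSums(P) > 0])
  O <- as.matrix(expand.grid(rep(list(c(1, 0)), n)))   # 1 = survives
  pd_surv <- as.vector(((O %*% P) > 0) %*% L)
  p <- unname(probs[assemblage])
  prmat <- t(t(O) * (1 - p) + t(1 - O) * p)
  pr <- apply(prmat, 1, prod)
  sum(pr * (pd_a - pd_surv))
}

# HED by the conditional-expectation definition: expected surviving PD given
# species i survives minus that given i goes extinct, by enumeration.
oracle_hed <- function(tree, probs) {
  tips <- tree$tip.label
  n <- length(tips)
  P <- edge_path_matrix(tree, tips)
  L <- tree$edge.length
  O <- as.matrix(expand.grid(rep(list(c(1, 0)), n)))
  pd_surv <- as.vector(((O %*% P) > 0) %*% L)
  p <- unname(probs[tips])
  prmat <- t(t(O) * (1 - p) + t(1 - O) * p)
  hed <- vapply(seq_len(n), function(i) {
    s <- O[, i] == 1
    pr_s <- apply(prmat[s, -i, drop = FALSE], 1, prod)
    pr_e <- apply(prmat[!s, -i, drop = FALSE], 1, prod)
    sum(pr_s * pd_surv[s]) - sum(pr_e * pd_surv[!s])
  }, numeric(1))
  stats::setNames(hed, tips)
}

# Connectivity check by flood fill over row/column arithmetic.
flood_connected <- function(cell_idx, nrow, ncol, neighbourhood = 4) {
  if (length(cell_idx) <= 1L) return(TRUE)
  inset <- logical(nrow * ncol)
  inset[cell_idx] <- TRUE
  seen <- logical(nrow * ncol)
  queue <- cell_idx[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    r <- (i - 1L) %/% ncol + 1L
    c <- (i - 1L) %% ncol + 1L
    steps <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    if (neighbourhood == 8) {
      steps <- c(steps, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
    }
    for (s in steps) {
      rr <- r + s[1]; cc <- c + s[2]
      if (rr < 1 || rr > nrow || cc < 1 || cc > ncol) next
      j <- (rr - 1) * ncol + cc
      if (inset[j] && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen[cell_idx])
}

# Small occurrence matrix from a named list of species -> cell ids.
comm_from_ranges <- function(ranges, cells) {
  m <- matrix(0L, length(cells), length(ranges),
              dimnames = list(cells, names(ranges)))
  for (sp in names(ranges)) m[ranges[[sp]], sp] <- 1L
  m
}
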
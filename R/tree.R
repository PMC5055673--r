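#' Parse and validate a Newick phylogeny
#'
#' Reads a rooted phylogeny from a Newick string or file and enforces the
#' invariants the downstream metrics rely on: branch lengths present, finite
#' and non-negative, and unique tip labels. A zero-length root edge is
#' tolerated (common in dated trees exported with an explicit root).
#'
#' @param x A Newick string, or the path of a file containing one.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2):0;")
#' sum(tr$edge.length)
#' @export
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- x
  if (!grepl("[(;]", x)) {
    if (!file.exists(x)) {
      stop("'", x, "' is neither a Newick string nor an existing file")
    }
    txt <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  chars <- strsplit(txt, "")[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  bad <- which(depth < 0)
  if (length(bad)) {
    stop("malformed Newick: unmatched ')' at position ", bad[1L])
  }
  if (depth[length(depth)] != 0L) {
    stop("malformed Newick: ", depth[length(depth)],
         " unclosed '(' by position ", length(chars))
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string: ", txt)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  tree
}

# Materialized branch incidence: per branch its length and the set of tip
# descendants, the substrate for all product-form metrics. Edges are returned
# in postorder; `desc` is a branches x tips logical matrix with tip labels as
# column names.
branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  n_node <- n_tip + tree$Nnode
  node_desc <- matrix(FALSE, n_node, n_tip)
  node_desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(edge))) {
    node_desc[edge[e, 1L], ] <- node_desc[edge[e, 1L], ] | node_desc[edge[e, 2L], ]
  }
  desc <- node_desc[edge[, 2L], , drop = FALSE]
  colnames(desc) <- tree$tip.label
  list(edge = edge, length = tree$edge.length, desc = desc,
       tips = tree$tip.label, n_tip = n_tip)
}

# Root-to-node distances (root = 0), ape node numbering.
node_depths <- function(tree) ape::node.depth.edgelength(tree)

# All nodes (tips and internals) of the clade rooted at `node`, inclusive.
node_descendants <- function(tree, node) {
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    ch <- kids[[as.character(cur)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  sort(out)
}

#' Graft a missing species onto a phylogeny within its genus
#'
#' Species absent from a source phylogeny but assignable to a genus are added
#' by creating polytomies with congeners. `mrca_polytomy` attaches the new tip
#' at the most recent common ancestor of the genus members with a terminal
#' branch equal to the mean root-to-tip depth below that node, so an
#' ultrametric tree stays ultrametric. `random_within_genus` attaches at a
#' uniformly chosen node (internal or tip) of the genus subtree, the
#' randomization used to test sensitivity of cell rankings to graft placement.
#' Attachment at a tip (including the forced single-member-genus case) splits
#' the terminal branch at its midpoint into a cherry.
#'
#' @param tree A `phylo` object.
#' @param species Label of the new tip (must not already be present).
#' @param genus_members Character vector of existing tip labels in the genus.
#' @param mode `"mrca_polytomy"` or `"random_within_genus"`.
#' @param seed Optional integer seed for the random placement.
#' @return The enlarged `phylo` object (one extra tip).
#' @export
graft_polytomy <- function(tree, species, genus_members,
                           mode = c("mrca_polytomy", "random_within_genus"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (length(genus_members) == 0L) stop("genus_members must be non-empty")
  missing <- setdiff(genus_members, tree$tip.label)
  if (length(missing)) {
    stop("genus members not in tree: ", paste(missing, collapse = ", "))
  }
  if (species %in% tree$tip.label) {
    stop("'", species, "' is already a tip of the tree")
  }
  n_tip <- length(tree$tip.label)
  depths <- node_depths(tree)

  attach_at_tip <- function(tip_idx) {
    ei <- which(tree$edge[, 2L] == tip_idx)
    half <- tree$edge.length[ei] / 2
    bind_new_tip(tree, species, where = tip_idx, position = half,
                 tip_length = half)
  }
  attach_at_node <- function(node) {
    under <- node_descendants(tree, node)
    tips_under <- under[under <= n_tip]
    len <- mean(depths[tips_under]) - depths[node]
    bind_new_tip(tree, species, where = node, position = 0, tip_length = len)
  }

  if (length(genus_members) == 1L) {
    # single attachment point regardless of mode
    return(attach_at_tip(match(genus_members, tree$tip.label)))
  }
  mrca <- ape::getMRCA(tree, genus_members)
  if (mode == "mrca_polytomy") return(attach_at_node(mrca))
  pick <- with_seed(seed, {
    cand <- node_descendants(tree, mrca)
    cand[sample.int(length(cand), 1L)]
  })
  if (pick <= n_tip) attach_at_tip(pick) else attach_at_node(pick)
}

bind_new_tip <- function(tree, label, where, position, tip_length) {
  graft <- structure(
    list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
         edge.length = tip_length, Nnode = 1L),
    class = "phylo")
  ape::bind.tree(tree, graft, where = where, position = position)
}

# Genus labels derived from subtree membership at a fraction of the maximum
# tip depth: tips sharing their shallowest ancestor at or below that height
# share a genus. Used by the synthetic-data module.
genus_from_tree <- function(tree, depth_fraction = 0.6) {
  n_tip <- length(tree$tip.label)
  depths <- node_depths(tree)
  h <- depth_fraction * max(depths[seq_len(n_tip)])
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  anc <- vapply(seq_len(n_tip), function(i) {
    a <- i
    while (!is.na(parent[a]) && depths[parent[a]] >= h) a <- parent[a]
    as.integer(a)
  }, integer(1))
  stats::setNames(sprintf("g%02d", as.integer(factor(anc))), tree$tip.label)
}
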
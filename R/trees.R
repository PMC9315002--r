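#' Read and write phylogenies
#'
#' Thin, validating wrappers around the `ape` readers/writers. Newick and
#' Nexus (trees block) files are supported; multi-tree Newick files with one
#' tree per line come back as a list of trees.
#'
#' @param text a Newick string, or `file` a path.
#' @param file path to a Newick (`.nwk`, `.tre`, ...) or Nexus (`.nex`) file.
#' @return a `phylo` object, or a `multiPhylo` list for multi-tree input.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text)
  else {
    if (!file.exists(file)) stop("tree file not found: ", file)
    if (grepl("\\.nex(us)?$", file, ignore.case = TRUE)) ape::read.nexus(file)
    else ape::read.tree(file)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  check_tree <- function(x) {
    if (anyDuplicated(x$tip.label)) stop("duplicate tip labels")
    if (!is.null(x$edge.length) && any(x$edge.length < 0))
      stop("negative branch lengths")
    x
  }
  if (inherits(tr, "multiPhylo")) {
    for (x in tr) check_tree(x)
    tr
  } else check_tree(tr)
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Majority-rule consensus with least-squares edge lengths
#'
#' Computes the topology containing exactly the bipartitions present in more
#' than half of the input trees, then assigns branch lengths by nonnegative
#' least squares against the mean patristic distance matrix of the sample
#' (the distance summary is the package's choice; the consensus itself is the
#' standard strict-majority rule with ties excluded).
#'
#' @param trees a `multiPhylo` list (same tip set in every tree).
#' @return a `phylo` consensus tree with least-squares edge lengths.
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) < 1) stop("need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!identical(sort(t$tip.label), tips))
    stop("all trees must share the same tip set")
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE, rooted = TRUE)
  dm <- mean_patristic(trees)
  least_squares_edge_lengths(cons, dm)
}

#' Mean patristic distance matrix over a tree sample
#'
#' @param trees a `multiPhylo` list.
#' @return symmetric matrix of mean tip-to-tip path lengths.
#' @export
mean_patristic <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  tips <- sort(trees[[1]]$tip.label)
  acc <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (t in trees) {
    d <- ape::cophenetic.phylo(t)[tips, tips]
    acc <- acc + d
  }
  acc / length(trees)
}

#' Nonnegative least-squares branch lengths for a fixed topology
#'
#' Finds edge lengths minimising the sum of squared differences between the
#' tree's patristic distances and a target distance matrix, constrained
#' nonnegative (negative solutions are clamped to zero with refit, repeated
#' until the free set is stable). The normal-equation blocks are computed in
#' closed form from the bipartition structure: for edges with descendant tip
#' sets `A_e`, the Gram entry is `|A_f| * (n - |A_e|)` when nested and
#' `|A_e| * |A_f|` when disjoint.
#'
#' For a rooted binary root the two root edges induce the same bipartition
#' and only their sum is identifiable; the minimum-norm solution (equal
#' split) is returned for that pair.
#'
#' @param topology a `phylo` tree (branch lengths ignored).
#' @param dist_matrix symmetric tip-distance matrix with zero diagonal,
#'   dimnames matching the tips.
#' @return the topology with fitted `edge.length`.
#' @export
least_squares_edge_lengths <- function(topology, dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (!isTRUE(all.equal(dist_matrix, t(dist_matrix), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dist_matrix)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(dimnames(dist_matrix)) ||
      !setequal(rownames(dist_matrix), topology$tip.label))
    stop("distance matrix dimnames must match the tips")
  d <- dist_matrix[topology$tip.label, topology$tip.label]
  n <- length(topology$tip.label)
  desc <- node_descendants(topology)
  child <- topology$edge[, 2]
  m <- length(child)
  M <- matrix(FALSE, m, n)
  for (e in seq_len(m)) M[e, desc[[child[e]]]] <- TRUE
  se <- rowSums(M)
  inter <- M %*% t(M)                        # |A_e intersect A_f|
  sz_max <- outer(se, se, pmax)
  XtX <- ifelse(inter == 0, outer(se, se), inter * (n - sz_max))
  R <- rowSums(d)
  Md <- M %*% d
  Xtd <- as.numeric(M %*% R) - rowSums(Md * M)
  # rank check beyond the expected rooted-binary-root deficiency
  qrX <- qr(XtX)
  expected_rank <- m - as.integer(sum(topology$edge[, 1] == n + 1L) == 2L)
  if (qrX$rank < expected_rank)
    warning("singular least-squares design; unidentifiable edges set by minimum norm")
  solve_mn <- function(A, b) drop(MASS::ginv(A) %*% b)
  fixed <- integer(0)
  for (it in seq_len(m + 1L)) {
    free <- setdiff(seq_len(m), fixed)
    b <- numeric(m)
    if (length(free))
      b[free] <- solve_mn(XtX[free, free, drop = FALSE], Xtd[free])
    neg <- which(b < -1e-12)
    if (!length(neg)) break
    fixed <- union(fixed, neg)
  }
  b[b < 0] <- 0
  out <- topology
  out$edge.length <- b
  out
}

#' Node depths of a rooted tree
#'
#' Depth is the summed branch length from the root to a node or tip
#' (`depth(root) = 0`). Names are tip labels for tips and node numbers for
#' internal nodes.
#'
#' @param tree a rooted `phylo`.
#' @return named numeric vector of length `Ntip + Nnode`.
#' @export
node_depths <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label, seq_len(tree$Nnode) + length(tree$tip.label))
  d
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a rooted `phylo`.
#' @param tips character vector of tip labels (or tip indices).
#' @return internal node number (ape convention, > Ntip); for a single tip,
#'   the tip index itself.
#' @export
mrca_node <- function(tree, tips) {
  if (is.character(tips)) {
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad)) stop("unknown tip name(s): ", paste(bad, collapse = ", "))
  }
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# tip descendants of every node, as a list (tips first, then internal nodes)
node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(desc, sort)
}
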
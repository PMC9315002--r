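# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Reissner point-load stiffness of a thin spherical shell; the plate-to-plate
# stiffness of a compressed sphere is two pole dimples in series.
reissner_sphere_K <- function(E, t, R, nu) {
  k_single <- 4 * E * t^2 / (R * sqrt(3 * (1 - nu^2)))
  k_single / 2
}

# Brute-force CTMC likelihood by enumerating all internal-node states.
enum_ctmc_loglik <- function(tree, states, Q, root_rule = "weighted") {
  tre <- ape::reorder.phylo(tree, "postorder")
  k <- nrow(Q)
  ntip <- length(tre$tip.label)
  nn <- tre$Nnode
  P <- lapply(seq_len(nrow(tre$edge)), function(e)
    as.matrix(Matrix::expm(Q * tre$edge.length[e])))
  tipst <- as.integer(states[tre$tip.label])
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  Lroot <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + nn)
    st[seq_len(ntip)] <- tipst
    st[ntip + seq_len(nn)] <- grid[g, ]
    pr <- 1
    for (e in seq_len(nrow(tre$edge)))
      pr <- pr * P[[e]][st[tre$edge[e, 1]], st[tre$edge[e, 2]]]
    Lroot[st[ntip + 1]] <- Lroot[st[ntip + 1]] + pr
  }
  if (root_rule == "weighted") log(sum(Lroot^2) / sum(Lroot))
  else log(mean(Lroot))
}

# OLS closed form via normal equations (oracle for PGLS at lambda = 0 on a
# star-like covariance and for the design algebra).
ols_normal_eq <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# Exhaustive basis search for the p = 2 quantile-regression optimum.
enum_rq_objective <- function(X, y, tau) {
  n <- nrow(X)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M <- X[c(i, j), , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    b <- solve(M, y[c(i, j)])
    r <- y - drop(X %*% b)
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

# All bipartitions (as sorted tip-label subsets, smaller side, excluding
# trivial splits) of a tree -- brute-force consensus oracle.
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  out <- character(0)
  if (tree$Nnode < 2) return(out)
  for (node in (ntip + 2):(ntip + tree$Nnode)) {
    dd <- ape::extract.clade(tree, node)$tip.label
    if (length(dd) <= 1 || length(dd) >= ntip - 1) next
    a <- sort(dd); b <- sort(setdiff(tips, dd))
    key <- if (length(a) < length(b) || (length(a) == length(b) && a[1] < b[1]))
      paste(a, collapse = ",") else paste(b, collapse = ",")
    out <- c(out, key)
  }
  unique(out)
}

# small shared fixtures (built once per test run)
fixture_env <- new.env()
fix_tree <- function(n, seed) {
  key <- paste0("tr", n, "_", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- simulate_tree(n, seed = seed)
  fixture_env[[key]]
}

dep_names <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
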
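#' Closed-form Brownian ancestral state estimates
#'
#' Maximum-likelihood (GLS) ancestral states under Brownian motion: the
#' internal-node values minimising the quadratic form
#' `sum_edges (x_parent - x_child)^2 / branch length` with tips fixed at the
#' data. This is the deterministic counterpart of the MCMC estimator in
#' [asr_mcmc()] and its validation oracle.
#'
#' @param tree rooted `phylo` with positive branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @return data frame (one row per internal node, ape numbering): `node`,
#'   `depth`, `estimate`, and exemplar tips `tip1`, `tip2` whose MRCA the
#'   node is.
#' @export
asr_gls <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss)) stop("missing tip values: ", paste(utils::head(miss, 3), collapse = ", "))
  x <- tip_values[tree$tip.label]
  nn <- tree$Nnode
  b <- pmax(tree$edge.length, 1e-12)
  w <- 1 / b
  E <- nrow(tree$edge)
  # Laplacian over internal nodes; tips contribute to the RHS
  ii <- jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(nn)
  diag_acc <- numeric(nn)
  off_i <- integer(0); off_j <- integer(0); off_v <- numeric(0)
  for (e in seq_len(E)) {
    p <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    diag_acc[p] <- diag_acc[p] + w[e]
    if (ch <= ntip) {
      rhs[p] <- rhs[p] + w[e] * x[ch]
    } else {
      c2 <- ch - ntip
      diag_acc[c2] <- diag_acc[c2] + w[e]
      off_i <- c(off_i, p, c2); off_j <- c(off_j, c2, p)
      off_v <- c(off_v, -w[e], -w[e])
    }
  }
  L <- Matrix::sparseMatrix(i = c(seq_len(nn), off_i), j = c(seq_len(nn), off_j),
                            x = c(diag_acc, off_v), dims = c(nn, nn))
  est <- as.numeric(Matrix::solve(L, rhs))
  depths <- ape::node.depth.edgelength(tree)
  ex <- mrca_exemplars(tree)
  data.frame(node = (ntip + 1):(ntip + nn), depth = depths[(ntip + 1):(ntip + nn)],
             estimate = est, tip1 = ex$tip1, tip2 = ex$tip2)
}

# two exemplar tips per internal node whose MRCA identifies it (one tip from
# each of the first two child subtrees)
mrca_exemplars <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- node_descendants(tree)
  first_tip <- vapply(desc, function(d) d[1], integer(1))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tip1 <- tip2 <- character(tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    node <- ntip + i
    ch <- kids[[as.character(node)]]
    tip1[i] <- tree$tip.label[first_tip[ch[1]]]
    tip2[i] <- tree$tip.label[first_tip[ch[2]]]
  }
  list(tip1 = tip1, tip2 = tip2)
}

#' MCMC ancestral state reconstruction under Brownian motion
#'
#' Random-walk (non-directional Brownian) model: internal-node values are
#' Gibbs-sampled from their Gaussian full conditionals given the neighbours,
#' and the Brownian rate `sigma^2` takes Metropolis-Hastings steps under an
#' exponential prior. Posterior means coincide with the closed form of
#' [asr_gls()]; the sampler adds posterior medians and SDs per node.
#'
#' @param tree rooted `phylo`.
#' @param tip_values named numeric vector covering every tip.
#' @param iterations,burnin,thin chain settings (defaults follow the usual
#'   BayesTraits-style run: 500k iterations, 200k burn-in, sample every
#'   1000).
#' @param prior_mean mean of the exponential prior on `sigma^2`.
#' @param seed RNG seed (required).
#' @return list of class `asr_mcmc`: `nodes` (data frame with node, depth,
#'   mean, median, sd, tip1, tip2), `sigma2` (posterior samples), settings.
#' @export
asr_mcmc <- function(tree, tip_values, iterations = 500000, burnin = 200000,
                     thin = 1000, prior_mean = 0.001, seed) {
  if (missing(seed)) stop("asr_mcmc requires an explicit seed")
  if (burnin >= iterations) stop("burnin must be below iterations")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- tip_values[tree$tip.label]
  b <- pmax(tree$edge.length, 1e-12)
  E <- nrow(tree$edge)
  # neighbour lists per internal node: (node index or tip, weight)
  nb_idx <- vector("list", nn)   # neighbour node id (ape numbering)
  nb_w <- vector("list", nn)
  for (e in seq_len(E)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; we <- 1 / b[e]
    pi <- p - ntip
    nb_idx[[pi]] <- c(nb_idx[[pi]], ch); nb_w[[pi]] <- c(nb_w[[pi]], we)
    if (ch > ntip) {
      ci <- ch - ntip
      nb_idx[[ci]] <- c(nb_idx[[ci]], p); nb_w[[ci]] <- c(nb_w[[ci]], we)
    }
  }
  wsum <- vapply(nb_w, sum, numeric(1))
  # state: all node values (tips fixed), init at GLS estimates
  v <- numeric(ntip + nn)
  v[seq_len(ntip)] <- x
  v[(ntip + 1):(ntip + nn)] <- asr_gls(tree, tip_values)$estimate
  s2 <- max(1e-10, prior_mean)
  keep <- floor((iterations - burnin) / thin)
  smp <- matrix(NA_real_, keep, nn)
  s2smp <- numeric(keep)
  ki <- 0L
  edge_p <- tree$edge[, 1]; edge_c <- tree$edge[, 2]
  for (it in seq_len(iterations)) {
    for (i in seq_len(nn)) {
      m <- sum(nb_w[[i]] * v[nb_idx[[i]]]) / wsum[i]
      v[ntip + i] <- stats::rnorm(1, m, sqrt(s2 / wsum[i]))
    }
    ss <- sum((v[edge_p] - v[edge_c])^2 / b)
    s2_new <- s2 * exp(0.5 * stats::rnorm(1))
    loga <- (-E / 2 * log(s2_new) - ss / (2 * s2_new) - s2_new / prior_mean) -
            (-E / 2 * log(s2) - ss / (2 * s2) - s2 / prior_mean) +
            log(s2_new / s2)
    if (is.finite(loga) && log(stats::runif(1)) < loga) s2 <- s2_new
    if (it > burnin && (it - burnin) %% thin == 0 && ki < keep) {
      ki <- ki + 1L
      smp[ki, ] <- v[(ntip + 1):(ntip + nn)]
      s2smp[ki] <- s2
    }
  }
  smp <- smp[seq_len(ki), , drop = FALSE]
  depths <- ape::node.depth.edgelength(tree)
  ex <- mrca_exemplars(tree)
  nodes <- data.frame(node = (ntip + 1):(ntip + nn),
                      depth = depths[(ntip + 1):(ntip + nn)],
                      mean = colMeans(smp),
                      median = apply(smp, 2, stats::median),
                      sd = apply(smp, 2, stats::sd),
                      tip1 = ex$tip1, tip2 = ex$tip2)
  structure(list(nodes = nodes, sigma2 = s2smp[seq_len(ki)],
                 iterations = iterations, burnin = burnin, thin = thin,
                 prior_mean = prior_mean, seed = seed),
            class = "asr_mcmc")
}

#' @export
print.asr_mcmc <- function(x, ...) {
  cat(sprintf("<asr_mcmc> %d internal nodes, %d samples, sigma2 ~ %.4g\n",
              nrow(x$nodes), length(x$sigma2), stats::median(x$sigma2)))
  invisible(x)
}

#' Across-run convergence check for the ancestral sampler
#'
#' Runs the sampler `n_runs` times with derived seeds and reports the
#' across-run standard deviation of each node's posterior mean, flagging
#' non-convergence when it exceeds `tol` times the tip SD.
#'
#' @param tree,tip_values,iterations,burnin,thin,prior_mean,seed as in
#'   [asr_mcmc()].
#' @param n_runs number of independent runs.
#' @param tol tolerance as a fraction of the tip standard deviation.
#' @return list: `across_run_sd` per node, `converged` flag, `runs`.
#' @export
asr_convergence <- function(tree, tip_values, n_runs = 3, tol = 0.05,
                            iterations = 20000, burnin = 5000, thin = 10,
                            prior_mean = 0.001, seed) {
  if (missing(seed)) stop("asr_convergence requires an explicit seed")
  runs <- lapply(seq_len(n_runs), function(r)
    asr_mcmc(tree, tip_values, iterations, burnin, thin, prior_mean,
             seed = seed + r))
  means <- sapply(runs, function(r) r$nodes$mean)
  sds <- apply(means, 1, stats::sd)
  list(across_run_sd = sds,
       converged = max(sds) < tol * stats::sd(tip_values),
       runs = runs)
}
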
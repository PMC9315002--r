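#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree rescaled to a fixed root-to-tip depth (the time scale of
#' avian phylogenies, nominally millions of years).
#'
#' @param n_tips number of tips (>= 3).
#' @param birth speciation rate.
#' @param depth root-to-tip depth after rescaling.
#' @param seed RNG seed (required).
#' @return a `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, depth = 100, seed) {
  if (missing(seed)) stop("simulate_tree requires an explicit seed")
  if (n_tips < 3) stop("n_tips must be >= 3")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr
}

#' Simulate continuous trait evolution with Pagel's lambda signal
#'
#' Generates `y = X beta + e` where the residual `e` has covariance
#' `sigma2 * V(lambda)`: a Brownian component (weight `sqrt(lambda)`) plus
#' an independent tip-specific component (weight `sqrt(1 - lambda)`), so
#' the marginal variances equal the Brownian ones while off-diagonal
#' covariances are scaled by `lambda`. True internal-node states of the
#' Brownian component are returned for ancestral-reconstruction checks
#' (exactly interpretable when `lambda = 1`).
#'
#' @param tree rooted `phylo`.
#' @param lambda signal parameter in `[0, 1]`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root root state (added to all values).
#' @param X optional design matrix (rows named by tips).
#' @param beta coefficients matching `X`.
#' @param seed RNG seed (required).
#' @return list: `tips` (named values), `nodes` (true Brownian node states,
#'   ape numbering), `lambda`, `sigma2`.
#' @export
simulate_continuous <- function(tree, lambda = 1, sigma2 = 1, root = 0,
                                X = NULL, beta = NULL, seed) {
  if (missing(seed)) stop("simulate_continuous requires an explicit seed")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  # Brownian realisation over all nodes, preorder
  bm <- numeric(ntot)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]
    bm[ch] <- bm[p] + stats::rnorm(1, 0, sqrt(sigma2 * elen[i]))
  }
  depths <- ape::node.depth.edgelength(tree)
  eps <- sqrt(lambda) * bm[seq_len(ntip)] +
    sqrt((1 - lambda) * sigma2 * depths[seq_len(ntip)]) * stats::rnorm(ntip)
  y <- root + eps
  names(y) <- tree$tip.label
  if (!is.null(X)) {
    X <- as.matrix(X)
    y <- y + drop(X[tree$tip.label, , drop = FALSE] %*% beta)
  }
  list(tips = y, nodes = root + bm[(ntip + 1):ntot], lambda = lambda,
       sigma2 = sigma2)
}

#' Simulate discrete character evolution along a tree
#'
#' Exact stochastic simulation of a continuous-time Markov chain along every
#' branch (exponential waiting times, embedded jump chain).
#'
#' @param tree rooted `phylo`.
#' @param Q k x k rate matrix (zero row sums).
#' @param root_state integer in 1..k.
#' @param seed RNG seed (required).
#' @return list: `tips` (named integer states), `nodes` (internal-node
#'   states), `n_events` (total number of state changes).
#' @export
simulate_discrete <- function(tree, Q, root_state = 1L, seed) {
  if (missing(seed)) stop("simulate_discrete requires an explicit seed")
  k <- nrow(Q)
  if (root_state < 1 || root_state > k) stop("root_state out of range")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  st <- integer(ntot)
  st[ntip + 1L] <- as.integer(root_state)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  n_events <- 0L
  for (i in seq_len(nrow(edges))) {
    s <- st[edges[i, 1]]
    remaining <- elen[i]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      wait <- stats::rexp(1, rate)
      if (wait > remaining) break
      remaining <- remaining - wait
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(k, 1, prob = probs)
      n_events <- n_events + 1L
    }
    st[edges[i, 2]] <- s
  }
  list(tips = stats::setNames(st[seq_len(ntip)], tree$tip.label),
       nodes = st[(ntip + 1L):ntot], n_events = n_events)
}

#' Default effect sizes for the synthetic study
#'
#' Additive effects on log10 C mirroring the scale of the published PGLS
#' coefficients: clutch +0.017 per egg; attachment lateral/horizontal
#' +0.052, pensile +0.111; site tree +0.050, non-tree vegetation +0.081;
#' structure cavity +0.066, cup +0.070, dome +0.136; intercept 4.10.
#'
#' @return named list of effect vectors.
#' @export
study_effects <- function() {
  list(intercept = 4.10,
       clutch = 0.017,
       attachment = c("lateral/horizontal" = 0.052, "pensile" = 0.111),
       site = c("tree" = 0.050, "non-tree vegetation" = 0.081),
       structure = c("cavity" = 0.066, "cup" = 0.070, "dome" = 0.136))
}

# mildly asymmetric Mk rates so lower-risk categories are commoner,
# roughly mirroring the prevalence of basal / tree / cup nests
nest_rate_matrix <- function(levels, rate = 0.01) {
  k <- length(levels)
  Q <- matrix(rate, k, k, dimnames = list(levels, levels))
  Q[upper.tri(Q)] <- rate * 0.6          # risk-increasing moves rarer
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Simulate nest characters on a tree
#'
#' Each character evolves under a mildly asymmetric Mk process on its closed
#' vocabulary (see [nest_vocab]).
#'
#' @param tree rooted `phylo`.
#' @param seed RNG seed.
#' @param rate baseline transition rate per unit branch length.
#' @return data frame (rownames = species) with factors `attachment`,
#'   `site`, `structure`.
#' @export
simulate_nest_characters <- function(tree, seed, rate = 0.01) {
  if (missing(seed)) stop("simulate_nest_characters requires an explicit seed")
  out <- list()
  for (i in seq_along(nest_vocab)) {
    ch <- names(nest_vocab)[i]
    levs <- nest_vocab[[ch]]
    sim <- simulate_discrete(tree, nest_rate_matrix(levs, rate),
                             root_state = 1L, seed = seed + i)
    out[[ch]] <- factor(levs[sim$tips], levels = levs)
  }
  df <- as.data.frame(out, check.names = FALSE)
  names(df) <- names(nest_vocab)
  rownames(df) <- tree$tip.label
  df
}

#' Simulate egg geometries with allometric structure
#'
#' Egg mass is drawn lognormally; breadth and length follow from the volume
#' (whole-egg density 1.031 g cm^-3) and a lognormal shape ratio `B/A`;
#' shell thickness follows the classical allometry `t ~ mass^0.456` with
#' lognormal noise. The thin-shell constraint `t/A < 0.05` is enforced.
#'
#' @param n number of specimens.
#' @param seed RNG seed (required).
#' @param mass_meanlog,mass_sdlog lognormal parameters of egg mass (g).
#' @param shape_meanlog,shape_sdlog lognormal parameters of `B/A`.
#' @param thick_coef,thick_exp,thick_sdlog thickness allometry `t_mm =
#'   coef * mass^exp` and its lognormal noise SD.
#' @return data frame: `species`, `A_mm`, `B_mm`, `thickness_mm`, `mass_g`,
#'   `ellipticity`, `asymmetry`.
#' @export
simulate_geometry <- function(n, seed, mass_meanlog = log(20),
                              mass_sdlog = 0.8, shape_meanlog = log(1.35),
                              shape_sdlog = 0.05, thick_coef = 0.06,
                              thick_exp = 0.456, thick_sdlog = 0.08) {
  if (missing(seed)) stop("simulate_geometry requires an explicit seed")
  if (thick_coef <= 0 || thick_exp <= 0) stop("allometry parameters must be positive")
  set.seed(seed)
  mass <- stats::rlnorm(n, mass_meanlog, mass_sdlog)
  vol_cm3 <- mass / 1.031
  shp <- stats::rlnorm(n, shape_meanlog, shape_sdlog)
  A_cm <- (6 * vol_cm3 / (pi * shp))^(1 / 3)
  B_cm <- shp * A_cm
  t_mm <- thick_coef * mass^thick_exp * stats::rlnorm(n, 0, thick_sdlog)
  t_mm <- pmin(t_mm, 0.049 * A_cm * 10)    # thin-shell constraint t/A < 0.05
  data.frame(species = paste0("t", seq_len(n)),
             A_mm = A_cm * 10, B_mm = B_cm * 10, thickness_mm = t_mm,
             mass_g = mass,
             ellipticity = pmax(0, stats::rnorm(n, 0.05, 0.03)),
             asymmetry = pmin(0.3, pmax(0, stats::rnorm(n, 0.10, 0.05))))
}

#' Simulate a complete synthetic study
#'
#' Generates a Yule tree, nest characters, clutch sizes, a passerine clade
#' flag, and log10 C values with additive category/clutch effects plus a
#' Pagel's-lambda phylogenetic residual, so every stage of the comparative
#' pipeline can be run against known ground truth.
#'
#' @param n_tips number of species.
#' @param seed RNG seed (required).
#' @param lambda_signal residual phylogenetic signal in `[0, 1]`.
#' @param sigma2 Brownian residual rate per unit branch length (default
#'   2.56e-4 on a depth-100 tree: residual SD about 0.16 on log10 C).
#' @param effects effect list as in [study_effects()].
#' @param clutch_lambda Poisson mean of (clutch size - 1).
#' @param nest_rate Mk rate for nest characters.
#' @return list: `tree`, `traits` (data frame: species, log10_C, clutch,
#'   attachment, site, structure, passerine), `truth` (effects, lambda,
#'   sigma2, true node states of the Brownian residual, design matrix).
#' @export
simulate_study <- function(n_tips = 200, seed, lambda_signal = 0.5,
                           sigma2 = 2.56e-4, effects = study_effects(),
                           clutch_lambda = 2.5, nest_rate = 0.01) {
  if (missing(seed)) stop("simulate_study requires an explicit seed")
  tree <- simulate_tree(n_tips, seed = seed)
  nests <- simulate_nest_characters(tree, seed = seed + 1, rate = nest_rate)
  set.seed(seed + 2)
  clutch <- 1 + stats::rpois(n_tips, clutch_lambda)
  # passerine flag: the clade closest to 45% of tips
  desc <- node_descendants(tree)
  sizes <- vapply(desc, length, integer(1))
  target <- round(0.45 * n_tips)
  cand <- which.min(abs(sizes[-(seq_len(n_tips))] - target)) + n_tips
  passerine <- logical(n_tips)
  passerine[desc[[cand]]] <- TRUE
  X <- cbind(intercept = rep(1, n_tips), clutch = clutch)
  beta <- c(effects$intercept, effects$clutch)
  for (ch in c("attachment", "site", "structure")) {
    f <- nests[[ch]]
    for (lev in names(effects[[ch]])) {
      X <- cbind(X, as.numeric(f == lev))
      colnames(X)[ncol(X)] <- paste0(ch, ":", lev)
      beta <- c(beta, effects[[ch]][[lev]])
    }
  }
  rownames(X) <- tree$tip.label
  sim <- simulate_continuous(tree, lambda = lambda_signal, sigma2 = sigma2,
                             root = 0, X = X, beta = beta, seed = seed + 3)
  traits <- data.frame(species = tree$tip.label,
                       log10_C = unname(sim$tips),
                       clutch = clutch,
                       attachment = nests$attachment,
                       site = nests$site,
                       structure = nests$structure,
                       passerine = passerine)
  list(tree = tree, traits = traits,
       truth = list(beta = stats::setNames(beta, colnames(X)),
                    lambda = lambda_signal, sigma2 = sigma2,
                    nodes = sim$nodes, design = X))
}
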
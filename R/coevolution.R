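#' Rate matrix for two binary traits
#'
#' States are ordered `(0,0), (0,1), (1,0), (1,1)` where the first position
#' is trait 1 (e.g. C-number class, 1 = high) and the second trait 2 (e.g.
#' nest class). The dependent model has 8 free rates (double transitions are
#' zero); the independent model constrains each trait's gain/loss rates to
#' ignore the other trait's state (4 free rates).
#'
#' @param rates named numeric vector: for `"dependent"`, `q12, q13, q21,
#'   q24, q31, q34, q42, q43`; for `"independent"`, `alpha1, beta1, alpha2,
#'   beta2` (gain/loss of trait 1, gain/loss of trait 2).
#' @param model `"dependent"` or `"independent"`.
#' @return 4x4 rate matrix with zero row sums.
#' @export
rate_matrix <- function(rates, model = c("dependent", "independent")) {
  model <- match.arg(model)
  Q <- matrix(0, 4, 4, dimnames = rep(list(c("00", "01", "10", "11")), 2))
  if (model == "dependent") {
    need <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
    r <- rates[need]
    if (anyNA(r)) stop("dependent model needs rates: ", paste(need, collapse = ", "))
    Q[1, 2] <- r["q12"]; Q[1, 3] <- r["q13"]
    Q[2, 1] <- r["q21"]; Q[2, 4] <- r["q24"]
    Q[3, 1] <- r["q31"]; Q[3, 4] <- r["q34"]
    Q[4, 2] <- r["q42"]; Q[4, 3] <- r["q43"]
  } else {
    need <- c("alpha1", "beta1", "alpha2", "beta2")
    r <- rates[need]
    if (anyNA(r)) stop("independent model needs rates: ", paste(need, collapse = ", "))
    Q[1, 3] <- Q[2, 4] <- r["alpha1"]
    Q[3, 1] <- Q[4, 2] <- r["beta1"]
    Q[1, 2] <- Q[3, 4] <- r["alpha2"]
    Q[2, 1] <- Q[4, 3] <- r["beta2"]
  }
  if (any(Q < 0)) stop("rates must be nonnegative")
  diag(Q) <- -rowSums(Q)
  Q
}

coevo_par_names <- function(model) {
  if (model == "dependent") c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
  else c("alpha1", "beta1", "alpha2", "beta2")
}

#' Median split of C numbers into low/high classes
#'
#' Values strictly above the median are `"high"`, the rest `"low"` (ties go
#' to `"low"`, the reference class).
#'
#' @param values numeric vector (C numbers or log10 C).
#' @return factor with levels `low`, `high`.
#' @export
binarize_c <- function(values) {
  if (!length(values)) stop("empty values")
  med <- stats::median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Combine two binary traits into 4-state codes
#'
#' @param trait1,trait2 logical/0-1 vectors (or 2-level factors; the second
#'   level counts as 1), named by species.
#' @return integer vector in 1..4 coding `(0,0), (0,1), (1,0), (1,1)`, named
#'   by species.
#' @export
pair_states <- function(trait1, trait2) {
  tobin <- function(x) {
    if (is.factor(x)) as.integer(x) - 1L
    else if (is.logical(x)) as.integer(x)
    else as.integer(x != 0)
  }
  x <- tobin(trait1); y <- tobin(trait2)
  if (length(x) != length(y)) stop("traits must have equal length")
  if (anyNA(x) || anyNA(y)) stop("complete cases only")
  st <- 1L + 2L * x + y
  names(st) <- names(trait1)
  st
}

# prepare postorder structures once per dataset
ctmc_prep <- function(tree, states, branch_scale = 1) {
  if (is.null(names(states))) stop("states must be named by species")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("missing states for tips: ", paste(miss[1:min(3, length(miss))], collapse = ", "))
  tre <- ape::reorder.phylo(tree, "postorder")
  list(edge = tre$edge, blen = tre$edge.length * branch_scale,
       ntip = length(tre$tip.label), nnode = tre$Nnode,
       tipstate = as.integer(states[tre$tip.label]))
}

#' Pruning log-likelihood of a two-trait CTMC
#'
#' Felsenstein pruning with per-branch transition matrices `expm(Q b)`.
#' Root states are combined by the configured rule (default:
#' likelihood-weighted frequencies).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states integer 1..4 per species (see [pair_states()]), named.
#' @param Q 4x4 rate matrix (see [rate_matrix()]); any k x k matrix with
#'   states coded 1..k is accepted.
#' @param root_rule `"weighted"`, `"uniform"` or `"stationary"`.
#' @param branch_scale multiplier applied to branch lengths before the
#'   likelihood (the analysis convention is 0.001 so that rates are O(1-10)).
#' @return log-likelihood, with attribute `rootp` (likelihood-weighted root
#'   state frequencies).
#' @export
ctmc_loglik <- function(tree, states, Q,
                        root_rule = c("weighted", "uniform", "stationary"),
                        branch_scale = 1) {
  root_rule <- match.arg(root_rule)
  pr <- ctmc_prep(tree, states, branch_scale)
  res <- ctmc_pruning_cpp(pr$edge, pr$blen, pr$ntip, pr$nnode, pr$tipstate,
                          Q, match(root_rule, c("weighted", "uniform", "stationary")) - 1L)
  structure(res$loglik, rootp = res$rootp)
}

#' MCMC configuration
#'
#' @param iterations total MCMC iterations.
#' @param burnin discarded initial iterations.
#' @param thin keep every `thin`-th iteration.
#' @param prior_mean mean of the exponential prior on every rate.
#' @param branch_scale branch-length multiplier applied before the
#'   likelihood.
#' @param seed RNG seed (required: unseeded runs are an error).
#' @param proposal_scale initial log-normal proposal SD (adapted during
#'   burn-in only).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 110000, burnin = 10000, thin = 5,
                        prior_mean = 10, branch_scale = 0.001, seed = NULL,
                        proposal_scale = 0.7) {
  if (is.null(seed)) stop("mcmc_config requires an explicit seed")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 prior_mean = prior_mean, branch_scale = branch_scale,
                 seed = as.integer(seed), proposal_scale = proposal_scale),
            class = "mcmc_config")
}

# effective sample size from the initial positive sequence of the ACF
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  m <- if (length(pos)) pos[1] - 1 else length(rho)
  n / (1 + 2 * sum(rho[seq_len(m)]))
}

#' Metropolis-Hastings sampler for the correlated-evolution models
#'
#' Samples the transition rates of the dependent or independent model under
#' independent exponential priors. One randomly chosen rate is updated per
#' iteration with a log-normal multiplier; the proposal scale is adapted
#' during burn-in only, so the post-burn-in chain is a fixed-kernel
#' Metropolis-Hastings and runs are bitwise reproducible given the seed.
#'
#' @param tree rooted `phylo`.
#' @param states integer 1..4 per species (see [pair_states()]); ignored
#'   when `data_free = TRUE`.
#' @param model `"dependent"` (8 rates) or `"independent"` (4 rates).
#' @param config an [mcmc_config()].
#' @param root_rule root-state weighting rule, see [ctmc_loglik()].
#' @param power likelihood tempering exponent (1 = posterior; used by
#'   stepping-stone sampling).
#' @param data_free if `TRUE` the likelihood is constant and the chain
#'   samples the prior (prior-recovery checks).
#' @param init optional named starting rates.
#' @return object of class `coevolution_mcmc`: `samples` (matrix), `loglik`,
#'   `rootp` (matrix of root-state weights per sample), `mean_rates`,
#'   `root_probs` (posterior mean), `acceptance`, `ess`, `model`, `config`.
#' @export
mcmc_coevolution <- function(tree, states, model = c("dependent", "independent"),
                             config, root_rule = "weighted", power = 1,
                             data_free = FALSE, init = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(config, "mcmc_config"))
  set.seed(config$seed)
  pn <- coevo_par_names(model)
  np <- length(pn)
  pm <- config$prior_mean
  pr <- if (!data_free) ctmc_prep(tree, states, config$branch_scale) else NULL
  rr <- match(root_rule, c("weighted", "uniform", "stationary")) - 1L
  ll_fun <- function(q) {
    if (data_free) return(list(loglik = 0, rootp = rep(0.25, 4)))
    ctmc_pruning_cpp(pr$edge, pr$blen, pr$ntip, pr$nnode, pr$tipstate,
                     rate_matrix(stats::setNames(q, pn), model), rr)
  }
  q <- if (!is.null(init)) unname(init[pn]) else rep(pm, np)
  cur <- ll_fun(q)
  cur_ll <- cur$loglik
  cur_lp <- -sum(q) / pm
  scales <- rep(config$proposal_scale, np)
  acc <- num <- rep(0, np)
  keep <- floor((config$iterations - config$burnin) / config$thin)
  samples <- matrix(NA_real_, keep, np, dimnames = list(NULL, pn))
  lls <- numeric(keep)
  rootps <- matrix(NA_real_, keep, 4)
  ki <- 0L
  zero_window <- 0L
  for (it in seq_len(config$iterations)) {
    j <- sample.int(np, 1)
    qj_new <- q[j] * exp(scales[j] * stats::rnorm(1))
    qnew <- q; qnew[j] <- qj_new
    cand <- ll_fun(qnew)
    lp_new <- -sum(qnew) / pm
    loga <- power * (cand$loglik - cur_ll) + (lp_new - cur_lp) +
      log(qj_new / q[j])   # Jacobian of the multiplicative proposal
    num[j] <- num[j] + 1
    if (is.finite(loga) && log(stats::runif(1)) < loga) {
      q <- qnew; cur_ll <- cand$loglik; cur_lp <- lp_new; cur <- cand
      acc[j] <- acc[j] + 1
    }
    if (it <= config$burnin && it %% 200 == 0) {
      rate <- ifelse(num > 0, acc / pmax(num, 1), 0.3)
      scales <- pmin(5, pmax(0.05, scales * exp(rate - 0.3)))
      if (sum(acc) == 0) zero_window <- zero_window + 1L
      acc[] <- 0; num[] <- 0
    }
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0 && ki < keep) {
      ki <- ki + 1L
      samples[ki, ] <- q
      lls[ki] <- cur_ll
      rootps[ki, ] <- cur$rootp
    }
  }
  if (zero_window > 2)
    warning("MCMC accepted nothing over several adaptation windows; check scaling")
  acc_rate <- sum(acc) / max(1, sum(num))
  structure(list(samples = samples[seq_len(ki), , drop = FALSE],
                 loglik = lls[seq_len(ki)],
                 rootp = rootps[seq_len(ki), , drop = FALSE],
                 mean_rates = colMeans(samples[seq_len(ki), , drop = FALSE]),
                 root_probs = colMeans(rootps[seq_len(ki), , drop = FALSE]),
                 acceptance = acc_rate,
                 ess = apply(samples[seq_len(ki), , drop = FALSE], 2, ess),
                 model = model, config = config),
            class = "coevolution_mcmc")
}

#' @export
print.coevolution_mcmc <- function(x, ...) {
  cat(sprintf("<coevolution_mcmc> %s model, %d samples, acceptance %.2f\n",
              x$model, nrow(x$samples), x$acceptance))
  print(round(x$mean_rates, 4))
  cat("root probs:", paste(sprintf("%.3f", x$root_probs), collapse = " "), "\n")
  invisible(x)
}

#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood along a power path from the prior
#' (`beta = 0`) to the posterior (`beta = 1`), with `beta_j = (j/K)^(1/0.3)`
#' (stones clustered near the prior). The prior stone is sampled exactly
#' (iid exponential draws); subsequent stones are warm-started MCMC runs.
#'
#' @param tree,states,model,config,root_rule as in [mcmc_coevolution()].
#' @param n_stones number of stones `K` (>= 10).
#' @param iter_per_stone MCMC iterations per stone (burn-in: first quarter).
#' @return object of class `stepping_stone`: `logml`, `se`, `stones` (data
#'   frame with beta, log ratio contributions).
#' @export
marginal_likelihood <- function(tree, states, model, config, n_stones = 10,
                                iter_per_stone = 1000,
                                root_rule = "weighted") {
  if (n_stones < 10) stop("n_stones must be >= 10")
  stopifnot(inherits(config, "mcmc_config"))
  set.seed(config$seed)
  pn <- coevo_par_names(model)
  np <- length(pn)
  pm <- config$prior_mean
  pr <- ctmc_prep(tree, states, config$branch_scale)
  rr <- match(root_rule, c("weighted", "uniform", "stationary")) - 1L
  ll_fun <- function(q) {
    ctmc_pruning_cpp(pr$edge, pr$blen, pr$ntip, pr$nnode, pr$tipstate,
                     rate_matrix(stats::setNames(q, pn), model), rr)$loglik
  }
  betas <- (seq(0, n_stones) / n_stones)^(1 / 0.3)
  m_keep <- max(100, floor(iter_per_stone * 0.75))
  logr <- se2 <- numeric(n_stones)
  cur_q <- rep(pm, np)
  for (s in seq_len(n_stones)) {
    b <- betas[s]
    db <- betas[s + 1] - b
    if (b == 0) {
      lls <- vapply(seq_len(m_keep), function(i) {
        ll_fun(stats::rexp(np, rate = 1 / pm))
      }, numeric(1))
    } else {
      burn <- iter_per_stone - m_keep
      cfg_s <- config
      cfg_s$iterations <- iter_per_stone
      cfg_s$burnin <- burn
      cfg_s$thin <- 1
      cfg_s$seed <- config$seed + s   # sub-chain seeds derived from config
      run <- mcmc_coevolution(tree, states, model, cfg_s,
                              root_rule = root_rule, power = b,
                              init = stats::setNames(cur_q, pn))
      lls <- run$loglik
      cur_q <- run$samples[nrow(run$samples), ]
    }
    mx <- max(db * lls)
    u <- exp(db * lls - mx)
    logr[s] <- mx + log(mean(u))
    ne <- ess(u)
    se2[s] <- stats::var(u) / (ne * mean(u)^2)
  }
  structure(list(logml = sum(logr), se = sqrt(sum(se2)),
                 stones = data.frame(beta = betas[-length(betas)],
                                     log_ratio = logr)),
            class = "stepping_stone")
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("<stepping_stone> logML = %.3f (SE %.3f, %d stones)\n",
              x$logml, x$se, nrow(x$stones)))
  invisible(x)
}

#' Bayes factor on the 2 log scale
#'
#' `BF = 2 (logML_dep - logML_indep)`; values above 2 read as positive and
#' above 10 as strong support for the dependent model.
#'
#' @param dep,indep `stepping_stone` results (or bare log marginal
#'   likelihoods) for the dependent and independent models.
#' @return numeric Bayes factor.
#' @export
bayes_factor <- function(dep, indep) {
  lml <- function(x) if (inherits(x, "stepping_stone")) x$logml else as.numeric(x)
  2 * (lml(dep) - lml(indep))
}
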
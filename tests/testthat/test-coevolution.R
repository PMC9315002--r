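test_that("rate matrices implement the dependent/independent structure", {
  q <- setNames(1:8, dep_names)
  Q <- rate_matrix(q, "dependent")
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  # double transitions forbidden
  expect_equal(Q[1, 4], 0); expect_equal(Q[4, 1], 0)
  expect_equal(Q[2, 3], 0); expect_equal(Q[3, 2], 0)
  r <- setNames(c(0.3, 0.7, 0.2, 0.5), c("alpha1", "beta1", "alpha2", "beta2"))
  Qi <- rate_matrix(r, "independent")
  # each trait's rates ignore the other trait's state
  expect_equal(Qi[1, 3], Qi[2, 4]); expect_equal(Qi[3, 1], Qi[4, 2])
  expect_equal(Qi[1, 2], Qi[3, 4]); expect_equal(Qi[2, 1], Qi[4, 3])
  # independent matrix is the tied special case of the dependent one
  qd <- setNames(c(r["alpha2"], r["alpha1"], r["beta2"], r["alpha1"],
                   r["beta1"], r["alpha2"], r["beta1"], r["beta2"]), dep_names)
  expect_equal(rate_matrix(qd, "dependent"), Qi)
  expect_error(rate_matrix(setNames(-1:6 * 1.0, dep_names), "dependent"),
               "nonnegative")
})

test_that("median binarization uses a strict-greater rule", {
  expect_equal(as.character(binarize_c(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_true(all(binarize_c(rep(2, 5)) == "low"))
  x <- seq_len(1001)  # odd count of distinct values
  expect_equal(sum(binarize_c(x) == "high"), 500)
  expect_error(binarize_c(numeric(0)), "empty")
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:4, 1)
    tr <- ape::rtree(n)
    Q <- rate_matrix(setNames(rexp(8, 1 / 2), dep_names), "dependent")
    st <- setNames(sample(1:4, n, TRUE), tr$tip.label)
    expect_equal(as.numeric(ctmc_loglik(tr, st, Q, "weighted")),
                 enum_ctmc_loglik(tr, st, Q, "weighted"), tolerance = 1e-10)
    expect_equal(as.numeric(ctmc_loglik(tr, st, Q, "uniform")),
                 enum_ctmc_loglik(tr, st, Q, "uniform"), tolerance = 1e-10)
  }
})

test_that("independent 4-state likelihood factorizes into 2-state prunings", {
  set.seed(32)
  tr <- ape::rtree(12)
  r <- setNames(rexp(4), c("alpha1", "beta1", "alpha2", "beta2"))
  x1 <- sample(0:1, 12, TRUE); x2 <- sample(0:1, 12, TRUE)
  st <- pair_states(setNames(x1, tr$tip.label), x2)
  ll4 <- as.numeric(ctmc_loglik(tr, st, rate_matrix(r, "independent"), "uniform"))
  Q1 <- matrix(c(-r["alpha1"], r["alpha1"], r["beta1"], -r["beta1"]), 2, byrow = TRUE)
  Q2 <- matrix(c(-r["alpha2"], r["alpha2"], r["beta2"], -r["beta2"]), 2, byrow = TRUE)
  l1 <- as.numeric(ctmc_loglik(tr, setNames(x1 + 1L, tr$tip.label), Q1, "uniform"))
  l2 <- as.numeric(ctmc_loglik(tr, setNames(x2 + 1L, tr$tip.label), Q2, "uniform"))
  expect_equal(ll4, l1 + l2, tolerance = 1e-10)
})

test_that("likelihood respects the CTMC rate-time rescaling identity", {
  set.seed(33)
  tr <- ape::rtree(15)
  Q <- rate_matrix(setNames(rexp(8), dep_names), "dependent")
  st <- setNames(sample(1:4, 15, TRUE), tr$tip.label)
  a <- as.numeric(ctmc_loglik(tr, st, Q * 3, branch_scale = 1))
  b <- as.numeric(ctmc_loglik(tr, st, Q, branch_scale = 3))
  expect_equal(a, b, tolerance = 1e-10)
  # Q = 0 with identical tips: likelihood = root weight of the shared state
  Q0 <- matrix(0, 4, 4)
  same <- setNames(rep(2L, 15), tr$tip.label)
  expect_equal(as.numeric(ctmc_loglik(tr, same, Q0, "uniform")), log(1 / 4),
               tolerance = 1e-10)
  mixed <- setNames(c(1L, rep(2L, 14)), tr$tip.label)
  expect_lt(as.numeric(ctmc_loglik(tr, mixed, Q0, "uniform")), -1e200)
})

test_that("MCMC is deterministic given the seed and recovers rate order", {
  tr <- fix_tree(300, 34)
  Qsim <- rate_matrix(setNames(c(0.01, 0.05, 0.01, 0.005, 0.01, 0.01, 0.01, 0.01),
                               dep_names), "dependent")
  sim <- simulate_discrete(tr, Qsim, root_state = 1L, seed = 35)
  cfg <- mcmc_config(iterations = 3000, burnin = 500, thin = 2, seed = 36)
  r1 <- mcmc_coevolution(tr, sim$tips, "dependent", cfg)
  r2 <- mcmc_coevolution(tr, sim$tips, "dependent", cfg)
  expect_identical(r1$samples, r2$samples)  # bitwise reproducibility
  expect_true(all(rowSums(r1$rootp) - 1 < 1e-9))
  # q13 >> q24 in truth (gain of trait1 10x faster when trait2 = 0)
  hits <- 0
  for (r in 1:20) {
    sim_r <- simulate_discrete(tr, Qsim, root_state = 1L, seed = 400 + r)
    cfg_r <- mcmc_config(iterations = 4000, burnin = 1000, thin = 2, seed = 500 + r)
    run <- mcmc_coevolution(tr, sim_r$tips, "dependent", cfg_r)
    hits <- hits + (run$mean_rates["q13"] > run$mean_rates["q24"])
  }
  expect_gte(hits / 20, 0.9)
})

test_that("stepping-stone marginal likelihood is exact for constant likelihood", {
  # two zero-length branches with identical tip states: the pruning
  # likelihood is exactly 1 for every Q, so logML must be exactly 0
  tr <- ape::read.tree(text = "(a:0,b:0);")
  st <- setNames(c(1L, 1L), c("a", "b"))
  cfg <- mcmc_config(iterations = 500, burnin = 100, thin = 1, seed = 37)
  ml <- marginal_likelihood(tr, st, "dependent", cfg, n_stones = 10,
                            iter_per_stone = 200)
  expect_equal(ml$logml, 0, tolerance = 1e-12)
})

test_that("marginal likelihood is stable in the number of stones", {
  tr <- fix_tree(80, 38)
  sim <- simulate_discrete(tr, rate_matrix(setNames(rep(0.01, 4),
                                                    c("alpha1", "beta1", "alpha2", "beta2")),
                                           "independent"),
                           root_state = 1L, seed = 39)
  cfg <- mcmc_config(iterations = 1000, burnin = 200, thin = 1, seed = 40)
  m1 <- marginal_likelihood(tr, sim$tips, "independent", cfg,
                            n_stones = 10, iter_per_stone = 600)
  m2 <- marginal_likelihood(tr, sim$tips, "independent", cfg,
                            n_stones = 20, iter_per_stone = 600)
  expect_lt(abs(m1$logml - m2$logml), 0.5)
})

test_that("Bayes factor arithmetic follows the 2-log-units convention", {
  expect_equal(bayes_factor(-100, -100), 0)
  expect_equal(bayes_factor(-100, -104.65), 9.3)
  fake <- structure(list(logml = -50), class = "stepping_stone")
  expect_equal(bayes_factor(fake, -51), 2)
})
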
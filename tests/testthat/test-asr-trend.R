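test_that("GLS ancestral states match closed forms and a minimizer oracle", {
  # two-tip tree: inverse-branch-length weighted mean at the root
  tr2 <- ape::read.tree(text = "(a:1,b:3);")
  g2 <- asr_gls(tr2, c(a = 0, b = 4))
  expect_equal(g2$estimate, (0 / 1 + 4 / 3) / (1 / 1 + 1 / 3), tolerance = 1e-12)
  # star tree: arithmetic mean
  star <- ape::stree(8, type = "star"); star$edge.length <- rep(1, 8)
  xs <- setNames(rnorm(8), star$tip.label)
  expect_equal(asr_gls(star, xs)$estimate, mean(xs), tolerance = 1e-10)
  # 50-tip tree: equals direct minimization of the Brownian quadratic form
  tr <- fix_tree(50, 41)
  sim <- simulate_continuous(tr, lambda = 1, sigma2 = 2.56e-4, root = 4.1,
                             seed = 42)
  g <- asr_gls(tr, sim$tips)
  qf <- function(v) {
    all_v <- c(sim$tips[tr$tip.label], v)
    sum((all_v[tr$edge[, 1]] - all_v[tr$edge[, 2]])^2 / tr$edge.length)
  }
  opt <- optim(rep(mean(sim$tips), tr$Nnode), qf, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(g$estimate, opt$par, tolerance = 1e-6, ignore_attr = TRUE)
  # depths bounded by tip depth; exemplar tips identify the node via MRCA
  expect_true(all(g$depth >= 0 & g$depth <= max(node_depths(tr))))
  idx <- sample(nrow(g), 5)
  for (i in idx)
    expect_equal(mrca_node(tr, c(g$tip1[i], g$tip2[i])), g$node[i])
})

test_that("MCMC ancestral states agree with the GLS closed form", {
  tr <- fix_tree(50, 41)
  sim <- simulate_continuous(tr, lambda = 1, sigma2 = 2.56e-4, root = 4.1,
                             seed = 42)
  g <- asr_gls(tr, sim$tips)
  a <- asr_mcmc(tr, sim$tips, iterations = 20000, burnin = 5000, thin = 10,
                prior_mean = 0.001, seed = 43)
  agree <- mean(abs(a$nodes$mean - g$estimate) <= 2 * a$nodes$sd)
  expect_gte(agree, 0.95)
  # same seed -> identical output; different seeds -> close node means
  a2 <- asr_mcmc(tr, sim$tips, iterations = 20000, burnin = 5000, thin = 10,
                 prior_mean = 0.001, seed = 43)
  expect_identical(a$nodes$mean, a2$nodes$mean)
  conv <- asr_convergence(tr, sim$tips, n_runs = 2, seed = 44)
  expect_true(conv$converged)
  expect_lt(max(conv$across_run_sd), 0.05 * sd(sim$tips))
})

test_that("quantile fit is exact on exact data and optimal against enumeration", {
  set.seed(45)
  d <- runif(40, 0, 10)
  y <- 2 + 3 * d
  f <- rq_fit(cbind(1, d), y, 0.5)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-8)
  expect_lt(f$objective, 1e-10)
  # median-regression balance: few exact zeros, signed counts differ <= p
  set.seed(46)
  y2 <- 1 + 2 * d + rt(40, 3)
  X <- cbind(1, d)
  f2 <- rq_fit(X, y2, 0.5)
  nzero <- sum(abs(f2$residuals) < 1e-9)
  expect_lte(nzero, 2 + 2)
  expect_lte(abs(sum(f2$residuals > 1e-9) - sum(f2$residuals < -1e-9)), 2)
  # objective matches exhaustive basis enumeration on 30 points
  for (tau in c(0.25, 0.5, 0.9)) {
    set.seed(47)
    d3 <- runif(30); y3 <- 1 - d3 + rnorm(30)
    X3 <- cbind(1, d3)
    f3 <- rq_fit(X3, y3, tau)
    expect_equal(f3$objective, enum_rq_objective(X3, y3, tau), tolerance = 1e-9)
  }
  expect_error(rq_fit(cbind(1, rep(2, 30)), rnorm(30), 0.5), "degenerate")
})

test_that("quantile trend recovers simulated depth and passerine effects", {
  slope <- -0.002; offset <- 0.15
  cover_s <- cover_o <- 0
  nrep <- 25
  for (r in seq_len(nrep)) {
    set.seed(600 + r)
    n <- 600
    depth <- runif(n, 0, 100)
    pass <- rbinom(n, 1, 0.4)
    yv <- 4.1 + slope * depth + offset * pass + rnorm(n, 0, 0.12)
    tf <- quantile_trend(yv, depth, pass, tau = 0.5, n_boot = 200,
                         seed = 700 + r)
    ci <- function(term) tf$coefficients[term, "estimate"] +
      c(-1.96, 1.96) * tf$coefficients[term, "se"]
    cs <- ci("depth"); co <- ci("passerine")
    cover_s <- cover_s + (slope >= cs[1] && slope <= cs[2])
    cover_o <- cover_o + (offset >= co[1] && offset <= co[2])
  }
  expect_gte(cover_s / nrep, 0.9)
  expect_gte(cover_o / nrep, 0.9)
})

test_that("spline curves track linear data and isolate groups", {
  set.seed(48)
  d <- runif(60, 0, 10)
  y <- 1 + 0.5 * d
  out <- spline_trend(y, d, taus = 0.5, df = 4)
  fit <- out$all$fitted[, 1]
  expect_lt(max(abs(fit - (1 + 0.5 * out$all$grid))), 1e-6)
  # group isolation: one group's fit is unchanged by the other's data
  g <- rep(c("A", "B"), each = 30)
  y2 <- y; y2[g == "B"] <- rnorm(30, 10)
  two <- spline_trend(y2, d, g, taus = 0.5, df = 4)
  solo <- spline_trend(y2[g == "A"], d[g == "A"], taus = 0.5, df = 4)
  expect_equal(two$A$fitted, solo$all$fitted, tolerance = 1e-9)
  # hump-shaped trend: maximum of the fitted median inside the hump window
  set.seed(49)
  dh <- runif(300, 0, 10)
  yh <- -(dh - 4)^2 + rnorm(300, 0, 0.5)
  hf <- spline_trend(yh, dh, taus = 0.5, df = 5)
  peak <- hf$all$grid[which.max(hf$all$fitted[, 1])]
  expect_gt(peak, 3); expect_lt(peak, 5)
  expect_error(spline_trend(rnorm(5), rnorm(5)), "at least 10")
})
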
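test_that("risk recoding picks the highest-risk category", {
  expect_equal(as.character(recode_nest_risk(list(c("basal", "pensile")), "attachment")),
               "pensile")
  expect_equal(as.character(recode_nest_risk("cup", "structure")), "cup")
  expect_equal(as.character(recode_nest_risk(list(c("scrape/platform", "dome", "cup")),
                                             "structure")), "dome")
  expect_equal(as.character(recode_nest_risk(list(c("others", "tree")), "site")), "tree")
  # reference level is the lowest-risk category
  expect_equal(levels(recode_nest_risk("cup", "structure"))[1], "scrape/platform")
  expect_error(recode_nest_risk("hanging", "attachment"), "unknown")
})

test_that("lambda transform keeps the diagonal and scales off-diagonals", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  V <- ape::vcv(tr)
  expect_equal(lambda_covariance(tr, 1), V)
  expect_equal(lambda_covariance(tr, 0), diag(diag(V)), ignore_attr = TRUE)
  Vh <- lambda_covariance(tr, 0.5)
  expect_equal(Vh["a", "b"], 0.5)
  expect_equal(Vh["a", "a"], 2)
  expect_error(lambda_covariance(tr, 1.2), "lambda")
})

test_that("AICc formula and limits", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(-10, 0, 20), 20)
  expect_lt(abs(aicc(-5, 4, 1e9) - (10 + 8)), 1e-6)
  expect_error(aicc(-10, 19, 20), "undefined")
})

test_that("PGLS reduces to OLS on a star tree and at lambda = 0", {
  star <- ape::stree(30, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(21)
  y <- setNames(rnorm(30), star$tip.label)
  X <- cbind(intercept = 1, x = rnorm(30))
  rownames(X) <- star$tip.label
  f <- fit_pgls(y, X, star)
  expect_equal(f$coefficients$estimate, ols_normal_eq(X, y),
               tolerance = 1e-10, ignore_attr = TRUE)
  # fixed lambda = 0 on a structured tree: textbook OLS closed form
  tr <- fix_tree(40, 22)
  y2 <- setNames(rnorm(40), tr$tip.label)
  X2 <- cbind(intercept = 1, x = rnorm(40)); rownames(X2) <- tr$tip.label
  f0 <- fit_pgls(y2, X2, tr, lambda = 0)
  expect_equal(f0$coefficients$estimate, ols_normal_eq(X2, y2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # OLS standard errors too
  res <- y2 - drop(X2 %*% ols_normal_eq(X2, y2))
  s2 <- sum(res^2) / (40 - 2)
  expect_equal(f0$coefficients$se, sqrt(diag(s2 * solve(t(X2) %*% X2))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ML lambda and likelihood agree with an independent GLS fit", {
  skip_if_not_installed("nlme")
  tr <- fix_tree(60, 23)
  V <- ape::vcv(tr)
  set.seed(24)
  x <- rnorm(60)
  y <- setNames(2 + 0.4 * x +
                  MASS::mvrnorm(1, rep(0, 60), 3e-4 * lambda_covariance(tr, 0.6)),
                tr$tip.label)
  X <- cbind(`(Intercept)` = 1, x = x); rownames(X) <- tr$tip.label
  f <- fit_pgls(y, X, tr)
  dat <- data.frame(y = y, x = x, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corPagel(0.5, tr, form = ~sp), method = "ML")
  expect_equal(f$lambda, unname(coef(g$modelStruct$corStruct)), tolerance = 1e-4)
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  # profile property: reported logLik beats any fixed lambda on a grid
  for (l in c(0, 0.25, 0.5, 0.75, 1))
    expect_gte(f$logLik + 1e-6, fit_pgls(y, X, tr, lambda = l)$logLik)
})

test_that("rank-deficient designs are repaired with a warning", {
  tr <- fix_tree(40, 22)
  set.seed(25)
  y <- setNames(rnorm(40), tr$tip.label)
  X <- cbind(intercept = 1, a = rnorm(40))
  X <- cbind(X, b = X[, "a"] * 2)
  rownames(X) <- tr$tip.label
  expect_warning(f <- fit_pgls(y, X, tr), "rank-deficient")
  expect_equal(nrow(f$coefficients), 2)
})

test_that("partial residual group offsets equal coefficient differences", {
  study <- simulate_study(120, seed = 26, lambda_signal = 1)
  y <- setNames(study$traits$log10_C, study$traits$species)
  f <- factor(study$traits$structure)
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0("f", levels(f)[-1]))
  X <- cbind(X, clutch = study$traits$clutch)
  rownames(X) <- study$traits$species
  fit <- fit_pgls(y, X, study$tree)
  focal <- grep("^f", colnames(X), value = TRUE)
  pres <- partial_residuals(fit, y, X, focal)
  # fitted offsets between groups equal beta differences exactly after
  # removing the residual part
  bb <- setNames(fit$coefficients$estimate, rownames(fit$coefficients))
  contrib <- drop(X[, focal] %*% bb[focal])
  expect_equal(pres - (y[fit$species] - drop(X %*% bb[colnames(X)])),
               contrib, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("grouping selection enumerates Bell-many partitions and finds truth", {
  tr <- fix_tree(150, 27)
  # 4 levels -> exactly 15 candidate models
  set.seed(28)
  g4 <- factor(sample(c("w", "x", "y", "z"), 150, TRUE))
  names(g4) <- tr$tip.label
  y4 <- setNames(rnorm(150, 0, 0.05), tr$tip.label)
  gs4 <- grouping_selection(y4, g4, tr, lambda = 0)
  expect_equal(nrow(gs4$table), 15)

  # null: all means equal -> the single group is modal (AICc admits a
  # ~15% spurious-split chance per competing partition, so the expected
  # null win rate sits near 0.65)
  wins_null <- 0
  for (r in 1:25) {
    set.seed(100 + r)
    g <- factor(sample(c("p", "q", "r"), 150, TRUE)); names(g) <- tr$tip.label
    y <- setNames(rnorm(150, 0, 0.1), tr$tip.label)
    gs <- grouping_selection(y, g, tr, lambda = 0)
    if (length(gs$best) == 1) wins_null <- wins_null + 1
  }
  expect_gte(wins_null / 25, 0.5)

  # separated means (0, 0, 0.3), small sd -> {p,q} vs {r} is modal and the
  # separated level is never merged with the others
  wins_alt <- 0
  for (r in 1:25) {
    set.seed(200 + r)
    g <- factor(sample(c("p", "q", "r"), 150, TRUE)); names(g) <- tr$tip.label
    mu <- c(p = 0, q = 0, r = 0.3)[as.character(g)]
    y <- setNames(mu + rnorm(150, 0, 0.1), tr$tip.label)
    gs <- grouping_selection(y, g, tr, lambda = 0)
    groups <- lapply(gs$best, sort)
    r_alone <- any(vapply(groups, function(gg) identical(gg, "r"), logical(1)))
    expect_true(r_alone)  # the big effect is always isolated
    if (length(groups) == 2 &&
        any(vapply(groups, function(gg) identical(gg, c("p", "q")), logical(1))))
      wins_alt <- wins_alt + 1
  }
  expect_gte(wins_alt / 25, 0.7)
  # letter display: same letter iff same group
  gsep <- grouping_selection(
    setNames(c(rnorm(75, 0, 0.05), rnorm(75, 1, 0.05)), tr$tip.label),
    setNames(factor(rep(c("lo", "hi"), each = 75)), tr$tip.label), tr, lambda = 0)
  expect_false(gsep$letters[["lo"]] == gsep$letters[["hi"]])
})
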
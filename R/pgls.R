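#' Closed category vocabularies for nest characters
#'
#' Levels are ordered by presumed egg-collision risk: attachment by nest
#' steadiness (basal steadiest), site by substrate stability, structure by
#' enclosure (dome most enclosed).
#'
#' @format named list of character vectors, lowest risk first.
#' @export
nest_vocab <- list(
  attachment = c("basal", "lateral/horizontal", "pensile"),
  site       = c("others", "tree", "non-tree vegetation"),
  structure  = c("scrape/platform", "cavity", "cup", "dome")
)

#' Recode multi-valued nest categories to the highest-risk category
#'
#' Species that use several nest types are assigned the category with the
#' lowest stability or highest enclosure (highest collision risk) among
#' those reported.
#'
#' @param raw a list (one element per species) of character vectors, or a
#'   single character vector of categories for one species.
#' @param character one of `"attachment"`, `"site"`, `"structure"`.
#' @return character vector (one category per species), as an ordered factor
#'   with the reference (lowest-risk) level first.
#' @examples
#' recode_nest_risk(list(c("basal", "pensile"), "cup"), "attachment")
#' @export
recode_nest_risk <- function(raw, character = c("attachment", "site", "structure")) {
  character <- match.arg(character)
  vocab <- nest_vocab[[character]]
  if (!is.list(raw)) raw <- list(raw)
  out <- vapply(raw, function(v) {
    idx <- match(v, vocab)
    if (anyNA(idx))
      stop("unknown ", character, " category: ",
           paste(v[is.na(idx)], collapse = ", "))
    vocab[max(idx)]
  }, character(1))
  factor(out, levels = vocab)
}

#' Pagel's lambda transform of the phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of the Brownian-motion covariance
#' (shared path lengths) by `lambda`, keeping the diagonal.
#'
#' @param tree a rooted `phylo` with branch lengths, or a covariance matrix.
#' @param lambda signal parameter in `[0, 1]`.
#' @return covariance matrix with tip-label dimnames.
#' @export
lambda_covariance <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  V <- if (inherits(tree, "phylo")) ape::vcv(tree) else as.matrix(tree)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects + sigma^2 +
#'   lambda when estimated).
#' @param n number of observations.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# profile ML machinery ------------------------------------------------------

# Fast path for ultrametric trees: V(lambda) = U (lambda*L + (1-lambda)*T) U'
# with V = U L U' and T the common tip depth, so each lambda evaluation is a
# weighted least squares in the rotated frame.
pgls_profile_ultra <- function(ey, eX, evals, Tdepth) {
  n <- length(ey); p <- ncol(eX)
  function(lambda) {
    w <- lambda * evals + (1 - lambda) * Tdepth
    if (any(w <= 0)) return(list(logLik = -Inf))
    sw <- 1 / sqrt(w)
    yw <- ey * sw; Xw <- eX * sw
    qrX <- qr(Xw)
    beta <- qr.coef(qrX, yw)
    res <- yw - Xw %*% beta
    rss <- sum(res^2)
    s2ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2ml) + sum(log(w)) + n)
    list(logLik = ll, beta = drop(beta), rss = rss, s2ml = s2ml,
         XtVinvX = crossprod(Xw))
  }
}

pgls_profile_general <- function(y, X, V, Vdiag) {
  n <- length(y)
  function(lambda) {
    Vl <- lambda * V
    diag(Vl) <- Vdiag
    ch <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(ch)) return(list(logLik = -Inf))
    yw <- backsolve(ch, y, transpose = TRUE)
    Xw <- backsolve(ch, X, transpose = TRUE)
    qrX <- qr(Xw)
    beta <- qr.coef(qrX, yw)
    res <- yw - Xw %*% beta
    rss <- sum(res^2)
    s2ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2ml) + 2 * sum(log(diag(ch))) + n)
    list(logLik = ll, beta = drop(beta), rss = rss, s2ml = s2ml,
         XtVinvX = crossprod(Xw))
  }
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V(lambda))` where `V(lambda)`
#' keeps the Brownian diagonal and scales off-diagonals by `lambda`. Lambda
#' is estimated by maximum likelihood (bounded search on `[0, 1]`) unless
#' fixed. ML (not REML) is used throughout so that models with different
#' fixed effects are AICc-comparable; the parameter count includes `sigma^2`
#' and, when estimated, `lambda`.
#'
#' @param y numeric response named by species, or a formula.
#' @param design model matrix (rows named by species), or a data frame when
#'   `y` is a formula.
#' @param tree rooted `phylo` whose tips cover the species.
#' @param lambda `NULL` to estimate by ML, or a fixed value in `[0, 1]`.
#' @return object of class `pgls_fit`: `coefficients` table (estimate, SE,
#'   t, p with `n - p` df), `lambda`, `sigma2` (ML), `logLik`, `AICc`, `n`,
#'   `k`.
#' @examples
#' tr <- ape::rcoal(20)
#' y <- stats::setNames(rnorm(20), tr$tip.label)
#' fit_pgls(y, cbind(intercept = rep(1, 20)), tr)
#' @export
fit_pgls <- function(y, design, tree, lambda = NULL) {
  if (inherits(y, "formula")) {
    mf <- stats::model.frame(y, data = design)
    design <- stats::model.matrix(y, mf)
    rownames(design) <- rownames(mf)
    y <- stats::model.response(mf)
    names(y) <- rownames(design)
  }
  X <- as.matrix(design)
  if (is.null(names(y)) || is.null(rownames(X)))
    stop("y and design must be named by species")
  sp <- intersect(names(y), tree$tip.label)
  if (length(sp) < ncol(X) + 2) stop("too few species shared with the tree")
  if (length(sp) < length(y))
    warning(length(y) - length(sp), " species not in the tree were dropped")
  y <- y[sp]; X <- X[sp, , drop = FALSE]
  qr0 <- qr(X)
  if (qr0$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr0$pivot[(qr0$rank + 1):ncol(X)]]
    warning("rank-deficient design; dropping: ", paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }
  V <- ape::vcv(tree)[sp, sp]
  n <- length(y); p <- ncol(X)
  Vdiag <- diag(V)
  ultra <- diff(range(Vdiag)) < 1e-8 * max(Vdiag)
  if (ultra) {
    eg <- eigen(V, symmetric = TRUE)
    ey <- drop(crossprod(eg$vectors, y))
    eX <- crossprod(eg$vectors, X)
    prof <- pgls_profile_ultra(ey, eX, eg$values, Vdiag[1])
  } else {
    prof <- pgls_profile_general(y, X, V, Vdiag)
  }
  if (is.null(lambda)) {
    op <- stats::optimize(function(l) prof(l)$logLik, c(0, 1),
                          maximum = TRUE, tol = 1e-6)
    # the optimum can sit at a boundary; compare explicitly
    cand <- c(op$maximum, 0, 1)
    lls <- vapply(cand, function(l) prof(l)$logLik, numeric(1))
    lambda_hat <- cand[which.max(lls)]
    k <- p + 2
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    lambda_hat <- lambda
    k <- p + 1
  }
  at <- prof(lambda_hat)
  s2res <- at$rss / (n - p)
  covb <- s2res * solve(at$XtVinvX)
  se <- sqrt(diag(covb))
  tval <- at$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coef_tab <- data.frame(estimate = at$beta, se = se, t = tval, p = pval,
                         row.names = colnames(X))
  structure(list(coefficients = coef_tab, lambda = lambda_hat,
                 lambda_estimated = is.null(lambda), sigma2 = at$s2ml,
                 logLik = at$logLik, AICc = aicc(at$logLik, k, n),
                 n = n, k = k, vcov = covb, species = sp),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, lambda = %.3f%s, logLik = %.2f, AICc = %.2f)\n",
              x$n, x$lambda, if (x$lambda_estimated) " [ML]" else " [fixed]",
              x$logLik, x$AICc))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# set partitions of 1..n as restricted growth strings
set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxval) {
    if (i > n) { out[[length(out) + 1]] <<- rgs[seq_len(n)]; return(invisible()) }
    for (v in seq_len(maxval + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxval, v))
    }
  }
  recurse(1, 0)
  out
}

#' AICc model selection over all category groupings
#'
#' Enumerates every set-partition of a character's levels (Bell-number many
#' candidate models), refits the PGLS with levels merged per partition, and
#' returns the lowest-AICc partition with a compact letter display (levels
#' sharing a letter belong to the same group).
#'
#' @param y named numeric response (log10 C).
#' @param groups factor of category levels, named by species.
#' @param tree rooted `phylo`.
#' @param covariates optional numeric matrix (rows named by species), e.g.
#'   clutch size.
#' @param lambda passed to [fit_pgls()] (`NULL` = ML).
#' @return object of class `grouping_selection`: `best` (list of level
#'   groups), `letters` (named by level), `table` (partition, k groups,
#'   AICc), `fits` omitted for size.
#' @export
grouping_selection <- function(y, groups, tree, covariates = NULL,
                               lambda = NULL) {
  groups <- droplevels(as.factor(groups))
  if (is.null(names(groups))) stop("groups must be named by species")
  levs <- levels(groups)
  if (any(table(groups) == 0)) stop("empty level in groups")
  if (length(levs) > 6) stop("grouping selection supports at most 6 levels")
  parts <- set_partitions(length(levs))
  res <- vector("list", length(parts))
  for (j in seq_along(parts)) {
    assign <- parts[[j]]
    merged <- factor(assign[as.integer(groups)])
    X <- if (nlevels(merged) > 1) stats::model.matrix(~merged)
         else matrix(1, length(groups), 1, dimnames = list(NULL, "(Intercept)"))
    rownames(X) <- names(groups)
    if (!is.null(covariates)) {
      cv <- as.matrix(covariates)
      X <- cbind(X, cv[names(groups), , drop = FALSE])
    }
    fit <- fit_pgls(y, X, tree, lambda = lambda)
    res[[j]] <- list(assign = assign, AICc = fit$AICc, fit = fit)
  }
  aiccs <- vapply(res, `[[`, numeric(1), "AICc")
  best <- res[[which.min(aiccs)]]
  grp <- split(levs, best$assign)
  # letters ordered by fitted group means (low to high)
  gm <- tapply(y[names(groups)], best$assign[as.integer(groups)], mean)
  ord <- order(gm)
  letter_of_group <- stats::setNames(letters[seq_along(ord)], names(gm)[ord])
  lets <- stats::setNames(letter_of_group[as.character(best$assign)], levs)
  tab <- data.frame(
    partition = vapply(res, function(r)
      paste(vapply(split(levs, r$assign), paste, character(1), collapse = "+"),
            collapse = " | "), character(1)),
    n_groups = vapply(res, function(r) length(unique(r$assign)), integer(1)),
    AICc = aiccs)
  tab <- tab[order(tab$AICc), ]
  structure(list(best = grp, letters = lets, table = tab,
                 best_fit = best$fit),
            class = "grouping_selection")
}

#' @export
print.grouping_selection <- function(x, ...) {
  cat("Best grouping (lowest AICc):\n")
  for (g in x$best) cat("  {", paste(g, collapse = ", "), "}\n")
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Partial residuals for a focal character
#'
#' Residuals from the fitted model plus the focal character's fitted
#' contribution, the quantity plotted per category in group-difference
#' figures; group offsets equal differences of the fitted coefficients
#' exactly.
#'
#' @param fit a `pgls_fit`.
#' @param y named response used in the fit.
#' @param design model matrix used in the fit.
#' @param focal column names of the focal character's columns in `design`.
#' @return named numeric vector of partial residuals.
#' @export
partial_residuals <- function(fit, y, design, focal) {
  X <- as.matrix(design)[fit$species, , drop = FALSE]
  b <- fit$coefficients$estimate
  names(b) <- rownames(fit$coefficients)
  yhat <- drop(X %*% b[colnames(X)])
  resid <- y[fit$species] - yhat
  contrib <- drop(X[, focal, drop = FALSE] %*% b[focal])
  resid + contrib
}
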
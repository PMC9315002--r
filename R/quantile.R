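#' Quantile regression by check-loss minimisation
#'
#' Minimises the check loss `sum rho_tau(y - X b)` with
#' `rho_tau(r) = r (tau - 1[r < 0])`. The solver is an MM/IRLS scheme on a
#' smoothed loss with a decreasing smoothing schedule, followed by a
#' combinatorial polish over exact-fit bases drawn from the smallest
#' residuals (a tau-quantile solution interpolates `p` observations).
#'
#' @param X design matrix (first column typically the intercept).
#' @param y response.
#' @param tau quantile in (0, 1).
#' @return list: `coefficients`, `objective`, `residuals`.
#' @export
rq_fit <- function(X, y, tau = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (n <= p) stop("need more observations than parameters")
  if (qr(X)$rank < p) stop("degenerate design (rank deficient)")
  obj <- function(b) {
    r <- y - drop(X %*% b)
    sum(r * (tau - (r < 0)))
  }
  # MM iterations: weights tau/|r| (r>0) or (1-tau)/|r| (r<0), smoothed
  b <- stats::lm.fit(X, y)$coefficients
  eps <- max(stats::sd(y), 1e-8)
  for (it in 1:60) {
    r <- y - drop(X %*% b)
    a <- pmax(abs(r), eps)
    w <- ifelse(r >= 0, tau, 1 - tau) / a
    b_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(b_new - b)) < 1e-12 && eps <= 1e-10) { b <- b_new; break }
    b <- b_new
    eps <- max(eps * 0.5, 1e-10)
  }
  best <- b; best_obj <- obj(b)
  # polish: exact-fit bases among the 2p smallest absolute residuals
  r <- y - drop(X %*% b)
  cand <- order(abs(r))[seq_len(min(n, 2 * p))]
  if (length(cand) >= p) {
    combs <- utils::combn(cand, p)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      Xb <- X[idx, , drop = FALSE]
      if (abs(det(Xb)) < 1e-12) next
      bb <- tryCatch(solve(Xb, y[idx]), error = function(e) NULL)
      if (is.null(bb)) next
      ob <- obj(bb)
      if (ob < best_obj - 1e-12) { best <- bb; best_obj <- ob }
    }
  }
  r <- y - drop(X %*% best)
  list(coefficients = stats::setNames(drop(best), colnames(X)),
       objective = best_obj, residuals = r)
}

#' Quantile-regression trend of C number against node depth
#'
#' Fits the tau-th quantile of (log10) C values pooled over tips and
#' internal nodes against node depth, optionally with a passerine indicator
#' and its depth interaction. Standard errors come from a seeded
#' case-resampling bootstrap.
#'
#' @param values numeric responses (tips: observed; nodes: posterior
#'   medians).
#' @param depths node depths matching `values`.
#' @param passerine optional logical/0-1 vector; adds the indicator and its
#'   depth interaction.
#' @param tau quantile level.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed (required when `n_boot > 0`).
#' @return object of class `trend_fit`: `coefficients` table (estimate,
#'   boot SE, z, p), `tau`, `n`, `objective`.
#' @export
quantile_trend <- function(values, depths, passerine = NULL, tau = 0.5,
                           n_boot = 1000, seed = NULL) {
  n <- length(values)
  if (n <= 4) stop("need more than 4 observations")
  if (!all(is.finite(depths))) stop("depths must be finite")
  if (stats::sd(depths) == 0) stop("degenerate design: constant depth")
  X <- cbind(intercept = 1, depth = depths)
  if (!is.null(passerine)) {
    pz <- as.numeric(passerine)
    X <- cbind(X, passerine = pz, `depth:passerine` = depths * pz)
  }
  fit <- rq_fit(X, values, tau)
  se <- rep(NA_real_, ncol(X))
  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires an explicit seed")
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, ncol(X))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bs[bi, ] <- tryCatch(rq_fit(X[idx, , drop = FALSE], values[idx], tau)$coefficients,
                           error = function(e) rep(NA_real_, ncol(X)))
    }
    se <- apply(bs, 2, stats::sd, na.rm = TRUE)
  }
  z <- fit$coefficients / se
  tab <- data.frame(estimate = fit$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    row.names = colnames(X))
  structure(list(coefficients = tab, tau = tau, n = n,
                 objective = fit$objective),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Quantile trend (tau = %.2f, n = %d, check loss = %.4g)\n",
              x$tau, x$n, x$objective))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Polynomial-spline quantile curves per group
#'
#' Visualisation curves: for each group, fits B-spline quantile regressions
#' at the requested quantile levels (default median with 5th/95th
#' percentiles) over node depth. Purely descriptive; no inference.
#'
#' @param values,depths numeric vectors.
#' @param group grouping factor (e.g. passerine vs non-passerine).
#' @param taus quantile levels.
#' @param df spline degrees of freedom.
#' @param n_grid evaluation grid size per group.
#' @return list per group: `grid` (depths) and `fitted` (matrix, one column
#'   per tau).
#' @export
spline_trend <- function(values, depths, group = NULL,
                         taus = c(0.05, 0.5, 0.95), df = 4, n_grid = 100) {
  if (is.null(group)) group <- factor(rep("all", length(values)))
  group <- as.factor(group)
  out <- list()
  for (g in levels(group)) {
    sel <- group == g
    if (sum(sel) < 10) stop("need at least 10 points per group (group ", g, ")")
    d <- depths[sel]; v <- values[sel]
    basis <- splines::bs(d, df = df)
    X <- cbind(1, basis)
    grid <- seq(min(d), max(d), length.out = n_grid)
    Xg <- cbind(1, stats::predict(basis, grid))
    fitted <- sapply(taus, function(tt) drop(Xg %*% rq_fit(X, v, tt)$coefficients))
    colnames(fitted) <- paste0("tau", taus)
    out[[g]] <- list(grid = grid, fitted = fitted)
  }
  out
}
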
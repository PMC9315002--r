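#' Build a parametric egg meridian profile
#'
#' Constructs the meridian of an egg-shaped surface of revolution. The long
#' axis is `z` (length `B`), the radius function is
#' `r(theta) = (A/2) * sin(theta) * P(x) / M` with `x = -cos(theta)`,
#' `z(theta) = (B/2) * (1 - cos(theta))`, where `P` is a shape polynomial and
#' `M` normalises the maximum radius to `A/2`. With
#' `ellipticity = asymmetry = 0` the profile is a prolate spheroid with
#' semi-axes `A/2` and `B/2` (a sphere when `A == B`).
#'
#' @param A breadth of the egg (maximum diameter, metres).
#' @param B length of the egg along the long axis (metres).
#' @param ellipticity even shape coefficient; positive values flatten the
#'   equator region (`x^2` term of the shape polynomial).
#' @param asymmetry odd shape coefficient; positive values make the end at
#'   `z = B` blunter than the end at `z = 0` (`x` term).
#' @return An object of class `egg_profile` with fields `A`, `B`, `shape`
#'   (polynomial coefficients of `P`, constant term first) and `Mnorm`.
#' @examples
#' p <- build_profile(0.04, 0.06)
#' profile_radius(p, 0.03)  # A/2 at the equator of a spheroid
#' @export
build_profile <- function(A, B, ellipticity = 0, asymmetry = 0) {
  if (!is.finite(A) || !is.finite(B) || A <= 0 || B <= 0)
    stop("egg dimensions A and B must be positive")
  shape <- c(1, asymmetry, ellipticity)
  new_egg_profile(A, B, shape)
}

new_egg_profile <- function(A, B, shape) {
  # admissibility: the shape polynomial must stay positive on [-1, 1]
  xg <- seq(-1, 1, length.out = 2001)
  pg <- drop(outer(xg, seq_along(shape) - 1, `^`) %*% shape)
  if (min(pg) <= 0)
    stop("shape parameters produce non-positive radii (shape polynomial <= 0 on [-1,1])")
  Mnorm <- max(sqrt(1 - xg^2) * pg)
  structure(list(A = A, B = B, shape = shape, Mnorm = Mnorm),
            class = "egg_profile")
}

#' @export
print.egg_profile <- function(x, ...) {
  cat(sprintf("<egg_profile> A = %.4g m, B = %.4g m, shape = [%s]\n",
              x$A, x$B, paste(signif(x$shape, 4), collapse = ", ")))
  invisible(x)
}

poly_eval <- function(coef, x, deriv = 0L) {
  k <- seq_along(coef) - 1
  if (deriv > 0) {
    for (d in seq_len(deriv)) {
      coef <- coef[-1] * k[-1]
      k <- seq_along(coef) - 1
      if (!length(coef)) return(rep(0, length(x)))
    }
  }
  drop(outer(x, k, `^`) %*% coef)
}

# Meridian geometry at parameter theta in [0, pi]: position, derivatives,
# arclength rate, unit tangent and signed curvature (normal convention
# n = (z', -r'), pointing outward; kappa = -1/R on a sphere of radius R).
egg_meridian <- function(profile, theta) {
  A <- profile$A; B <- profile$B
  cc <- A / (2 * profile$Mnorm)
  x <- -cos(theta); sn <- sin(theta); cs <- cos(theta)
  p0 <- poly_eval(profile$shape, x)
  p1 <- poly_eval(profile$shape, x, 1L)
  p2 <- poly_eval(profile$shape, x, 2L)
  r    <- cc * sn * p0
  r_t  <- cc * (cs * p0 + sn^2 * p1)
  r_tt <- cc * (-sn * p0 + 3 * sn * cs * p1 + sn^3 * p2)
  z    <- (B / 2) * (1 - cs)
  z_t  <- (B / 2) * sn
  z_tt <- (B / 2) * cs
  s_t  <- sqrt(r_t^2 + z_t^2)
  s_tt <- (r_t * r_tt + z_t * z_tt) / s_t
  kappa <- (r_tt * z_t - z_tt * r_t) / s_t^3
  list(r = r, z = z, r_t = r_t, z_t = z_t, s_t = s_t, s_tt = s_tt,
       kappa = kappa)
}

# d kappa / d theta by central difference of the analytic geometry
egg_kappa_t <- function(profile, theta, h = 1e-6) {
  kp <- egg_meridian(profile, theta + h)$kappa
  km <- egg_meridian(profile, theta - h)$kappa
  (kp - km) / (2 * h)
}

#' Meridian radius at axial coordinate z
#'
#' @param profile an [build_profile()] object.
#' @param z axial coordinate(s) in `[0, B]` (metres).
#' @return radius (metres).
#' @export
profile_radius <- function(profile, z) {
  stopifnot(inherits(profile, "egg_profile"))
  if (any(z < -1e-12 | z > profile$B + 1e-12)) stop("z outside [0, B]")
  theta <- acos(pmin(1, pmax(-1, 1 - 2 * z / profile$B)))
  egg_meridian(profile, theta)$r
}

#' Enclosed volume of an egg profile
#'
#' Volume of the solid of revolution, `pi * integral of r(z)^2 dz`, computed
#' by quadrature in the meridian parameter. Accepts either an `egg_profile`
#' or a two-column table of `(z, r)` pairs (trapezoidal rule).
#'
#' @param profile an `egg_profile`, or a data frame / matrix with columns
#'   `z` and `r`.
#' @return volume in cubic metres.
#' @examples
#' profile_volume(build_profile(0.04, 0.06))  # pi * A^2 * B / 6
#' @export
profile_volume <- function(profile) {
  if (inherits(profile, "egg_profile")) {
    f <- function(theta) {
      g <- egg_meridian(profile, theta)
      g$r^2 * g$z_t
    }
    pi * stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
  } else {
    tab <- as.data.frame(profile)
    if (!all(c("z", "r") %in% names(tab))) {
      if (ncol(tab) >= 2) names(tab)[1:2] <- c("z", "r")
      else stop("tabulated profile needs columns z and r")
    }
    tab <- tab[order(tab$z), ]
    if (any(tab$r < 0)) stop("negative radii in tabulated profile")
    pi * sum(diff(tab$z) * (tab$r[-1]^2 + tab$r[-nrow(tab)]^2) / 2)
  }
}

#' Fit a parametric profile to a tabulated meridian
#'
#' Least-squares fit of the shape-polynomial family used by
#' [build_profile()] to a dense table of `(z, r)` pairs, so that tabulated
#' profiles (e.g. from image processing) can enter the stiffness solver.
#'
#' @param tab data frame or matrix with columns `z` and `r` (metres).
#' @param degree degree of the shape polynomial (default 4).
#' @return an `egg_profile`.
#' @export
as_egg_profile <- function(tab, degree = 4) {
  tab <- as.data.frame(tab)
  if (!all(c("z", "r") %in% names(tab))) names(tab)[1:2] <- c("z", "r")
  tab <- tab[order(tab$z), ]
  B <- max(tab$z) - min(tab$z)
  z0 <- min(tab$z)
  A <- 2 * max(tab$r)
  if (A <= 0 || B <= 0) stop("degenerate tabulated profile")
  x <- pmin(1, pmax(-1, 2 * (tab$z - z0) / B - 1))
  sn <- sqrt(1 - x^2)
  keep <- sn > 0.05                     # exclude pole points (r/sin 0/0)
  q <- tab$r[keep] / ((A / 2) * sn[keep])
  X <- outer(x[keep], 0:degree, `^`)
  coef <- stats::lm.fit(X, q)$coefficients
  coef[!is.finite(coef)] <- 0
  new_egg_profile(A, B, unname(coef))
}
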
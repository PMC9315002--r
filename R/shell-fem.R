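#' Shell material properties
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio (dimensionless, in `[0, 0.5)`).
#' @param thickness uniform shell thickness (m).
#' @return an object of class `shell_material`.
#' @export
shell_material <- function(E = 3e10, nu = 0.3, thickness) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must be in [0, 0.5)")
  if (thickness <= 0) stop("thickness must be positive")
  structure(list(E = E, nu = nu, thickness = thickness),
            class = "shell_material")
}

#' Assemble an egg specimen
#'
#' Bundles geometry, material and weight for one species' egg. If `mass` is
#' missing it is estimated from the enclosed volume and `density`.
#'
#' @param profile an [build_profile()] object.
#' @param material a [shell_material()] object.
#' @param mass egg mass (kg), optional.
#' @param density whole-egg density used when mass is missing (kg m^-3);
#'   default 1031 (fresh-egg value).
#' @param g gravitational acceleration (m s^-2).
#' @return object of class `egg_specimen` with fields `profile`, `material`,
#'   `mass` (kg) and `weight` (N).
#' @export
egg_specimen <- function(profile, material, mass = NULL, density = 1031,
                         g = 9.81) {
  stopifnot(inherits(profile, "egg_profile"), inherits(material, "shell_material"))
  if (is.null(mass)) mass <- profile_volume(profile) * density
  if (mass <= 0) stop("egg mass must be positive")
  structure(list(profile = profile, material = material, mass = mass,
                 weight = mass * g),
            class = "egg_specimen")
}

# Hermite cubic shape functions on xi in [0, 1] with derivative dofs scaled
# by the element length h (dofs: value and d/dtheta at each end).
hermite_basis <- function(xi, h) {
  H  <- c(1 - 3 * xi^2 + 2 * xi^3, h * (xi - 2 * xi^2 + xi^3),
          3 * xi^2 - 2 * xi^3,     h * (-xi^2 + xi^3))
  H1 <- c(-6 * xi + 6 * xi^2, h * (1 - 4 * xi + 3 * xi^2),
          6 * xi - 6 * xi^2,  h * (-2 * xi + 3 * xi^2)) / h
  H2 <- c(-6 + 12 * xi, h * (-4 + 6 * xi),
          6 - 12 * xi,  h * (-2 + 6 * xi)) / h^2
  list(N = H, N1 = H1, N2 = H2)
}

# Linear axisymmetric (torsionless) Kirchhoff-Love shell of revolution under
# axial pole loads. Meridian displacements u (tangential) and w (normal) are
# interpolated with Hermite cubics in the meridian parameter theta; strains:
#   eps_s  = u' - kappa w           (meridional membrane, ' = d/ds)
#   eps_th = (u r' + w z') / r      (hoop membrane)
#   beta   = w' + kappa u           (meridional rotation)
#   chi_s  = beta'                  (meridional bending)
#   chi_th = beta r' / r            (hoop bending)
# Returns the plate-to-plate stiffness K = F / approach.
fem_axial_stiffness <- function(profile, material, n_elem) {
  E <- material$E; nu <- material$nu; t <- material$thickness
  Cm <- E * t / (1 - nu^2) * matrix(c(1, nu, nu, 1), 2)
  Db <- E * t^3 / (12 * (1 - nu^2)) * matrix(c(1, nu, nu, 1), 2)

  # nodes graded toward both poles to resolve the sqrt(R t) boundary layer
  xg <- seq(0, 1, length.out = n_elem + 1)
  th <- pi * (xg - sin(2 * pi * xg) / (2 * pi))
  th[1] <- 0; th[n_elem + 1] <- pi

  gp <- c(0.069431844202974, 0.330009478207572,
          0.669990521792428, 0.930568155797026)
  gw <- c(0.173927422568727, 0.326072577431273,
          0.326072577431273, 0.173927422568727)

  ndof <- 4 * (n_elem + 1)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  idx_all <- matrix(0L, n_elem, 8)
  Ke_list <- vector("list", n_elem)
  for (e in seq_len(n_elem)) {
    ta <- th[e]; tb <- th[e + 1]; h <- tb - ta
    Ke <- matrix(0, 8, 8)
    for (q in seq_along(gp)) {
      theta <- ta + gp[q] * h
      g <- egg_meridian(profile, theta)
      kap <- g$kappa
      kap_t <- egg_kappa_t(profile, theta)
      st <- g$s_t; stt <- g$s_tt
      hb <- hermite_basis(gp[q], h)
      zeros <- numeric(4)
      Nu  <- c(hb$N[1:2], zeros[1:2], hb$N[3:4], zeros[1:2])
      Nu1 <- c(hb$N1[1:2], zeros[1:2], hb$N1[3:4], zeros[1:2])
      Nw  <- c(zeros[1:2], hb$N[1:2], zeros[1:2], hb$N[3:4])
      Nw1 <- c(zeros[1:2], hb$N1[1:2], zeros[1:2], hb$N1[3:4])
      Nw2 <- c(zeros[1:2], hb$N2[1:2], zeros[1:2], hb$N2[3:4])
      # dof order per node: (u, u_theta, w, w_theta)
      eps_s  <- Nu1 / st - kap * Nw
      eps_th <- (Nu * g$r_t + Nw * g$z_t) / (g$r * st)
      beta   <- Nw1 / st + kap * Nu
      beta_t <- Nw2 / st - Nw1 * stt / st^2 + kap_t * Nu + kap * Nu1
      chi_s  <- beta_t / st
      chi_th <- beta * g$r_t / (g$r * st)
      Bm <- rbind(eps_s, eps_th)
      Bb <- rbind(chi_s, chi_th)
      wq <- gw[q] * h * st * 2 * pi * g$r
      Ke <- Ke + wq * (t(Bm) %*% Cm %*% Bm + t(Bb) %*% Db %*% Bb)
    }
    base <- 4 * (e - 1)
    idx <- base + 1:8
    idx_all[e, ] <- idx
    Ke_list[[e]] <- Ke
  }
  ii <- rep(seq_len(8), times = 8)
  jj <- rep(seq_len(8), each = 8)
  tri_i <- integer(64 * n_elem); tri_j <- integer(64 * n_elem)
  tri_v <- numeric(64 * n_elem)
  for (e in seq_len(n_elem)) {
    off <- 64 * (e - 1)
    idx <- idx_all[e, ]
    tri_i[off + 1:64] <- idx[ii]
    tri_j[off + 1:64] <- idx[jj]
    tri_v[off + 1:64] <- as.numeric(Ke_list[[e]])
  }
  K <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_v,
                            dims = c(ndof, ndof))

  # pole conditions: u = 0 and w_theta = 0 at both poles (axisymmetry and
  # regularity); w = 0 at the bottom pole grounds the axial rigid mode.
  nlast <- 4 * n_elem
  fixed <- c(1, 4, 3, nlast + 1, nlast + 4)
  free <- setdiff(seq_len(ndof), fixed)
  Fload <- 1
  f <- numeric(ndof)
  f[nlast + 3] <- -Fload      # axial push on the top pole (d_z(top) = w)
  # Jacobi equilibration: membrane/bending and value/derivative dofs give the
  # raw matrix a ~1e15 condition number; symmetric diagonal scaling fixes it.
  Kff <- K[free, free]
  sc <- 1 / sqrt(Matrix::diag(Kff))
  Dsc <- Matrix::Diagonal(x = sc)
  Ks <- Matrix::forceSymmetric(Dsc %*% Kff %*% Dsc)
  d <- numeric(ndof)
  d[free] <- sc * as.numeric(Matrix::solve(Ks, sc * f[free]))
  compliance <- sum(f * d)    # = F * approach
  if (compliance <= 0) stop("indefinite shell system (non-physical geometry?)")
  Fload^2 / compliance
}

#' Axial compression stiffness of an eggshell
#'
#' Solves the linear plate-compression problem for an egg between two rigid
#' frictionless plates along the long axis. Axial compression of a surface
#' of revolution is axisymmetric, so the shell is modelled with
#' one-dimensional meridian elements (Kirchhoff-Love membrane + bending,
#' small strain) and the plate contacts reduce, in the linear limit, to
#' concentrated axial loads at the two poles. The reported `K` is the
#' plate-to-plate stiffness (both pole dimples in series). The mesh is
#' refined at least once and the relative change between the two finest
#' solutions is reported.
#'
#' @param specimen an [egg_specimen()].
#' @param mesh_elements meridian elements for the coarsest solve (>= 50).
#' @param tol relative-change convergence tolerance between refinements.
#' @param max_refine maximum number of mesh refinements (factor 1.5 each).
#' @return object of class `stiffness_result`: `K` (N/m), `axis`,
#'   `mesh_elements` used at the finest level, `converged`, `rel_change`.
#' @examples
#' sp <- egg_specimen(build_profile(0.04, 0.04),
#'                    shell_material(3e10, 0.3, 3e-4), mass = 0.03)
#' solve_axial_stiffness(sp, mesh_elements = 80)
#' @export
solve_axial_stiffness <- function(specimen, mesh_elements = 200, tol = 0.005,
                                  max_refine = 3) {
  stopifnot(inherits(specimen, "egg_specimen"))
  if (mesh_elements < 50) stop("mesh_elements must be >= 50")
  t <- specimen$material$thickness
  if (t / specimen$profile$A >= 0.1)
    warning("t/A >= 0.1: outside the thin-shell regime, results unreliable")
  m <- as.integer(mesh_elements)
  K_prev <- fem_axial_stiffness(specimen$profile, specimen$material, m)
  rel <- Inf; K_cur <- K_prev
  for (i in seq_len(max_refine)) {
    m <- as.integer(ceiling(m * 1.5))
    K_cur <- fem_axial_stiffness(specimen$profile, specimen$material, m)
    rel <- abs(K_cur - K_prev) / abs(K_cur)
    if (rel < tol) break
    K_prev <- K_cur
  }
  structure(list(K = K_cur, axis = "long", mesh_elements = m,
                 converged = rel < tol, rel_change = rel),
            class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result> K = %.6g N/m (%s axis), %d elements, %s (rel change %.2e)\n",
              x$K, x$axis, x$mesh_elements,
              if (x$converged) "converged" else "NOT converged", x$rel_change))
  invisible(x)
}
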
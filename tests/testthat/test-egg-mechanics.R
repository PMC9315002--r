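test_that("profiles satisfy the geometric invariants", {
  # degenerate sphere
  p <- build_profile(0.04, 0.04)
  expect_equal(profile_radius(p, 0.02), 0.02, tolerance = 1e-10)
  expect_equal(profile_radius(p, 0), 0, tolerance = 1e-12)
  expect_equal(profile_radius(p, 0.04), 0, tolerance = 1e-12)
  # prolate spheroid: max radius A/2 at midpoint
  p2 <- build_profile(0.04, 0.06)
  expect_equal(profile_radius(p2, 0.03), 0.02, tolerance = 1e-10)
  zg <- seq(0.001, 0.059, length.out = 200)
  expect_true(all(profile_radius(p2, zg) > 0))
  expect_lt(max(profile_radius(p2, zg)), 0.02 + 1e-10)
  # asymmetry breaks the z -> B - z mirror symmetry
  p3 <- build_profile(0.04, 0.06, asymmetry = 0.15)
  expect_gt(abs(profile_radius(p3, 0.015) - profile_radius(p3, 0.045)), 1e-5)
  # symmetric profile keeps it
  expect_equal(profile_radius(p2, 0.015), profile_radius(p2, 0.045),
               tolerance = 1e-10)
  expect_error(build_profile(-1, 0.06), "positive")
  expect_error(build_profile(0.04, 0.06, asymmetry = 2), "non-positive radii")
})

test_that("profile volume matches closed forms and tabulated quadrature", {
  expect_equal(profile_volume(build_profile(0.04, 0.04)), pi * 0.04^3 / 6,
               tolerance = 1e-8)
  expect_equal(profile_volume(build_profile(0.04, 0.06)),
               pi * 0.04^2 * 0.06 / 6, tolerance = 1e-8)
  # dense table of the same spheroid
  z <- seq(0, 0.06, length.out = 2000)
  r <- 0.02 * sqrt(pmax(0, 1 - ((z - 0.03) / 0.03)^2))
  vol_tab <- profile_volume(data.frame(z = z, r = r))
  expect_equal(vol_tab, pi * 0.04^2 * 0.06 / 6, tolerance = 1e-4)
  # fitting the table back to the parametric family
  pf <- as_egg_profile(data.frame(z = z, r = r))
  expect_equal(profile_volume(pf), pi * 0.04^2 * 0.06 / 6, tolerance = 1e-4)
})

test_that("solver matches the Reissner closed form for thin spheres", {
  R <- 0.02; E <- 3e10; nu <- 0.3
  for (tr in c(0.005, 0.01, 0.02)) {
    t <- tr * R
    sp <- egg_specimen(build_profile(2 * R, 2 * R),
                       shell_material(E, nu, t), mass = 0.03)
    res <- solve_axial_stiffness(sp, mesh_elements = 150)
    expect_true(res$converged)
    expect_lt(res$rel_change, 0.005)
    expect_lt(abs(res$K / reissner_sphere_K(E, t, R, nu) - 1), 0.05)
  }
})

test_that("stiffness scales linearly in E and approximately as t^2", {
  R <- 0.02; nu <- 0.3; E <- 3e10
  sp1 <- egg_specimen(build_profile(0.04, 0.06), shell_material(E, nu, 3e-4),
                      mass = 0.05)
  sp2 <- egg_specimen(build_profile(0.04, 0.06), shell_material(2 * E, nu, 3e-4),
                      mass = 0.05)
  K1 <- solve_axial_stiffness(sp1, mesh_elements = 100)$K
  K2 <- solve_axial_stiffness(sp2, mesh_elements = 100)$K
  expect_equal(K2 / K1, 2, tolerance = 1e-6)
  # thickness exponent fitted over t/R in [0.005, 0.02]
  ts <- c(0.005, 0.01, 0.02) * R
  Ks <- vapply(ts, function(t) {
    sp <- egg_specimen(build_profile(2 * R, 2 * R), shell_material(E, nu, t),
                       mass = 0.03)
    solve_axial_stiffness(sp, mesh_elements = 150)$K
  }, numeric(1))
  expo <- coef(lm(log(Ks) ~ log(ts)))[2]
  expect_gt(expo, 1.8); expect_lt(expo, 2.2)
})

test_that("elongating the egg at fixed breadth stiffens the axial response", {
  # pole curvature radius (A/2)^2/(B/2) shrinks as B grows, so the pole
  # dimple stiffens; recorded from a solver sweep at high resolution
  E <- 3e10; nu <- 0.3
  Ks <- vapply(c(1.0, 1.25, 1.5), function(BA) {
    sp <- egg_specimen(build_profile(0.04, 0.04 * BA),
                       shell_material(E, nu, 3e-4), mass = 0.05)
    solve_axial_stiffness(sp, mesh_elements = 150)$K
  }, numeric(1))
  expect_true(all(diff(Ks) > 0))
})

test_that("thick shells warn and bad meshes error", {
  sp <- egg_specimen(build_profile(0.01, 0.012), shell_material(3e10, 0.3, 2e-3),
                     mass = 0.001)
  expect_warning(solve_axial_stiffness(sp, mesh_elements = 60), "thin-shell")
  expect_error(solve_axial_stiffness(sp, mesh_elements = 10), ">= 50")
})

test_that("C number arithmetic, sphere coincidence, unit invariance", {
  expect_equal(c_number(1e4, 0.5, 0.04, 0.06)$value, (1e4 / 0.5) * 0.0016 / 0.06,
               tolerance = 1e-12)
  ch <- c_number(1.5e5, 0.6, 0.0443, 0.0570)
  expect_equal(ch$value, (1.5e5 / 0.6) * 0.0443^2 / 0.057, tolerance = 1e-12)
  expect_gt(ch$value, 4776); expect_lt(ch$value, 233377)
  expect_equal(ch$log10, log10(ch$value))
  # sphere: both axes coincide with K D / W
  s_long <- c_number(2e4, 0.4, 0.05, 0.05, "long")
  s_short <- c_number(2e4, 0.4, 0.05, 0.05, "short")
  expect_equal(s_long$value, s_short$value, tolerance = 1e-12)
  expect_equal(s_long$value, 2e4 * 0.05 / 0.4, tolerance = 1e-12)
  # unit invariance: mm / mN (1 N/m = 1 mN/mm)
  C_si <- c_number(1.5e5, 0.6, 0.0443, 0.0570)$value
  C_mm <- c_number(1.5e5, 0.6 * 1e3, 44.3, 57.0)$value
  expect_equal(C_mm / C_si, 1, tolerance = 1e-10)
  expect_error(c_number(-1, 1, 1, 1), "positive")
})

test_that("batch stiffness produces consistent SI outputs", {
  eggs <- simulate_geometry(4, seed = 99)
  out <- stiffness_batch(eggs, mesh_elements = 80)
  expect_equal(nrow(out), 4)
  expect_true(all(out$K_N_per_m > 0))
  expect_true(all(out$converged))
  expect_equal(out$log10_C, log10(out$C_long))
  # weight consistent with mass
  expect_equal(out$W_N, eggs$mass_g / 1000 * 9.81, tolerance = 1e-10)
})
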
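#' Dimensionless eggshell stiffness (C number)
#'
#' The C number removes egg size and weight effects from the absolute
#' compression stiffness `K`, allowing stiffness comparisons across species
#' with very different eggs. Along the long axis
#' `C = (K / W) * (A^2 / B)`; along the short axis
#' `C = (K / W) * (2 A B / (A + B))`. For a sphere (`A == B`) both forms
#' reduce to `K * D / W`.
#'
#' @param K absolute stiffness (N/m) along the chosen axis.
#' @param W egg weight (N).
#' @param A egg breadth (m).
#' @param B egg length (m).
#' @param axis `"long"` (default) or `"short"`.
#' @return object of class `c_number`: `value`, `log10`, `axis`.
#' @examples
#' c_number(1.5e5, 0.6, 0.0443, 0.0570)  # a chicken-sized egg, C ~ 8607
#' @export
c_number <- function(K, W, A, B, axis = c("long", "short")) {
  axis <- match.arg(axis)
  if (any(c(K, W, A, B) <= 0) || any(!is.finite(c(K, W, A, B))))
    stop("K, W, A, B must all be positive and finite")
  value <- if (axis == "long") (K / W) * A^2 / B else (K / W) * 2 * A * B / (A + B)
  structure(list(value = value, log10 = log10(value), axis = axis),
            class = "c_number")
}

#' @export
print.c_number <- function(x, ...) {
  cat(sprintf("<c_number> C = %.6g (log10 = %.4f, %s axis)\n",
              x$value, x$log10, x$axis))
  invisible(x)
}

#' Batch eggshell stiffness from a trait table
#'
#' Runs the thin-shell compression solver and C-number computation for each
#' row of a species table. Input units are millimetres and grams (the usual
#' units of oological tables); outputs are SI plus the dimensionless C.
#'
#' @param eggs data frame with columns `species`, `A_mm`, `B_mm`,
#'   `thickness_mm`, and optionally `mass_g`, `ellipticity`, `asymmetry`.
#' @param E,nu shell Young's modulus (Pa) and Poisson ratio applied to all
#'   rows (per-species values rescale C multiplicatively).
#' @param density whole-egg density (kg m^-3) for rows with missing mass.
#' @param mesh_elements passed to [solve_axial_stiffness()].
#' @return data frame with `species`, `K_N_per_m`, `W_N`, `C_long`,
#'   `C_short`, `log10_C`, `converged`.
#' @export
stiffness_batch <- function(eggs, E = 3e10, nu = 0.3, density = 1031,
                            mesh_elements = 120) {
  eggs <- as.data.frame(eggs)
  need <- c("species", "A_mm", "B_mm", "thickness_mm")
  if (!all(need %in% names(eggs)))
    stop("eggs table needs columns: ", paste(need, collapse = ", "))
  n <- nrow(eggs)
  out <- data.frame(species = eggs$species, K_N_per_m = NA_real_,
                    W_N = NA_real_, C_long = NA_real_, C_short = NA_real_,
                    log10_C = NA_real_, converged = NA)
  for (i in seq_len(n)) {
    prof <- build_profile(eggs$A_mm[i] / 1000, eggs$B_mm[i] / 1000,
                          ellipticity = if ("ellipticity" %in% names(eggs)) eggs$ellipticity[i] else 0,
                          asymmetry = if ("asymmetry" %in% names(eggs)) eggs$asymmetry[i] else 0)
    mat <- shell_material(E, nu, eggs$thickness_mm[i] / 1000)
    mass <- if ("mass_g" %in% names(eggs) && is.finite(eggs$mass_g[i]))
      eggs$mass_g[i] / 1000 else NULL
    sp <- egg_specimen(prof, mat, mass = mass, density = density)
    st <- solve_axial_stiffness(sp, mesh_elements = mesh_elements)
    cl <- c_number(st$K, sp$weight, prof$A, prof$B, "long")
    cs <- c_number(st$K, sp$weight, prof$A, prof$B, "short")
    out$K_N_per_m[i] <- st$K
    out$W_N[i] <- sp$weight
    out$C_long[i] <- cl$value
    out$C_short[i] <- cs$value
    out$log10_C[i] <- cl$log10
    out$converged[i] <- st$converged
  }
  out
}
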
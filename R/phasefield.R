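# Phase-field construction: rasterize the sharp channel indicator, smooth it
# with a semi-implicit Allen-Cahn step (double-well F(phi) = 2 phi^2
# (phi-1)^2 - 1/8, so dF/dphi = 4 phi (phi-1) (2 phi-1)), and refine the
# mesh in the diffuse layer.

#' Phase-field smoothing parameters
#'
#' @param D_phi Allen-Cahn diffusivity. Together with `T_phi` it sets the
#'   diffuse-layer half-width, approximately `sqrt(2 * D_phi * T_phi)`; the
#'   default pair gives ~0.001 cm, below the size of the adapted interface
#'   elements, so the realized layer width is set by the mesh (about one
#'   interface element). A wider layer artificially constricts channels:
#'   the near-no-slip slip condition suppresses tangential flow wherever
#'   `|grad phi|` is appreciable, so each channel loses roughly 2.5 x the
#'   half-width per side of effective cross-section.
#' @param T_phi smoothing horizon.
#' @param dt_phi Allen-Cahn time step (semi-implicit: implicit diffusion,
#'   explicit double-well).
#' @param beta regularization floor: the regularized field is
#'   `(1 - 2 beta) * phi + beta`, keeping both phi and 1 - phi >= beta.
#' @param n_adapt_cycles number of rasterize/adapt/smooth cycles.
#' @param bisect_per_cycle longest-edge bisection passes per cycle (each pass
#'   shrinks interface-element size by about sqrt(2)); either one count or a
#'   vector with one entry per cycle.
#' @param grad_frac refine elements whose |grad phi| exceeds this fraction of
#'   the global maximum.
#' @param interior_h target element size inside the channels (cm). The flow
#'   profile across a channel must be resolved by the velocity space, not
#'   just the diffuse layer; elements whose centroid is in the fluid are
#'   refined until their diameter is below ~1.5x this value.
#' @param max_elements element-count budget for adaptation.
#' @return a `phasefield_params` list.
#' @export
phasefield_params <- function(D_phi = 2.5e-5, T_phi = 2e-2, dt_phi = T_phi / 20,
                              beta = 1e-4, n_adapt_cycles = 2L,
                              bisect_per_cycle = 2L, grad_frac = 0.1,
                              interior_h = 0.01, max_elements = 80000L) {
  stopifnot(D_phi > 0, T_phi > 0, dt_phi > 0, dt_phi <= T_phi,
            beta > 0, beta < 0.5, n_adapt_cycles >= 1,
            all(bisect_per_cycle >= 0))
  structure(list(D_phi = D_phi, T_phi = T_phi, dt_phi = dt_phi, beta = beta,
                 n_adapt_cycles = as.integer(n_adapt_cycles),
                 bisect_per_cycle = as.integer(bisect_per_cycle),
                 grad_frac = grad_frac, interior_h = interior_h,
                 max_elements = max_elements),
            class = "phasefield_params")
}

#' Affine regularization of a phase field
#'
#' `phi_beta = (1 - 2 beta) * phi + beta`, so that both `phi_beta` and
#' `1 - phi_beta` stay at least `beta` and the weighted linear systems have
#' no zero rows. Exactly invertible.
#'
#' @param phi nodal phase-field values in `[0, 1]`.
#' @param beta regularization floor, `0 < beta < 1/2`.
#' @return regularized nodal values in `[beta, 1 - beta]`.
#' @export
regularize_phasefield <- function(phi, beta) {
  stopifnot(beta > 0, beta < 0.5)
  (1 - 2 * beta) * phi + beta
}

dwell_prime <- function(phi) 4 * phi * (phi - 1) * (2 * phi - 1)

#' Smooth an indicator into a phase field by an Allen-Cahn solve
#'
#' Solves `d/dt phi - D_phi lap(phi) + F'(phi) = 0` on `(0, T_phi]` with the
#' standard double-well `F`, homogeneous Neumann boundary and initial datum
#' `chi`, using P1 elements and semi-implicit backward-Euler steps (implicit
#' diffusion, explicit potential). If the solution escapes `[0, 1]` by more
#' than `1e-6`, the step is halved and the solve repeated (up to 3 times,
#' with a warning); the result is then clipped to `[0, 1]`.
#'
#' @param chi nodal initial indicator in `[0, 1]`.
#' @param mesh an `sf_mesh`.
#' @param params a [phasefield_params()] list.
#' @return nodal phase field at `T_phi`.
#' @export
allen_cahn_smooth <- function(chi, mesh, params = phasefield_params()) {
  stopifnot(all(chi >= 0), all(chi <= 1))
  p1 <- fem_space(mesh, "P1")
  # lumped mass: keeps the semi-implicit step monotone (discrete maximum
  # principle on the non-obtuse bisection meshes used here)
  ML <- as.vector(op_mass(p1) %*% rep(1, p1$ndof))
  K <- op_stiffness(p1)
  dt <- params$dt_phi
  for (attempt in 1:3) {
    n <- max(1L, round(params$T_phi / dt))
    A <- Matrix::Diagonal(x = ML / dt) + params$D_phi * K
    fac <- fem_factorize(A)
    phi <- chi
    ok <- TRUE
    for (s in seq_len(n)) {
      rhs <- ML * (phi / dt - dwell_prime(phi))
      phi <- sf_solve(fac, rhs)
      if (min(phi) < -1e-3 || max(phi) > 1 + 1e-3) { ok <- FALSE; break }
    }
    if (ok) return(pmin(1, pmax(0, phi)))
    dt <- dt / 2
    warning(sprintf(
      "allen_cahn_smooth: phase field escaped [0,1]; retrying with dt = %.3g", dt))
  }
  stop("allen_cahn_smooth: unstable even after halving the time step twice")
}

# interpolate P1 nodal values to a refined mesh (new nodes are edge midpoints)
refine_interp <- function(vals, refined_mesh) {
  lin <- attr(refined_mesh, "lineage")
  if (is.null(lin) || !nrow(lin)) return(vals)
  c(vals, (vals[lin[, 1]] + vals[lin[, 2]]) / 2)
}

elem_grad_norm <- function(mesh, phi) {
  eg <- mesh_element_geometry(mesh)
  gx <- rowSums(eg$gx * matrix(phi[mesh$tri], ncol = 3))
  gy <- rowSums(eg$gy * matrix(phi[mesh$tri], ncol = 3))
  sqrt(gx^2 + gy^2)
}

#' Build the adapted mesh and smoothed phase field for a geometry
#'
#' Executes the cycle rasterize -> refine near the interface -> re-rasterize
#' -> Allen-Cahn smooth, `n_adapt_cycles` times. Refinement marks elements
#' whose `|grad phi|` exceeds `grad_frac` of the global maximum, plus a
#' geometric safeguard (elements whose centroid is within one diameter plus
#' the expected diffuse half-width of a sharp channel boundary), so thin
#' channels cannot fall between coarse grid nodes.
#'
#' @param geom an `sf_geometry`.
#' @param params a [phasefield_params()].
#' @param h0 base mesh size in cm.
#' @return an object of class `sf_phasefield`: list with `mesh`, `phi`
#'   (nodal, in `[0,1]`), `phi_reg` (regularized), `beta`, `geom`.
#' @export
build_adapted_phasefield <- function(geom, params = phasefield_params(),
                                     h0 = 0.015) {
  mesh <- scaffold_base_mesh(geom, h0)
  delta <- sqrt(2 * params$D_phi * params$T_phi)   # diffuse half-width
  phi <- NULL
  passes <- rep_len(params$bisect_per_cycle, params$n_adapt_cycles)
  for (cycle in seq_len(params$n_adapt_cycles)) {
    for (pass in seq_len(passes[cycle])) {
      eg <- mesh_element_geometry(mesh)
      cent <- cbind(rowMeans(eg$x), rowMeans(eg$y))
      diam <- 2 * sqrt(eg$area)
      d <- geometry_boundary_dist(geom, cent[, 1], cent[, 2])
      marked <- d < 0.7 * diam + delta
      # resolve the flow profile inside the channels, not just the layer
      if (is.finite(params$interior_h)) {
        influid <- geometry_indicator(geom, cent[, 1], cent[, 2])
        marked <- marked | (influid & diam > 1.5 * params$interior_h)
      }
      if (!is.null(phi)) {
        g <- elem_grad_norm(mesh, phi)
        marked <- marked | (g > params$grad_frac * max(g))
      }
      newmesh <- mesh_refine(mesh, marked)
      if (nrow(newmesh$tri) > params$max_elements)
        stop(sprintf("mesh adaptation exceeded the %d-element budget",
                     params$max_elements))
      if (!is.null(phi)) phi <- refine_interp(phi, newmesh)
      mesh <- newmesh
    }
    chi <- rasterize_ramp(geom, mesh)
    phi <- allen_cahn_smooth(chi, mesh, params)
  }
  structure(list(mesh = mesh, phi = phi,
                 phi_reg = regularize_phasefield(phi, params$beta),
                 beta = params$beta, geom = geom, params = params),
            class = "sf_phasefield")
}

#' @export
print.sf_phasefield <- function(x, ...) {
  cat(sprintf(
    "<sf_phasefield> %s: %d nodes, %d triangles; phi in [%.3g, %.3g]\n",
    x$geom$architecture, nrow(x$mesh$nodes), nrow(x$mesh$tri),
    min(x$phi), max(x$phi)))
  cat(sprintf("  int phi dV = %.4f cm^2 (sharp fluid area %.4f cm^2)\n",
              p1_integral(x$mesh, x$phi), x$geom$areas$fluid))
  invisible(x)
}

# exact integral of a P1 nodal field
p1_integral <- function(mesh, u) {
  eg <- mesh_element_geometry(mesh)
  sum(eg$area * rowMeans(matrix(u[mesh$tri], ncol = 3)))
}
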
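# Advection-reaction-diffusion oxygen transport on the frozen steady flow
# field: P2 elements, backward Euler with implicit advection/diffusion and
# the Michaelis-Menten consumption term lagged at the previous step.

#' Oxygen-transport parameters
#'
#' Defaults: oxygen diffusivity in plasma (`D_F`) and in the islet-bearing
#' agarose gel (`D_P`), maximum consumption rate `R_max` (negative =
#' consumption), Michaelis-Menten half-saturation `c_MM`, necrosis threshold
#' `c_CR` (consumption switches off at or below it), inlet concentration
#' `c_in`, and the transport time grid.
#'
#' @param D_F diffusivity in the channels, cm^2/s.
#' @param D_P diffusivity in the gel, cm^2/s.
#' @param R_max maximum consumption rate, mol/(cm^3 s), negative.
#' @param c_MM Michaelis-Menten constant, mol/cm^3.
#' @param c_CR critical (necrosis) concentration, mol/cm^3.
#' @param c_in inlet concentration, mol/cm^3.
#' @param dt transport time step, s.
#' @param T_end transport final time, s.
#' @param supg logical; add a streamline-diffusion stabilizer (off by
#'   default; useful on very coarse meshes).
#' @return a `transport_params` list.
#' @export
transport_params <- function(D_F = 3e-5, D_P = 1.3e-5, R_max = -3.4e-8,
                             c_MM = 1e-9, c_CR = 1e-10, c_in = 2e-7,
                             dt = 5e-2, T_end = 200, supg = FALSE) {
  stopifnot(D_F > 0, D_P > 0, R_max <= 0, c_CR > 0, c_MM > c_CR,
            c_in >= 0, dt > 0, T_end >= dt)
  structure(list(D_F = D_F, D_P = D_P, R_max = R_max, c_MM = c_MM,
                 c_CR = c_CR, c_in = c_in, dt = dt, T_end = T_end,
                 supg = supg),
            class = "transport_params")
}

#' Phase-field blends of velocity and diffusivity
#'
#' `u = v phi + q (1 - phi)` and `D = D_F phi + D_P (1 - phi)`, nodewise.
#'
#' @param v nodal fluid velocity (n x 2).
#' @param q nodal Darcy velocity (n x 2).
#' @param phi nodal phase field.
#' @param params a [transport_params()].
#' @return list with `u` (n x 2) and `D` (length n).
#' @export
blended_coefficients <- function(v, q, phi, params = transport_params()) {
  list(u = v * phi + q * (1 - phi),
       D = params$D_F * phi + params$D_P * (1 - phi))
}

#' Michaelis-Menten oxygen consumption rate
#'
#' `R_max c / (c + c_MM) H`, with the necrosis switch `H = 0` for
#' `c <= c_CR` and `H = 1` above, weighted by `1 - phi_sharp` (threshold
#' 0.5) so consumption is confined to the gel. Negative concentrations are
#' evaluated as zero inside the saturating ratio.
#'
#' @param c concentration values, mol/cm^3.
#' @param phi_local phase-field values at the same points.
#' @param params a [transport_params()].
#' @return volumetric rate, mol/(cm^3 s) (non-positive).
#' @export
reaction_rate <- function(c, phi_local, params = transport_params()) {
  cpos <- pmax(c, 0)
  H <- as.numeric(c > params$c_CR)
  gel <- as.numeric(phi_local <= 0.5)
  params$R_max * cpos / (cpos + params$c_MM) * H * gel
}

#' Assemble the transport operator
#'
#' Time-invariant backward-Euler matrix `M/dt + A(u) + K(D)` on P2, with
#' the advective term in convective form, plus the maps used to build each
#' step's right-hand side (`M/dt` and the gel-masked reaction mass matrix).
#'
#' @param pf an `sf_phasefield`.
#' @param flow an `sf_flowstate` solved on the same mesh.
#' @param params a [transport_params()].
#' @param bc `"standard"` (inlet concentration + zero on the top wall,
#'   natural elsewhere) or `"none"` (pure Neumann; used e.g. for well-mixed
#'   reaction benchmarks).
#' @return an `sf_transport_operator`.
#' @export
assemble_transport_operator <- function(pf, flow, params = transport_params(),
                                        bc = c("standard", "none")) {
  bc <- match.arg(bc)
  mesh <- pf$mesh
  p2 <- fem_space(mesh, "P2")
  mini <- fem_space(mesh, "MINI")
  p1 <- fem_space(mesh, "P1")
  phi_q <- weight_at_quad(p1, pf$phi)
  # quadrature-point blends of velocity and diffusivity
  vx_q <- field_at_quad(mini, flow$v_full[, 1])
  vy_q <- field_at_quad(mini, flow$v_full[, 2])
  qx_q <- weight_at_quad(p1, flow$q[, 1])
  qy_q <- weight_at_quad(p1, flow$q[, 2])
  ux <- vx_q * phi_q + qx_q * (1 - phi_q)
  uy <- vy_q * phi_q + qy_q * (1 - phi_q)
  D_q <- params$D_F * phi_q + params$D_P * (1 - phi_q)

  M <- op_mass(p2, p2)
  K <- fem_op(p2, p2, 1, 1, D_q) + fem_op(p2, p2, 2, 2, D_q)
  ADV <- fem_op(p2, p2, 0, 1, ux) + fem_op(p2, p2, 0, 2, uy)
  A <- M / params$dt + ADV + K
  if (isTRUE(params$supg)) {
    # streamline diffusion: tau |u|^2 along streamlines, tau = h/(2|u|)
    eg <- mesh_element_geometry(mesh)
    h_e <- sqrt(2 * eg$area)
    un <- sqrt(ux^2 + uy^2)
    tau <- matrix(h_e, nrow(ux), ncol(ux)) / (2 * pmax(un, 1e-12))
    pe <- un * matrix(h_e, nrow(ux), ncol(ux)) / (2 * D_q)
    tau <- tau * pmin(1, pe / 3)
    A <- A + fem_op(p2, p2, 1, 1, tau * ux * ux) +
      fem_op(p2, p2, 1, 2, tau * ux * uy) +
      fem_op(p2, p2, 2, 1, tau * uy * ux) +
      fem_op(p2, p2, 2, 2, tau * uy * uy)
  }
  phis <- as.numeric(pf$phi > 0.5)
  Mr <- op_mass(p2, p2, 1 - weight_at_quad(p1, phis))
  # P2 dof values of the phase field (vertex + edge-midpoint average)
  em <- mesh_edges(mesh)
  phi_p2 <- c(pf$phi, (pf$phi[em$edges[, 1]] + pf$phi[em$edges[, 2]]) / 2)

  if (bc == "standard") {
    fixed_in <- space_boundary_dofs(p2, "inlet")
    fixed_0 <- setdiff(space_boundary_dofs(p2, "top_wall"), fixed_in)
    fixed <- c(fixed_in, fixed_0)
    vals <- c(rep(params$c_in, length(fixed_in)), rep(0, length(fixed_0)))
  } else {
    fixed <- integer(0); vals <- numeric(0)
  }
  solver <- fem_factorize(A, fixed, vals)
  structure(list(A = A, M = M, Mr = Mr, p2 = p2, phi_p2 = phi_p2,
                 params = params, solver = solver, fixed = fixed,
                 vals = vals, mesh = mesh, pf = pf),
            class = "sf_transport_operator")
}

#' Advance the concentration by one backward-Euler step
#'
#' @param c_n P2 coefficient vector at the previous step.
#' @param op an `sf_transport_operator`.
#' @return coefficients at the next step.
#' @export
advance_concentration <- function(c_n, op) {
  r <- reaction_rate(c_n, op$phi_p2, op$params)
  b <- as.vector(op$M %*% (c_n / op$params$dt)) + as.vector(op$Mr %*% r)
  sf_solve(op$solver, b)
}

#' Run the oxygen-transport problem on a frozen flow field
#'
#' `N_t = T_end/dt` backward-Euler steps from `c = 0`, with the flow
#' solver's final-time velocities held fixed. Reports concentration extrema
#' and a steadiness diagnostic.
#'
#' @param flow an `sf_flowstate`.
#' @param pf the `sf_phasefield` the flow was solved on.
#' @param params a [transport_params()].
#' @param track_every record (t, min c, max c) every this many steps.
#' @return an `sf_concentration`: `c` (P2 coefficients, mol/cm^3), `space`,
#'   `t`, `series` (data.frame), `steady_rel_change`.
#' @export
run_transport <- function(flow, pf, params = transport_params(),
                          track_every = 40L) {
  op <- assemble_transport_operator(pf, flow, params)
  Nt <- round(params$T_end / params$dt)
  c_n <- rep(0, op$p2$ndof)
  series <- list()
  prev <- c_n
  for (n in seq_len(Nt)) {
    c_n1 <- advance_concentration(c_n, op)
    if (n %% track_every == 0 || n == Nt)
      series[[length(series) + 1]] <- data.frame(
        t = n * params$dt, c_min = min(c_n1), c_max = max(c_n1))
    prev <- c_n
    c_n <- c_n1
  }
  rel <- sqrt(sum((c_n - prev)^2)) / max(sqrt(sum(c_n^2)), 1e-300)
  structure(list(c = c_n, space = op$p2, t = Nt * params$dt,
                 mesh = pf$mesh, pf = pf, params = params,
                 series = do.call(rbind, series), steady_rel_change = rel),
            class = "sf_concentration")
}

#' @export
print.sf_concentration <- function(x, ...) {
  cat(sprintf("<sf_concentration> t = %g s; c in [%.3g, %.3g] mol/cm^3 (inlet %.3g)\n",
              x$t, min(x$c), max(x$c), x$params$c_in))
  cat(sprintf("  steadiness: relative change over last step %.3g\n",
              x$steady_rel_change))
  invisible(x)
}
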
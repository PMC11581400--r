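# Diffuse-interface fluid-poroelastic structure interaction (Stokes-Biot)
# solver. Monolithic unknown (v, p_F, p_P, eta) with MINI velocity, P1
# pressures and displacement; backward-Euler in time with a time-invariant
# system matrix factored once per run. All physical quantities in CGS.

#' Physical parameters of the flow problem
#'
#' Defaults are the blood-plasma / agarose-hydrogel values: density and
#' viscosity of plasma, Saint Venant-Kirchhoff elasticity of the gel (Lame
#' parameters derived from Young's modulus and Poisson ratio by the
#' plane-strain conversion), Biot storage/permeability, the 2D spring term
#' that stands in for out-of-plane elastic support, and the
#' Beavers-Joseph-Saffman slip rate.
#'
#' @param rho_F fluid density g/cm^3.
#' @param mu_F dynamic viscosity dyn s/cm^2.
#' @param rho_S matrix density g/cm^3.
#' @param E Young's modulus dyn/cm^2.
#' @param nu Poisson ratio (< 0.5).
#' @param gamma_E spring coefficient dyn/cm^4 (2D only; 0 in 3D).
#' @param c0 storage coefficient cm^2/dyn.
#' @param kappa permeability cm^3 s/g.
#' @param alpha Biot-Willis coefficient.
#' @param gamma_bjs slip rate g/(cm^2 s).
#' @param v_in inlet speed cm/s, directed into the domain.
#' @return a `flow_params` list including derived `mu_E`, `lambda_E`.
#' @export
flow_params <- function(rho_F = 1, mu_F = 0.04, rho_S = 1.2, E = 2.5e5,
                        nu = 0.49, gamma_E = 1e6, c0 = 1e-7, kappa = 1e-5,
                        alpha = 1, gamma_bjs = 1e3, v_in = 3.5) {
  stopifnot(rho_F > 0, mu_F > 0, rho_S > 0, E > 0, nu > 0, nu < 0.5,
            gamma_E >= 0, c0 > 0, kappa > 0, gamma_bjs >= 0)
  mu_E <- E / (2 * (1 + nu))
  lambda_E <- E * nu / ((1 + nu) * (1 - 2 * nu))
  structure(list(rho_F = rho_F, mu_F = mu_F, rho_S = rho_S, E = E, nu = nu,
                 mu_E = mu_E, lambda_E = lambda_E, gamma_E = gamma_E,
                 c0 = c0, kappa = kappa, alpha = alpha,
                 gamma_bjs = gamma_bjs, v_in = v_in),
            class = "flow_params")
}

#' Time grid
#' @param dt time step (s).
#' @param T_end final time (s).
#' @return list with `dt`, `T_end`, `N`.
#' @export
time_grid <- function(dt = 1e-3, T_end = 1) {
  N <- round(T_end / dt)
  stopifnot(N >= 1, abs(N * dt - T_end) < 1e-9 * max(1, T_end))
  list(dt = dt, T_end = T_end, N = N)
}

#' Tangential projection with respect to a (gradient) direction
#'
#' Returns `w - (w . g) g / |g|^2`, the component of `w` orthogonal to `g`
#' (the approximate tangential component at a diffuse interface, where `g`
#' is the phase-field gradient). Rows with `|g|` below `tol` are returned
#' unchanged.
#'
#' @param w n x 2 matrix (or length-2 vector) of vectors.
#' @param g n x 2 matrix (or length-2 vector) of direction vectors.
#' @param tol threshold on `|g|` below which no projection is applied.
#' @return matrix of projected vectors.
#' @export
tangential_project <- function(w, g, tol = 1e-12) {
  w <- matrix(w, ncol = 2); g <- matrix(g, ncol = 2)
  if (nrow(g) == 1 && nrow(w) > 1) g <- g[rep(1, nrow(w)), , drop = FALSE]
  g2 <- rowSums(g^2)
  f <- ifelse(g2 > tol^2, rowSums(w * g) / pmax(g2, tol^2), 0)
  w - f * g
}

# per-element grad(phi) of a P1 field, plus the BJS tangential weights
# |g| * (I - g g^T / |g|^2); elements with |g| below frac * max dropped
interface_weights <- function(mesh, phi, frac = 1e-6) {
  eg <- mesh_element_geometry(mesh)
  gx <- rowSums(eg$gx * matrix(phi[mesh$tri], ncol = 3))
  gy <- rowSums(eg$gy * matrix(phi[mesh$tri], ncol = 3))
  gn <- sqrt(gx^2 + gy^2)
  off <- gn < frac * max(gn)
  gx[off] <- 0; gy[off] <- 0
  gn2 <- ifelse(off, 1, gn^2)  # avoid 0/0; numerators already zeroed
  list(gx = gx, gy = gy, gn = gn,
       wxx = ifelse(off, 0, gn - gx^2 / gn),
       wxy = ifelse(off, 0, -gx * gy / gn),
       wyy = ifelse(off, 0, gn - gy^2 / gn))
}

#' Assemble the diffuse-interface Stokes-Biot operator
#'
#' Builds the time-invariant monolithic sparse matrix over
#' `(v, p_F, p_P, eta)` for one backward-Euler step: phase-field-weighted
#' fluid inertia/viscosity/incompressibility, `(1-phi)`-weighted structure
#' inertia (second difference), storage, Darcy stiffness, spring,
#' elasticity and Biot coupling (the storage-side coupling enters as the
#' discrete time derivative `alpha/dt div(eta^{n+1} - eta^n)`), the
#' `|grad phi|`-weighted Beavers-Joseph-Saffman slip on tangentially
#' projected differences, and the `grad phi`-weighted pressure/mass
#' interface exchange. Also builds the right-hand-side maps from the
#' previous state.
#'
#' @param pf an `sf_phasefield` (regularized field `phi_reg` is used).
#' @param params a [flow_params()].
#' @param dt time step (s).
#' @return an `sf_fpsi_operator`: system matrix `S`, state maps `R1`, `R2`
#'   (for `x^n` and the older displacement), dof `offsets`, spaces, and the
#'   Dirichlet set.
#' @export
assemble_fpsi_operator <- function(pf, params, dt) {
  mesh <- pf$mesh
  phi <- pf$phi_reg
  one_m <- 1 - phi
  mini <- fem_space(mesh, "MINI")
  p1 <- fem_space(mesh, "P1")
  nm <- mini$ndof; nv <- p1$ndof
  off <- list(vx = 0L, vy = nm, pF = 2L * nm, pP = 2L * nm + nv,
              ex = 2L * nm + 2L * nv, ey = 2L * nm + 3L * nv)
  N <- 2L * nm + 4L * nv

  iw <- interface_weights(mesh, phi)
  g <- params

  ii <- list(); jj <- list(); xx <- list()
  r1i <- list(); r1j <- list(); r1x <- list()
  add <- function(io, jo, M, dest = "S") {
    tp <- Matrix::mat2triplet(methods::as(M, "TsparseMatrix"))
    if (dest == "S") {
      ii[[length(ii) + 1]] <<- tp$i + io; jj[[length(jj) + 1]] <<- tp$j + jo
      xx[[length(xx) + 1]] <<- tp$x
    } else {
      r1i[[length(r1i) + 1]] <<- tp$i + io; r1j[[length(r1j) + 1]] <<- tp$j + jo
      r1x[[length(r1x) + 1]] <<- tp$x
    }
  }

  # fluid: inertia, viscosity, incompressibility ----------------------------
  Am <- op_mass(mini, mini, phi)
  add(off$vx, off$vx, (g$rho_F / dt) * Am); add(off$vy, off$vy, (g$rho_F / dt) * Am)
  add(off$vx, off$vx, (g$rho_F / dt) * Am, "R1"); add(off$vy, off$vy, (g$rho_F / dt) * Am, "R1")
  V11 <- fem_op(mini, mini, 1, 1, phi); V22 <- fem_op(mini, mini, 2, 2, phi)
  V21 <- fem_op(mini, mini, 2, 1, phi)
  add(off$vx, off$vx, g$mu_F * (2 * V11 + V22))
  add(off$vy, off$vy, g$mu_F * (2 * V22 + V11))
  add(off$vx, off$vy, g$mu_F * V21); add(off$vy, off$vx, g$mu_F * Matrix::t(V21))
  BFx <- fem_op(mini, p1, 1, 0, phi); BFy <- fem_op(mini, p1, 2, 0, phi)
  add(off$vx, off$pF, -BFx); add(off$vy, off$pF, -BFy)
  add(off$pF, off$vx, Matrix::t(BFx)); add(off$pF, off$vy, Matrix::t(BFy))

  # poroelastic: storage, Darcy, spring, elasticity, Biot -------------------
  Mp <- op_mass(p1, p1, one_m)
  add(off$pP, off$pP, (g$c0 / dt) * Mp)
  add(off$pP, off$pP, (g$c0 / dt) * Mp, "R1")
  add(off$pP, off$pP, g$kappa * op_stiffness(p1, p1, one_m))
  add(off$ex, off$ex, (g$rho_S / dt^2 ) * Mp + g$gamma_E * Mp)
  add(off$ey, off$ey, (g$rho_S / dt^2 ) * Mp + g$gamma_E * Mp)
  add(off$ex, off$ex, (2 * g$rho_S / dt^2) * Mp, "R1")
  add(off$ey, off$ey, (2 * g$rho_S / dt^2) * Mp, "R1")
  E11 <- fem_op(p1, p1, 1, 1, one_m); E22 <- fem_op(p1, p1, 2, 2, one_m)
  E21 <- fem_op(p1, p1, 2, 1, one_m)
  add(off$ex, off$ex, g$mu_E * (2 * E11 + E22) + g$lambda_E * E11)
  add(off$ey, off$ey, g$mu_E * (2 * E22 + E11) + g$lambda_E * E22)
  add(off$ex, off$ey, g$mu_E * E21 + g$lambda_E * Matrix::t(E21))
  add(off$ey, off$ex, g$mu_E * Matrix::t(E21) + g$lambda_E * E21)
  BPx <- fem_op(p1, p1, 1, 0, one_m); BPy <- fem_op(p1, p1, 2, 0, one_m)
  add(off$ex, off$pP, -g$alpha * BPx); add(off$ey, off$pP, -g$alpha * BPy)
  # storage-side Biot coupling: alpha/dt * div(eta^{n+1} - eta^n)
  add(off$pP, off$ex, (g$alpha / dt) * Matrix::t(BPx))
  add(off$pP, off$ey, (g$alpha / dt) * Matrix::t(BPy))
  add(off$pP, off$ex, (g$alpha / dt) * Matrix::t(BPx), "R1")
  add(off$pP, off$ey, (g$alpha / dt) * Matrix::t(BPy), "R1")

  # interface: BJS slip on tangential projections ---------------------------
  if (g$gamma_bjs > 0 && max(iw$gn) > 0) {
    Txx_mm <- fem_op(mini, mini, 0, 0, iw$wxx)
    Txy_mm <- fem_op(mini, mini, 0, 0, iw$wxy)
    Tyy_mm <- fem_op(mini, mini, 0, 0, iw$wyy)
    Txx_mp <- fem_op(mini, p1, 0, 0, iw$wxx)
    Txy_mp <- fem_op(mini, p1, 0, 0, iw$wxy)
    Tyy_mp <- fem_op(mini, p1, 0, 0, iw$wyy)
    Txx_pp <- fem_op(p1, p1, 0, 0, iw$wxx)
    Txy_pp <- fem_op(p1, p1, 0, 0, iw$wxy)
    Tyy_pp <- fem_op(p1, p1, 0, 0, iw$wyy)
    gb <- g$gamma_bjs
    add(off$vx, off$vx, gb * Txx_mm); add(off$vy, off$vy, gb * Tyy_mm)
    add(off$vx, off$vy, gb * Txy_mm); add(off$vy, off$vx, gb * Matrix::t(Txy_mm))
    add(off$vx, off$ex, -(gb / dt) * Txx_mp); add(off$vx, off$ey, -(gb / dt) * Txy_mp)
    add(off$vy, off$ex, -(gb / dt) * Txy_mp); add(off$vy, off$ey, -(gb / dt) * Tyy_mp)
    add(off$ex, off$vx, -gb * Matrix::t(Txx_mp)); add(off$ex, off$vy, -gb * Matrix::t(Txy_mp))
    add(off$ey, off$vx, -gb * Matrix::t(Txy_mp)); add(off$ey, off$vy, -gb * Matrix::t(Tyy_mp))
    add(off$ex, off$ex, (gb / dt) * Txx_pp); add(off$ex, off$ey, (gb / dt) * Txy_pp)
    add(off$ey, off$ex, (gb / dt) * Matrix::t(Txy_pp)); add(off$ey, off$ey, (gb / dt) * Tyy_pp)
    # right-hand side: -(gb/dt) T eta^n in the fluid rows, +(gb/dt) in structure rows
    add(off$vx, off$ex, -(gb / dt) * Txx_mp, "R1"); add(off$vx, off$ey, -(gb / dt) * Txy_mp, "R1")
    add(off$vy, off$ex, -(gb / dt) * Txy_mp, "R1"); add(off$vy, off$ey, -(gb / dt) * Tyy_mp, "R1")
    add(off$ex, off$ex, (gb / dt) * Txx_pp, "R1"); add(off$ex, off$ey, (gb / dt) * Txy_pp, "R1")
    add(off$ey, off$ex, (gb / dt) * Matrix::t(Txy_pp), "R1"); add(off$ey, off$ey, (gb / dt) * Tyy_pp, "R1")
  }

  # interface: pressure / mass exchange (grad-phi weighted) -----------------
  Gx_m <- fem_op(mini, p1, 0, 0, iw$gx); Gy_m <- fem_op(mini, p1, 0, 0, iw$gy)
  Gx_p <- fem_op(p1, p1, 0, 0, iw$gx);  Gy_p <- fem_op(p1, p1, 0, 0, iw$gy)
  add(off$vx, off$pP, -Gx_m); add(off$vy, off$pP, -Gy_m)
  add(off$ex, off$pP, Gx_p);  add(off$ey, off$pP, Gy_p)
  add(off$pP, off$vx, Matrix::t(Gx_m)); add(off$pP, off$vy, Matrix::t(Gy_m))
  add(off$pP, off$ex, -(1 / dt) * Gx_p); add(off$pP, off$ey, -(1 / dt) * Gy_p)
  add(off$pP, off$ex, -(1 / dt) * Gx_p, "R1"); add(off$pP, off$ey, -(1 / dt) * Gy_p, "R1")

  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  R1 <- Matrix::sparseMatrix(i = unlist(r1i), j = unlist(r1j), x = unlist(r1x),
                             dims = c(N, N))
  # R2: the older displacement in the second difference
  MpT <- methods::as(Mp, "TsparseMatrix"); tp <- Matrix::mat2triplet(MpT)
  R2 <- Matrix::sparseMatrix(
    i = c(tp$i + off$ex, tp$i + off$ey), j = c(tp$j + off$ex, tp$j + off$ey),
    x = rep(-(g$rho_S / dt^2) * tp$x, 2), dims = c(N, N))

  # Dirichlet set: v on inlet (0, -v_in), v = 0 on exterior walls,
  # eta = 0 on the whole exterior boundary; outlet bottoms natural for v
  vdofs_in <- space_boundary_dofs(mini, "inlet")
  vdofs_wall <- setdiff(space_boundary_dofs(mini, c("wall", "top_wall")), vdofs_in)
  edofs <- space_boundary_dofs(p1, c("inlet", "outlet", "wall", "top_wall"))
  fixed <- c(off$vx + vdofs_in, off$vy + vdofs_in,
             off$vx + vdofs_wall, off$vy + vdofs_wall,
             off$ex + edofs, off$ey + edofs)
  vals <- c(rep(0, length(vdofs_in)), rep(-g$v_in, length(vdofs_in)),
            rep(0, 2 * length(vdofs_wall)), rep(0, 2 * length(edofs)))

  structure(list(S = S, R1 = R1, R2 = R2, offsets = off, N = N,
                 nm = nm, nv = nv, dt = dt, params = g, pf = pf,
                 fixed = fixed, fixed_vals = vals, solver = NULL),
            class = "sf_fpsi_operator")
}

fpsi_state0 <- function(op) {
  list(x = rep(0, op$N), eta_prev = rep(0, op$N), t = 0)
}

#' Advance the coupled flow problem by one backward-Euler step
#'
#' @param state list with full state vector `x`, `eta_prev` (state vector
#'   holding the displacement one step further back), and time `t`.
#' @param op an `sf_fpsi_operator` (factored on first use).
#' @return updated state.
#' @export
advance_flow <- function(state, op) {
  if (is.null(op$solver))
    stop("operator not factored; use solve_flow_to_steady() or fpsi_factor()")
  b <- as.vector(op$R1 %*% state$x) + as.vector(op$R2 %*% state$eta_prev)
  xn <- fpsi_solve(op$solver, b)
  list(x = xn, eta_prev = state$x, t = state$t + op$dt)
}

#' Factor the coupled-flow operator
#'
#' The monolithic matrix is exactly symmetrizable: substituting the scaled
#' displacement `w = eta / dt` and negating the two pressure equations
#' turns it into a symmetric quasi-definite saddle matrix (positive
#' velocity/displacement blocks, negative Darcy-pressure block, and a zero
#' fluid-pressure block that a tiny negative penalty makes strictly
#' negative). Quasi-definite matrices admit a stable no-pivot LDL'
#' factorization under any fill-reducing ordering, which is dramatically
#' sparser than a pivoted LU of the unsymmetric form; the penalty is then
#' removed by two steps of iterative refinement per solve.
#'
#' @param op an `sf_fpsi_operator` from [assemble_fpsi_operator()].
#' @return the operator with `$solver` attached.
#' @export
fpsi_factor <- function(op) {
  S <- op$S; off <- op$offsets; nv <- op$nv; nm <- op$nm; dt <- op$dt
  n <- op$N
  rowsign <- rep(1, n)
  rowsign[off$pF + seq_len(nv)] <- -1
  rowsign[off$pP + seq_len(nv)] <- -1
  cscl <- rep(1, n)
  cscl[c(off$ex + seq_len(nv), off$ey + seq_len(nv))] <- dt
  Ssym <- Matrix::Diagonal(x = rowsign) %*% S %*% Matrix::Diagonal(x = cscl)
  free <- setdiff(seq_len(n), op$fixed)
  Aff <- Ssym[free, free, drop = FALSE]
  asym <- max(abs(Aff - Matrix::t(Aff))) / max(abs(Aff))
  if (asym > 1e-10)
    stop(sprintf("symmetrized flow matrix asymmetry %.2e; assembly bug", asym))
  Aff <- Matrix::forceSymmetric((Aff + Matrix::t(Aff)) / 2)
  # symmetric equilibration: the blocks span ~11 orders of magnitude
  sc <- 1 / sqrt(sqrt(pmax(Matrix::rowSums(Aff^2), 1e-300)))
  Aff <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = sc) %*% Aff %*% Matrix::Diagonal(x = sc))
  dg <- Matrix::diag(Aff)
  pen <- Matrix::Diagonal(x = ifelse(abs(dg) < 1e-8, -1e-8, 0))
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Aff + pen),
                          LDL = TRUE, perm = TRUE, super = FALSE)
  Afd <- Ssym[free, op$fixed, drop = FALSE]
  vals_sym <- op$fixed_vals / cscl[op$fixed]
  op$solver <- structure(list(
    n = n, free = free, fixed = op$fixed, vals = op$fixed_vals,
    vals_sym = vals_sym, fac = fac, Aff = Aff, Afd = Afd, sc = sc,
    rowsign = rowsign, cscl = cscl), class = "sf_fpsi_solver")
  op
}

# solve S x = b for the full state vector (Dirichlet dofs at their values)
fpsi_solve <- function(solver, b) {
  bs <- (solver$rowsign * b)[solver$free]
  if (length(solver$fixed))
    bs <- bs - as.vector(solver$Afd %*% solver$vals_sym)
  bs <- solver$sc * bs             # scaled system: (D A D) y = D b, x = D y
  y <- as.vector(Matrix::solve(solver$fac, bs))
  # one refinement step removes the quasi-definite penalty (relative size
  # 1e-8) to far below discretization error
  r <- bs - as.vector(solver$Aff %*% y)
  y <- y + as.vector(Matrix::solve(solver$fac, r))
  out <- numeric(solver$n)
  out[solver$fixed] <- solver$vals_sym
  out[solver$free] <- solver$sc * y
  out * solver$cscl
}

#' Solve the coupled flow problem to its steady state
#'
#' Runs `N = T_end/dt` backward-Euler steps from rest (`v = 0`, `eta =
#' eta_prev = 0`, `p_P = 0`). The system matrix is factored once. The
#' relative state change over the last step is reported as a steadiness
#' diagnostic (a warning, not an error, if above `1e-4`).
#'
#' @param pf an `sf_phasefield`.
#' @param params a [flow_params()].
#' @param grid a [time_grid()].
#' @param verbose print progress every 100 steps.
#' @return an `sf_flowstate`: fields `v` (nodal 2-col matrix, cm/s),
#'   `v_full` (MINI coefficients), `p_F`, `p_P` (nodal, dyn/cm^2), `eta`
#'   (nodal 2-col, cm), `q` (postprocessed Darcy velocity, cm/s), `u`
#'   (combined velocity `v phi + q (1 - phi)`), `steady_rel_change`.
#' @export
solve_flow_to_steady <- function(pf, params = flow_params(),
                                 grid = time_grid(), verbose = FALSE) {
  op <- assemble_fpsi_operator(pf, params, grid$dt)
  op <- fpsi_factor(op)
  st <- fpsi_state0(op)
  prev <- st$x
  for (n in seq_len(grid$N)) {
    st <- advance_flow(st, op)
    if (verbose && n %% 100 == 0)
      cat(sprintf("  flow step %d/%d, max|x| = %.4g\n", n, grid$N, max(abs(st$x))))
    if (n == grid$N - 1) prev <- st$x
  }
  denom <- sqrt(sum(st$x^2))
  rel <- if (denom > 0) sqrt(sum((st$x - prev)^2)) / denom else 0
  if (grid$N > 1 && rel > 1e-4)
    warning(sprintf("flow not steady at T = %g s: relative change %.3g", grid$T_end, rel))
  fpsi_extract(op, st, rel)
}

fpsi_extract <- function(op, st, rel = NA_real_) {
  off <- op$offsets; nv <- op$nv; nm <- op$nm
  mesh <- op$pf$mesh
  nnode <- nrow(mesh$nodes)
  v_full <- cbind(st$x[off$vx + seq_len(nm)], st$x[off$vy + seq_len(nm)])
  p_F <- st$x[off$pF + seq_len(nv)]
  p_P <- st$x[off$pP + seq_len(nv)]
  eta <- cbind(st$x[off$ex + seq_len(nv)], st$x[off$ey + seq_len(nv)])
  pv <- postprocess_velocities(
    list(v_full = v_full, p_P = p_P), op$pf, op$params$kappa)
  structure(list(mesh = mesh, pf = op$pf, params = op$params, dt = op$dt,
                 v = v_full[seq_len(nnode), , drop = FALSE], v_full = v_full,
                 p_F = p_F, p_P = p_P, eta = eta, q = pv$q, u = pv$u,
                 steady_rel_change = rel, x = st$x, eta_prev = st$eta_prev),
            class = "sf_flowstate")
}

#' @export
print.sf_flowstate <- function(x, ...) {
  cat(sprintf("<sf_flowstate> %d nodes; max|v| %.3f cm/s, max|q| %.4f cm/s, p range [%.0f, %.0f] dyn/cm^2\n",
              nrow(x$mesh$nodes), max(sqrt(rowSums(x$v^2))),
              max(sqrt(rowSums(x$q^2))), min(x$p_P), max(x$p_F)))
  if (!is.na(x$steady_rel_change))
    cat(sprintf("  steadiness: relative change over last step %.3g\n",
                x$steady_rel_change))
  invisible(x)
}

#' Postprocess Darcy and combined velocities
#'
#' `q = -kappa grad(p_P)` projected to nodes, and the total fluid velocity
#' `u = v phi + q (1 - phi)` (unregularized phase field), evaluated
#' nodewise.
#'
#' @param state list with `v_full` (MINI coefficients) and `p_P`.
#' @param pf an `sf_phasefield`.
#' @param kappa permeability.
#' @return list with nodal `q` and `u` (n x 2 matrices).
#' @export
postprocess_velocities <- function(state, pf, kappa) {
  mesh <- pf$mesh
  nnode <- nrow(mesh$nodes)
  q <- -kappa * grad_project_p1(mesh, state$p_P)
  vn <- state$v_full[seq_len(nnode), , drop = FALSE]
  u <- vn * pf$phi + q * (1 - pf$phi)
  list(q = q, u = u)
}

#' Discrete energy of the coupled state (diagnostic)
#'
#' Kinetic + elastic + storage + spring energy; used to check dissipation
#' with homogeneous data.
#'
#' @param op an `sf_fpsi_operator`.
#' @param st a state as used by [advance_flow()].
#' @return scalar energy (erg/cm, per unit out-of-plane thickness).
#' @export
flow_energy <- function(op, st) {
  mesh <- op$pf$mesh
  phi <- op$pf$phi_reg; one_m <- 1 - phi
  mini <- fem_space(mesh, "MINI"); p1 <- fem_space(mesh, "P1")
  off <- op$offsets; nm <- op$nm; nv <- op$nv
  g <- op$params
  vx <- st$x[off$vx + seq_len(nm)]; vy <- st$x[off$vy + seq_len(nm)]
  ex <- st$x[off$ex + seq_len(nv)]; ey <- st$x[off$ey + seq_len(nv)]
  exp_ <- st$eta_prev[off$ex + seq_len(nv)]; eyp <- st$eta_prev[off$ey + seq_len(nv)]
  pP <- st$x[off$pP + seq_len(nv)]
  Am <- op_mass(mini, mini, phi); Mp <- op_mass(p1, p1, one_m)
  dex <- (ex - exp_) / op$dt; dey <- (ey - eyp) / op$dt
  E11 <- fem_op(p1, p1, 1, 1, one_m); E22 <- fem_op(p1, p1, 2, 2, one_m)
  E21 <- fem_op(p1, p1, 2, 1, one_m)
  elast <- g$mu_E * (2 * sum(ex * (E11 %*% ex)) + 2 * sum(ey * (E22 %*% ey)) +
                       sum(ex * (E22 %*% ex)) + sum(ey * (E11 %*% ey)) +
                       2 * sum(ex * (E21 %*% ey))) +
    g$lambda_E * (sum(ex * (E11 %*% ex)) + sum(ey * (E22 %*% ey)) +
                    2 * sum(ex * (Matrix::t(E21) %*% ey)))
  0.5 * g$rho_F * (sum(vx * (Am %*% vx)) + sum(vy * (Am %*% vy))) +
    0.5 * g$rho_S * (sum(dex * (Mp %*% dex)) + sum(dey * (Mp %*% dey))) +
    0.5 * g$c0 * sum(pP * (Mp %*% pP)) +
    0.5 * g$gamma_E * (sum(ex * (Mp %*% ex)) + sum(ey * (Mp %*% ey))) +
    0.5 * elast
}
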
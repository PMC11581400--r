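test_that("tangential projection is orthogonal, idempotent and guarded", {
  expect_equal(drop(tangential_project(c(1, 1), c(0, 2))), c(1, 0))
  expect_equal(drop(tangential_project(c(3, 0), c(0, 1))), c(3, 0))
  w <- tangential_project(c(1, 2), c(1, 1))
  expect_equal(drop(w), c(-0.5, 0.5))
  expect_equal(sum(w * c(1, 1)), 0)                       # orthogonality
  expect_equal(tangential_project(w, c(1, 1)), w)          # idempotent
  # vanishing gradient: returned unchanged
  expect_equal(drop(tangential_project(c(1, 2), c(0, 0))), c(1, 2))
})

make_const_pf <- function(mesh, value, beta = 1e-4) {
  structure(list(mesh = mesh, phi = rep(value, nrow(mesh$nodes)),
                 phi_reg = regularize_phasefield(rep(value, nrow(mesh$nodes)),
                                                 beta),
                 beta = beta, geom = NULL), class = "sf_phasefield")
}

test_that("interface terms vanish for a constant phase field", {
  m <- unit_mesh(0.25)
  m$tagger <- function(mid) ifelse(abs(mid[, 2] - 1) < 1e-9, "inlet", "wall")
  m$boundary <- scaffoldflow:::mesh_boundary(m)
  pf <- make_const_pf(m, 0.5)
  op <- assemble_fpsi_operator(pf, flow_params(), 1e-3)
  off <- op$offsets; nm <- op$nm; nv <- op$nv
  # velocity rows must not couple to the Darcy pressure (no |grad phi|)
  blk <- op$S[off$vx + seq_len(nm), off$pP + seq_len(nv), drop = FALSE]
  expect_equal(max(abs(blk)), 0)
  blk2 <- op$S[off$pP + seq_len(nv), off$vy + seq_len(nm), drop = FALSE]
  expect_equal(max(abs(blk2)), 0)
})

test_that("operator blocks have the expected algebraic structure", {
  pf <- small_phasefield("straight")
  g <- flow_params()
  dt <- 1e-3
  op <- assemble_fpsi_operator(pf, g, dt)
  off <- op$offsets; nm <- op$nm; nv <- op$nv
  eidx <- off$ex + seq_len(2 * nv)
  # structure-structure block is symmetric
  Se <- op$S[eidx, eidx]
  expect_lt(max(abs(Se - Matrix::t(Se))), 1e-8 * max(abs(Se)))
  # Biot coupling blocks are negative transposes up to the 1/dt of the
  # time-differenced storage coupling
  B_e_p <- op$S[off$ex + seq_len(nv), off$pP + seq_len(nv)]
  B_p_e <- op$S[off$pP + seq_len(nv), off$ex + seq_len(nv)]
  expect_lt(max(abs(B_p_e + Matrix::t(B_e_p) / dt)),
            1e-10 * max(abs(B_p_e)))
  # doubling mu_F scales exactly the viscous block and nothing else
  op2 <- assemble_fpsi_operator(pf, flow_params(mu_F = 2 * g$mu_F), dt)
  D <- op2$S - op$S
  vidx <- seq_len(2 * nm)
  expect_equal(max(abs(D[-vidx, ])), 0)            # only velocity rows
  expect_equal(max(abs(D[, -vidx])), 0)            # only velocity columns
  mini <- fem_space(pf$mesh, "MINI")
  V11 <- scaffoldflow:::fem_op(mini, mini, 1, 1, pf$phi_reg)
  V22 <- scaffoldflow:::fem_op(mini, mini, 2, 2, pf$phi_reg)
  expect_lt(max(abs(D[off$vx + seq_len(nm), off$vx + seq_len(nm)] -
                      g$mu_F * (2 * V11 + V22))), 1e-12)
})

test_that("zero data gives the zero solution at every step", {
  pf <- small_phasefield("straight")
  op <- fpsi_factor(assemble_fpsi_operator(pf, flow_params(v_in = 0), 1e-3))
  st <- scaffoldflow:::fpsi_state0(op)
  for (k in 1:3) {
    st <- advance_flow(st, op)
    expect_equal(max(abs(st$x)), 0)
  }
})

test_that("discrete energy is non-increasing with homogeneous data", {
  pf <- small_phasefield("straight")
  op <- fpsi_factor(assemble_fpsi_operator(pf, flow_params(v_in = 0), 1e-3))
  st <- scaffoldflow:::fpsi_state0(op)
  # nonzero initial displacement: smooth interior bump (zero on the boundary)
  nd <- pf$mesh$nodes; nv <- op$nv; off <- op$offsets
  bump <- 1e-3 * sin(pi * nd[, 1] / 0.9) *
    sin(pi * pmin(pmax(nd[, 2], 0), 0.42) / 0.42)
  bd <- unique(as.vector(pf$mesh$boundary$edges))
  bump[bd] <- 0
  st$x[off$ex + seq_len(nv)] <- bump
  st$eta_prev[off$ex + seq_len(nv)] <- bump      # starts at rest
  E <- flow_energy(op, st)
  for (k in 1:5) {
    st <- advance_flow(st, op)
    En <- flow_energy(op, st)
    expect_lte(En, E * (1 + 1e-10))
    E <- En
  }
})

test_that("the all-fluid limit reproduces plane Poiseuille flow within 3%", {
  # straight 0.06 cm channel, uniform inflow at the top, outflow below
  tol <- 1e-9
  tagger <- function(mid) {
    tag <- rep("wall", nrow(mid))
    tag[abs(mid[, 2] - 0.3) < tol] <- "inlet"
    tag[abs(mid[, 2]) < tol] <- "outlet"
    tag
  }
  m <- mesh_rect_union(list(c(0, 0.06, 0, 0.3)), 0.004, tagger = tagger)
  pf <- make_const_pf(m, 1)
  g <- flow_params(v_in = 3.5)
  fs <- solve_flow_to_steady(pf, g, time_grid(2e-3, 0.3))
  # developed centerline speed = 1.5 x mean
  pr <- line_profile(m, fs$v[, 2], c(0.03, 0.02), c(0.03, 0.1), 20)
  expect_equal(mean(-pr$value), 1.5 * 3.5, tolerance = 0.03)
  # parabolic profile across the channel
  prx <- line_profile(m, fs$v[, 2], c(0.002, 0.05), c(0.058, 0.05), 15)
  xx <- prx$x
  para <- -6 * 3.5 * xx * (0.06 - xx) / 0.06^2
  expect_equal(prx$value, para, tolerance = 0.05)
})

test_that("global mass balance closes at steady state", {
  pf <- small_phasefield("straight")
  fs <- solve_flow_to_steady(pf, flow_params(), time_grid(2e-3, 0.5))
  bd <- pf$mesh$boundary
  edge_flux <- function(tags) {
    sel <- bd$tag %in% tags
    e <- bd$edges[sel, , drop = FALSE]
    len <- sqrt(rowSums((pf$mesh$nodes[e[, 1], , drop = FALSE] -
                           pf$mesh$nodes[e[, 2], , drop = FALSE])^2))
    vy <- fs$v[, 2]
    sum(len * (vy[e[, 1]] + vy[e[, 2]]) / 2)
  }
  # discrete inflow includes the corner ramps where the P1 inlet profile
  # decays to zero over the first top-wall element, so integrate over the
  # whole top boundary (the wall itself carries v = 0)
  Q_in <- -edge_flux(c("inlet", "top_wall"))
  Q_out <- -edge_flux("outlet")
  expect_equal(Q_out, Q_in, tolerance = 0.01)
  expect_equal(Q_in, 2 * 0.06 * 3.5, tolerance = 0.3)
})

test_that("backward Euler converges at first order in time", {
  pf <- small_phasefield("straight")
  solve_T <- function(dt) {
    op <- fpsi_factor(assemble_fpsi_operator(pf, flow_params(), dt))
    st <- scaffoldflow:::fpsi_state0(op)
    for (k in seq_len(round(0.02 / dt))) st <- advance_flow(st, op)
    st$x
  }
  x1 <- solve_T(4e-3); x2 <- solve_T(2e-3); x3 <- solve_T(1e-3)
  d1 <- sqrt(sum((x1 - x2)^2)); d2 <- sqrt(sum((x2 - x3)^2))
  expect_equal(d1 / d2, 2, tolerance = 0.5)
})

test_that("Darcy postprocessing and combined velocity are consistent", {
  pf <- small_phasefield("straight")
  nv <- nrow(pf$mesh$nodes)
  nm <- nv + nrow(pf$mesh$tri)
  # linear Darcy pressure with slope s gives uniform q = -kappa s
  s <- 2500
  state <- list(v_full = matrix(0, nm, 2), p_P = s * pf$mesh$nodes[, 1])
  pv <- postprocess_velocities(state, pf, kappa = 1e-5)
  expect_equal(pv$q[, 1], rep(-1e-5 * s, nv), tolerance = 1e-8)
  expect_equal(max(abs(pv$q[, 2])), 0, tolerance = 1e-10)
  # phi = 1 limit: u = v; phi = 0.5: u = (v + q)/2
  vf <- matrix(rnorm(2 * nm), nm, 2)
  st2 <- list(v_full = vf, p_P = s * pf$mesh$nodes[, 1])
  pf1 <- pf; pf1$phi <- rep(1, nv)
  expect_equal(postprocess_velocities(st2, pf1, 1e-5)$u,
               vf[seq_len(nv), ])
  pf5 <- pf; pf5$phi <- rep(0.5, nv)
  pv5 <- postprocess_velocities(st2, pf5, 1e-5)
  expect_equal(pv5$u, (vf[seq_len(nv), ] + pv5$q) / 2)
})
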
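test_that("phase-field blends interpolate velocity and diffusivity", {
  p <- transport_params()
  v <- matrix(c(1, 2), 1); q <- matrix(c(3, -1), 1)
  expect_equal(blended_coefficients(v, q, 1, p)$u, v)
  expect_equal(blended_coefficients(v, q, 0, p)$u, q)
  expect_equal(blended_coefficients(v, q, 1, p)$D, p$D_F)
  expect_equal(blended_coefficients(v, q, 0, p)$D, p$D_P)
  expect_equal(blended_coefficients(v, q, 0.5, p)$D, 2.15e-5)
})

test_that("Michaelis-Menten rate saturates, halves at c_MM, and switches off", {
  p <- transport_params()
  # at c = c_MM the rate is half-maximal
  expect_equal(reaction_rate(1e-9, 0, p), p$R_max / 2)
  # at the necrosis threshold consumption stops
  expect_equal(reaction_rate(1e-10, 0, p), 0)
  expect_equal(reaction_rate(5e-11, 0, p), 0)
  # near saturation: direct formula evaluation
  expect_equal(reaction_rate(2e-7, 0, p),
               p$R_max * 2e-7 / (2e-7 + 1e-9), tolerance = 1e-12)
  expect_equal(reaction_rate(2e-7, 0, p), -3.383e-8, tolerance = 1e-3)
  # no consumption in channels, negative c clamped
  expect_equal(reaction_rate(2e-7, 1, p), 0)
  expect_equal(reaction_rate(-1e-8, 0, p), 0)
})

zero_flow <- function(pf) {
  nm <- nrow(pf$mesh$nodes) + nrow(pf$mesh$tri)
  list(v_full = matrix(0, nm, 2),
       q = matrix(0, nrow(pf$mesh$nodes), 2))
}

test_that("zero inflow and no reaction keep the concentration at zero", {
  pf <- small_phasefield("straight")
  p <- transport_params(R_max = 0, c_in = 0, dt = 1, T_end = 3)
  op <- assemble_transport_operator(pf, zero_flow(pf), p)
  cc <- rep(0, op$p2$ndof)
  for (k in 1:3) {
    cc <- advance_concentration(cc, op)
    expect_equal(max(abs(cc)), 0)
  }
})

test_that("pure-diffusion limit relaxes to the boundary value everywhere", {
  # two-layer domain: Dirichlet on the whole top edge, no advection, no
  # reaction -> steady state is uniform at c_in
  g <- two_layer_domain()
  m <- scaffold_base_mesh(g, 0.02)
  pf <- structure(list(mesh = m, phi = rep(0, nrow(m$nodes)),
                       phi_reg = regularize_phasefield(rep(0, nrow(m$nodes)), 1e-4),
                       beta = 1e-4, geom = g), class = "sf_phasefield")
  p <- transport_params(R_max = 0, D_P = 1e-3, dt = 5, T_end = 500)
  op <- assemble_transport_operator(pf, zero_flow(pf), p)
  cc <- rep(0, op$p2$ndof)
  for (k in seq_len(100)) cc <- advance_concentration(cc, op)
  expect_equal(range(cc), rep(p$c_in, 2), tolerance = 0.01)
})

test_that("well-mixed consumption follows the Michaelis-Menten ODE within 1%", {
  m <- unit_mesh(0.25)
  m$tagger <- function(mid) rep("wall", nrow(mid))
  m$boundary <- scaffoldflow:::mesh_boundary(m)
  pf <- structure(list(mesh = m, phi = rep(0, nrow(m$nodes)),
                       phi_reg = regularize_phasefield(rep(0, nrow(m$nodes)), 1e-4),
                       beta = 1e-4, geom = NULL), class = "sf_phasefield")
  p <- transport_params(dt = 0.05, T_end = 5, D_P = 1)  # large D: well mixed
  op <- assemble_transport_operator(pf, zero_flow(pf), p, bc = "none")
  c0 <- 2e-7
  cc <- rep(c0, op$p2$ndof)
  Nt <- round(p$T_end / p$dt)
  for (k in seq_len(Nt)) cc <- advance_concentration(cc, op)
  # high-accuracy ODE oracle: dc/dt = R_max c / (c + c_MM), H = 1 above c_CR
  ode <- deSolve::ode(y = c(c = c0), times = c(0, p$T_end), parms = NULL,
                      func = function(t, y, parms)
                        list(p$R_max * y / (y + p$c_MM) * (y > p$c_CR)),
                      method = "ode45", rtol = 1e-10, atol = 1e-16)
  c_ref <- ode[2, "c"]
  expect_equal(mean(cc), unname(c_ref), tolerance = 0.01)
})

test_that("the advective operator is exactly linear in the velocity", {
  pf <- small_phasefield("straight")
  fl1 <- zero_flow(pf)
  fl1$v_full[, 2] <- -1
  fl2 <- fl1; fl2$v_full[, 2] <- -2
  p <- transport_params()
  A0 <- assemble_transport_operator(pf, zero_flow(pf), p)$A
  A1 <- assemble_transport_operator(pf, fl1, p)$A
  A2 <- assemble_transport_operator(pf, fl2, p)$A
  expect_lt(max(abs((A2 - A1) - (A1 - A0))), 1e-12)
})

test_that("steady 1D advection-diffusion matches the exponential profile", {
  # strip with Dirichlet ends: c(0) = 0, c(1) = 1, velocity a along x
  a <- 5e-4; D <- 1e-4
  err_of <- function(h) {
    m <- mesh_rect_union(list(c(0, 1, 0, 2 * h)), h)
    p2 <- fem_space(m, "P2")
    nt <- nrow(m$tri)
    ux <- matrix(a, nt, p2$nq)
    A <- scaffoldflow:::fem_op(p2, p2, 0, 1, ux) + D * op_stiffness(p2)
    left <- which(abs(p2$coords[, 1]) < 1e-12)
    right <- which(abs(p2$coords[, 1] - 1) < 1e-12)
    sol <- solve_linear(A, rep(0, p2$ndof),
                        list(dofs = c(left, right),
                             values = c(rep(0, length(left)), rep(1, length(right)))))
    pe <- a / D
    exact <- function(x, y) (exp(pe * x) - 1) / (exp(pe) - 1)
    scaffoldflow:::fem_l2_error(p2, sol, exact)
  }
  e1 <- err_of(0.1); e2 <- err_of(0.05)
  expect_lt(e2, e1 / 3)     # at least O(h^2) decay observed
})

test_that("stronger consumption never increases the concentration", {
  # pointwise up to the small non-monotone wiggles of the consistent-mass
  # P2 scheme (about 0.5% of the field scale on this fixture); the bulk
  # comparison is strict
  pf <- small_phasefield("straight")
  run_short <- function(p) {
    op <- assemble_transport_operator(pf, zero_flow(pf), p)
    cc <- rep(0, op$p2$ndof)
    for (k in seq_len(round(p$T_end / p$dt))) cc <- advance_concentration(cc, op)
    cc
  }
  p1 <- transport_params(dt = 0.5, T_end = 20)
  p2 <- transport_params(dt = 0.5, T_end = 20, R_max = 2 * -3.4e-8)
  c1 <- run_short(p1); c2 <- run_short(p2)
  expect_true(all(c2 <= c1 + 0.01 * max(c1)))
  expect_lt(mean(c2), mean(c1))
  # removing the necrosis switch (consumption everywhere) cannot increase
  # c; with the default thresholds the switch only acts below c_CR, so the
  # bulk effect is essentially nil
  p3 <- transport_params(dt = 0.5, T_end = 20, c_CR = 1e-300)
  c3 <- run_short(p3)
  expect_true(all(c3 <= c1 + 0.01 * max(c1)))
  expect_equal(mean(c3), mean(c1), tolerance = 1e-3)
})
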
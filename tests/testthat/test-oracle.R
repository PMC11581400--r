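test_that("manufactured solutions converge at the nominal element orders", {
  mc <- manufactured_convergence("darcy")
  expect_equal(mc$order, 2, tolerance = 0.3 / 2)     # P1: 2 +- 0.3
  mc2 <- manufactured_convergence("transport")
  expect_equal(mc2$order, 3, tolerance = 0.3 / 3)    # P2: 3 +- 0.3
  mc3 <- manufactured_convergence("elasticity")
  expect_equal(mc3$order, 2, tolerance = 0.3 / 2)
  mc4 <- manufactured_convergence("stokes")
  expect_gt(mc4$order, 1.5)
})

test_that("solutions inside the element space are exact to round-off", {
  for (h in c(0.25, 0.125)) {
    m <- mesh_rect_union(list(c(0, 1, 0, 1)), h)
    sp <- fem_space(m, "P1")
    K <- op_stiffness(sp)
    bd <- scaffoldflow:::space_boundary_dofs(sp, "wall")
    g <- 2 * sp$coords[, 1] - sp$coords[, 2]
    u <- solve_linear(K, rep(0, sp$ndof), list(dofs = bd, values = g[bd]))
    expect_lt(max(abs(u - g)), 1e-10)
  }
})

test_that("the sharp-interface reference returns zero for zero data", {
  dom <- two_layer_domain()
  sol <- sharp_interface_reference(dom, flow_params(v_in = 0),
                                   time_grid(5e-3, 0.02), h = 0.02)
  expect_equal(max(abs(sol$x)), 0)
})

test_that("sharp solver conserves mass across the interface", {
  dom <- two_layer_domain()
  sol <- sharp_interface_reference(dom, flow_params(), time_grid(2e-3, 0.5),
                                   h = 0.0075)
  fl <- scaffoldflow:::sharp_interface_flux(sol)
  Q_in <- dom$W * flow_params()$v_in
  expect_equal(fl$fluid_side, fl$darcy_side,
               tolerance = 0.05 * abs(Q_in) / max(abs(fl$fluid_side), 1e-12))
})

test_that("diffuse solution approaches the sharp reference as the layer thins", {
  dom <- two_layer_domain()
  grid <- time_grid(2e-3, 0.5)
  sharp <- sharp_interface_reference(dom, flow_params(), grid, h = 0.0075)
  errs <- vapply(c(8e-2, 2e-2, 2.5e-3), function(Tphi) {
    pp <- phasefield_params(D_phi = 1.5e-4, T_phi = Tphi,
                            n_adapt_cycles = 1L, bisect_per_cycle = 2L)
    pf <- build_adapted_phasefield(dom, pp, h0 = 0.015)
    dif <- solve_flow_to_steady(pf, flow_params(), grid)
    compare_sharp_diffuse(sharp, dif)$rel_l2[1]
  }, 0)
  expect_true(all(diff(errs) < 0))   # monotone decrease with layer width
  # pressure is the more sensitive field on this benchmark
  pp <- phasefield_params(D_phi = 1.5e-4, T_phi = 2e-2,
                          n_adapt_cycles = 1L, bisect_per_cycle = 2L)
  pf <- build_adapted_phasefield(dom, pp, h0 = 0.015)
  dif <- solve_flow_to_steady(pf, flow_params(), grid)
  cmp <- compare_sharp_diffuse(sharp, dif)
  expect_gt(cmp$rel_l2[cmp$field == "pressure"],
            cmp$rel_l2[cmp$field == "velocity"])
})
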
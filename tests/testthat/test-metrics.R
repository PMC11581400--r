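test_that("insulin-support area handles the uniform limits exactly", {
  pf <- small_phasefield("straight")
  p2 <- fem_space(pf$mesh, "P2")
  # saturated everywhere -> the whole poroelastic region supports production
  isa <- insulin_support_area(rep(2e-7, p2$ndof), pf)
  expect_equal(isa$area_rel, 1)
  expect_equal(isa$area_opt, isa$poro_area)
  # anoxic everywhere -> nothing does
  isa0 <- insulin_support_area(rep(0, p2$ndof), pf)
  expect_equal(isa0$area_rel, 0)
  # the poroelastic area is the complement of the channel area
  expect_equal(isa$poro_area,
               pf$geom$areas$domain - pf$geom$areas$fluid, tolerance = 0.03)
  # threshold comparison is closed: c == c_opt counts
  isa_eq <- insulin_support_area(rep(5e-8, p2$ndof), pf)
  expect_equal(isa_eq$area_rel, 1)
})

test_that("relative area is monotone in the concentration field", {
  pf <- small_phasefield("straight")
  p2 <- fem_space(pf$mesh, "P2")
  set.seed(3)
  c2 <- runif(p2$ndof, 0, 1e-7)
  c1 <- c2 + runif(p2$ndof, 0, 5e-8)   # c1 >= c2 pointwise
  expect_gte(insulin_support_area(c1, pf)$area_rel,
             insulin_support_area(c2, pf)$area_rel)
})

test_that("field extrema respect the phase-field mask", {
  pf <- small_phasefield("straight")
  n <- nrow(pf$mesh$nodes)
  fx <- field_extrema(rep(3, n), pf, "all")
  expect_equal(fx$min, 3); expect_equal(fx$max, 3)
  # vector magnitude, channel vs gel masks
  f <- cbind(pf$phi, 0)    # magnitude = phi
  expect_gt(field_extrema(f, pf, "channel")$max, 0.99)
  expect_lte(field_extrema(f, pf, "gel")$max, 0.5)
  expect_error(field_extrema(rep(1, n), pf, "bogus"))
})

test_that("line profiles interpolate linear fields exactly", {
  m <- unit_mesh(0.2)
  f <- m$nodes[, 1]
  pr <- line_profile(m, f, c(0.1, 0.5), c(0.9, 0.5), 17)
  expect_true(all(pr$inside))
  expect_equal(pr$value, pr$x, tolerance = 1e-12)
  expect_true(all(diff(pr$s) > 0))
  # constant field -> flat profile
  prc <- line_profile(m, rep(7, nrow(m$nodes)), c(0, 0.3), c(1, 0.7), 9)
  expect_equal(prc$value, rep(7, 9), tolerance = 1e-12)
  # sample exactly at mesh vertices matches nodal values
  v <- 42
  idx <- which(abs(m$nodes[, 1] - 0.4) < 1e-9 & abs(m$nodes[, 2] - 0.4) < 1e-9)
  f2 <- rep(0, nrow(m$nodes)); f2[idx] <- v
  pr2 <- line_profile(m, f2, c(0.4, 0.4), c(0.4, 0.4001), 2)
  expect_equal(pr2$value[1], v)
  # outside points flagged
  pr3 <- line_profile(m, f, c(0.5, 0.5), c(1.5, 0.5), 11)
  expect_true(any(!pr3$inside))
  expect_true(all(is.na(pr3$value[!pr3$inside])))
})
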
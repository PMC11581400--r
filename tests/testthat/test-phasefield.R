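test_that("regularization is affine, bounded and exactly invertible", {
  phi <- seq(0, 1, by = 0.05)
  beta <- 1e-4
  pr <- regularize_phasefield(phi, beta)
  expect_equal(pr[1], beta)
  expect_equal(pr[length(pr)], 1 - beta)
  expect_equal(regularize_phasefield(0.5, beta), 0.5)
  expect_true(all(pr >= beta & pr <= 1 - beta))
  expect_equal((pr - beta) / (1 - 2 * beta), phi, tolerance = 1e-15)
  expect_error(regularize_phasefield(phi, 0.6))
})

test_that("uniform indicators are stationary under Allen-Cahn smoothing", {
  m <- unit_mesh(0.2)
  pp <- phasefield_params()
  expect_equal(allen_cahn_smooth(rep(1, nrow(m$nodes)), m, pp),
               rep(1, nrow(m$nodes)), tolerance = 1e-10)
  expect_equal(allen_cahn_smooth(rep(0, nrow(m$nodes)), m, pp),
               rep(0, nrow(m$nodes)), tolerance = 1e-10)
})

test_that("a step datum smooths to a monotone profile crossing 1/2 in place", {
  # quasi-1D strip, fine in x
  m <- mesh_rect_union(list(c(0, 1, 0, 0.02)), h = 0.005)
  chi <- as.numeric(m$nodes[, 1] > 0.5)
  prof_of <- function(D) {
    pp <- phasefield_params(D_phi = D)
    phi <- allen_cahn_smooth(chi, m, pp)
    row <- which(abs(m$nodes[, 2]) < 1e-12)
    ord <- order(m$nodes[row, 1])
    list(x = m$nodes[row[ord], 1], phi = phi[row[ord]])
  }
  p1 <- prof_of(2e-3)      # widths well above the grid pitch
  expect_true(all(diff(p1$phi) >= -1e-8))            # monotone
  expect_true(all(p1$phi >= -1e-8 & p1$phi <= 1 + 1e-8))
  x_half <- approx(p1$phi, p1$x, xout = 0.5, ties = "ordered")$y
  expect_equal(x_half, 0.5, tolerance = 0.01)        # crossing stays put
  # interface width grows with sqrt(D): compare 10-90% widths against a
  # fine-grid 1D reference ratio sqrt(4) = 2
  p2 <- prof_of(4 * 2e-3)
  width <- function(p)
    diff(approx(p$phi, p$x, xout = c(0.1, 0.9), ties = "ordered")$y)
  expect_equal(width(p2) / width(p1), 2, tolerance = 0.25)
})

test_that("adapted phase field is bounded, refined at the interface, and area-faithful", {
  pf <- small_phasefield("straight")
  expect_gte(min(pf$phi), 0)
  expect_lte(max(pf$phi), 1)
  expect_true(all(pf$phi_reg >= pf$beta - 1e-12))
  expect_true(all(pf$phi_reg <= 1 - pf$beta + 1e-12))
  # two full adaptation cycles: element density in the diffuse layer at
  # least 4x the density far from the interface
  pf2 <- build_adapted_phasefield(make_architecture("straight"),
                                  phasefield_params(), h0 = 0.03)
  eg <- scaffoldflow:::mesh_element_geometry(pf2$mesh)
  cent <- cbind(rowMeans(eg$x), rowMeans(eg$y))
  d <- scaffoldflow:::geometry_boundary_dist(pf2$geom, cent[, 1], cent[, 2])
  layer <- d < 0.005
  # compare against gel far from any interface (channel interiors carry
  # their own flow-resolution refinement)
  influid <- geometry_indicator(pf2$geom, cent[, 1], cent[, 2])
  far <- d > 0.02 & !influid
  density <- function(sel) sum(sel) / sum(eg$area[sel])
  expect_gt(density(layer), 4 * density(far))
  # int phi dV within 2% of the sharp channel area
  a <- scaffoldflow:::p1_integral(pf$mesh, pf$phi)
  expect_equal(a, pf$geom$areas$fluid, tolerance = 0.02)
})

test_that("interface normal from -grad phi is accurate on a flat channel wall", {
  pf <- small_phasefield("straight")
  m <- pf$mesh
  eg <- scaffoldflow:::mesh_element_geometry(m)
  gx <- rowSums(eg$gx * matrix(pf$phi[m$tri], ncol = 3))
  gy <- rowSums(eg$gy * matrix(pf$phi[m$tri], ncol = 3))
  # elements on the left wall of the middle vertical channel (x = 0.42),
  # away from junctions. -grad phi is the fluid's outward normal: on this
  # wall it points from the channel into the hydrogel, i.e. along (-1, 0)
  cx <- rowMeans(eg$x); cy <- rowMeans(eg$y)
  gn <- sqrt(gx^2 + gy^2)
  sel <- abs(cx - 0.42) < 0.01 & cy > 0.15 & cy < 0.27 & gn > 0.2 * max(gn)
  expect_gt(sum(sel), 5)
  expect_true(all(-gx[sel] < 0))
  # the |grad phi|-weighted normal is within 5 degrees of (-1, 0)
  nx <- sum(-gx[sel] * gn[sel]) / sum(gn[sel])
  ny <- sum(-gy[sel] * gn[sel]) / sum(gn[sel])
  expect_lt(abs(atan2(ny, -nx)) * 180 / pi, 5)
})

test_that("channel area converges toward the sharp area under refinement", {
  g <- make_architecture("straight")
  a_of <- function(h0, passes) {
    pp <- phasefield_params(n_adapt_cycles = 1L, bisect_per_cycle = passes)
    pf <- build_adapted_phasefield(g, pp, h0 = h0)
    scaffoldflow:::p1_integral(pf$mesh, pf$phi)
  }
  e1 <- abs(a_of(0.03, 1L) - g$areas$fluid)
  e2 <- abs(a_of(0.03, 3L) - g$areas$fluid)
  expect_lt(e2, e1)
})
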
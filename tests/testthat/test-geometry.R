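archs <- c("straight", "bifurcating", "hexagonal", "narrow_straight",
           "narrow_zigzag")

test_that("all architectures satisfy the equal-channel-area constraint", {
  geoms <- lapply(archs, make_architecture)
  chk <- equal_area_check(geoms)
  # analytic reference: 3 channels x 0.06 cm x 0.30 cm
  expect_equal(chk$interior_area_cm2, rep(0.054, 5), tolerance = 1e-6)
  expect_true(all(abs(chk$rel_deviation) <= 0.01))
  # straight layout arithmetic: horizontals + verticals + outlet stubs
  g <- geoms[[1]]
  expect_equal(g$areas$horizontals, 2 * 0.9 * 0.06)
  expect_equal(g$areas$interior, 3 * 0.06 * (0.42 - 2 * 0.06))
  expect_equal(g$areas$stubs, 2 * 0.1 * 0.06)
})

test_that("the one-third-width rule gives nine narrow channels", {
  g <- make_architecture("narrow_straight")
  expect_equal(g$channel_width, 0.02)
  expect_equal(length(g$interior), 9L)
})

test_that("construction errors are raised as specified", {
  expect_error(make_architecture("spiral"))
  expect_error(equal_area_check(list()), "empty")
  # pinned width that breaks the equal-area constraint
  expect_error(make_architecture("narrow_zigzag",
                                 list(zigzag_width = 0.05)),
               "misses the reference")
})

test_that("rasterized indicator separates channel and hydrogel", {
  g <- make_architecture("straight")
  pf <- small_phasefield("straight")
  chi <- rasterize_indicator(g, pf$mesh)
  expect_true(all(chi %in% c(0, 1)))
  # center of the top horizontal channel / middle vertical channel
  expect_true(geometry_indicator(g, 0.45, 0.39))
  expect_true(geometry_indicator(g, 0.45, 0.2))
  # center of a hydrogel pocket
  expect_false(geometry_indicator(g, 0.33, 0.2))
  # area-weighted indicator integral tracks the analytic polygon area
  a <- scaffoldflow:::p1_integral(pf$mesh, chi)
  expect_equal(a, g$areas$fluid, tolerance = 0.03)
})

test_that("boundary tags partition the exterior boundary", {
  g <- make_architecture("hexagonal")
  m <- scaffold_base_mesh(g, 0.015)
  tags <- m$boundary$tag
  expect_setequal(unique(tags), c("inlet", "outlet", "top_wall", "wall"))
  # two inlets of width 0.06 at the top
  sel <- tags == "inlet"
  mids <- (m$nodes[m$boundary$edges[sel, 1], , drop = FALSE] +
             m$nodes[m$boundary$edges[sel, 2], , drop = FALSE]) / 2
  expect_true(all(abs(mids[, 2] - 0.42) < 1e-9))
  len <- sum(sqrt(rowSums((m$nodes[m$boundary$edges[sel, 1], ] -
                             m$nodes[m$boundary$edges[sel, 2], ])^2)))
  expect_equal(len, 2 * 0.06, tolerance = 1e-9)
  # outlets at the stub bottoms
  sel <- tags == "outlet"
  mids <- (m$nodes[m$boundary$edges[sel, 1], , drop = FALSE] +
             m$nodes[m$boundary$edges[sel, 2], , drop = FALSE]) / 2
  expect_true(all(abs(mids[, 2] + 0.1) < 1e-9))
})

test_that("polygon area utilities are exact on known shapes", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  expect_equal(scaffoldflow:::poly_area(sq), 2)
  # union of two overlapping unit squares offset by 0.5
  s2 <- sq; s2[, 1] <- s2[, 1] + 1
  ua <- scaffoldflow:::union_area_convex(list(sq, s2))
  expect_equal(ua, 3)
  # triple overlap counted once
  s3 <- sq; s3[, 1] <- s3[, 1] + 0.5
  ua3 <- scaffoldflow:::union_area_convex(list(sq, s2, s3))
  expect_equal(ua3, 3)
  # convex clip
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  cl <- scaffoldflow:::clip_convex(tri, rbind(c(0, 0), c(0.5, 0), c(0.5, 1), c(0, 1)))
  expect_equal(scaffoldflow:::poly_area(cl), 0.5 - 0.125)
})
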
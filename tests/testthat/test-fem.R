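test_that("element spaces have the expected dof counts on one triangle", {
  m <- mesh_create(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
  expect_equal(fem_space(m, "P1")$ndof, 3L)
  expect_equal(fem_space(m, "P2")$ndof, 6L)
  expect_equal(fem_space(m, "MINI")$ndof, 4L)  # one scalar component
  sp <- build_spaces(m)
  expect_equal(sp$v$family, "MINI")
  expect_equal(sp$pP$family, "P1")
  expect_equal(sp$c$family, "P2")
})

test_that("mass matrices integrate to the domain area", {
  m <- unit_mesh(0.1)
  for (fam in c("P1", "P2")) {
    sp <- fem_space(m, fam)
    expect_equal(sum(op_mass(sp)), 1, tolerance = 1e-12)
  }
})

test_that("P1 interpolation reproduces linear functions exactly (patch test)", {
  m <- unit_mesh(0.2)
  sp <- fem_space(m, "P1")
  u <- 2 * sp$coords[, 1] - 3 * sp$coords[, 2] + 1
  expect_lt(scaffoldflow:::fem_l2_error(sp, u, function(x, y) 2 * x - 3 * y + 1),
            1e-12)
  # stiffness annihilates constants
  K <- op_stiffness(sp)
  expect_lt(max(abs(K %*% rep(1, sp$ndof))), 1e-12)
})

test_that("weighted assembly is linear and affine in the weight", {
  pf <- small_phasefield("straight")
  sp <- fem_space(pf$mesh, "P1")
  w <- pf$phi
  M1 <- op_mass(sp, sp, w)
  M2 <- op_mass(sp, sp, 2 * w)
  expect_lt(max(abs(M2 - 2 * M1)), 1e-14)
  # constant weight beta gives beta x unweighted operator
  M0 <- op_mass(sp)
  Mb <- op_mass(sp, sp, rep(1e-4, sp$ndof))
  expect_lt(max(abs(Mb - 1e-4 * M0)), 1e-18)
})

test_that("assembled stiffness energy matches the analytic integral", {
  # u = x^2 + y^2 interpolated on P2 is exact; int |grad u|^2 = 8/3 on unit square
  m <- unit_mesh(0.1)
  sp <- fem_space(m, "P2")
  u <- sp$coords[, 1]^2 + sp$coords[, 2]^2
  K <- op_stiffness(sp)
  expect_equal(as.numeric(t(u) %*% K %*% u), 8 / 3, tolerance = 1e-10)
})

test_that("solve_linear matches a dense factorization oracle", {
  set.seed(42)
  n <- 100
  B <- matrix(rnorm(n * n), n)
  Ad <- crossprod(B) + n * diag(n)          # SPD
  A <- methods::as(Ad, "CsparseMatrix")
  b <- rnorm(n)
  x_dense <- solve(Ad, b)                   # dense oracle
  x <- solve_linear(A, b)
  expect_lt(max(abs(x - x_dense)), 1e-10)
  # identity system
  I <- Matrix::Diagonal(5)
  expect_equal(solve_linear(I, 1:5), as.numeric(1:5))
})

test_that("constrained solves honour Dirichlet data and detect zero rows", {
  m <- unit_mesh(0.25)
  sp <- fem_space(m, "P1")
  K <- op_stiffness(sp)
  bd <- scaffoldflow:::space_boundary_dofs(sp, "wall")
  g <- sp$coords[, 1]                        # u = x on boundary
  x <- solve_linear(K, rep(0, sp$ndof), list(dofs = bd, values = g[bd]))
  expect_equal(x, g, tolerance = 1e-12)      # harmonic extension of x is x
  # a zero row (missing regularization) is reported with the dof index
  interior <- setdiff(seq_len(sp$ndof), bd)[1]
  K2 <- K; K2[interior, ] <- 0
  expect_error(solve_linear(K2, rep(0, sp$ndof),
                            list(dofs = bd, values = 0)),
               "zero rows")
})
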
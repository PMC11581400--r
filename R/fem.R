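# Finite-element infrastructure shared by the flow and transport solvers:
# P1 / P2 / MINI (P1 + cubic bubble) spaces on triangles, a 12-point
# degree-6 quadrature rule (exact well beyond the degree-4 products of
# bubble terms with nodal weights), weighted assembly primitives, and
# factor-once constrained sparse solves.

# Dunavant degree-6 rule on the reference triangle; barycentric coordinates,
# weights sum to 1 (multiply by the physical element area).
quad_rule <- function() {
  g1a <- 0.873821971016996; g1b <- 0.063089014491502
  g2a <- 0.501426509658179; g2b <- 0.249286745170910
  g3a <- 0.636502499121399; g3b <- 0.310352451033785; g3c <- 0.053145049844816
  w1 <- 0.050844906370207; w2 <- 0.116786275726379; w3 <- 0.082851075618374
  L <- rbind(
    c(g1a, g1b, g1b), c(g1b, g1a, g1b), c(g1b, g1b, g1a),
    c(g2a, g2b, g2b), c(g2b, g2a, g2b), c(g2b, g2b, g2a),
    c(g3a, g3b, g3c), c(g3a, g3c, g3b), c(g3b, g3a, g3c),
    c(g3b, g3c, g3a), c(g3c, g3a, g3b), c(g3c, g3b, g3a))
  w <- c(rep(w1, 3), rep(w2, 3), rep(w3, 6))
  list(lambda = L, w = w, nq = length(w))
}

#' Build a finite-element space on a mesh
#'
#' Supported families: `"P1"` (nodal linear), `"P2"` (quadratic, node +
#' edge-midpoint dofs) and `"MINI"` (one scalar component of the MINI
#' element: P1 plus a cubic bubble per element). Vector-valued fields are
#' handled by the solvers as two stacked scalar components.
#'
#' @param mesh an `sf_mesh`.
#' @param family `"P1"`, `"P2"` or `"MINI"`.
#' @return an `sf_space` with dof map `edof` (nt x nloc), basis values `N`
#'   (nloc x nq) at the quadrature points, gradient arrays `gradx`, `grady`
#'   (nt x nq x nloc), dof coordinates `coords`, and `ndof`.
#' @export
fem_space <- function(mesh, family = c("P1", "P2", "MINI")) {
  family <- match.arg(family)
  qr <- quad_rule()
  eg <- mesh_element_geometry(mesh)
  nt <- nrow(mesh$tri); nv <- nrow(mesh$nodes); nq <- qr$nq
  L <- qr$lambda

  if (family == "P1") {
    nloc <- 3
    edof <- mesh$tri
    N <- t(L)                                # nloc x nq
    gradx <- array(0, c(nt, nq, nloc)); grady <- array(0, c(nt, nq, nloc))
    for (k in 1:3) {
      gradx[, , k] <- matrix(eg$gx[, k], nt, nq)
      grady[, , k] <- matrix(eg$gy[, k], nt, nq)
    }
    coords <- mesh$nodes
    ndof <- nv
  } else if (family == "P2") {
    em <- mesh_edges(mesh)
    nloc <- 6
    edof <- cbind(mesh$tri, nv + em$tri2edge)
    N <- matrix(0, nloc, nq)
    for (k in 1:3) N[k, ] <- L[, k] * (2 * L[, k] - 1)
    oth <- list(c(2, 3), c(3, 1), c(1, 2))   # edge k opposite vertex k
    for (k in 1:3) N[3 + k, ] <- 4 * L[, oth[[k]][1]] * L[, oth[[k]][2]]
    gradx <- array(0, c(nt, nq, nloc)); grady <- array(0, c(nt, nq, nloc))
    for (k in 1:3) for (q in 1:nq) {
      cfac <- 4 * L[q, k] - 1
      gradx[, q, k] <- cfac * eg$gx[, k]
      grady[, q, k] <- cfac * eg$gy[, k]
    }
    for (k in 1:3) {
      a <- oth[[k]][1]; b <- oth[[k]][2]
      for (q in 1:nq) {
        gradx[, q, 3 + k] <- 4 * (L[q, a] * eg$gx[, b] + L[q, b] * eg$gx[, a])
        grady[, q, 3 + k] <- 4 * (L[q, a] * eg$gy[, b] + L[q, b] * eg$gy[, a])
      }
    }
    mids <- (mesh$nodes[em$edges[, 1], , drop = FALSE] +
               mesh$nodes[em$edges[, 2], , drop = FALSE]) / 2
    coords <- rbind(mesh$nodes, mids)
    ndof <- nv + nrow(em$edges)
  } else { # MINI scalar component
    nloc <- 4
    edof <- cbind(mesh$tri, nv + seq_len(nt))
    N <- matrix(0, nloc, nq)
    for (k in 1:3) N[k, ] <- L[, k]
    N[4, ] <- 27 * L[, 1] * L[, 2] * L[, 3]
    gradx <- array(0, c(nt, nq, nloc)); grady <- array(0, c(nt, nq, nloc))
    for (k in 1:3) {
      gradx[, , k] <- matrix(eg$gx[, k], nt, nq)
      grady[, , k] <- matrix(eg$gy[, k], nt, nq)
    }
    for (q in 1:nq) {
      l1 <- L[q, 1]; l2 <- L[q, 2]; l3 <- L[q, 3]
      gradx[, q, 4] <- 27 * (l2 * l3 * eg$gx[, 1] + l1 * l3 * eg$gx[, 2] +
                               l1 * l2 * eg$gx[, 3])
      grady[, q, 4] <- 27 * (l2 * l3 * eg$gy[, 1] + l1 * l3 * eg$gy[, 2] +
                               l1 * l2 * eg$gy[, 3])
    }
    cent <- (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
               mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
               mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
    coords <- rbind(mesh$nodes, cent)
    ndof <- nv + nt
  }
  structure(list(family = family, mesh = mesh, edof = edof, N = N,
                 gradx = gradx, grady = grady, coords = coords,
                 ndof = ndof, nloc = nloc, nq = qr$nq, qw = qr$w,
                 area = eg$area),
            class = "sf_space")
}

#' Element spaces for the coupled scaffold problem
#'
#' MINI for the fluid velocity components, P1 for the fluid pressure, Darcy
#' pressure and displacement components, P2 for the oxygen concentration.
#'
#' @param mesh an `sf_mesh`.
#' @return named list of `sf_space` objects `v`, `pF`, `pP`, `eta`, `c`.
#' @export
build_spaces <- function(mesh) {
  p1 <- fem_space(mesh, "P1")
  list(v = fem_space(mesh, "MINI"), pF = p1, pP = p1, eta = p1,
       c = fem_space(mesh, "P2"))
}

# weight matrix (nt x nq) from a P1 nodal field, or recycle scalars/vectors
weight_at_quad <- function(spaceA, w) {
  nt <- nrow(spaceA$edof); nq <- spaceA$nq
  if (is.null(w)) return(matrix(1, nt, nq))
  if (is.matrix(w)) return(w)
  if (length(w) == 1) return(matrix(w, nt, nq))
  if (length(w) == nt) return(matrix(w, nt, nq))
  # P1 nodal field
  tri <- spaceA$mesh$tri
  qr <- quad_rule()
  w[tri[, 1]] %o% qr$lambda[, 1] + w[tri[, 2]] %o% qr$lambda[, 2] +
    w[tri[, 3]] %o% qr$lambda[, 3]
}

# core assembler: sum_e area_e sum_q qw_q Arow(e,q) Bcol(e,q) W(e,q)
# da/db: 0 = value, 1 = d/dx, 2 = d/dy
fem_op <- function(A, B, da = 0, db = 0, weight = NULL) {
  W <- weight_at_quad(A, weight)
  nt <- nrow(A$edof); nq <- A$nq
  aw <- A$area
  nnz <- nt * A$nloc * B$nloc
  ii <- integer(nnz); jj <- integer(nnz); xx <- numeric(nnz)
  pos <- 0L
  for (i in seq_len(A$nloc)) {
    Ai <- switch(da + 1L,
                 matrix(A$N[i, ], nt, nq, byrow = TRUE),
                 A$gradx[, , i], A$grady[, , i])
    for (j in seq_len(B$nloc)) {
      Bj <- switch(db + 1L,
                   matrix(B$N[j, ], nt, nq, byrow = TRUE),
                   B$gradx[, , j], B$grady[, , j])
      s <- aw * as.vector((Ai * Bj * W) %*% A$qw)
      idx <- pos + seq_len(nt)
      ii[idx] <- A$edof[, i]; jj[idx] <- B$edof[, j]; xx[idx] <- s
      pos <- pos + nt
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(A$ndof, B$ndof))
}

#' Assemble a weighted mass matrix  \eqn{\int u\, z\, w\, dV}
#' @param A,B test / trial `sf_space`s on the same mesh.
#' @param weight scalar, per-element vector, nt x nq matrix, or P1 nodal field.
#' @return sparse matrix (rows = A dofs, cols = B dofs).
#' @export
op_mass <- function(A, B = A, weight = NULL) fem_op(A, B, 0, 0, weight)

#' Assemble a weighted stiffness matrix \eqn{\int \nabla u\cdot\nabla z\, w\, dV}
#' @inheritParams op_mass
#' @export
op_stiffness <- function(A, B = A, weight = NULL)
  fem_op(A, B, 1, 1, weight) + fem_op(A, B, 2, 2, weight)

# value-row x gradient-component-col: int z (d_db u) w
op_valgrad <- function(A, B, db, weight = NULL) fem_op(A, B, 0, db, weight)

# grad-row x grad-col for specific components
op_gg <- function(A, B, da, db, weight = NULL) fem_op(A, B, da, db, weight)

# load vector int f z dV with f given at quad points (nt x nq) or P1 nodal
op_load <- function(A, f) {
  W <- weight_at_quad(A, f)
  nt <- nrow(A$edof)
  b <- numeric(A$ndof)
  for (i in seq_len(A$nloc)) {
    s <- A$area * as.vector((matrix(A$N[i, ], nt, A$nq, byrow = TRUE) * W) %*% A$qw)
    b <- b + as.vector(Matrix::sparseMatrix(
      i = A$edof[, i], j = rep(1L, nt), x = s, dims = c(A$ndof, 1L)))
  }
  b
}

# evaluate a coefficient vector at the quadrature points -> nt x nq
field_at_quad <- function(space, u, deriv = 0L) {
  nt <- nrow(space$edof); nq <- space$nq
  out <- matrix(0, nt, nq)
  for (i in seq_len(space$nloc)) {
    ui <- u[space$edof[, i]]
    out <- out + switch(deriv + 1L,
                        ui %o% space$N[i, ],
                        ui * space$gradx[, , i],
                        ui * space$grady[, , i])
  }
  out
}

# L2 norm of (a P1/P2/MINI coefficient) field minus a function fun(x, y)
fem_l2_error <- function(space, u, fun) {
  qr <- quad_rule()
  eg <- mesh_element_geometry(space$mesh)
  xq <- eg$x %*% t(qr$lambda); yq <- eg$y %*% t(qr$lambda)
  diff2 <- (field_at_quad(space, u) - fun(xq, yq))^2
  sqrt(sum(eg$area * as.vector(diff2 %*% qr$w)))
}

# dofs of a space lying on boundary edges with the given tags
space_boundary_dofs <- function(space, tags) {
  mesh <- space$mesh
  bd <- mesh$boundary
  sel <- bd$tag %in% tags
  if (!any(sel)) return(integer(0))
  nodes <- unique(as.vector(bd$edges[sel, , drop = FALSE]))
  if (space$family == "P2") {
    em <- mesh_edges(mesh)
    key_b <- edge_key(bd$edges[sel, 1], bd$edges[sel, 2])
    key_all <- edge_key(em$edges[, 1], em$edges[, 2])
    eidx <- match(key_b, key_all)
    return(sort(c(nodes, nrow(mesh$nodes) + eidx)))
  }
  sort(nodes)   # P1 and MINI: bubbles vanish on edges
}

#' Factor a constrained sparse system once for repeated right-hand sides
#'
#' Essential (Dirichlet) constraints are imposed by row/column elimination
#' with lifting of the fixed values into the right-hand side.
#'
#' @param A square sparse matrix.
#' @param fixed integer dof indices to constrain.
#' @param values constraint values (recycled).
#' @return an `sf_solver`; call `sf_solve(solver, b)` per right-hand side.
#' @export
fem_factorize <- function(A, fixed = integer(0), values = 0) {
  n <- nrow(A)
  fixed <- as.integer(fixed)
  vals <- rep_len(values, length(fixed))
  free <- setdiff(seq_len(n), fixed)
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Aff <- A[free, free, drop = FALSE]
  dg <- as.vector(abs(Aff) %*% rep(1, length(free)))
  if (any(dg == 0)) {
    bad <- free[which(dg == 0)]
    stop("singular system: zero rows at dofs ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (is the phase-field regularization applied?)")
  }
  # two-sided norm equilibration: the monolithic multiphysics blocks span
  # many orders of magnitude, which otherwise trips condition checks
  r <- 1 / sqrt(pmax(Matrix::rowSums(Aff^2), 1e-300))
  A1 <- Matrix::Diagonal(x = r) %*% Aff
  cs <- 1 / sqrt(pmax(Matrix::colSums(A1^2), 1e-300))
  A2 <- A1 %*% Matrix::Diagonal(x = cs)
  fac <- Matrix::lu(A2, order = 1L)
  Afd <- if (length(fixed)) A[free, fixed, drop = FALSE] else NULL
  structure(list(n = n, free = free, fixed = fixed, vals = vals,
                 fac = fac, rscale = r, cscale = cs, Afd = Afd),
            class = "sf_solver")
}

#' Solve a factored constrained system
#' @param solver an `sf_solver` from [fem_factorize()].
#' @param b right-hand side vector.
#' @return full solution vector (constrained dofs at their fixed values).
#' @export
sf_solve <- function(solver, b) {
  rhs <- b[solver$free]
  if (length(solver$fixed))
    rhs <- rhs - as.vector(solver$Afd %*% solver$vals)
  x <- rep(0, solver$n)
  x[solver$fixed] <- solver$vals
  x[solver$free] <- solver$cscale *
    as.vector(Matrix::solve(solver$fac, solver$rscale * rhs))
  x
}

#' One-shot constrained sparse solve
#'
#' Direct sparse factorization with essential boundary conditions imposed by
#' elimination; the relative residual of the returned solution is checked
#' against 1e-9.
#'
#' @param A square sparse matrix.
#' @param b right-hand side.
#' @param constraints optional list with `dofs` and `values`.
#' @return solution vector.
#' @export
solve_linear <- function(A, b, constraints = NULL) {
  s <- fem_factorize(A, constraints$dofs %||% integer(0),
                     constraints$values %||% 0)
  x <- sf_solve(s, b)
  free <- s$free
  r <- as.vector(A[free, , drop = FALSE] %*% x) - b[free]
  nb <- sqrt(sum(b[free]^2))
  if (nb > 0 && sqrt(sum(r^2)) / nb > 1e-9)
    warning(sprintf("solve_linear: relative residual %.2e above 1e-9",
                    sqrt(sum(r^2)) / nb))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nodal (lumped) projection of the P1 per-element gradient to nodes
grad_project_p1 <- function(mesh, u) {
  eg <- mesh_element_geometry(mesh)
  gxe <- rowSums(eg$gx * matrix(u[mesh$tri], ncol = 3))
  gye <- rowSums(eg$gy * matrix(u[mesh$tri], ncol = 3))
  nv <- nrow(mesh$nodes)
  acc <- function(vals) {
    num <- as.vector(Matrix::sparseMatrix(
      i = as.vector(mesh$tri), j = rep(1L, 3 * nrow(mesh$tri)),
      x = rep(vals * eg$area, 3), dims = c(nv, 1)))
    den <- as.vector(Matrix::sparseMatrix(
      i = as.vector(mesh$tri), j = rep(1L, 3 * nrow(mesh$tri)),
      x = rep(eg$area, 3), dims = c(nv, 1)))
    num / den
  }
  cbind(acc(gxe), acc(gye))
}
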
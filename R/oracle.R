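# Verification tools: a sharp-interface monolithic Stokes-Biot reference on
# a two-layer rectangle (fluid on top of gel, flat interface), utilities to
# compare it with the diffuse-interface solver, and manufactured-solution
# convergence harnesses for the element spaces.

#' Two-layer verification domain
#'
#' Rectangle with a flat horizontal interface; fluid on top (driven by a
#' uniform inlet velocity on the whole top edge, outflow on the fluid-side
#' lateral edges), poroelastic gel below (fixed, no-flux exterior).
#'
#' @param W,H rectangle width and height, cm.
#' @param yint interface height, strictly between 0 and `H`.
#' @return an `sf_geometry` of architecture `"two_layer_oracle"`.
#' @export
two_layer_domain <- function(W = 0.45, H = 0.21, yint = H / 2) {
  stopifnot(yint > 0, yint < H)
  make_architecture("two_layer_oracle",
                    list(domain_width = W, domain_height = H,
                         interface_y = yint))
}

# 1D P1 mass matrix along a set of edges, returned as triplets over the
# given node index maps (rowmap/colmap: global node -> dof index)
edge_mass_triplets <- function(nodes, edges, rowmap, colmap) {
  h <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
  i <- c(rowmap[edges[, 1]], rowmap[edges[, 1]],
         rowmap[edges[, 2]], rowmap[edges[, 2]])
  j <- c(colmap[edges[, 1]], colmap[edges[, 2]],
         colmap[edges[, 1]], colmap[edges[, 2]])
  x <- c(h / 3, h / 6, h / 6, h / 3)
  list(i = i, j = j, x = x)
}

submesh <- function(mesh, keep, tagger) {
  tri <- mesh$tri[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  mesh_create(mesh$nodes[used, , drop = FALSE],
              matrix(remap[tri], ncol = 3), tagger = tagger)
}

#' Sharp-interface Stokes-Biot reference solver on the two-layer domain
#'
#' Classical monolithic formulation: Stokes unknowns live on the fluid
#' submesh, Biot unknowns on the gel submesh, and the interface conditions
#' (mass continuity, Beavers-Joseph-Saffman slip, pressure/stress balance)
#' enter as line integrals along the flat interface. Same element families
#' and backward-Euler stepping as the diffuse solver; the matrix is
#' factored once.
#'
#' @param domain an `sf_geometry` from [two_layer_domain()].
#' @param params a [flow_params()].
#' @param grid a [time_grid()].
#' @param h mesh size, cm (the structured mesh conforms to the interface).
#' @return an `sf_sharpstate`: nodal `v`, `p_F` on the fluid submesh,
#'   `p_P`, `eta`, `q` on the gel submesh, plus the submeshes and interface
#'   node lists.
#' @export
sharp_interface_reference <- function(domain, params = flow_params(),
                                      grid = time_grid(), h = 0.01) {
  stopifnot(domain$architecture == "two_layer_oracle")
  W <- domain$W; H <- domain$H; yint <- domain$interface_y
  tol <- 1e-9
  tagger <- function(mid) {
    tag <- rep("wall", nrow(mid))
    tag[abs(mid[, 2] - H) < tol] <- "inlet"
    tag[(abs(mid[, 1]) < tol | abs(mid[, 1] - W) < tol) &
          mid[, 2] > yint] <- "outlet"
    tag[abs(mid[, 2] - yint) < tol] <- "iface"
    tag
  }
  base <- mesh_rect_union(list(c(0, W, 0, yint), c(0, W, yint, H)), h,
                          tagger = tagger)
  eg <- mesh_element_geometry(base)
  centy <- rowMeans(eg$y)
  mF <- submesh(base, centy > yint, tagger)
  mP <- submesh(base, centy < yint, tagger)

  miniF <- fem_space(mF, "MINI"); p1F <- fem_space(mF, "P1")
  p1P <- fem_space(mP, "P1")
  nmF <- miniF$ndof; nvF <- p1F$ndof; nvP <- p1P$ndof
  off <- list(vx = 0L, vy = nmF, pF = 2L * nmF, pP = 2L * nmF + nvF,
              ex = 2L * nmF + nvF + nvP, ey = 2L * nmF + nvF + 2L * nvP)
  N <- 2L * nmF + nvF + 3L * nvP
  g <- params; dt <- grid$dt

  ii <- list(); jj <- list(); xx <- list()
  r1i <- list(); r1j <- list(); r1x <- list()
  add <- function(io, jo, M, dest = "S") {
    if (is.list(M)) { tp <- M } else
      tp <- Matrix::mat2triplet(methods::as(M, "TsparseMatrix"))
    if (dest == "S") {
      ii[[length(ii) + 1]] <<- tp$i + io; jj[[length(jj) + 1]] <<- tp$j + jo
      xx[[length(xx) + 1]] <<- tp$x
    } else {
      r1i[[length(r1i) + 1]] <<- tp$i + io; r1j[[length(r1j) + 1]] <<- tp$j + jo
      r1x[[length(r1x) + 1]] <<- tp$x
    }
  }

  # fluid volume terms
  Am <- op_mass(miniF, miniF)
  add(off$vx, off$vx, (g$rho_F / dt) * Am); add(off$vy, off$vy, (g$rho_F / dt) * Am)
  add(off$vx, off$vx, (g$rho_F / dt) * Am, "R1"); add(off$vy, off$vy, (g$rho_F / dt) * Am, "R1")
  V11 <- fem_op(miniF, miniF, 1, 1); V22 <- fem_op(miniF, miniF, 2, 2)
  V21 <- fem_op(miniF, miniF, 2, 1)
  add(off$vx, off$vx, g$mu_F * (2 * V11 + V22))
  add(off$vy, off$vy, g$mu_F * (2 * V22 + V11))
  add(off$vx, off$vy, g$mu_F * V21); add(off$vy, off$vx, g$mu_F * Matrix::t(V21))
  BFx <- fem_op(miniF, p1F, 1, 0); BFy <- fem_op(miniF, p1F, 2, 0)
  add(off$vx, off$pF, -BFx); add(off$vy, off$pF, -BFy)
  add(off$pF, off$vx, Matrix::t(BFx)); add(off$pF, off$vy, Matrix::t(BFy))

  # gel volume terms
  MpP <- op_mass(p1P, p1P)
  add(off$pP, off$pP, (g$c0 / dt) * MpP)
  add(off$pP, off$pP, (g$c0 / dt) * MpP, "R1")
  add(off$pP, off$pP, g$kappa * op_stiffness(p1P, p1P))
  for (oo in c(off$ex, off$ey)) {
    add(oo, oo, (g$rho_S / dt^2) * MpP + g$gamma_E * MpP)
    add(oo, oo, (2 * g$rho_S / dt^2) * MpP, "R1")
  }
  E11 <- fem_op(p1P, p1P, 1, 1); E22 <- fem_op(p1P, p1P, 2, 2)
  E21 <- fem_op(p1P, p1P, 2, 1)
  add(off$ex, off$ex, g$mu_E * (2 * E11 + E22) + g$lambda_E * E11)
  add(off$ey, off$ey, g$mu_E * (2 * E22 + E11) + g$lambda_E * E22)
  add(off$ex, off$ey, g$mu_E * E21 + g$lambda_E * Matrix::t(E21))
  add(off$ey, off$ex, g$mu_E * Matrix::t(E21) + g$lambda_E * E21)
  BPx <- fem_op(p1P, p1P, 1, 0); BPy <- fem_op(p1P, p1P, 2, 0)
  add(off$ex, off$pP, -g$alpha * BPx); add(off$ey, off$pP, -g$alpha * BPy)
  add(off$pP, off$ex, (g$alpha / dt) * Matrix::t(BPx))
  add(off$pP, off$ey, (g$alpha / dt) * Matrix::t(BPy))
  add(off$pP, off$ex, (g$alpha / dt) * Matrix::t(BPx), "R1")
  add(off$pP, off$ey, (g$alpha / dt) * Matrix::t(BPy), "R1")

  # interface line integrals (flat, horizontal; fluid outward normal
  # nF = (0,-1); tangential component = x component)
  ifF <- mF$boundary$edges[mF$boundary$tag == "iface", , drop = FALSE]
  ifP <- mP$boundary$edges[mP$boundary$tag == "iface", , drop = FALSE]
  # node maps: interface nodes matched by x coordinate
  nodesF_if <- sort(unique(as.vector(ifF))); nodesP_if <- sort(unique(as.vector(ifP)))
  xF <- mF$nodes[nodesF_if, 1]; xP <- mP$nodes[nodesP_if, 1]
  mapFP <- integer(nrow(mF$nodes))  # fluid node -> matched gel node
  mapFP[nodesF_if] <- nodesP_if[match(round(xF, 9), round(xP, 9))]
  MFF <- edge_mass_triplets(mF$nodes, ifF, seq_len(nrow(mF$nodes)),
                            seq_len(nrow(mF$nodes)))
  MFP <- edge_mass_triplets(mF$nodes, ifF, seq_len(nrow(mF$nodes)), mapFP)
  MPP <- edge_mass_triplets(mF$nodes, ifF, mapFP, mapFP)
  gb <- g$gamma_bjs
  sc <- function(tp, s) list(i = tp$i, j = tp$j, x = s * tp$x)
  tr <- function(tp) list(i = tp$j, j = tp$i, x = tp$x)
  # BJS slip (x components)
  add(off$vx, off$vx, sc(MFF, gb)); add(off$vx, off$ex, sc(MFP, -gb / dt))
  add(off$ex, off$vx, sc(tr(MFP), -gb)); add(off$ex, off$ex, sc(MPP, gb / dt))
  add(off$vx, off$ex, sc(MFP, -gb / dt), "R1")
  add(off$ex, off$ex, sc(MPP, gb / dt), "R1")
  # pressure balance: + int pP (w - zeta) . nF
  add(off$vy, off$pP, sc(MFP, -1))
  add(off$ey, off$pP, sc(MPP, 1))
  # mass continuity: - int psiP (v - d eta) . nF
  add(off$pP, off$vy, sc(tr(MFP), 1)); add(off$pP, off$ey, sc(MPP, -1 / dt))
  add(off$pP, off$ey, sc(MPP, -1 / dt), "R1")

  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  R1 <- Matrix::sparseMatrix(i = unlist(r1i), j = unlist(r1j), x = unlist(r1x),
                             dims = c(N, N))
  tpM <- Matrix::mat2triplet(methods::as(MpP, "TsparseMatrix"))
  R2 <- Matrix::sparseMatrix(
    i = c(tpM$i + off$ex, tpM$i + off$ey), j = c(tpM$j + off$ex, tpM$j + off$ey),
    x = rep(-(g$rho_S / dt^2) * tpM$x, 2), dims = c(N, N))

  vin <- space_boundary_dofs(miniF, "inlet")
  edofs <- space_boundary_dofs(p1P, "wall")
  fixed <- c(off$vx + vin, off$vy + vin, off$ex + edofs, off$ey + edofs)
  vals <- c(rep(0, length(vin)), rep(-g$v_in, length(vin)),
            rep(0, 2 * length(edofs)))
  solver <- fem_factorize(S, fixed, vals)
  x <- rep(0, N); eta_prev <- x
  for (n in seq_len(grid$N)) {
    b <- as.vector(R1 %*% x) + as.vector(R2 %*% eta_prev)
    xn <- sf_solve(solver, b)
    eta_prev <- x; x <- xn
  }
  nvFn <- nrow(mF$nodes); nvPn <- nrow(mP$nodes)
  v <- cbind(x[off$vx + seq_len(nvFn)], x[off$vy + seq_len(nvFn)])
  p_P <- x[off$pP + seq_len(nvP)]
  q <- -g$kappa * grad_project_p1(mP, p_P)
  structure(list(
    mesh_fluid = mF, mesh_gel = mP, v = v,
    v_full = cbind(x[off$vx + seq_len(nmF)], x[off$vy + seq_len(nmF)]),
    p_F = x[off$pF + seq_len(nvF)], p_P = p_P,
    eta = cbind(x[off$ex + seq_len(nvP)], x[off$ey + seq_len(nvP)]),
    eta_prev = cbind(eta_prev[off$ex + seq_len(nvP)],
                     eta_prev[off$ey + seq_len(nvP)]),
    q = q, dt = dt, params = g, domain = domain,
    iface_nodes_fluid = nodesF_if, iface_nodes_gel = mapFP[nodesF_if],
    x = x), class = "sf_sharpstate")
}

# interface flux balance of the sharp solution:
# int_Gamma (v - d_t eta) . n dA  vs  int_Gamma q . n dA
sharp_interface_flux <- function(sol) {
  nf <- sol$iface_nodes_fluid; ng <- sol$iface_nodes_gel
  xs <- sol$mesh_fluid$nodes[nf, 1]
  ord <- order(xs); xs <- xs[ord]
  w <- diff(xs)
  trap <- function(vals) sum((vals[-1] + vals[-length(vals)]) / 2 * w)
  deta <- (sol$eta - sol$eta_prev) / sol$dt
  vn <- -(sol$v[nf, 2])[ord]              # v . nF, nF = (0,-1)
  dn <- -(deta[ng, 2])[ord]
  qn <- -(sol$q[ng, 2])[ord]
  list(fluid_side = trap(vn - dn), darcy_side = trap(qn))
}

#' Compare sharp- and diffuse-interface solutions on a common grid
#'
#' Fields are interpolated from both solutions onto a regular evaluation
#' grid over the two-layer domain and compared in the relative L2 norm.
#' For the diffuse solution, velocity means the combined velocity `u`;
#' pressure is `p_F` in the fluid layer and `p_P` in the gel.
#'
#' @param sharp an `sf_sharpstate`.
#' @param diffuse an `sf_flowstate` solved on the same `two_layer_domain`.
#' @param fields character subset of `c("velocity", "pressure")`.
#' @param nx,ny evaluation grid resolution.
#' @return data.frame with one row per field: relative L2 difference.
#' @export
compare_sharp_diffuse <- function(sharp, diffuse,
                                  fields = c("velocity", "pressure"),
                                  nx = 45, ny = 21) {
  dom <- sharp$domain
  gx <- seq(dom$W * 0.02, dom$W * 0.98, length.out = nx)
  gy <- seq(dom$H * 0.02, dom$H * 0.98, length.out = ny)
  pts <- cbind(rep(gx, ny), rep(gy, each = nx))
  up <- pts[, 2] > dom$interface_y
  interp_p1 <- function(mesh, vals, pts) {
    loc <- mesh_locate(mesh, pts, tol = 1e-8)
    out <- rep(NA_real_, nrow(pts)); ok <- !is.na(loc$elem)
    tri <- mesh$tri[loc$elem[ok], , drop = FALSE]
    out[ok] <- rowSums(matrix(vals[tri], ncol = 3) * loc$bary[ok, , drop = FALSE])
    out
  }
  res <- list()
  if ("velocity" %in% fields) {
    sx <- ifelse(up, interp_p1(sharp$mesh_fluid, sharp$v[, 1], pts),
                 interp_p1(sharp$mesh_gel, sharp$q[, 1], pts))
    sy <- ifelse(up, interp_p1(sharp$mesh_fluid, sharp$v[, 2], pts),
                 interp_p1(sharp$mesh_gel, sharp$q[, 2], pts))
    dx <- interp_p1(diffuse$mesh, diffuse$u[, 1], pts)
    dy <- interp_p1(diffuse$mesh, diffuse$u[, 2], pts)
    ok <- !is.na(sx) & !is.na(dx)
    num <- sqrt(sum((sx - dx)[ok]^2 + (sy - dy)[ok]^2))
    den <- sqrt(sum(sx[ok]^2 + sy[ok]^2))
    res$velocity <- num / den
  }
  if ("pressure" %in% fields) {
    sp <- ifelse(up, interp_p1(sharp$mesh_fluid, sharp$p_F, pts),
                 interp_p1(sharp$mesh_gel, sharp$p_P, pts))
    dp <- ifelse(up, interp_p1(diffuse$mesh, diffuse$p_F, pts),
                 interp_p1(diffuse$mesh, diffuse$p_P, pts))
    ok <- !is.na(sp) & !is.na(dp)
    res$pressure <- sqrt(sum((sp - dp)[ok]^2)) / sqrt(sum(sp[ok]^2))
  }
  data.frame(field = names(res), rel_l2 = unlist(res), row.names = NULL)
}

#' Manufactured-solution convergence orders
#'
#' Solves a manufactured problem on a sequence of uniformly refined unit
#' squares and returns the least-squares slope of log L2-error vs log h.
#' Problems: `"darcy"` (P1 Poisson), `"transport"` (P2 diffusion),
#' `"elasticity"` (P1 vector), `"stokes"` (MINI/P1, stream-function
#' manufactured solution).
#'
#' @param problem one of `"stokes"`, `"darcy"`, `"elasticity"`, `"transport"`.
#' @param h_seq decreasing mesh sizes (at least 3).
#' @return list with `h`, `errors`, and the observed `order`.
#' @export
manufactured_convergence <- function(problem = c("darcy", "transport",
                                                 "elasticity", "stokes"),
                                     h_seq = c(0.2, 0.1, 0.05)) {
  problem <- match.arg(problem)
  stopifnot(length(h_seq) >= 3)
  errs <- vapply(h_seq, function(h) manufactured_error(problem, h), 0)
  fit <- stats::lm(log(errs) ~ log(h_seq))
  list(h = h_seq, errors = errs, order = unname(stats::coef(fit)[2]))
}

manufactured_error <- function(problem, h) {
  m <- mesh_rect_union(list(c(0, 1, 0, 1)), h)
  qr <- quad_rule(); eg <- mesh_element_geometry(m)
  xq <- eg$x %*% t(qr$lambda); yq <- eg$y %*% t(qr$lambda)
  if (problem %in% c("darcy", "transport")) {
    sp <- fem_space(m, if (problem == "darcy") "P1" else "P2")
    K <- op_stiffness(sp)
    f <- 2 * pi^2 * sin(pi * xq) * sin(pi * yq)
    bd <- space_boundary_dofs(sp, "wall")
    u <- solve_linear(K, op_load(sp, f), list(dofs = bd, values = 0))
    return(fem_l2_error(sp, u, function(x, y) sin(pi * x) * sin(pi * y)))
  }
  if (problem == "elasticity") {
    mu <- 1; lam <- 1
    sp <- fem_space(m, "P1")
    E11 <- fem_op(sp, sp, 1, 1); E22 <- fem_op(sp, sp, 2, 2)
    E21 <- fem_op(sp, sp, 2, 1)
    Axx <- mu * (2 * E11 + E22) + lam * E11
    Ayy <- mu * (2 * E22 + E11) + lam * E22
    Axy <- mu * E21 + lam * Matrix::t(E21)
    A <- rbind(cbind(Axx, Axy), cbind(Matrix::t(Axy), Ayy))
    s <- sin(pi * xq); S <- sin(pi * yq); cc <- cos(pi * xq); C <- cos(pi * yq)
    fx <- 2 * mu * pi^2 * s * S - (mu + lam) * pi^2 * (cc * C - s * S)
    b <- c(op_load(sp, fx), op_load(sp, fx))
    bd <- space_boundary_dofs(sp, "wall")
    u <- solve_linear(A, b, list(dofs = c(bd, sp$ndof + bd), values = 0))
    ex <- fem_l2_error(sp, u[seq_len(sp$ndof)],
                       function(x, y) sin(pi * x) * sin(pi * y))
    ey <- fem_l2_error(sp, u[sp$ndof + seq_len(sp$ndof)],
                       function(x, y) sin(pi * x) * sin(pi * y))
    return(sqrt(ex^2 + ey^2))
  }
  # stokes: psi = x^2(1-x)^2 y^2(1-y)^2, u = (psi_y, -psi_x), p = x^3 + y^3
  mini <- fem_space(m, "MINI"); p1 <- fem_space(m, "P1")
  X2 <- function(t) t^2 * (1 - t)^2
  X2p <- function(t) 2 * t * (1 - t) * (1 - 2 * t)
  X2pp <- function(t) 2 * (6 * t^2 - 6 * t + 1)
  X2ppp <- function(t) 12 * (2 * t - 1)
  u1 <- function(x, y) X2(x) * X2p(y)
  u2 <- function(x, y) -X2p(x) * X2(y)
  # mu = 1: f = -lap u + grad p
  lap_u1 <- X2pp(xq) * X2p(yq) + X2(xq) * X2ppp(yq)
  lap_u2 <- -(X2ppp(xq) * X2(yq) + X2p(xq) * X2pp(yq))
  f1 <- -lap_u1 + 3 * xq^2
  f2 <- -lap_u2 + 3 * yq^2
  nm <- mini$ndof; nv <- p1$ndof
  V11 <- fem_op(mini, mini, 1, 1); V22 <- fem_op(mini, mini, 2, 2)
  Avv <- V11 + V22
  Bx <- fem_op(mini, p1, 1, 0); By <- fem_op(mini, p1, 2, 0)
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nv, nv))
  A <- rbind(cbind(Avv, Avv * 0, -Bx),
             cbind(Avv * 0, Avv, -By),
             cbind(Matrix::t(Bx), Matrix::t(By), Z))
  b <- c(op_load(mini, f1), op_load(mini, f2), rep(0, nv))
  bd <- space_boundary_dofs(mini, "wall")
  # pin one pressure dof (velocity Dirichlet everywhere -> p up to constant)
  constraints <- list(dofs = c(bd, nm + bd, 2L * nm + 1L),
                      values = c(rep(0, 2 * length(bd)), 0))
  sol <- solve_linear(A, b, constraints)
  e1 <- fem_l2_error(mini, sol[seq_len(nm)], u1)
  e2 <- fem_l2_error(mini, sol[nm + seq_len(nm)], u2)
  sqrt(e1^2 + e2^2)
}
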
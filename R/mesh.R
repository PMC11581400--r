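#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve lu
#' @importFrom stats uniroot
#' @importFrom utils capture.output
NULL

# Node coordinates are in cm throughout (CGS units).

#' Create a triangular mesh object
#'
#' Builds a conforming triangulation object from node coordinates and a
#' connectivity table. Triangles are re-oriented counter-clockwise, boundary
#' edges (edges adjacent to exactly one triangle) are extracted, and boundary
#' tags are assigned by the optional `tagger` function.
#'
#' @param nodes numeric matrix (n x 2) of node coordinates in cm.
#' @param tri integer matrix (nt x 3) of node indices per triangle.
#' @param tagger optional function taking a matrix of edge midpoints (m x 2)
#'   and returning a character vector of boundary tags (e.g. "inlet",
#'   "outlet", "top_wall", "wall").
#' @return an object of class `sf_mesh` with fields `nodes`, `tri`,
#'   `boundary` (list of `edges`, `tag`) and the stored `tagger`.
#' @export
mesh_create <- function(nodes, tri, tagger = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(tri) <- "integer"
  # orient CCW
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(det2 == 0)) stop("degenerate (zero-area) triangle in mesh")
  flip <- det2 < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]
  m <- structure(list(nodes = nodes, tri = tri, tagger = tagger),
                 class = "sf_mesh")
  m$boundary <- mesh_boundary(m)
  m
}

#' @export
print.sf_mesh <- function(x, ...) {
  cat(sprintf("<sf_mesh> %d nodes, %d triangles, %d boundary edges\n",
              nrow(x$nodes), nrow(x$tri), nrow(x$boundary$edges)))
  if (length(x$boundary$tag))
    print(table(x$boundary$tag))
  invisible(x)
}

# Encode an undirected edge (i,j) as a single double key.
edge_key <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  a * 2^26 + b
}

# All (directed per-triangle) edges: rows = 3*nt, columns from/to.
tri_edges <- function(tri) {
  rbind(tri[, c(2, 3)], tri[, c(3, 1)], tri[, c(1, 2)])
}

mesh_boundary <- function(mesh) {
  ed <- tri_edges(mesh$tri)
  key <- edge_key(ed[, 1], ed[, 2])
  cnt <- table(key)
  bkey <- as.numeric(names(cnt)[cnt == 1L])
  sel <- match(bkey, key)
  edges <- ed[sel, , drop = FALSE]
  tag <- rep("wall", nrow(edges))
  if (!is.null(mesh$tagger) && nrow(edges)) {
    mid <- (mesh$nodes[edges[, 1], , drop = FALSE] +
              mesh$nodes[edges[, 2], , drop = FALSE]) / 2
    tag <- mesh$tagger(mid)
  }
  list(edges = edges, tag = tag)
}

#' Per-element geometry: areas and P1 basis gradients
#'
#' @param mesh an `sf_mesh`.
#' @return list with `area` (nt), `gx`, `gy` (nt x 3 matrices of the constant
#'   gradients of the three nodal P1 basis functions on each element).
#' @keywords internal
mesh_element_geometry <- function(mesh) {
  nd <- mesh$nodes; tr <- mesh$tri
  x1 <- nd[tr[, 1], 1]; y1 <- nd[tr[, 1], 2]
  x2 <- nd[tr[, 2], 1]; y2 <- nd[tr[, 2], 2]
  x3 <- nd[tr[, 3], 1]; y3 <- nd[tr[, 3], 2]
  det2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det2 / 2
  # grad lambda_i, lambda_i barycentric wrt node i
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det2
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det2
  list(area = area, gx = gx, gy = gy,
       x = cbind(x1, x2, x3), y = cbind(y1, y2, y3))
}

#' Total mesh area
#' @param mesh an `sf_mesh`.
#' @return total area in cm^2.
#' @export
mesh_area <- function(mesh) sum(mesh_element_geometry(mesh)$area)

#' Unique edge enumeration (for P2 spaces)
#'
#' @param mesh an `sf_mesh`.
#' @return list with `edges` (ne x 2 node pairs, i < j) and `tri2edge`
#'   (nt x 3; edge k of a triangle is opposite local vertex k).
#' @keywords internal
mesh_edges <- function(mesh) {
  ed <- tri_edges(mesh$tri)           # rows: opposite v1, v2, v3 stacked
  key <- edge_key(ed[, 1], ed[, 2])
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  nt <- nrow(mesh$tri)
  tri2edge <- matrix(idx, nt, 3)
  sel <- match(ukey, key)
  edges <- cbind(pmin(ed[sel, 1], ed[sel, 2]), pmax(ed[sel, 1], ed[sel, 2]))
  list(edges = edges, tri2edge = tri2edge)
}

# ---------------------------------------------------------------------------
# Structured base mesh over a union of axis-aligned rectangles
# ---------------------------------------------------------------------------

#' Structured triangular mesh over a union of axis-aligned rectangles
#'
#' A tensor grid is laid over the bounding box, with grid lines forced at
#' every rectangle edge so that all rectangle boundaries are mesh-conforming;
#' cells whose centre falls inside one of the rectangles are kept and split
#' into two triangles.
#'
#' @param rects list of numeric vectors `c(x0, x1, y0, y1)`.
#' @param h target cell size in cm.
#' @param tagger optional boundary tagging function (see [mesh_create()]).
#' @return an `sf_mesh`.
#' @export
mesh_rect_union <- function(rects, h, tagger = NULL) {
  stopifnot(length(rects) >= 1, h > 0)
  xs <- ys <- numeric(0)
  for (r in rects) { xs <- c(xs, r[1], r[2]); ys <- c(ys, r[3], r[4]) }
  forced_x <- sort(unique(xs)); forced_y <- sort(unique(ys))
  grid_1d <- function(forced, h) {
    out <- numeric(0)
    for (k in seq_len(length(forced) - 1)) {
      a <- forced[k]; b <- forced[k + 1]
      n <- max(1L, round((b - a) / h))
      out <- c(out, seq(a, b, length.out = n + 1L)[-(n + 1L)])
    }
    c(out, forced[length(forced)])
  }
  gx <- grid_1d(forced_x, h); gy <- grid_1d(forced_y, h)
  nx <- length(gx); ny <- length(gy)
  node_id <- matrix(seq_len(nx * ny), nx, ny)
  nodes <- cbind(rep(gx, ny), rep(gy, each = nx))
  # keep cells whose center is inside some rectangle
  cx <- (gx[-nx] + gx[-1]) / 2; cy <- (gy[-ny] + gy[-1]) / 2
  CX <- matrix(cx, nx - 1, ny - 1)
  CY <- matrix(cy, nx - 1, ny - 1, byrow = TRUE)
  inside <- matrix(FALSE, nx - 1, ny - 1)
  for (r in rects)
    inside <- inside | (CX > r[1] & CX < r[2] & CY > r[3] & CY < r[4])
  ci <- which(inside, arr.ind = TRUE)
  i <- ci[, 1]; j <- ci[, 2]
  v00 <- node_id[cbind(i, j)];     v10 <- node_id[cbind(i + 1, j)]
  v01 <- node_id[cbind(i, j + 1)]; v11 <- node_id[cbind(i + 1, j + 1)]
  tri <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nx * ny); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  mesh_create(nodes[used, , drop = FALSE], tri, tagger = tagger)
}

# ---------------------------------------------------------------------------
# Conforming longest-edge bisection refinement (Rivara)
# ---------------------------------------------------------------------------

#' Refine marked elements by conforming longest-edge bisection
#'
#' Longest edges of marked elements are split; the split set is closed under
#' the Rivara rule (any element containing a split edge must also split its
#' own longest edge), which guarantees a conforming result in one pass.
#'
#' @param mesh an `sf_mesh`.
#' @param marked integer or logical vector of elements to refine.
#' @return the refined `sf_mesh`.
#' @export
mesh_refine <- function(mesh, marked) {
  if (is.logical(marked)) marked <- which(marked)
  if (!length(marked)) return(mesh)
  nd <- mesh$nodes; tr <- mesh$tri
  nt <- nrow(tr)
  em <- mesh_edges(mesh)
  ne <- nrow(em$edges)
  elen <- sqrt(rowSums((nd[em$edges[, 1], , drop = FALSE] -
                          nd[em$edges[, 2], , drop = FALSE])^2))
  # longest edge per element (ties: larger edge index, deterministic)
  L <- matrix(elen[em$tri2edge], nt, 3)
  longest <- max.col(L, ties.method = "last")
  longest_edge <- em$tri2edge[cbind(seq_len(nt), longest)]
  split <- logical(ne)
  split[longest_edge[marked]] <- TRUE
  repeat {
    has_split <- matrix(split[em$tri2edge], nt, 3)
    need <- rowSums(has_split) > 0 & !split[longest_edge]
    if (!any(need)) break
    split[longest_edge[need]] <- TRUE
  }
  sidx <- which(split)
  mid_id <- integer(ne)
  mids <- (nd[em$edges[sidx, 1], , drop = FALSE] +
             nd[em$edges[sidx, 2], , drop = FALSE]) / 2
  mid_id[sidx] <- nrow(nd) + seq_along(sidx)
  nodes_new <- rbind(nd, mids)

  bisect <- function(v, e_mid) {
    # v = c(v1,v2,v3) with local edge k opposite v_k; returns list of tris
    # split by the element's longest local edge first, then children by
    # their inherited split edges.
    m <- e_mid  # midpoint node id per local edge (0 if unsplit)
    lens <- c(sum((nodes_new[v[2], ] - nodes_new[v[3], ])^2),
              sum((nodes_new[v[3], ] - nodes_new[v[1], ])^2),
              sum((nodes_new[v[1], ] - nodes_new[v[2], ])^2))
    lk <- which(lens == max(lens)); lk <- lk[length(lk)]  # same tie-break as closure
    if (m[lk] == 0L) {
      if (any(m != 0L)) stop("refinement closure failed (hanging node)")
      return(list(v))
    }
    o <- lk; a <- (lk %% 3L) + 1L; b <- (a %% 3L) + 1L
    # longest edge connects v[a], v[b]; apex v[o]; midpoint m[lk]
    c1 <- c(v[o], v[a], m[lk])  # edge (v[o],v[a]) was local edge b
    c2 <- c(v[o], m[lk], v[b])  # edge (v[o],v[b]) was local edge a
    out <- list()
    if (m[b] != 0L) {
      out <- c(out, list(c(v[o], m[b], m[lk]), c(m[b], v[a], m[lk])))
    } else out <- c(out, list(c1))
    if (m[a] != 0L) {
      out <- c(out, list(c(v[o], m[lk], m[a]), c(m[lk], v[b], m[a])))
    } else out <- c(out, list(c2))
    out
  }

  emid_tab <- matrix(mid_id[em$tri2edge], nt, 3)
  touched <- which(rowSums(emid_tab > 0L) > 0L)
  keep <- tr[setdiff(seq_len(nt), touched), , drop = FALSE]
  newtris <- vector("list", length(touched))
  for (k in seq_along(touched)) {
    e <- touched[k]
    newtris[[k]] <- bisect(tr[e, ], emid_tab[e, ])
  }
  newtris <- do.call(rbind, lapply(newtris, function(l) do.call(rbind, l)))
  out <- mesh_create(nodes_new, rbind(keep, newtris), tagger = mesh$tagger)
  # new nodes are midpoints of these edges (for P1 interpolation to the
  # refined mesh)
  attr(out, "lineage") <- em$edges[sidx, , drop = FALSE]
  out
}

# ---------------------------------------------------------------------------
# Point location and interpolation
# ---------------------------------------------------------------------------

#' Locate points in a mesh
#'
#' @param mesh an `sf_mesh`.
#' @param pts m x 2 matrix of query points.
#' @param tol barycentric tolerance for membership.
#' @return list with `elem` (element index or NA) and `bary` (m x 3).
#' @export
mesh_locate <- function(mesh, pts, tol = 1e-10) {
  pts <- matrix(pts, ncol = 2)
  eg <- mesh_element_geometry(mesh)
  m <- nrow(pts)
  elem <- rep(NA_integer_, m)
  bary <- matrix(NA_real_, m, 3)
  # barycentric coords of point p in element e:
  # lambda_i(p) = lambda_i(x1,y1) + gx_i (px-x1) + gy_i (py-y1)
  for (p in seq_len(m)) {
    dx <- pts[p, 1] - eg$x[, 1]; dy <- pts[p, 2] - eg$y[, 1]
    l1 <- 1 + eg$gx[, 1] * dx + eg$gy[, 1] * dy
    l2 <- eg$gx[, 2] * dx + eg$gy[, 2] * dy
    l3 <- eg$gx[, 3] * dx + eg$gy[, 3] * dy
    ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(ok)) {
      e <- ok[1]
      elem[p] <- e
      bary[p, ] <- c(l1[e], l2[e], l3[e])
    }
  }
  list(elem = elem, bary = bary)
}
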
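# Channel-architecture geometry for the 0.9 x 0.42 cm scaffold domain.
# Origin at the bottom-left of the rectangle; the two outlet stubs extend
# below y = 0. All lengths in cm (CGS units).

# ---------------------------------------------------------------------------
# polygon utilities (all polygons are 2-column matrices, vertices in order)
# ---------------------------------------------------------------------------

poly_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# clip polygon (convex or not, but convex guarantees a clean result) against
# the half-plane a.x + b.y <= c  (Sutherland-Hodgman step)
clip_halfplane <- function(p, a, b, cc) {
  if (is.null(p) || nrow(p) < 3) return(NULL)
  n <- nrow(p)
  d <- a * p[, 1] + b * p[, 2] - cc
  out <- matrix(0, 2 * n, 2); m <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0; djn <- d[j] <= 0
    if (din) { m <- m + 1; out[m, ] <- p[i, ] }
    if (xor(din, djn)) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1; out[m, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  if (m < 3) return(NULL)
  out[seq_len(m), , drop = FALSE]
}

clip_rect <- function(p, x0, x1, y0, y1) {
  p <- clip_halfplane(p, -1, 0, -x0)
  p <- clip_halfplane(p, 1, 0, x1)
  p <- clip_halfplane(p, 0, -1, -y0)
  clip_halfplane(p, 0, 1, y1)
}

# intersection of two convex polygons (q must be convex, CCW)
clip_convex <- function(p, q) {
  if (is.null(p) || is.null(q)) return(NULL)
  # ensure q is CCW
  n <- nrow(q); i2 <- c(2:n, 1)
  if (sum(q[, 1] * q[i2, 2] - q[i2, 1] * q[, 2]) < 0) q <- q[n:1, , drop = FALSE]
  n <- nrow(q)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- q[j, 1] - q[i, 1]; ey <- q[j, 2] - q[i, 2]
    # inside (left of CCW edge): -ey*(x-xi) + ex*(y-yi) >= 0
    p <- clip_halfplane(p, ey, -ex, ey * q[i, 1] - ex * q[i, 2])
    if (is.null(p)) return(NULL)
  }
  p
}

# union area of convex polygons by inclusion-exclusion up to triples
# (valid when no four polygons share area, as in the layouts built here)
union_area_convex <- function(polys) {
  np <- length(polys)
  if (!np) return(0)
  tot <- sum(vapply(polys, poly_area, 0))
  if (np == 1) return(tot)
  bb <- t(vapply(polys, function(p) c(range(p[, 1]), range(p[, 2])), numeric(4)))
  pairs <- list()
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
        bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
    pq <- clip_convex(polys[[i]], polys[[j]])
    if (!is.null(pq)) {
      a <- poly_area(pq)
      if (a > 0) { tot <- tot - a; pairs[[length(pairs) + 1]] <- c(i, j) }
    }
  }
  if (length(pairs) > 1) {
    trios <- character(0)
    for (u in seq_len(length(pairs) - 1)) for (v in (u + 1):length(pairs)) {
      trio <- sort(unique(c(pairs[[u]], pairs[[v]])))
      if (length(trio) != 3) next
      key <- paste(trio, collapse = "-")
      if (key %in% trios) next
      trios <- c(trios, key)
      pq <- clip_convex(clip_convex(polys[[trio[1]]], polys[[trio[2]]]),
                        polys[[trio[3]]])
      if (!is.null(pq)) tot <- tot + poly_area(pq)
    }
  }
  tot
}

# half-open even-odd point-in-polygon (lower/left boundary inclusive by the
# crossing convention); vectorized over points
points_in_poly <- function(x, y, p) {
  inside <- logical(length(x))
  n <- nrow(p)
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

points_in_any <- function(x, y, polys) {
  inside <- logical(length(x))
  for (p in polys) {
    bbx <- range(p[, 1]); bby <- range(p[, 2])
    cand <- which(!inside & x >= bbx[1] & x <= bbx[2] &
                    y >= bby[1] & y <= bby[2])
    if (length(cand))
      inside[cand] <- points_in_poly(x[cand], y[cand], p)
  }
  inside
}

# ribbon of half-width w/2 around a polyline, split into one convex quad per
# segment with shared miter edges at interior vertices (no overlap, no gap)
ribbon_quads <- function(pts, w) {
  ns <- nrow(pts) - 1
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  t <- d / len                       # unit tangents
  nrm <- cbind(-t[, 2], t[, 1])      # left normals
  off <- matrix(0, nrow(pts), 2)
  off[1, ] <- nrm[1, ] * w / 2
  off[nrow(pts), ] <- nrm[ns, ] * w / 2
  if (ns > 1) for (i in 2:ns) {
    m <- nrm[i - 1, ] + nrm[i, ]
    m <- m / sqrt(sum(m^2))
    off[i, ] <- m * (w / 2) / sum(m * nrm[i, ])   # miter offset
  }
  lapply(seq_len(ns), function(i) {
    rbind(pts[i, ] + off[i, ], pts[i + 1, ] + off[i + 1, ],
          pts[i + 1, ] - off[i + 1, ], pts[i, ] - off[i, ])
  })
}

# axis-aligned rectangle polygon
rect_poly <- function(x0, x1, y0, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))

# regular flat-top hexagon, center (cx,cy), apothem a (half across-flats)
hex_poly <- function(cx, cy, a) {
  R <- 2 * a / sqrt(3)
  ang <- pi / 180 * c(0, 60, 120, 180, 240, 300)
  cbind(cx + R * cos(ang), cy + R * sin(ang))
}

# ---------------------------------------------------------------------------
# architectures
# ---------------------------------------------------------------------------

ARCHITECTURES <- c("straight", "bifurcating", "hexagonal",
                   "narrow_straight", "narrow_zigzag", "two_layer_oracle")

default_layout <- function() {
  list(
    domain_width  = 0.9,   # cm
    domain_height = 0.42,  # cm
    horizontal_channel_width = 0.06,  # top and bottom gasket channels
    outlet_height = 0.1, outlet_width = 0.06,
    outlet_centers = c(0.225, 0.675),
    inlet_width = 0.06, inlet_centers = c(0.225, 0.675),
    straight_width = 0.06, straight_count = 3,
    zigzag_count = 9, zigzag_segments = 4, zigzag_halfamp = 0.0375,
    bif_levels = 2, bif_taper = 0.5,
    bif_spread = c(0.12, 0.06),   # horizontal reach per bifurcation level
    hex_flat = 0.15   # across-flats size of the hexagon tiling
  )
}

#' Construct a scaffold channel architecture
#'
#' Builds one of the supported channel-network layouts on the
#' 0.9 x 0.42 cm scaffold domain (with two 0.06 x 0.1 cm outlet stubs below
#' the bottom gasket channel). All architectures are calibrated so that the
#' channel area between the two horizontal gasket channels equals the
#' straight-architecture reference area (3 vertical channels of width
#' 0.06 cm), enforced numerically to a relative tolerance of 1e-6 on the
#' sharp (polygonal) areas.
#'
#' @param name one of `"straight"`, `"bifurcating"`, `"hexagonal"`,
#'   `"narrow_straight"`, `"narrow_zigzag"`, `"two_layer_oracle"`.
#' @param overrides named list overriding layout parameters (see
#'   `scaffoldflow:::default_layout` for names). Overriding a width that is
#'   normally calibrated (e.g. `zigzag_width`) fixes it; an error is raised
#'   if the fixed value misses the equal-area constraint by more than 1%.
#' @return an object of class `sf_geometry` with the channel polygons,
#'   boundary partition (inlets / outlets / exterior walls) and exact sharp
#'   areas (`$areas`).
#' @export
make_architecture <- function(name, overrides = list()) {
  name <- match.arg(name, ARCHITECTURES)
  L <- utils::modifyList(default_layout(), overrides)
  W <- L$domain_width; H <- L$domain_height; hw <- L$horizontal_channel_width
  band <- c(hw, H - hw)
  bh <- band[2] - band[1]
  A_ref <- L$straight_count * L$straight_width * bh   # 0.054 cm^2

  stub_x <- lapply(L$outlet_centers,
                   function(cc) c(cc - L$outlet_width / 2, cc + L$outlet_width / 2))
  inlet_x <- lapply(L$inlet_centers,
                    function(cc) c(cc - L$inlet_width / 2, cc + L$inlet_width / 2))

  horizontals <- list(rect_poly(0, W, 0, hw), rect_poly(0, W, band[2], H))
  stubs <- lapply(stub_x, function(s) rect_poly(s[1], s[2], -L$outlet_height, 0))

  mode <- "channels"; pockets <- list(); interior <- list()
  calibrated <- NA_real_

  band_quads_area <- function(quads) {
    qs <- lapply(quads, clip_rect, x0 = 0, x1 = W, y0 = band[1], y1 = band[2])
    union_area_convex(Filter(Negate(is.null), qs))
  }

  if (name == "straight") {
    wch <- L$straight_width
    centers <- W * seq_len(L$straight_count) / (L$straight_count + 1)
    if (L$straight_count == 3) centers <- c(0.225, 0.45, 0.675)
    interior <- lapply(centers, function(cc)
      rect_poly(cc - wch / 2, cc + wch / 2, band[1], band[2]))
    calibrated <- wch
  } else if (name == "narrow_straight") {
    # one third of the straight vertical-channel width; count restores area
    wch <- if (!is.null(overrides$narrow_width)) overrides$narrow_width else
      L$straight_width / 3
    n <- round(A_ref / (wch * bh))
    centers <- W * seq_len(n) / (n + 1)
    interior <- lapply(centers, function(cc)
      rect_poly(cc - wch / 2, cc + wch / 2, band[1], band[2]))
    calibrated <- wch
  } else if (name == "narrow_zigzag") {
    n <- L$zigzag_count; nseg <- L$zigzag_segments; amp <- L$zigzag_halfamp
    centers <- W * seq_len(n) / (n + 1)
    yv <- seq(band[1] - 0.01, band[2] + 0.01, length.out = nseg + 1)
    make_quads <- function(w) {
      unlist(lapply(centers, function(cc) {
        xo <- cc + amp * rep_len(c(-1, 1), nseg + 1)
        ribbon_quads(cbind(xo, yv), w)
      }), recursive = FALSE)
    }
    if (!is.null(overrides$zigzag_width)) {
      wch <- overrides$zigzag_width
    } else {
      wch <- uniroot(function(w) band_quads_area(make_quads(w)) - A_ref,
                     c(1e-4, 0.05), tol = 1e-10)$root
    }
    interior <- make_quads(wch); calibrated <- wch
  } else if (name == "bifurcating") {
    # two symmetric trees with `bif_levels` bifurcation levels, spread to
    # cover the domain width; widths taper by bif_taper per generation;
    # every segment is overshot by half its width so junctions stay
    # connected
    make_quads <- function(w0) {
      quads <- list()
      nlev <- L$bif_levels
      dy <- (band[2] - band[1]) / (nlev + 1)
      offs <- rep_len(L$bif_spread, nlev)   # horizontal spread per level
      for (cc in c(0.225, 0.675)) {
        segs <- list(list(p = c(cc, band[2]), q = c(cc, band[2] - dy), w = w0))
        tips <- list(cc)
        for (g in seq_len(nlev)) {
          y0 <- band[2] - g * dy; y1 <- y0 - dy
          w <- w0 * L$bif_taper^g
          newtips <- list()
          for (x0 in tips) for (s in c(-1, 1)) {
            x1 <- x0 + s * offs[g]
            segs <- c(segs, list(list(p = c(x0, y0), q = c(x1, y1), w = w)))
            newtips <- c(newtips, list(x1))
          }
          tips <- newtips
        }
        for (sg in segs) {
          d <- sg$q - sg$p; d <- d / sqrt(sum(d^2))
          p <- sg$p - d * sg$w / 2; q <- sg$q + d * sg$w / 2
          quads <- c(quads, ribbon_quads(rbind(p, q), sg$w))
        }
      }
      quads
    }
    if (!is.null(overrides$bif_width)) {
      wch <- overrides$bif_width
    } else {
      wch <- uniroot(function(w) band_quads_area(make_quads(w)) - A_ref,
                     c(1e-3, 0.12), tol = 1e-10)$root
    }
    interior <- make_quads(wch); calibrated <- wch
  } else if (name == "hexagonal") {
    mode <- "pockets"
    f <- L$hex_flat; a0 <- f / 2; s <- f / sqrt(3)
    make_pockets <- function(t) {
      sc <- (a0 - t) / a0
      pk <- list()
      jmax <- ceiling(W / (1.5 * s)) + 1
      for (j in 0:jmax) {
        cx <- j * 1.5 * s
        ys <- if (j %% 2 == 0) seq(band[1] + f / 2, band[2], by = f) else
          seq(band[1], band[2] + f / 2, by = f)
        for (cy in ys) {
          hp <- clip_rect(hex_poly(cx, cy, a0 * sc), 0, W, band[1], band[2])
          if (!is.null(hp) && poly_area(hp) > 1e-12) pk[[length(pk) + 1]] <- hp
        }
      }
      pk
    }
    pocket_chan_area <- function(t) {
      W * bh - sum(vapply(make_pockets(t), poly_area, 0))
    }
    if (!is.null(overrides$hex_channel_halfwidth)) {
      tch <- overrides$hex_channel_halfwidth
    } else {
      tch <- uniroot(function(t) pocket_chan_area(t) - A_ref,
                     c(1e-4, a0 * 0.45), tol = 1e-10)$root
    }
    pockets <- make_pockets(tch); calibrated <- 2 * tch
  } else if (name == "two_layer_oracle") {
    W <- if (!is.null(overrides$domain_width)) L$domain_width else 0.45
    H <- if (!is.null(overrides$domain_height)) L$domain_height else 0.21
    yint <- if (!is.null(overrides$interface_y)) overrides$interface_y else H / 2
    g <- structure(list(
      architecture = name, W = W, H = H, band = c(0, yint),
      interface_y = yint, mode = "channels",
      horizontals = list(), stubs = list(),
      interior = list(rect_poly(0, W, yint, H)),
      pockets = list(), inlet_x = list(c(0, W)), stub_x = list(),
      layout = L, channel_width = NA_real_), class = "sf_geometry")
    g$areas <- list(domain = W * H, fluid = W * (H - yint),
                    interior = W * (H - yint), poro = W * yint)
    g$iface <- interface_segments(g)
    return(g)
  }

  interior_area <- if (mode == "channels") band_quads_area(interior) else
    W * bh - sum(vapply(pockets, poly_area, 0))
  if (abs(interior_area - A_ref) / A_ref > 0.01)
    stop(sprintf(
      "architecture '%s': channel area %.5f cm^2 misses the reference %.5f cm^2 by more than 1%%",
      name, interior_area, A_ref))

  A_horiz <- 2 * W * hw
  A_stub <- length(stubs) * L$outlet_width * L$outlet_height
  A_dom <- W * H + A_stub
  areas <- list(interior = interior_area, horizontals = A_horiz,
                stubs = A_stub, fluid = interior_area + A_horiz + A_stub,
                domain = A_dom,
                poro = A_dom - (interior_area + A_horiz + A_stub))

  g <- structure(list(
    architecture = name, W = W, H = H, band = band, mode = mode,
    horizontals = horizontals, stubs = stubs, interior = interior,
    pockets = pockets, inlet_x = inlet_x, stub_x = stub_x,
    layout = L, channel_width = calibrated, areas = areas),
    class = "sf_geometry")
  g$iface <- interface_segments(g)
  g
}

#' @export
print.sf_geometry <- function(x, ...) {
  cat(sprintf("<sf_geometry> %s: domain %.2f x %.2f cm, channel width %.4g cm\n",
              x$architecture, x$W, x$H, x$channel_width))
  cat(sprintf("  fluid area %.4f cm^2 (interior %.4f), poroelastic %.4f cm^2\n",
              x$areas$fluid, x$areas$interior, x$areas$poro))
  invisible(x)
}

#' Sharp channel indicator at arbitrary points
#'
#' @param geom an `sf_geometry`.
#' @param x,y coordinates of query points (cm).
#' @return logical vector: inside a channel (fluid) region.
#' @export
geometry_indicator <- function(geom, x, y) {
  if (geom$architecture == "two_layer_oracle")
    return(y > geom$interface_y)
  fl <- points_in_any(x, y, c(geom$horizontals, geom$stubs))
  # closed band: points exactly on the gasket lines y = band[1], band[2]
  # must still be tested against the interior channel polygons (whose
  # bottom-inclusive edges claim them), or channel mouths would be walled
  inband <- y >= geom$band[1] & y <= geom$band[2] & x > 0 & x < geom$W
  if (geom$mode == "channels") {
    cand <- which(!fl & inband)
    if (length(cand))
      fl[cand] <- points_in_any(x[cand], y[cand], geom$interior)
  } else {
    cand <- which(inband & !fl)
    if (length(cand))
      fl[cand] <- !points_in_any(x[cand], y[cand], geom$pockets)
  }
  fl
}

#' Rasterize the sharp channel indicator onto mesh nodes
#'
#' Sets chi = 1 at nodes inside any channel polygon and 0 elsewhere, using a
#' half-open even-odd membership rule to break ties for nodes exactly on a
#' polygon edge.
#'
#' @param geom an `sf_geometry`.
#' @param mesh an `sf_mesh` covering the domain.
#' @return numeric vector of 0/1 values, one per mesh node.
#' @export
rasterize_indicator <- function(geom, mesh) {
  indicator_at_nodes(geom, mesh)
}

# nodal sharp indicator with domain-boundary nodes nudged inward
indicator_at_nodes <- function(geom, mesh) {
  nd <- mesh$nodes
  # sample domain-boundary nodes just inside the domain, so fluid regions
  # touching the exterior walls are not shaved by the point-in-polygon rule
  be <- mesh$boundary$edges
  if (nrow(be)) {
    d <- nd[be[, 2], , drop = FALSE] - nd[be[, 1], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    nin <- cbind(-d[, 2], d[, 1]) / len   # inward normal (CCW triangles)
    acc <- matrix(0, nrow(nd), 2)
    for (k in 1:2) {
      acc[, 1] <- acc[, 1] + as.vector(Matrix::sparseMatrix(
        i = be[, k], j = rep(1L, nrow(be)), x = nin[, 1], dims = c(nrow(nd), 1)))
      acc[, 2] <- acc[, 2] + as.vector(Matrix::sparseMatrix(
        i = be[, k], j = rep(1L, nrow(be)), x = nin[, 2], dims = c(nrow(nd), 1)))
    }
    nb <- sqrt(rowSums(acc^2))
    sel <- nb > 0
    nd <- nd + 1e-7 * acc / pmax(nb, 1)
    nd[!sel, ] <- mesh$nodes[!sel, ]
  }
  as.numeric(geometry_indicator(geom, nd[, 1], nd[, 2]))
}

# sharp indicator softened to a one-cell linear ramp of the signed distance
# to the channel boundary; removes the O(h) node-alignment bias of point
# sampling while staying within one element of the sharp indicator
rasterize_ramp <- function(geom, mesh) {
  chi <- indicator_at_nodes(geom, mesh)
  d <- geometry_boundary_dist(geom, mesh$nodes[, 1], mesh$nodes[, 2])
  eg <- mesh_element_geometry(mesh)
  nv <- nrow(mesh$nodes)
  num <- as.vector(Matrix::sparseMatrix(
    i = as.vector(mesh$tri), j = rep(1L, 3 * nrow(mesh$tri)),
    x = rep(eg$area, 3), dims = c(nv, 1)))
  den <- as.vector(Matrix::sparseMatrix(
    i = as.vector(mesh$tri), j = rep(1L, 3 * nrow(mesh$tri)),
    x = rep(1, 3 * nrow(mesh$tri)), dims = c(nv, 1)))
  hloc <- sqrt(2 * num / pmax(den, 1))       # local element size at nodes
  s <- ifelse(chi > 0.5, 1, -1)
  pmin(1, pmax(0, 0.5 + s * d / (2 * hloc)))
}

#' Boundary tagging function for a geometry
#'
#' Tags: `"inlet"` (top segments over the inlet openings), `"outlet"`
#' (bottoms of the outlet stubs; for the two-layer benchmark, the fluid-layer
#' sides), `"top_wall"` (remaining top boundary, where the oxygen
#' concentration is clamped to zero), `"wall"` (all other exterior walls).
#'
#' @param geom an `sf_geometry`.
#' @return a function mapping edge midpoints to tags, for [mesh_create()].
#' @export
geometry_tagger <- function(geom) {
  tol <- 1e-9
  if (geom$architecture == "two_layer_oracle") {
    H <- geom$H; W <- geom$W; yint <- geom$interface_y
    return(function(mid) {
      tag <- rep("wall", nrow(mid))
      tag[abs(mid[, 2] - H) < tol] <- "inlet"
      tag[(abs(mid[, 1]) < tol | abs(mid[, 1] - W) < tol) &
            mid[, 2] > yint] <- "outlet"
      tag
    })
  }
  H <- geom$H; ylo <- -geom$layout$outlet_height
  inlx <- geom$inlet_x
  function(mid) {
    tag <- rep("wall", nrow(mid))
    top <- abs(mid[, 2] - H) < tol
    tag[top] <- "top_wall"
    for (rr in inlx)
      tag[top & mid[, 1] > rr[1] - tol & mid[, 1] < rr[2] + tol] <- "inlet"
    tag[abs(mid[, 2] - ylo) < tol] <- "outlet"
    tag
  }
}

#' Base (unrefined) mesh for a scaffold geometry
#'
#' @param geom an `sf_geometry`.
#' @param h0 target element size in cm.
#' @return an `sf_mesh` with tagged boundary.
#' @export
scaffold_base_mesh <- function(geom, h0 = 0.015) {
  if (geom$architecture == "two_layer_oracle") {
    return(mesh_rect_union(list(c(0, geom$W, 0, geom$H)), h0,
                           tagger = geometry_tagger(geom)))
  }
  rects <- c(list(c(0, geom$W, 0, geom$H)),
             lapply(geom$stub_x, function(s)
               c(s[1], s[2], -geom$layout$outlet_height, 0)))
  mesh_rect_union(rects, h0, tagger = geometry_tagger(geom))
}

#' Check the equal-channel-area constraint across architectures
#'
#' @param geoms non-empty list of `sf_geometry` objects.
#' @return data.frame with per-geometry sharp channel areas and relative
#'   deviation of the interior (between-gasket) channel area from the
#'   straight-architecture reference.
#' @export
equal_area_check <- function(geoms) {
  if (!length(geoms)) stop("equal_area_check: empty geometry list")
  ref <- default_layout()
  A_ref <- ref$straight_count * ref$straight_width *
    (0.42 - 2 * ref$horizontal_channel_width)
  data.frame(
    architecture = vapply(geoms, function(g) g$architecture, ""),
    interior_area_cm2 = vapply(geoms, function(g) g$areas$interior, 0),
    fluid_area_cm2 = vapply(geoms, function(g) g$areas$fluid, 0),
    poro_area_cm2 = vapply(geoms, function(g) g$areas$poro, 0),
    rel_deviation = vapply(geoms, function(g)
      (g$areas$interior - A_ref) / A_ref, 0)
  )
}

inside_domain <- function(geom, x, y) {
  if (geom$architecture == "two_layer_oracle")
    return(x > 0 & x < geom$W & y > 0 & y < geom$H)
  inr <- x > 0 & x < geom$W & y > 0 & y < geom$H
  for (s in geom$stub_x)
    inr <- inr | (x > s[1] & x < s[2] & y > -geom$layout$outlet_height & y < 0)
  inr
}

# true fluid/gel interface segments: polygon edges subdivided, pieces whose
# two sides are not exactly one fluid point and one in-domain gel point are
# dropped (this removes edges interior to the fluid union, e.g. miter joins
# and channel/gasket junctions, and the exterior walls), then contiguous
# interface pieces are merged back into long segments
interface_segments <- function(geom, piece = 0.003) {
  polys <- if (geom$architecture == "two_layer_oracle") geom$interior
  else if (geom$mode == "channels")
    c(geom$horizontals, geom$stubs, geom$interior)
  else c(geom$horizontals, geom$stubs, geom$pockets)
  E <- do.call(rbind, lapply(polys, function(p) {
    n <- nrow(p); i2 <- c(2:n, 1)
    cbind(p, p[i2, , drop = FALSE])
  }))
  len <- sqrt((E[, 3] - E[, 1])^2 + (E[, 4] - E[, 2])^2)
  E <- E[len > 1e-12, , drop = FALSE]; len <- len[len > 1e-12]
  k <- pmax(1L, ceiling(len / piece))
  eidx <- rep(seq_len(nrow(E)), k)
  tt <- unlist(lapply(k, function(m) (seq_len(m) - 0.5) / m))
  mx <- E[eidx, 1] + tt * (E[eidx, 3] - E[eidx, 1])
  my <- E[eidx, 2] + tt * (E[eidx, 4] - E[eidx, 2])
  dx <- (E[eidx, 3] - E[eidx, 1]) / len[eidx]
  dy <- (E[eidx, 4] - E[eidx, 2]) / len[eidx]
  eps <- 1e-6
  fl_l <- geometry_indicator(geom, mx - eps * dy, my + eps * dx)
  fl_r <- geometry_indicator(geom, mx + eps * dy, my - eps * dx)
  in_l <- inside_domain(geom, mx - eps * dy, my + eps * dx)
  in_r <- inside_domain(geom, mx + eps * dy, my - eps * dx)
  keep <- (fl_l & in_r & !fl_r) | (fl_r & in_l & !fl_l)
  segs <- list()
  for (e in unique(eidx[keep])) {
    sel <- eidx == e
    r <- rle(keep[sel])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    m <- sum(sel)
    for (q in which(r$values)) {
      t0 <- (starts[q] - 1) / m; t1 <- ends[q] / m
      segs[[length(segs) + 1]] <- c(
        E[e, 1] + t0 * (E[e, 3] - E[e, 1]), E[e, 2] + t0 * (E[e, 4] - E[e, 2]),
        E[e, 1] + t1 * (E[e, 3] - E[e, 1]), E[e, 2] + t1 * (E[e, 4] - E[e, 2]))
    }
  }
  do.call(rbind, segs)
}

# minimum distance from points to the fluid/gel interface (used by mesh
# adaptation and the ramp rasterization)
geometry_boundary_dist <- function(geom, x, y) {
  S <- geom$iface
  if (is.null(S)) S <- interface_segments(geom)
  d2 <- rep(Inf, length(x))
  for (k in seq_len(nrow(S))) {
    ax <- S[k, 1]; ay <- S[k, 2]; bx <- S[k, 3]; by <- S[k, 4]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 < 1e-24) { d2 <- pmin(d2, (x - ax)^2 + (y - ay)^2); next }
    t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    dd <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}
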
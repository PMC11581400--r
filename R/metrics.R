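# Comparison metrics: the insulin-support (chi_opt) area, field extrema,
# and 1D line profiles.

#' Area of the poroelastic region supporting uninhibited insulin production
#'
#' Computes `area_opt = int chi_opt (1 - phi) dV` by quadrature, where
#' `chi_opt = 1` wherever the oxygen concentration meets or exceeds the
#' uninhibited-insulin-production threshold `c_opt` (closed comparison,
#' `c >= c_opt`), together with the diffuse poroelastic area
#' `poro_area = int (1 - phi) dV` and the ratio `area_rel`.
#'
#' @param conc an `sf_concentration` (or a P2 coefficient vector).
#' @param pf the `sf_phasefield` on the same mesh.
#' @param c_opt threshold, mol/cm^3 (default 5e-8).
#' @return list with `area_opt` (cm^2), `area_rel` (fraction), `poro_area`
#'   (cm^2).
#' @export
insulin_support_area <- function(conc, pf, c_opt = 5e-8) {
  cvec <- if (inherits(conc, "sf_concentration")) conc$c else conc
  p2 <- if (inherits(conc, "sf_concentration")) conc$space else
    fem_space(pf$mesh, "P2")
  p1 <- fem_space(pf$mesh, "P1")
  one_m <- 1 - weight_at_quad(p1, pf$phi)
  c_q <- field_at_quad(p2, cvec)
  # closed comparison c >= c_opt; the 1e-12 relative slack keeps fields
  # sitting exactly at the threshold from flickering with round-off
  chi <- (c_q >= c_opt * (1 - 1e-12)) * 1
  eg <- mesh_element_geometry(pf$mesh)
  qw <- quad_rule()$w
  poro_area <- sum(eg$area * as.vector(one_m %*% qw))
  if (poro_area <= 0) stop("empty poroelastic region: int (1 - phi) dV = 0")
  area_opt <- sum(eg$area * as.vector((chi * one_m) %*% qw))
  list(area_opt = area_opt, area_rel = area_opt / poro_area,
       poro_area = poro_area)
}

#' Extrema of a field magnitude over a phase-field mask
#'
#' @param field numeric vector (scalar nodal field) or n x 2 matrix
#'   (vector field); magnitudes are used.
#' @param pf an `sf_phasefield`.
#' @param mask `"channel"` (phi > 0.5), `"gel"` (phi <= 0.5) or `"all"`.
#' @return list with `min`, `max` and `argmax` (coordinates of the maximum).
#' @export
field_extrema <- function(field, pf, mask = c("all", "channel", "gel")) {
  mask <- match.arg(mask)
  mag <- if (is.matrix(field)) sqrt(rowSums(field^2)) else abs(field)
  stopifnot(length(mag) == nrow(pf$mesh$nodes))
  sel <- switch(mask, all = rep(TRUE, length(mag)),
                channel = pf$phi > 0.5, gel = pf$phi <= 0.5)
  if (!any(sel)) stop("field_extrema: empty mask '", mask, "'")
  idx <- which(sel)
  am <- idx[which.max(mag[idx])]
  list(min = min(mag[idx]), max = max(mag[idx]),
       argmax = pf$mesh$nodes[am, ])
}

#' Sample a nodal field along a line segment
#'
#' @param mesh an `sf_mesh`.
#' @param field nodal (P1) scalar values, or an n x 2 matrix (the magnitude
#'   is sampled).
#' @param p0,p1 segment endpoints, cm.
#' @param n_samples number of equally spaced samples.
#' @return data.frame with arc length `s`, coordinates, `value`, and
#'   `inside` (FALSE for samples outside the mesh, whose value is NA).
#' @export
line_profile <- function(mesh, field, p0, p1, n_samples = 200) {
  if (is.matrix(field)) field <- sqrt(rowSums(field^2))
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
  loc <- mesh_locate(mesh, pts)
  val <- rep(NA_real_, n_samples)
  ok <- !is.na(loc$elem)
  if (any(ok)) {
    tri <- mesh$tri[loc$elem[ok], , drop = FALSE]
    lb <- loc$bary[ok, , drop = FALSE]
    val[ok] <- rowSums(matrix(field[tri], ncol = 3) * lb)
  }
  data.frame(s = tt * sqrt(sum((p1 - p0)^2)), x = pts[, 1], y = pts[, 2],
             value = val, inside = ok)
}

#' Full metrics report for one architecture run
#'
#' @param geom the `sf_geometry`.
#' @param pf the `sf_phasefield`.
#' @param flow the steady `sf_flowstate`.
#' @param conc the `sf_concentration` at the transport final time.
#' @param c_opt insulin-production threshold, mol/cm^3.
#' @return a one-row data.frame in the Table-1 schema plus flow peaks:
#'   `geometry`, `total_area_cm2`, `relative_area_pct`, `poro_area_cm2`,
#'   `peak_channel_speed_cms`, `peak_darcy_speed_cms`.
#' @export
metrics_report <- function(geom, pf, flow, conc, c_opt = 5e-8) {
  isa <- insulin_support_area(conc, pf, c_opt)
  pk_ch <- field_extrema(flow$v, pf, "channel")$max
  # the Darcy field only has meaning in the poroelastic region
  pk_dq <- field_extrema(flow$q, pf, "gel")$max
  data.frame(geometry = geom$architecture,
             total_area_cm2 = isa$area_opt,
             relative_area_pct = 100 * isa$area_rel,
             poro_area_cm2 = isa$poro_area,
             peak_channel_speed_cms = pk_ch,
             peak_darcy_speed_cms = pk_dq)
}
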
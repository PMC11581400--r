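# Structured-config entry point and minimal Gmsh MSH (v2.2 ASCII) mesh
# import/export.

#' Build a run configuration from a YAML file
#'
#' The file may contain any of the keys `architecture`, `resolution`,
#' `c_opt`, `output_dir`, plus nested blocks `phase`, `flow`, `transport`,
#' `fluid_grid` and `geometry` whose entries override the corresponding
#' parameter constructors ([phasefield_params()], [flow_params()],
#' [transport_params()], [time_grid()], layout overrides).
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(ctor, block) {
    if (is.null(block)) return(NULL)
    do.call(ctor, block)
  }
  run_config(
    architecture = y$architecture %||% "straight",
    resolution = y$resolution %||% "coarse",
    phase = grab(phasefield_params, y$phase),
    flow = grab(flow_params, y$flow) %||% flow_params(),
    transport = grab(transport_params, y$transport),
    fluid_grid = grab(time_grid, y$fluid_grid) %||% time_grid(1e-3, 1),
    c_opt = y$c_opt %||% 5e-8,
    geometry_overrides = y$geometry %||% list(),
    output_dir = y$output_dir)
}

#' Write a mesh as Gmsh MSH 2.2 ASCII
#'
#' @param mesh an `sf_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  np <- nrow(mesh$nodes); nc <- nrow(mesh$tri)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$Nodes"); w(np)
  writeLines(sprintf("%d %.12g %.12g 0", seq_len(np),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  w("$EndNodes")
  w("$Elements"); w(nc)
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", seq_len(nc),
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII file (nodes and triangles)
#'
#' @param path file path.
#' @param tagger optional boundary tagger (see [mesh_create()]).
#' @return an `sf_mesh`.
#' @export
read_msh <- function(path, tagger = NULL) {
  ln <- readLines(path)
  i0 <- which(ln == "$Nodes"); i1 <- which(ln == "$EndNodes")
  np <- as.integer(ln[i0 + 1])
  nd <- read.table(text = ln[(i0 + 2):(i1 - 1)])
  nodes <- unname(as.matrix(nd[order(nd[, 1]), 2:3]))
  e0 <- which(ln == "$Elements"); e1 <- which(ln == "$EndElements")
  el <- strsplit(ln[(e0 + 2):(e1 - 1)], "\\s+")
  tri <- do.call(rbind, lapply(el, function(v) {
    v <- as.integer(v)
    if (v[2] != 2) return(NULL)          # keep 3-node triangles only
    ntags <- v[3]
    v[(4 + ntags):(6 + ntags)]
  }))
  stopifnot(np == nrow(nodes), !is.null(tri))
  mesh_create(nodes, tri, tagger = tagger)
}
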
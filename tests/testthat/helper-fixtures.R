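# Shared light-weight fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small unit-square mesh
unit_mesh <- function(h = 0.1) {
  key <- paste0("unit_", h)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- mesh_rect_union(list(c(0, 1, 0, 1)), h)
  fixture_env[[key]]
}

# coarse straight-architecture phase field (cheap: one adaptation cycle)
small_phasefield <- function(arch = "straight") {
  key <- paste0("pf_", arch)
  if (is.null(fixture_env[[key]])) {
    g <- make_architecture(arch)
    pp <- phasefield_params(n_adapt_cycles = 1L, bisect_per_cycle = 2L)
    fixture_env[[key]] <- build_adapted_phasefield(g, pp, h0 = 0.03)
  }
  fixture_env[[key]]
}
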
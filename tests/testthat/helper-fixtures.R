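# Shared coarse fixtures, built once per test session.

fixture_env <- new.env(parent = emptyenv())

coarse_mesh <- function(hedge = 1.0) {
  key <- paste0("mesh_", hedge)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_reference_mesh(shell_geometry(hedge = hedge))
  fixture_env[[key]]
}

# inflated free sphere at a moderate pressure (shared by several tests)
inflated_state <- function(dP = 300, hedge = 1.0) {
  key <- paste0("infl_", dP, "_", hedge)
  if (is.null(fixture_env[[key]])) {
    mesh <- coarse_mesh(hedge)
    fixture_env[[key]] <- inflate_shell(mesh, material_params(), dP,
                                        n_steps = 4, z_symmetry = TRUE)
  }
  fixture_env[[key]]
}

# random rotation-free deformation gradients with J > 0
random_def_grads <- function(n, spread = 0.2, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, sd = spread), 3, 3)
      if (det(F) > 0.3) return(F)
    }
  })
}

table_measures <- function() {
  list(area_inner = 107.5, area_outer = 118.4, vol_nuc = 152.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
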
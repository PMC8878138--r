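# Shared fixtures: coarse meshes and fast scenario settings used across tests.
# The axial-compression solution is exactly uniform in z, so single-layer
# meshes reproduce the radial physics at a fraction of the cost.

coarse_mesh <- function(size = 0.1, n_z = 1L)
  build_mesh(bone_geometry(), size, n_z = n_z)

fast_config <- function(name, ...) {
  scenario_config(name, dt = 0.25, coupling_interval = 2, mesh_size = 0.1,
                  n_z = 1L, snapshot_interval = 7, ...)
}

# closed-form energy of a uniform-density column under axial force (mJ)
uniform_column_energy <- function(density = 1, load = load_case(),
                                  material = material_params(),
                                  geometry = bone_geometry()) {
  A <- pi * geometry$outer_radius^2
  E <- material$E0 * 1000 * density^2
  load$force_N^2 * geometry$length / (2 * E * A)
}

table3 <- list(W0 = 3.1847e-4, W1 = 3.7e-4, W2 = 3.72e-4, W3 = 3.78e-4,
               k1 = 386.64e5, k2 = -375e5, A1 = 1992.36, A2 = -2232.38)
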
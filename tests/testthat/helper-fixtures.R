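# Shared fixtures: small, fast phantom geometries used across tests.
# Fields are shrunk relative to the reference 460 um acquisition so each
# simulated stack renders in well under a second; voxel sizes stay at the
# reference geometry (1.8 um pixels, 6.7 um slices).

small_stack_spec <- function(..., field_size = c(140, 140), n_slices = 8) {
  stack_sim_spec(field_size = field_size, n_slices = n_slices, ...)
}

# One cluster plus isolated reference cells, defaults noiseless.
phantom_spec <- function(cluster_cells, n_singles = 6, intensity_cv = 0,
                         background_level = 0, seed = 1, ...) {
  small_stack_spec(
    cluster_specs = if (cluster_cells > 0) list(list(cell_count = cluster_cells))
    else list(),
    n_single_cells = n_singles,
    intensity_cv = intensity_cv,
    background_level = background_level,
    rng_seed = seed, ...)
}

# Largest segmented component (the cluster, in single-cluster phantoms).
largest_object <- function(seg) which.max(seg$sizes)
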